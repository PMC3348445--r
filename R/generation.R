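## Overlay generation: triplet counting, alignment fingerprints, greedy
## fingerprint searching, constraints and the stepwise supermolecule device.
##
## A triplet is three fitting points from one conformation, typed by the
## multiset of feature kinds and the distance bins of its three sides. For
## each highly ranked triplet type occurring in every ligand, all
## conformations containing such a "base triplet" are aligned on a canonical
## frame and their remaining fitting points hashed onto a 1.5 A grid as bit
## strings. Combinations of rows (one per ligand) with high concordance
## (B = wA - O over the ANDed and ORed strings) correspond to candidate
## overlays; each becomes a chromosome whose mapping table is the base
## triplet.

## Kind precedence for canonicalisation: acceptors get lower numbers than
## donors, donors lower than hydrophobes.
TRIPLET_KIND_ORDER <- c("acceptor", "donor", "hydrophobe", "custom",
                        "constraint")

## Roles eligible as triplet/fingerprint points. Hydrophobe normal points
## are excluded by default (config use_normals adds them).
triplet_point_selector <- function(meta, use_normals = FALSE) {
  roles <- c("atom_site", "hydrophobe_centroid", "custom_centroid")
  if (use_normals) roles <- c(roles, "hydrophobe_normal_plus",
                              "hydrophobe_normal_minus")
  meta$role %in% roles
}

## Collapse feature kinds to fingerprint kinds (both hydrophobe classes are
## one "hydrophobe" type for triplets and fingerprint segments).
fingerprint_kind <- function(kind) {
  ifelse(kind %in% c("hydrophobe_dir", "hydrophobe_nondir"), "hydrophobe",
         kind)
}

#' Assign distances to bins
#'
#' @param d distances, Angstrom.
#' @param bins ordered bin edges; distance in [edge_k, edge_k+1) gets bin k,
#'   outside any bin NA (such triplets are discarded).
#' @export
distance_bin <- function(d, bins) {
  k <- findInterval(d, bins, rightmost.closed = TRUE)
  k[k == 0L | k >= length(bins)] <- NA_integer_
  k
}

## Valid canonical orderings of one triplet. `kinds` are fingerprint kinds,
## `binm` a 3 x 3 matrix of pairwise distance bins. Returns a list of
## orderings (permutations of 1:3) and the canonical type code.
triplet_orderings <- function(kinds, binm) {
  prec <- match(kinds, TRIPLET_KIND_ORDER)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
                c(3L, 1L, 2L), c(3L, 2L, 1L))
  valid <- list(); codes <- character(0)
  for (p in perms) {
    k <- prec[p]
    if (k[1] > k[2] || k[2] > k[3]) next
    b12 <- binm[p[1], p[2]]; b13 <- binm[p[1], p[3]]; b23 <- binm[p[2], p[3]]
    if (k[1] == k[2] && k[2] == k[3]) {
      if (!(b23 <= b13 && b13 <= b12)) next
    } else if (k[1] == k[2]) {
      if (!(b23 <= b13)) next
    } else if (k[2] == k[3]) {
      if (!(b13 <= b12)) next
    }
    valid[[length(valid) + 1L]] <- p
    codes <- c(codes, paste(k[1], k[2], k[3], b12, b13, b23, sep = "-"))
  }
  if (!length(valid)) return(NULL)
  ord <- order(codes)
  list(orderings = valid[ord], code = codes[ord[1]])
}

## All typed triplets of one conformation's eligible fitting points.
## Returns a list of instances: point rows (indices into the ligand's full
## fitting-point list), code, orderings.
conformer_triplets <- function(fp, use_normals = FALSE, bins,
                               collinear_height = 0.1,
                               constraint_only = FALSE) {
  sel <- which(triplet_point_selector(fp$meta, use_normals))
  if (length(sel) < 3L) return(list())
  xyz <- fp$xyz[sel, , drop = FALSE]
  kinds <- fingerprint_kind(fp$meta$kind[sel])
  out <- list()
  combs <- utils::combn(length(sel), 3L)
  for (cc in seq_len(ncol(combs))) {
    tri <- combs[, cc]
    if (constraint_only && !any(kinds[tri] == "constraint")) next
    p <- xyz[tri, , drop = FALSE]
    d <- c(sqrt(sum((p[1, ] - p[2, ])^2)), sqrt(sum((p[1, ] - p[3, ])^2)),
           sqrt(sum((p[2, ] - p[3, ])^2)))
    b <- distance_bin(d, bins)
    if (anyNA(b)) next
    if (triangle_height(p) < collinear_height) next
    binm <- matrix(0L, 3, 3)
    binm[1, 2] <- binm[2, 1] <- b[1]
    binm[1, 3] <- binm[3, 1] <- b[2]
    binm[2, 3] <- binm[3, 2] <- b[3]
    to <- triplet_orderings(kinds[tri], binm)
    if (is.null(to)) next
    out[[length(out) + 1L]] <- list(points = sel[tri], code = to$code,
                                    orderings = to$orderings)
  }
  out
}

## Smallest height of the triangle (collinearity measure).
triangle_height <- function(p) {
  a <- sqrt(sum((p[2, ] - p[3, ])^2))
  b <- sqrt(sum((p[1, ] - p[3, ])^2))
  cc <- sqrt(sum((p[1, ] - p[2, ])^2))
  s <- (a + b + cc) / 2
  area2 <- max(s * (s - a) * (s - b) * (s - cc), 0)
  2 * sqrt(area2) / max(a, b, cc)
}

#' Canonical frame of an ordered triplet
#'
#' Returns the rigid transform placing the triplet centroid at the origin,
#' point 1 on the +x axis and point 2 in the xy plane with y >= 0.
#'
#' @param p 3 x 3 matrix, rows are the ordered triplet points.
#' @export
canonical_frame <- function(p) {
  cen <- colMeans(p)
  p1 <- p[1, ] - cen; p2 <- p[2, ] - cen
  e1 <- unit(p1)
  w <- p2 - sum(p2 * e1) * e1
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) stop("canonical_frame: collinear triplet")
  e2 <- w / nw
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- rbind(e1, e2, e3)
  dimnames(R) <- NULL
  structure(list(R = R, t = as.vector(-R %*% cen), rmsd = NA_real_,
                 underdetermined = FALSE), class = "rigid_transform")
}

#' Enumerate and rank triplet types
#'
#' Types all fitting-point triplets of every conformation, then ranks types
#' by L (number of ligands containing the type in at least one conformation,
#' descending) with ties broken by P-bar (mean over ligands of the
#' proportion of conformations containing the type, descending).
#'
#' @param system from [build_system()].
#' @param bins distance-bin edges.
#' @param constraint_only keep only triplets containing a constraint point.
#' @return Data frame with `code`, `L`, `P_bar` and `rank`, ordered by rank;
#'   the number of types occurring in all ligands is attached as attribute
#'   `"M"`.
#' @export
enumerate_and_rank_triplet_types <- function(system, bins,
                                             constraint_only = FALSE) {
  cfg <- system$config
  nlig <- system$nlig
  prop <- list()  # code -> per-ligand proportion of conformations
  for (li in seq_len(nlig)) {
    confs <- system$fp[[li]]
    ncf <- length(confs)
    seen <- list()  # code -> conformer count
    for (k in seq_len(ncf)) {
      tris <- conformer_triplets(confs[[k]], cfg$use_normals, bins,
                                 constraint_only = constraint_only)
      for (code in unique(vapply(tris, `[[`, "", "code")))
        seen[[code]] <- c(seen[[code]], k)
    }
    for (code in names(seen)) {
      v <- prop[[code]] %||% numeric(nlig)
      v[li] <- length(unique(seen[[code]])) / ncf
      prop[[code]] <- v
    }
  }
  if (!length(prop))
    return(structure(data.frame(code = character(0), L = integer(0),
                                P_bar = numeric(0), rank = integer(0)),
                     M = 0L))
  codes <- names(prop)
  L <- vapply(prop, function(v) sum(v > 0), integer(1))
  P_bar <- vapply(prop, mean, numeric(1))
  ord <- order(-L, -P_bar, codes)
  df <- data.frame(code = codes[ord], L = unname(L[ord]),
                   P_bar = unname(P_bar[ord]), rank = seq_along(ord))
  structure(df, M = sum(df$L == nlig))
}

#' Build an alignment fingerprint for a base triplet type
#'
#' Every conformation containing a base triplet contributes one row per
#' (base-triplet instance x valid canonical ordering): the conformation's
#' other fitting points are expressed in the canonical frame and hashed onto
#' a grid, setting the bit of the nearest grid point (plus its six axial
#' neighbours when smearing) in the segment of their feature kind.
#'
#' @param system from [build_system()].
#' @param type_code a `code` from [enumerate_and_rank_triplet_types()].
#' @param bins the bin edges used to type the triplets.
#' @param constraint_only as in the enumeration step.
#' @return An `alignment_fingerprint`: logical row matrix `bits`, row
#'   provenance (`ligand`, `conf`, `base_points`), the column map and grid.
#' @export
build_fingerprint <- function(system, type_code, bins,
                              constraint_only = FALSE) {
  cfg <- system$config
  h <- cfg$grid_spacing
  rows <- list()
  for (li in seq_len(system$nlig)) {
    for (k in seq_along(system$fp[[li]])) {
      fpk <- system$fp[[li]][[k]]
      tris <- conformer_triplets(fpk, cfg$use_normals, bins,
                                 constraint_only = constraint_only)
      for (tr in tris) {
        if (tr$code != type_code) next
        for (ordg in tr$orderings) {
          base <- tr$points[ordg]
          tf <- canonical_frame(fpk$xyz[base, , drop = FALSE])
          sel <- setdiff(which(triplet_point_selector(fpk$meta,
                                                      cfg$use_normals)),
                         tr$points)
          pts <- if (length(sel))
            apply_transform(fpk$xyz[sel, , drop = FALSE], tf)
          else matrix(numeric(0), 0, 3)
          rows[[length(rows) + 1L]] <- list(
            ligand = li, conf = k, base_points = base,
            xyz = pts, kinds = fingerprint_kind(fpk$meta$kind[sel]))
        }
      }
    }
  }
  if (!length(rows)) stop("no conformation contains base triplet ", type_code)
  allpts <- do.call(rbind, lapply(rows, `[[`, "xyz"))
  kinds_used <- sort(unique(unlist(lapply(rows, `[[`, "kinds"))))
  if (!nrow(allpts) || !length(kinds_used)) {
    # degenerate: no non-base points anywhere; single empty-bit column
    bits <- matrix(FALSE, length(rows), 1L)
    return(structure(list(bits = bits, rows = rows, colmap = NULL,
                          type_code = type_code, grid = NULL),
                     class = "alignment_fingerprint"))
  }
  origin <- floor(apply(allpts, 2, min) / h) * h - h
  dims <- ceiling((apply(allpts, 2, max) - origin) / h) + 3L
  G <- prod(dims)
  nk <- length(kinds_used)
  bit_index <- function(xyz, kinds, smear) {
    ijk <- round(sweep(xyz, 2, origin) / h) + 1L
    ijk <- pmin(pmax(ijk, 2L), matrix(dims - 1L, nrow(ijk), 3, byrow = TRUE))
    ks <- match(kinds, kinds_used)
    idx <- integer(0)
    for (r in seq_len(nrow(ijk))) {
      cells <- rbind(ijk[r, ])
      if (smear)
        cells <- rbind(cells,
                       cells + c(1, 0, 0), cells - c(1, 0, 0),
                       cells + c(0, 1, 0), cells - c(0, 1, 0),
                       cells + c(0, 0, 1), cells - c(0, 0, 1))
      flat <- (cells[, 1] - 1L) + dims[1] * (cells[, 2] - 1L) +
        dims[1] * dims[2] * (cells[, 3] - 1L)
      idx <- c(idx, (ks[r] - 1L) * G + flat + 1L)
    }
    unique(idx)
  }
  bits <- matrix(FALSE, length(rows), nk * G)
  for (r in seq_along(rows)) {
    if (!nrow(rows[[r]]$xyz)) next
    bits[r, bit_index(rows[[r]]$xyz, rows[[r]]$kinds, cfg$smear)] <- TRUE
  }
  keep <- which(colSums(bits) > 0L)
  colmap <- data.frame(column = seq_along(keep),
                       kind = kinds_used[(keep - 1L) %/% G + 1L],
                       cell = (keep - 1L) %% G + 1L)
  bits <- bits[, keep, drop = FALSE]
  structure(list(bits = bits, rows = rows, colmap = colmap,
                 type_code = type_code,
                 grid = list(origin = origin, spacing = h, dims = dims)),
            class = "alignment_fingerprint")
}

#' @export
print.alignment_fingerprint <- function(x, ...) {
  cat(sprintf("<alignment fingerprint '%s': %d rows x %d columns>\n",
              x$type_code, nrow(x$bits), ncol(x$bits)))
  invisible(x)
}

#' Greedy fingerprint search
#'
#' Produces up to P row combinations (one row per ligand), each scored by
#' B = wA - O where A and O count the on-bits of the ANDed and ORed rows.
#' Each run starts from a distinct row (runs are biased towards rows with
#' many on-bits in highly occupied columns), visits the remaining ligands in
#' random order and greedily picks the row maximising B (ties at random).
#' When P exceeds the row count, rows are reused with fresh ligand orders.
#'
#' @param fingerprint from [build_fingerprint()].
#' @param P number of solutions (default from config; 200).
#' @param w AND weight (default 2): the premium on full pharmacophore
#'   points.
#' @param system the ligand system (chromosomes need conformer indices).
#' @return List of `list(chromosome, B)`.
#' @export
greedy_search <- function(fingerprint, system,
                          P = system$config$p_per_fingerprint,
                          w = system$config$w) {
  bits <- fingerprint$bits
  rows <- fingerprint$rows
  row_lig <- vapply(rows, `[[`, integer(1), "ligand")
  nlig <- system$nlig
  if (length(unique(row_lig)) < nlig)
    stop("fingerprint lacks rows for some ligand; cannot search")
  occup <- colSums(bits)
  row_score <- as.vector(bits %*% occup)
  start_order <- order(-row_score, seq_along(rows))
  starts <- start_order[((seq_len(P) - 1L) %% length(rows)) + 1L]
  lig_rows <- lapply(seq_len(nlig), function(li) which(row_lig == li))
  out <- vector("list", P)
  for (run in seq_len(P)) {
    r0 <- starts[run]
    andv <- bits[r0, ]; orv <- bits[r0, ]
    chosen <- integer(nlig)
    chosen[row_lig[r0]] <- r0
    for (li in sample(setdiff(seq_len(nlig), row_lig[r0]))) {
      cand <- lig_rows[[li]]
      B <- as.vector(w * (bits[cand, , drop = FALSE] %*% andv) -
                     ((bits[cand, , drop = FALSE] + rep(orv, each = length(cand))) > 0) %*%
                       rep(1, ncol(bits)))
      best <- cand[B == max(B)]
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      chosen[li] <- pick
      andv <- andv & bits[pick, ]
      orv <- orv | bits[pick, ]
    }
    Bfinal <- w * sum(andv) - sum(orv)
    mapping <- t(vapply(chosen, function(r) rows[[r]]$base_points,
                        integer(3)))
    ch <- new_chromosome(
      conformers = vapply(chosen, function(r) rows[[r]]$conf, integer(1)),
      mapping = mapping)
    out[[run]] <- list(chromosome = ch, B = Bfinal)
  }
  out
}

#' Generate the overlay pool
#'
#' Runs the full triplet-counting / fingerprint / greedy-search procedure
#' for each of the two distance-bin schemes, pooling and deduplicating all
#' solutions. With `constraint = TRUE` only triplets containing a
#' constraint-feature point are used, so every solution superimposes the
#' constraint points.
#'
#' @param system from [build_system()].
#' @param constraint restrict triplets to those containing a constraint
#'   point (requires constraint features on every ligand).
#' @return List of `list(chromosome, B)` with generation statistics in
#'   attribute `"stats"`. Errors with advice to go stepwise when no triplet
#'   type is shared by all ligands under either bin scheme.
#' @export
generate_overlays <- function(system, constraint = FALSE) {
  cfg <- system$config
  if (constraint) {
    has_con <- vapply(system$features, function(fl)
      any(vapply(fl, `[[`, "", "kind") == "constraint"), logical(1))
    if (!all(has_con))
      stop("constrained generation requires a constraint feature on every ",
           "ligand (missing: ",
           paste(system$ids[!has_con], collapse = ", "), ")")
  }
  pool <- list()
  stats <- list()
  nfp_total <- 0L
  for (scheme in c("bins_a", "bins_b")) {
    bins <- cfg[[scheme]]
    ranked <- enumerate_and_rank_triplet_types(system, bins,
                                               constraint_only = constraint)
    M <- attr(ranked, "M")
    N <- min(M, cfg$n_max)
    stats[[scheme]] <- list(types = nrow(ranked), M = M, N = N)
    if (N == 0L) next
    for (r in seq_len(N)) {
      fp <- build_fingerprint(system, ranked$code[r], bins,
                              constraint_only = constraint)
      if (length(unique(vapply(fp$rows, `[[`, integer(1), "ligand"))) <
          system$nlig) next
      sols <- greedy_search(fp, system)
      pool <- c(pool, sols)
      nfp_total <- nfp_total + 1L
    }
  }
  if (nfp_total == 0L)
    stop("no common base triplet occurs in all ligands under either ",
         "distance-bin scheme; consider the stepwise approach ",
         "(merge_to_supermolecule)")
  keys <- vapply(pool, function(s) chromosome_key(s$chromosome), character(1))
  pool <- pool[!duplicated(keys)]
  stats$fingerprints <- nfp_total
  stats$pool_size <- length(pool)
  structure(pool, stats = stats)
}

#' @rdname generate_overlays
#' @export
constrained_generation <- function(system) generate_overlays(system,
                                                             constraint = TRUE)

#' Merge overlays of a ligand subset into a supermolecule
#'
#' Each overlay becomes one "conformation" of a pseudo-ligand whose fitting
#' points are the leader-cluster centroids (same kind, at most one point per
#' ligand, points farther apart than `merge_dist` never merged) of the
#' member ligands' fitting points. Provenance is retained so final overlays
#' can be unfolded back to individual ligands.
#'
#' @param overlays list of `overlay` objects over the same ligand subset.
#' @param merge_dist clustering radius, Angstrom (default 1.5).
#' @param id name of the pseudo-ligand.
#' @return A `supermolecule`: `fp` (one fitting-point set per overlay),
#'   `overlays` (provenance) and `id`.
#' @export
merge_to_supermolecule <- function(overlays, merge_dist = 1.5,
                                   id = "supermolecule") {
  if (inherits(overlays, "overlay")) overlays <- list(overlays)
  fps <- lapply(overlays, function(ov) {
    pts <- overlay_points(ov, roles = c("atom_site", "hydrophobe_centroid",
                                        "custom_centroid"))
    merged_xyz <- list(); merged_meta <- list()
    for (kind in unique(pts$meta$kind)) {
      sel <- which(pts$meta$kind == kind)
      cls <- leader_cluster(pts$xyz[sel, , drop = FALSE],
                            pts$meta$ligand[sel], merge_dist)
      for (cl in cls) {
        merged_xyz[[length(merged_xyz) + 1L]] <- cl$centroid
        merged_meta[[length(merged_meta) + 1L]] <- data.frame(
          kind = kind, role = pts$meta$role[sel[cl$members[1]]],
          feature = NA_integer_, atom = NA_integer_,
          strength = pts$meta$strength[sel[cl$members[1]]],
          n_merged = length(cl$members), stringsAsFactors = FALSE)
      }
    }
    list(xyz = do.call(rbind, merged_xyz), meta = do.call(rbind, merged_meta))
  })
  structure(list(id = id, fp = fps, overlays = overlays),
            class = "supermolecule")
}

#' @export
print.supermolecule <- function(x, ...) {
  cat(sprintf("<supermolecule '%s': %d conformations, %s fitting points>\n",
              x$id, length(x$fp),
              paste(range(vapply(x$fp, function(f) nrow(f$meta), integer(1))),
                    collapse = "-")))
  invisible(x)
}
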