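## Objective functions: union volume (V), hydrogen-bond (HB), hydrophobic
## (HY), strain energy (E) and customised-feature (CF) scores, their simple
## variants, and the leader cluster analysis they all share.

#' Leader cluster analysis
#'
#' Greedy clustering used throughout: each point gets a nearest-neighbour
#' list (NNL) containing itself plus, for each other ligand, the nearest
#' point of that ligand within `max_dist`. The longest NNL becomes the first
#' cluster (ties go to the NNL with the smaller mean square distance between
#' its members); its members are removed from the remaining NNLs, and the
#' process repeats until every point is clustered. Singletons are allowed;
#' a cluster never holds two points of the same ligand.
#'
#' @param xyz m x 3 matrix of points.
#' @param by_ligand length-m vector tagging each point with its ligand (or,
#'   for virtual points, its parent atom).
#' @param max_dist clustering radius, Angstrom (default 1.5).
#' @return List of clusters: `members` (row indices into `xyz`), `centroid`,
#'   `spread` (mean square distance of members from the centroid, A^2).
#' @export
leader_cluster <- function(xyz, by_ligand, max_dist = 1.5) {
  m <- nrow(xyz)
  if (m == 0L) return(list())
  if (length(by_ligand) != m) stop("leader_cluster: tag length mismatch")
  d2 <- as.matrix(stats::dist(xyz))^2
  lim2 <- max_dist^2
  tags <- as.character(by_ligand)
  nnl <- lapply(seq_len(m), function(i) {
    members <- i
    for (tg in setdiff(unique(tags), tags[i])) {
      js <- which(tags == tg)
      j <- js[which.min(d2[i, js])]
      if (d2[i, j] <= lim2 + 1e-12) members <- c(members, j)
    }
    members
  })
  alive <- rep(TRUE, m)
  clusters <- list()
  while (any(alive)) {
    lens <- vapply(seq_len(m), function(i)
      if (alive[i]) length(nnl[[i]]) else -1L, integer(1))
    best <- which(lens == max(lens))
    if (length(best) > 1L) {
      msd <- vapply(best, function(i) {
        mem <- nnl[[i]]
        if (length(mem) < 2) return(0)
        mean(d2[mem, mem][upper.tri(d2[mem, mem])])
      }, numeric(1))
      best <- best[which.min(msd)]
    } else best <- best[1]
    mem <- nnl[[best]]
    cen <- colMeans(xyz[mem, , drop = FALSE])
    clusters[[length(clusters) + 1L]] <- list(
      members = mem, centroid = cen,
      spread = mean(rowSums(sweep(xyz[mem, , drop = FALSE], 2, cen)^2)))
    alive[mem] <- FALSE
    for (i in which(alive)) nnl[[i]] <- setdiff(nnl[[i]], mem)
  }
  clusters
}

## Linear ramp helper: value y0 at/below x0, y1 at/beyond x1.
ramp <- function(x, x0, x1, y0, y1) {
  t <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  y0 + t * (y1 - y0)
}

f_hb <- function(a) ramp(a, 0.15, 0.75, 1.0, 0.3)
g_hb <- function(v) ramp(v, 0.5, 1.5, 1.0, 0.3)
f_hy <- function(n) ramp(n, 0.0, 1.25, 1.0, 0.0)
g_hy <- function(c) ramp(c, 1.0, 0.8, 2.0, 0.0)

VOLUME_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, P = 1.80)

element_radius <- function(el) {
  r <- VOLUME_RADII[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Union-volume score
#'
#' Places a grid over the overlay and counts the points inside at least one
#' van der Waals sphere; V is the count times the grid-cell volume. Smaller
#' is better (ligands must share a cavity of limited size). The default
#' 0.5 A grid keeps the error within about half a percent.
#'
#' @param overlay an `overlay`.
#' @param grid spacing in Angstrom (default from the system config, 0.5).
#' @return Volume in cubic Angstrom.
#' @export
volume_score <- function(overlay, grid = NULL) {
  if (is.null(grid)) grid <- overlay$system$config$volume_grid
  coords <- do.call(rbind, lapply(overlay$states, `[[`, "coords"))
  radii <- unlist(lapply(overlay$system$ligands, function(l)
    element_radius(l$elements)))
  grid_union_volume(coords, radii, grid)
}

## Grid-cell counting with antialiased boundaries: cells wholly inside a
## sphere count 1, cells crossing a surface are sub-sampled (3^3 points)
## against the whole union, so the count is accurate to a fraction of a
## percent even for single atoms at the default 0.5 A grid. The lattice is
## anchored at absolute cell centres, so the result is independent of the
## overlay's bounding box.
grid_union_volume <- function(coords, radii, grid) {
  rmax <- max(radii)
  lo <- apply(coords, 2, min) - rmax - grid
  hi <- apply(coords, 2, max) + rmax + grid
  ax <- lapply(1:3, function(k)
    seq(floor(lo[k] / grid) * grid + grid / 2, hi[k], by = grid))
  dims <- vapply(ax, length, integer(1))
  occ <- array(0, dims)                    # 1 = full, fractions on the rim
  margin <- grid * sqrt(3) / 2             # cell circumradius
  boundary <- list()
  for (a in seq_len(nrow(coords))) {
    p <- coords[a, ]; r <- radii[a]
    idx <- lapply(1:3, function(k)
      which(ax[[k]] >= p[k] - r - margin & ax[[k]] <= p[k] + r + margin))
    if (any(vapply(idx, length, integer(1)) == 0L)) next
    dx2 <- (ax[[1]][idx[[1]]] - p[1])^2
    dy2 <- (ax[[2]][idx[[2]]] - p[2])^2
    dz2 <- (ax[[3]][idx[[3]]] - p[3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    full <- d <= r - margin
    rim <- d < r + margin & !full
    sub <- occ[idx[[1]], idx[[2]], idx[[3]]]
    sub[full] <- 1
    occ[idx[[1]], idx[[2]], idx[[3]]] <- sub
    if (any(rim)) {
      w <- which(rim, arr.ind = TRUE)
      boundary[[length(boundary) + 1L]] <-
        cbind(idx[[1]][w[, 1]], idx[[2]][w[, 2]], idx[[3]][w[, 3]])
    }
  }
  if (length(boundary)) {
    bc <- unique(do.call(rbind, boundary))
    flat <- bc[, 1] + dims[1] * (bc[, 2] - 1L) +
      dims[1] * dims[2] * (bc[, 3] - 1L)
    todo <- occ[flat] < 1
    if (any(todo)) {
      bc <- bc[todo, , drop = FALSE]
      centres <- cbind(ax[[1]][bc[, 1]], ax[[2]][bc[, 2]], ax[[3]][bc[, 3]])
      offs <- as.matrix(expand.grid(o1 = (-1:1) / 3, o2 = (-1:1) / 3,
                                    o3 = (-1:1) / 3)) * grid
      frac <- numeric(nrow(centres))
      for (s in seq_len(nrow(offs))) {
        pt <- sweep(centres, 2, offs[s, ], "+")
        inside <- rep(FALSE, nrow(pt))
        for (a in seq_len(nrow(coords)))
          inside <- inside |
            (rowSums(sweep(pt, 2, coords[a, ])^2) <= radii[a]^2)
        frac <- frac + inside
      }
      occ[flat[todo]] <- frac / nrow(offs)
    }
  }
  sum(occ) * grid^3
}

## Effective cluster size m from member strengths: equal strengths keep
## m = n; each atom off the modal strength costs 0.5, and each strong/weak
## pair another 0.5 (mixing adjacent strengths is tolerated more than
## strong-with-weak). Floored at 1.
effective_m <- function(strengths) {
  n <- length(strengths)
  tab <- table(factor(strengths, levels = c("strong", "medium", "weak")))
  modal <- max(tab)
  off <- n - modal
  sw_pairs <- as.integer(tab["strong"]) * as.integer(tab["weak"])
  max(1, n - 0.5 * off - 0.5 * sw_pairs)
}

## Hydrophobic envelope atoms (used for occlusion): member atoms of
## hydrophobe features, with overlay-frame coordinates and scaled radii.
hydrophobe_envelope <- function(overlay) {
  xs <- list(); rs <- list()
  for (li in seq_along(overlay$states)) {
    feats <- overlay$system$features[[li]]
    atoms <- unique(unlist(lapply(feats, function(f)
      if (f$kind %in% c("hydrophobe_dir", "hydrophobe_nondir")) f$atoms)))
    if (!length(atoms)) next
    xs[[length(xs) + 1L]] <- overlay$states[[li]]$coords[atoms, , drop = FALSE]
    rs[[length(rs) + 1L]] <-
      0.85 * element_radius(overlay$system$ligands[[li]]$elements[atoms])
  }
  list(xyz = if (length(xs)) do.call(rbind, xs) else matrix(numeric(0), 0, 3),
       r = unlist(rs))
}

## Occlusion factor: sample the segment between the atom-cluster centroid
## and the virtual-cluster centroid every 0.5 A (strictly between); a sample
## inside the hydrophobic envelope is occluded. X = 1 - 0.9 * fraction,
## clamped to [0.1, 1].
occlusion_factor <- function(c_atoms, c_virtual, envelope) {
  L <- sqrt(sum((c_virtual - c_atoms)^2))
  if (L <= 0.5 || nrow(envelope$xyz) == 0L) return(1)
  ts <- seq(0.5, L - 1e-9, by = 0.5)
  if (!length(ts)) return(1)
  dirv <- (c_virtual - c_atoms) / L
  samples <- outer(ts, dirv) + rep(c_atoms, each = length(ts))
  occluded <- vapply(seq_len(nrow(samples)), function(s) {
    d2 <- rowSums(sweep(envelope$xyz, 2, samples[s, ])^2)
    any(d2 <= envelope$r^2)
  }, logical(1))
  max(0.1, min(1, 1 - 0.9 * mean(occluded)))
}

#' Hydrogen-bond score
#'
#' Donor and acceptor fitting points are leader-clustered separately. Each
#' cluster p contributes S_p X_p [A_p^2 f(a_p) + V_p^2 g(v_p)]: A_p member
#' atoms with spread a_p, V_p virtual points in the best consensus-direction
#' cluster with spread v_p, similarity S = (m/n)^2 from member strengths,
#' and occlusion X in [0.1, 1] from the line of sight to the virtual-point
#' centroid. f falls 1.0 to 0.3 over a_p in [0.15, 0.75] A^2, g over v_p in
#' [0.5, 1.5] A^2. Atoms contributing to both a donor and an acceptor
#' cluster (hydroxyls) count only their better-scoring cluster.
#'
#' @param overlay an `overlay`.
#' @return List with `HB` and a `clusters` breakdown.
#' @export
hbond_score <- function(overlay) {
  cfg <- overlay$system$config
  envelope <- hydrophobe_envelope(overlay)
  all_clusters <- list()
  for (kind in c("donor", "acceptor")) {
    pts <- overlay_points(overlay, roles = "atom_site", kinds = kind)
    if (!nrow(pts$xyz)) next
    cls <- leader_cluster(pts$xyz, pts$meta$ligand, cfg$cluster_dist)
    for (cl in cls) {
      mem <- cl$members
      n <- length(mem)
      strengths <- pts$meta$strength[mem]
      S <- (effective_m(strengths) / n)^2
      # virtual points, tagged by parent member
      vxyz <- list(); vtag <- list()
      for (k in seq_along(mem)) {
        i <- mem[k]
        li <- pts$meta$ligand[i]
        feat <- overlay$system$features[[li]][[pts$meta$feature[i]]]
        vp <- try(virtual_points(feat, overlay$system$ligands[[li]],
                                 overlay$states[[li]]$coords,
                                 hb_distance = cfg$hb_distance,
                                 n_points = cfg$vp_n_points,
                                 arc_points = cfg$vp_arc_points,
                                 cone_half_angle = cfg$vp_cone_half_angle),
                  silent = TRUE)
        if (inherits(vp, "try-error") || !nrow(vp)) next
        vxyz[[length(vxyz) + 1L]] <- vp
        vtag[[length(vtag) + 1L]] <- rep(k, nrow(vp))
      }
      Vp <- 0L; vp_spread <- 0; Xf <- 1; vcen <- NULL
      if (length(vxyz)) {
        vm <- do.call(rbind, vxyz)
        vt <- unlist(vtag)
        vcl <- leader_cluster(vm, vt, cfg$cluster_dist)
        sizes <- vapply(vcl, function(c) length(c$members), integer(1))
        cand <- which(sizes == max(sizes))
        # tie: score each candidate in turn, keep the best value
        best_term <- -Inf
        for (ci in cand) {
          v_n <- sizes[ci]; v_s <- vcl[[ci]]$spread
          xf <- occlusion_factor(cl$centroid, vcl[[ci]]$centroid, envelope)
          term <- S * xf * (n^2 * f_hb(cl$spread) + v_n^2 * g_hb(v_s))
          if (term > best_term) {
            best_term <- term; Vp <- v_n; vp_spread <- v_s; Xf <- xf
            vcen <- vcl[[ci]]$centroid
          }
        }
      }
      contrib <- S * Xf * (n^2 * f_hb(cl$spread) + Vp^2 * g_hb(vp_spread))
      all_clusters[[length(all_clusters) + 1L]] <- list(
        kind = kind, members = mem,
        ligands = pts$meta$ligand[mem], atoms = pts$meta$atom[mem],
        A = n, spread = cl$spread, S = S, X = Xf,
        V_p = Vp, v_spread = vp_spread, contribution = contrib)
    }
  }
  # hydroxyl rule: an atom in both a donor and an acceptor cluster counts
  # only in the better-scoring cluster
  drop <- rep(FALSE, length(all_clusters))
  if (length(all_clusters) > 1) {
    keys <- lapply(all_clusters, function(cl) paste(cl$ligands, cl$atoms))
    for (i in seq_along(all_clusters)) for (j in seq_along(all_clusters)) {
      if (i >= j) next
      if (all_clusters[[i]]$kind == all_clusters[[j]]$kind) next
      if (!length(intersect(keys[[i]], keys[[j]]))) next
      if (all_clusters[[i]]$contribution >= all_clusters[[j]]$contribution)
        drop[j] <- TRUE else drop[i] <- TRUE
    }
  }
  for (i in which(drop)) all_clusters[[i]]$contribution <- 0
  HB <- sum(vapply(all_clusters, `[[`, numeric(1), "contribution"))
  list(HB = HB, clusters = all_clusters)
}

#' Hydrophobic score
#'
#' Directional-hydrophobe centroids are leader-clustered; each cluster
#' contributes N_p^2 [f(n_p) + g(c_p)] where n_p is the centroid spread and
#' c_p the average unsigned cosine of pairwise inter-planar angles. f falls
#' 1.0 to 0.0 over [0, 1.25] A^2; g falls 2.0 to 0.0 as c_p drops from 1.0
#' to 0.8, so coplanarity carries more weight than coincidence. Singleton
#' clusters take c_p = 1.
#'
#' @param overlay an `overlay`.
#' @return List with `HY` and a `clusters` breakdown.
#' @export
hydrophobic_score <- function(overlay) {
  cfg <- overlay$system$config
  pts <- overlay_points(overlay, roles = "hydrophobe_centroid",
                        kinds = "hydrophobe_dir")
  if (!nrow(pts$xyz)) return(list(HY = 0, clusters = list()))
  normals <- t(vapply(seq_len(nrow(pts$xyz)), function(i) {
    li <- pts$meta$ligand[i]
    f <- overlay$system$features[[li]][[pts$meta$feature[i]]]
    plane_normal(overlay$states[[li]]$coords[f$atoms, , drop = FALSE])
  }, numeric(3)))
  cls <- leader_cluster(pts$xyz, pts$meta$ligand, cfg$cluster_dist)
  out <- list()
  for (cl in cls) {
    mem <- cl$members; N <- length(mem)
    cp <- 1
    if (N > 1) {
      nm <- normals[mem, , drop = FALSE]
      cos_abs <- abs(nm %*% t(nm))
      cp <- mean(cos_abs[upper.tri(cos_abs)])
    }
    contrib <- N^2 * (f_hy(cl$spread) + g_hy(cp))
    out[[length(out) + 1L]] <- list(members = mem,
                                    ligands = pts$meta$ligand[mem],
                                    N = N, spread = cl$spread, c_p = cp,
                                    contribution = contrib)
  }
  list(HY = sum(vapply(out, `[[`, numeric(1), "contribution")), clusters = out)
}

#' Customised-feature score
#'
#' Custom-feature centroids are leader-clustered per feature name; each
#' cluster contributes N_p^2 f(n_p) with the same f ramp as the hydrophobic
#' score. Zero when no custom features are defined.
#' @param overlay an `overlay`.
#' @export
custom_feature_score <- function(overlay) {
  cfg <- overlay$system$config
  pts <- overlay_points(overlay, kinds = "custom")
  if (!nrow(pts$xyz)) return(list(CF = 0, clusters = list()))
  names_ <- vapply(seq_len(nrow(pts$xyz)), function(i)
    overlay$system$features[[pts$meta$ligand[i]]][[pts$meta$feature[i]]]$name,
    character(1))
  out <- list()
  for (nm in unique(names_)) {
    sel <- which(names_ == nm)
    cls <- leader_cluster(pts$xyz[sel, , drop = FALSE],
                          pts$meta$ligand[sel], cfg$cluster_dist)
    for (cl in cls) {
      N <- length(cl$members)
      out[[length(out) + 1L]] <- list(
        name = nm, members = sel[cl$members], N = N, spread = cl$spread,
        contribution = N^2 * f_hy(cl$spread))
    }
  }
  list(CF = sum(vapply(out, `[[`, numeric(1), "contribution")), clusters = out)
}

#' Strain-energy score
#'
#' Sum over ligands of torsional plus repulsive-only van der Waals energy
#' (kcal/mol) from a minimal Tripos-style parameter set. Radii are scaled by
#' 0.85 because bond angles cannot relax, and each ligand's worst atom-atom
#' clash is forgiven provided it is below 150 kcal/mol. Missing parameters
#' contribute zero with a one-time warning.
#'
#' @param overlay an `overlay`.
#' @param vdw_scale radius scale factor (default 0.85).
#' @param clash_forgive_below worst-clash exemption threshold, kcal/mol.
#' @export
energy_score <- function(overlay, vdw_scale = 0.85,
                         clash_forgive_below = 150) {
  sys <- overlay$system
  total <- 0
  for (li in seq_along(overlay$states)) {
    lig <- sys$ligands[[li]]
    coords <- overlay$states[[li]]$coords
    types <- sys$atom_types[[li]]
    total <- total +
      ligand_strain(lig, coords, types, sys$vdw, sys$torsion_params,
                    vdw_scale, clash_forgive_below)
  }
  total
}

ligand_strain <- function(lig, coords, types, vdw, torpar, vdw_scale,
                          clash_forgive_below) {
  # torsional term: one contribution per acyclic single heavy-atom bond
  etor <- 0
  warned <- FALSE
  for (k in seq_len(nrow(lig$bonds))) {
    if (lig$bonds$order[k] != 1L || lig$bonds$aromatic[k] ||
        lig$bond_in_ring[k]) next
    bi <- lig$bonds$i[k]; bj <- lig$bonds$j[k]
    if (lig$elements[bi] == "H" || lig$elements[bj] == "H") next
    a <- anchor_neighbour(lig, bi, bj); d <- anchor_neighbour(lig, bj, bi)
    if (is.na(a) || is.na(d)) next
    tb <- types[bi]; tc <- types[bj]
    row <- which((torpar$a == tb & torpar$b == tc) |
                 (torpar$a == tc & torpar$b == tb))
    if (!length(row)) {
      if (!warned) {
        warning("no torsion parameters for ", tb, "-", tc,
                " (ligand ", lig$id, "); term contributes zero")
        warned <- TRUE
      }
      next
    }
    p <- torpar[row[1], ]
    phi <- measure_torsion(coords, c(a, bi, bj, d)) * DEG
    etor <- etor + p$V / 2 * (1 + p$s * cos(p$n * phi))
  }
  # repulsive vdW over pairs >= 3 bonds apart
  n <- lig$natoms
  gd <- graph_distances(lig)
  ri <- vdw$vdw_radius[match(types, vdw$type)]
  ei <- vdw$epsilon[match(types, vdw$type)]
  miss <- is.na(ri)
  if (any(miss)) {
    warning("no vdW parameters for type(s) ",
            paste(unique(types[miss]), collapse = ", "),
            " (ligand ", lig$id, "); pairs contribute zero")
    ri[miss] <- 0; ei[miss] <- 0
  }
  terms <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (gd[i, j] < 3L) next
    if (ri[i] == 0 || ri[j] == 0) next
    rm_ <- vdw_scale * (ri[i] + ri[j])
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d >= rm_) next  # attractive region excluded
    eps <- sqrt(ei[i] * ei[j])
    e <- eps * ((rm_ / d)^12 - 2 * (rm_ / d)^6)
    if (e > 0) terms <- c(terms, e)
  }
  evdw <- sum(terms)
  if (length(terms)) {
    worst <- max(terms)
    if (worst < clash_forgive_below) evdw <- evdw - worst
  }
  etor + evdw
}

## All-pairs bond-graph distances (small molecules; BFS per atom).
graph_distances <- function(lig) {
  n <- lig$natoms
  gd <- matrix(Inf, n, n); diag(gd) <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in lig$adj[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L; queue <- c(queue, u)
      }
    }
    gd[s, ] <- ifelse(is.na(dist), Inf, dist)
  }
  gd
}

#' Simple cluster-count scores
#'
#' The stripped-down variants: HB(simple) is the sum of squared donor- and
#' acceptor-cluster sizes, HY(simple) the sum of squared hydrophobe-cluster
#' sizes, with no similarity, occlusion or geometry factors.
#' @param overlay an `overlay`.
#' @return Named vector with `HB_simple` and `HY_simple`.
#' @export
simple_scores <- function(overlay) {
  cfg <- overlay$system$config
  hb <- 0
  for (kind in c("donor", "acceptor")) {
    pts <- overlay_points(overlay, roles = "atom_site", kinds = kind)
    if (!nrow(pts$xyz)) next
    cls <- leader_cluster(pts$xyz, pts$meta$ligand, cfg$cluster_dist)
    hb <- hb + sum(vapply(cls, function(c) length(c$members), integer(1))^2)
  }
  pts <- overlay_points(overlay, roles = "hydrophobe_centroid")
  hy <- 0
  if (nrow(pts$xyz)) {
    cls <- leader_cluster(pts$xyz, pts$meta$ligand, cfg$cluster_dist)
    hy <- sum(vapply(cls, function(c) length(c$members), integer(1))^2)
  }
  c(HB_simple = hb, HY_simple = hy)
}

#' Score an overlay on the requested objectives
#'
#' @param overlay an `overlay`.
#' @param objectives subset of c("V", "HB", "HY", "E", "CF").
#' @return Named numeric vector; cluster breakdowns are attached as the
#'   `"clusters"` attribute.
#' @export
score_overlay <- function(overlay, objectives = overlay$system$config$objectives) {
  out <- numeric(0); clusters <- list()
  for (obj in objectives) {
    val <- switch(obj,
      V = volume_score(overlay),
      HB = { r <- hbond_score(overlay); clusters$HB <- r$clusters; r$HB },
      HY = { r <- hydrophobic_score(overlay); clusters$HY <- r$clusters; r$HY },
      E = energy_score(overlay),
      CF = { r <- custom_feature_score(overlay); clusters$CF <- r$clusters; r$CF },
      stop("unknown objective: ", obj))
    out[obj] <- val
  }
  attr(out, "clusters") <- clusters
  out
}

## Which objectives are minimised.
OBJECTIVE_MINIMISE <- c(V = TRUE, HB = FALSE, HY = FALSE, E = TRUE, CF = FALSE)
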