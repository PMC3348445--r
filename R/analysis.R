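## Solution analysis: pharmacophore extraction, the pharmacophore (D_P),
## geometric (D_G) and consensus (D_C) dissimilarity coefficients, overlay
## superposition, and SMACOF multidimensional scaling of solution sets.

#' Extract the pharmacophore hypothesis of an overlay
#'
#' Leader-clusters the fitting points of each kind; clusters with at least
#' `min_ligands` contributors become pharmacophore points, flagged "full"
#' when every ligand contributes.
#'
#' @param overlay an `overlay`.
#' @param min_ligands minimum contributors per point (default 2; use the
#'   ligand count to keep only full points, 1 to keep singletons).
#' @return List of pharmacophore points: `kind`, `contributors` (data frame
#'   `ligand`, `point`), `centroid`, `full`.
#' @export
extract_pharmacophore <- function(overlay, min_ligands = 2L) {
  cfg <- overlay$system$config
  nlig <- length(overlay$states)
  pts <- overlay_points(overlay, roles = c("atom_site", "hydrophobe_centroid",
                                           "custom_centroid"))
  out <- list()
  if (!nrow(pts$xyz)) return(out)
  for (kind in unique(pts$meta$kind)) {
    sel <- which(pts$meta$kind == kind)
    cls <- leader_cluster(pts$xyz[sel, , drop = FALSE],
                          pts$meta$ligand[sel], cfg$cluster_dist)
    for (cl in cls) {
      mem <- sel[cl$members]
      if (length(mem) < min_ligands) next
      out[[length(out) + 1L]] <- list(
        kind = kind,
        contributors = data.frame(ligand = pts$meta$ligand[mem],
                                  point = pts$meta$point[mem]),
        centroid = cl$centroid,
        spread = cl$spread,
        full = length(mem) == nlig)
    }
  }
  out
}

#' Pharmacophore dissimilarity D_P
#'
#' Same-kind pharmacophore-point pairs are compared with the Tanimoto
#' coefficient T = N_AB / (N_A + N_B - N_AB) over their contributing
#' fitting points, and matched greedily in descending T (ties prefer the
#' larger weight w = ((N_A + N_B)/2)^2, then point order). Unmatched points
#' contribute U = sum N_i^2, and D_P = 1 - (sum w T) / (U + sum w).
#'
#' @param a,b overlays of the same ligand set.
#' @param min_ligands passed to [extract_pharmacophore()].
#' @return List with `D_P`, the `matches` table and `U`.
#' @export
pharmacophore_dissimilarity <- function(a, b, min_ligands = 2L) {
  pa <- extract_pharmacophore(a, min_ligands)
  pb <- extract_pharmacophore(b, min_ligands)
  if (!length(pa) && !length(pb))
    return(list(D_P = 0, matches = data.frame(), U = 0,
                pharm_a = pa, pharm_b = pb))
  key <- function(p) paste(p$contributors$ligand, p$contributors$point,
                           sep = ":")
  cand <- list()
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (pa[[i]]$kind != pb[[j]]$kind) next
    na <- nrow(pa[[i]]$contributors); nb <- nrow(pb[[j]]$contributors)
    nab <- length(intersect(key(pa[[i]]), key(pb[[j]])))
    cand[[length(cand) + 1L]] <- data.frame(
      i = i, j = j, T = nab / (na + nb - nab), w = ((na + nb) / 2)^2)
  }
  matches <- data.frame()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$T, -cand$w, cand$i, cand$j), , drop = FALSE]
    used_a <- logical(length(pa)); used_b <- logical(length(pb))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      matches <- rbind(matches, cand[r, ])
    }
  } else {
    used_a <- logical(length(pa)); used_b <- logical(length(pb))
  }
  U <- sum(vapply(pa[!used_a], function(p) nrow(p$contributors)^2,
                  numeric(1))) +
       sum(vapply(pb[!used_b], function(p) nrow(p$contributors)^2,
                  numeric(1)))
  num <- if (nrow(matches)) sum(matches$w * matches$T) else 0
  den <- U + if (nrow(matches)) sum(matches$w) else 0
  D_P <- if (den == 0) 0 else 1 - num / den
  list(D_P = D_P, matches = matches, U = U, pharm_a = pa, pharm_b = pb)
}

## Topological symmetry classes by iterated neighbourhood refinement
## (element + charge + degree, then sorted neighbour classes to a fixed
## point).
symmetry_classes <- function(lig) {
  lab <- paste(lig$elements, lig$charges,
               vapply(seq_len(lig$natoms), function(a)
                 length(lig$adj[[a]]), integer(1)))
  repeat {
    new <- vapply(seq_len(lig$natoms), function(a)
      paste(lab[a], paste(sort(lab[lig$adj[[a]]]), collapse = ","),
            sep = "|"), character(1))
    new <- match(new, unique(new))
    old_groups <- match(lab, unique(lab))
    if (identical(match(new, unique(new)), old_groups)) break
    lab <- as.character(new)
  }
  match(lab, unique(lab))
}

#' Probe atoms of a system
#'
#' One atom from (or very near to) every feature of every ligand: the member
#' atom closest to the feature centroid in the first conformer.
#' @param system a ligand system.
#' @return List per ligand of atom indices (one per feature).
#' @export
probe_atoms <- function(system) {
  lapply(seq_len(system$nlig), function(li) {
    coords <- system$ligands[[li]]$conformers[[1]]
    vapply(system$features[[li]], function(f) {
      if (length(f$atoms) == 1L) return(f$atoms)
      cen <- colMeans(coords[f$atoms, , drop = FALSE])
      f$atoms[which.min(rowSums(sweep(coords[f$atoms, , drop = FALSE],
                                      2, cen)^2))]
    }, integer(1))
  })
}

#' Geometric dissimilarity D_G
#'
#' Two-step procedure over probe atoms (one per feature per ligand).
#' Step 1 allows for local topological symmetry: for each ligand, all
#' pairings mapping each probe atom of overlay `a` onto a
#' symmetry-equivalent atom of the same ligand in overlay `b` are tried
#' (capped at `max_pairings`; beyond the cap the identity pairing is used
#' with a warning) and the lowest-rmsd pairing kept. Step 2 Kabsch-fits all
#' paired atoms of `a` onto `b`; each residual distance d maps to
#' q = 0 below 0.5 A, (d - 0.5)/3 up to 3.5 A and 1 above, and D_G is the
#' mean q.
#'
#' @param a,b overlays of the same ligand set.
#' @param max_pairings symmetry-pairing cap per ligand (default 5000).
#' @return List with `D_G`, the transform and the pairing used.
#' @export
geometric_dissimilarity <- function(a, b, max_pairings = 5000L) {
  # the two-step pairing procedure is directional; symmetrise by averaging
  # the two directions so D_G(a, b) = D_G(b, a) exactly
  fwd <- directed_geometric_dissimilarity(a, b, max_pairings)
  bwd <- directed_geometric_dissimilarity(b, a, max_pairings)
  list(D_G = (fwd$D_G + bwd$D_G) / 2, transform = fwd$transform,
       distances = fwd$distances)
}

directed_geometric_dissimilarity <- function(a, b, max_pairings = 5000L) {
  sys <- a$system
  if (!identical(sys$ids, b$system$ids))
    stop("geometric dissimilarity requires overlays of the same ligand set")
  probes <- probe_atoms(sys)
  src <- list(); dst <- list()
  for (li in seq_len(sys$nlig)) {
    pa <- probes[[li]]
    classes <- symmetry_classes(sys$ligands[[li]])
    opts <- lapply(pa, function(at) which(classes == classes[at]))
    nopt <- prod(vapply(opts, length, integer(1)))
    A <- a$states[[li]]$coords[pa, , drop = FALSE]
    if (nopt > max_pairings) {
      warning("symmetry pairings for ligand ", sys$ids[li],
              " exceed the cap; using identity pairing")
      best <- pa
    } else {
      grid <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
      best <- pa; best_rmsd <- Inf
      for (r in seq_len(nrow(grid))) {
        cand <- as.integer(grid[r, ])
        if (anyDuplicated(cand)) next
        rmsd <- kabsch_fit(A, b$states[[li]]$coords[cand, , drop = FALSE])$rmsd
        if (rmsd < best_rmsd) { best_rmsd <- rmsd; best <- cand }
      }
    }
    src[[li]] <- A
    dst[[li]] <- b$states[[li]]$coords[best, , drop = FALSE]
  }
  S <- do.call(rbind, src); D <- do.call(rbind, dst)
  tf <- kabsch_fit(S, D)
  d <- sqrt(rowSums((apply_transform(S, tf) - D)^2))
  q <- pmin(pmax((d - 0.5) / 3, 0), 1)
  list(D_G = mean(q), transform = tf, distances = d)
}

#' Consensus dissimilarity D_C
#'
#' The geometric mean sqrt(D_P * D_G) of the pharmacophore and geometric
#' coefficients.
#' @inheritParams geometric_dissimilarity
#' @export
consensus_dissimilarity <- function(a, b) {
  dp <- pharmacophore_dissimilarity(a, b)
  dg <- geometric_dissimilarity(a, b)
  list(D_C = sqrt(dp$D_P * dg$D_G), D_P = dp$D_P, D_G = dg$D_G)
}

#' Pairwise dissimilarity matrix of a solution set
#'
#' @param solutions a `solution_set` (or list of overlays).
#' @param coefficient "D_P", "D_G" or "D_C".
#' @export
dissimilarity_matrix <- function(solutions, coefficient = c("D_C", "D_P",
                                                            "D_G")) {
  coefficient <- match.arg(coefficient)
  ovs <- lapply(solutions, function(s)
    if (inherits(s, "overlay")) s else s$overlay)
  n <- length(ovs)
  m <- matrix(0, n, n)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- switch(coefficient,
      D_P = pharmacophore_dissimilarity(ovs[[i]], ovs[[j]])$D_P,
      D_G = geometric_dissimilarity(ovs[[i]], ovs[[j]])$D_G,
      D_C = consensus_dissimilarity(ovs[[i]], ovs[[j]])$D_C)
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Superimpose one overlay on another
#'
#' Atom mode least-squares fits the probe atoms (with the symmetry-aware
#' pairing from the D_G step); pharmacophore mode fits the matched
#' pharmacophore-point centroids from the D_P calculation and also returns
#' the consensus pharmacophore of the pair.
#'
#' @param a,b overlays of the same ligand set (`a` is moved onto `b`).
#' @param mode "atoms" or "pharmacophores".
#' @return List with the moved overlay `a`, the `transform`, and (in
#'   pharmacophore mode) the `consensus` pharmacophore.
#' @export
superimpose_overlays <- function(a, b, mode = c("atoms", "pharmacophores")) {
  mode <- match.arg(mode)
  if (mode == "atoms") {
    dg <- geometric_dissimilarity(a, b)
    tf <- dg$transform
    consensus <- NULL
  } else {
    dp <- pharmacophore_dissimilarity(a, b)
    if (!nrow(dp$matches))
      stop("no matched pharmacophore points; cannot superimpose")
    src <- t(vapply(dp$matches$i, function(i) dp$pharm_a[[i]]$centroid,
                    numeric(3)))
    dst <- t(vapply(dp$matches$j, function(j) dp$pharm_b[[j]]$centroid,
                    numeric(3)))
    tf <- kabsch_fit(src, dst)
    consensus <- lapply(seq_len(nrow(dp$matches)), function(r) {
      i <- dp$matches$i[r]; j <- dp$matches$j[r]
      list(kind = dp$pharm_a[[i]]$kind,
           centroid = (apply_transform(rbind(dp$pharm_a[[i]]$centroid),
                                       tf)[1, ] +
                       dp$pharm_b[[j]]$centroid) / 2,
           T = dp$matches$T[r])
    })
  }
  moved <- new_overlay(a$system, lapply(a$states, function(st) {
    st$coords <- apply_transform(st$coords, tf)
    st
  }), chromosome = a$chromosome)
  list(overlay = moved, transform = tf, consensus = consensus)
}

#' SMACOF multidimensional scaling
#'
#' Embeds a dissimilarity matrix in 2 or 3 dimensions by stress
#' majorisation (Guttman transform) from a classical-scaling start. The
#' raw stress sum((delta - d)^2) is non-increasing at every iteration.
#'
#' @param delta symmetric dissimilarity matrix.
#' @param dims 2 or 3.
#' @param maxit,tol iteration cap (300) and relative stress tolerance
#'   (1e-6).
#' @return List with `coords` (n x dims), `stress`, and the per-iteration
#'   `trace`.
#' @export
mds_map <- function(delta, dims = 2L, maxit = 300L, tol = 1e-6) {
  delta <- as.matrix(delta)
  n <- nrow(delta)
  if (n < 3L) {
    coords <- matrix(0, n, dims)
    if (n == 2L) coords[2, 1] <- delta[1, 2]
    return(list(coords = coords, stress = 0, trace = numeric(0)))
  }
  X <- tryCatch(stats::cmdscale(delta, k = dims), error = function(e) NULL)
  if (is.null(X) || ncol(X) < dims) {
    X <- cbind(X, matrix(0, n, dims - if (is.null(X)) 0 else ncol(X)))
  }
  stress_of <- function(X) {
    d <- as.matrix(stats::dist(X))
    sum((delta[upper.tri(delta)] - d[upper.tri(d)])^2)
  }
  trace <- stress_of(X)
  for (it in seq_len(maxit)) {
    d <- as.matrix(stats::dist(X))
    ratio <- ifelse(d > 1e-12, delta / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s <- stress_of(X)
    trace <- c(trace, s)
    if (abs(trace[it] - s) <= tol * max(trace[it], 1e-12)) break
  }
  list(coords = X, stress = trace[length(trace)], trace = trace)
}
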