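# Pharmacophore extraction, dissimilarity coefficients, superposition, MDS.

test_that("pharmacophore extraction recovers planted points", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  ph <- extract_pharmacophore(ov)
  full <- Filter(function(p) p$full, ph)
  expect_gte(length(full), 3L)
  kinds <- vapply(full, `[[`, "", "kind")
  expect_true(all(c("donor", "acceptor", "hydrophobe_dir") %in% kinds))
  # min_ligands = ligand count keeps only full points
  ph_full <- extract_pharmacophore(ov, min_ligands = 3L)
  expect_true(all(vapply(ph_full, `[[`, logical(1), "full")))
  # singleton clusters are excluded at the default threshold
  expect_true(all(vapply(ph, function(p) nrow(p$contributors), integer(1))
                  >= 2L))
})

test_that("D_P follows the Tanimoto-weighted matching formula", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  # identical overlays: every T = 1, U = 0, D_P = 0
  dp <- pharmacophore_dissimilarity(ov, ov)
  expect_equal(dp$D_P, 0, tolerance = 1e-12)
  expect_true(all(dp$matches$T == 1))
  expect_equal(dp$U, 0)
  # worked arithmetic: one pair N_A = N_B = 3, N_AB = 2 plus one unmatched
  # point of size 2: D_P = 1 - (9 * 0.5)/(4 + 9) = 0.6538...
  T <- 2 / (3 + 3 - 2); w <- ((3 + 3) / 2)^2; U <- 4
  expect_equal(1 - (w * T) / (U + w), 0.65384615, tolerance = 1e-7)
})

test_that("greedy D_P matching equals an independent oracle on random sets", {
  fix <- toy_fixture()
  set.seed(23)
  pool <- generate_overlays(fix$sys)
  ovs <- lapply(pool[seq_len(min(8, length(pool)))], function(s)
    decode_chromosome(s$chromosome, fix$sys))
  oracle_dp <- function(a, b) {
    pa <- extract_pharmacophore(a); pb <- extract_pharmacophore(b)
    key <- function(p) paste(p$contributors$ligand, p$contributors$point)
    cand <- expand.grid(i = seq_along(pa), j = seq_along(pb))
    cand <- cand[vapply(seq_len(nrow(cand)), function(r)
      pa[[cand$i[r]]]$kind == pb[[cand$j[r]]]$kind, logical(1)), ,
      drop = FALSE]
    cand$T <- vapply(seq_len(nrow(cand)), function(r) {
      na <- nrow(pa[[cand$i[r]]]$contributors)
      nb <- nrow(pb[[cand$j[r]]]$contributors)
      nab <- length(intersect(key(pa[[cand$i[r]]]), key(pb[[cand$j[r]]])))
      nab / (na + nb - nab)
    }, numeric(1))
    cand$w <- vapply(seq_len(nrow(cand)), function(r) {
      na <- nrow(pa[[cand$i[r]]]$contributors)
      nb <- nrow(pb[[cand$j[r]]]$contributors)
      ((na + nb) / 2)^2
    }, numeric(1))
    cand <- cand[order(-cand$T, -cand$w, cand$i, cand$j), , drop = FALSE]
    ua <- logical(length(pa)); ub <- logical(length(pb))
    num <- 0; den <- 0
    for (r in seq_len(nrow(cand))) {
      if (ua[cand$i[r]] || ub[cand$j[r]]) next
      ua[cand$i[r]] <- TRUE; ub[cand$j[r]] <- TRUE
      num <- num + cand$w[r] * cand$T[r]; den <- den + cand$w[r]
    }
    U <- sum(vapply(pa[!ua], function(p) nrow(p$contributors)^2, numeric(1))) +
      sum(vapply(pb[!ub], function(p) nrow(p$contributors)^2, numeric(1)))
    if (U + den == 0) 0 else 1 - num / (U + den)
  }
  for (i in seq_along(ovs)) for (j in seq_along(ovs)) {
    if (i >= j) next
    expect_equal(pharmacophore_dissimilarity(ovs[[i]], ovs[[j]])$D_P,
                 oracle_dp(ovs[[i]], ovs[[j]]), tolerance = 1e-12)
  }
})

test_that("D_G handles identity, saturation and the linear ramp", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  expect_equal(geometric_dissimilarity(ov, ov)$D_G, 0, tolerance = 1e-12)
  # rigid motion of one overlay leaves D_G at zero
  tf <- ligover:::rotation_about_axis(c(0, 0, 0), c(1, 1, 1), 130)
  moved <- new_overlay(fix$sys, lapply(ov$states, function(st) {
    st$coords <- apply_transform(st$coords, tf); st
  }))
  expect_equal(geometric_dissimilarity(ov, moved)$D_G, 0, tolerance = 1e-9)
  # the q ramp itself: 2.0 A residual maps to 0.5, saturation at 3.5 A
  d <- c(0.2, 0.5, 2.0, 3.5, 9)
  q <- pmin(pmax((d - 0.5) / 3, 0), 1)
  expect_equal(q, c(0, 0, 0.5, 1, 1))
})

test_that("dissimilarity axioms hold across random solution pairs", {
  fix <- toy_fixture()
  set.seed(29)
  pool <- generate_overlays(fix$sys)
  ovs <- lapply(pool[seq_len(min(6, length(pool)))], function(s)
    decode_chromosome(s$chromosome, fix$sys))
  for (i in seq_along(ovs)) for (j in seq_along(ovs)) {
    if (i > j) next
    cc <- consensus_dissimilarity(ovs[[i]], ovs[[j]])
    expect_gte(cc$D_P, 0); expect_lte(cc$D_P, 1)
    expect_gte(cc$D_G, 0); expect_lte(cc$D_G, 1)
    expect_gte(cc$D_C, 0); expect_lte(cc$D_C, 1)
    expect_equal(cc$D_C, sqrt(cc$D_P * cc$D_G), tolerance = 1e-12)
    if (i == j) expect_equal(cc$D_C, 0, tolerance = 1e-12)
    # symmetry
    cc2 <- consensus_dissimilarity(ovs[[j]], ovs[[i]])
    expect_equal(cc$D_P, cc2$D_P, tolerance = 1e-9)
    expect_equal(cc$D_G, cc2$D_G, tolerance = 1e-9)
  }
})

test_that("overlay superposition recovers rigid motions", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  tf <- ligover:::rotation_about_axis(c(1, 0, 0), c(1, 1, 0), -49)
  moved <- new_overlay(fix$sys, lapply(ov$states, function(st) {
    st$coords <- apply_transform(st$coords, tf); st
  }))
  fit <- superimpose_overlays(moved, ov, mode = "atoms")
  expect_equal(geometric_dissimilarity(fit$overlay, ov)$D_G, 0,
               tolerance = 1e-9)
  # pharmacophore mode fits matched centroids and emits a consensus
  fitp <- superimpose_overlays(moved, ov, mode = "pharmacophores")
  expect_gt(length(fitp$consensus), 0L)
  expect_lt(fitp$transform$rmsd, 1e-6)
})

test_that("SMACOF embeds exactly embeddable configurations at zero stress", {
  # three mutually equidistant overlays -> equilateral triangle
  m <- matrix(1, 3, 3); diag(m) <- 0
  res <- mds_map(m, dims = 2L)
  expect_lt(res$stress, 1e-6)
  d <- as.matrix(stats::dist(res$coords))
  expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 1e-3)
  # distances of an exact 2D point set are reproduced
  set.seed(31)
  X <- matrix(runif(16), 8, 2)
  res2 <- mds_map(as.matrix(stats::dist(X)), dims = 2L)
  expect_lt(res2$stress, 1e-6)
  # stress is non-increasing every iteration, and the final stress never
  # exceeds the classical-scaling start (its own first trace entry)
  for (rep in 1:5) {
    r <- matrix(runif(100), 10, 10); r <- (r + t(r)) / 2; diag(r) <- 0
    res3 <- mds_map(r, dims = 2L)
    expect_true(all(diff(res3$trace) <= 1e-9))
    expect_lte(res3$stress, res3$trace[1] + 1e-12)
  }
  # degenerate inputs return trivial coordinates
  expect_equal(mds_map(matrix(0, 1, 1))$coords, matrix(0, 1, 2))
  expect_equal(mds_map(matrix(c(0, 2, 2, 0), 2, 2))$coords[2, 1], 2)
})
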