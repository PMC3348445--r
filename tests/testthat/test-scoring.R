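# Leader clustering and the five objective functions.

# Independent leader-cluster re-implementation used as the oracle: same
# published procedure, written directly against the definition.
oracle_leader <- function(xyz, tags, max_dist = 1.5) {
  m <- nrow(xyz)
  dmat <- as.matrix(stats::dist(xyz))
  nnls <- list()
  for (i in seq_len(m)) {
    mem <- i
    for (t in unique(tags)) {
      if (t == tags[i]) next
      cand <- which(tags == t)
      best <- cand[order(dmat[i, cand])][1]
      if (dmat[i, best] <= max_dist + 1e-9) mem <- c(mem, best)
    }
    nnls[[i]] <- mem
  }
  done <- rep(FALSE, m)
  clusters <- list()
  while (!all(done)) {
    live <- which(!done)
    lens <- vapply(live, function(i) length(nnls[[i]]), integer(1))
    top <- live[lens == max(lens)]
    if (length(top) > 1) {
      spread <- vapply(top, function(i) {
        mem <- nnls[[i]]
        if (length(mem) < 2) 0 else mean(dmat[mem, mem][upper.tri(
          dmat[mem, mem])]^2)
      }, numeric(1))
      top <- top[which.min(spread)]
    }
    mem <- nnls[[top[1]]]
    clusters[[length(clusters) + 1]] <- sort(mem)
    done[mem] <- TRUE
    for (i in which(!done)) nnls[[i]] <- setdiff(nnls[[i]], mem)
  }
  clusters
}

test_that("leader clustering follows the nearest-neighbour-list procedure", {
  # coincident points, one per ligand -> a single cluster with zero spread
  xyz <- matrix(0, 3, 3)
  cl <- leader_cluster(xyz, 1:3)
  expect_length(cl, 1L)
  expect_identical(sort(cl[[1]]$members), 1:3)
  expect_equal(cl[[1]]$spread, 0)
  # beyond 1.5 A: two singletons
  cl <- leader_cluster(rbind(c(0, 0, 0), c(2, 0, 0)), 1:2)
  expect_length(cl, 2L)
  # equal-length NNL tie resolved toward the tighter cluster
  xyz <- rbind(c(0, 0, 0), c(1.0, 0, 0),      # ligands 1, 2 (loose pair)
               c(10, 0, 0), c(10.1, 0, 0))    # ligands 1, 2 (tight pair)
  cl <- leader_cluster(xyz, c(1, 2, 1, 2))
  expect_identical(sort(cl[[1]]$members), c(3L, 4L))
})

test_that("leader clustering equals an independent oracle on random input", {
  set.seed(33)
  for (rep in 1:40) {
    m <- sample(6:14, 1)
    xyz <- matrix(runif(3 * m, 0, 4), m, 3)
    tags <- sample(1:4, m, replace = TRUE)
    got <- lapply(leader_cluster(xyz, tags), function(c) sort(c$members))
    want <- oracle_leader(xyz, tags)
    expect_identical(got[order(vapply(got, min, integer(1)))],
                     want[order(vapply(want, min, integer(1)))])
  }
})

nitrile_trio <- function(spread_r = 0) {
  ligs <- lapply(1:3, function(k) {
    off <- if (spread_r > 0) {
      th <- 2 * pi * (k - 1) / 3
      c(spread_r * cos(th), spread_r * sin(th), 0)
    } else c(0, 0, 0)
    make_nitrile(paste0("nit", k), origin = off)
  })
  sys <- build_system(ligs)
  new_overlay(sys, lapply(ligs, function(l)
    list(conf = 1L, coords = l$conformers[[1]])))
}

test_that("hydrogen-bond score reproduces the cluster formula", {
  # 3 coincident collinear nitrile acceptors: A=3, a=0, S=1, X=1, V=3, v=0
  hb <- hbond_score(nitrile_trio(0))
  expect_equal(hb$HB, 18, tolerance = 1e-9)
  cl <- hb$clusters[[1]]
  expect_identical(cl$A, 3L)
  expect_identical(cl$V_p, 3L)
  expect_equal(cl$S, 1)
  expect_equal(cl$X, 1)
  # spread at the ramp midpoint: a_p = 0.45, f = 0.65, atom term 5.85
  hb2 <- hbond_score(nitrile_trio(sqrt(0.45)))
  cl2 <- hb2$clusters[[1]]
  expect_equal(cl2$spread, 0.45, tolerance = 1e-9)
  atom_term <- cl2$S * cl2$X * cl2$A^2 * ligover:::f_hb(cl2$spread)
  expect_equal(cl2$A^2 * ligover:::f_hb(cl2$spread), 9 * 0.65,
               tolerance = 1e-9)
  expect_equal(atom_term, 5.85, tolerance = 1e-9)
  # ramp endpoints
  expect_equal(ligover:::f_hb(c(0, 0.15, 0.75, 2)), c(1, 1, 0.3, 0.3))
  expect_equal(ligover:::g_hb(c(0.5, 1.0, 1.5)), c(1, 0.65, 0.3))
})

test_that("occlusion and strength factors scale HB as specified", {
  expect_equal(ligover:::effective_m(rep("medium", 4)), 4)
  # one off-modal atom costs 0.5; strong/weak mixing an extra 0.5 per pair
  expect_equal(ligover:::effective_m(c("medium", "medium", "weak")), 2.5)
  expect_equal(ligover:::effective_m(c("strong", "weak")), 1)
  expect_gte(ligover:::effective_m(rep("weak", 1)), 1)
  # occlusion factor: clear line of sight is 1; full occlusion floors at 0.1
  env_clear <- list(xyz = matrix(numeric(0), 0, 3), r = numeric(0))
  expect_equal(ligover:::occlusion_factor(c(0, 0, 0), c(0, 0, 3), env_clear), 1)
  env_block <- list(xyz = rbind(c(0, 0, 1.5)), r = 3)
  expect_equal(ligover:::occlusion_factor(c(0, 0, 0), c(0, 0, 3), env_block),
               0.1)
})

benzene_trio <- function(tilt_deg = 0, spread_r = 0) {
  ligs <- lapply(1:3, function(k) {
    lig <- make_benzene(paste0("benz", k))
    xyz <- lig$conformers[[1]]
    if (tilt_deg != 0 && k == 2) {
      tf <- ligover:::rotation_about_axis(c(0, 0, 0), c(1, 0, 0), tilt_deg)
      xyz <- apply_transform(xyz, tf)
    }
    if (spread_r > 0) {
      th <- 2 * pi * (k - 1) / 3
      xyz <- sweep(xyz, 2, c(spread_r * cos(th), spread_r * sin(th), 0), "+")
    }
    lig$conformers[[1]] <- xyz
    lig
  })
  sys <- build_system(ligs)
  new_overlay(sys, lapply(ligs, function(l)
    list(conf = 1L, coords = l$conformers[[1]])))
}

test_that("hydrophobic score rewards coincident, coplanar rings", {
  # 3 coincident coplanar rings: N^2 (f + g) = 9 * 3 = 27
  expect_equal(hydrophobic_score(benzene_trio())$HY, 27, tolerance = 1e-9)
  # two of three planes at 90 degrees: c_p drops, g falls to 0
  hy <- hydrophobic_score(benzene_trio(tilt_deg = 90))
  cl <- hy$clusters[[1]]
  expect_lt(cl$c_p, 0.8)
  # midpoint arithmetic: n = 0.625, c = 0.9 -> f = 0.5, g = 1.0
  expect_equal(ligover:::f_hy(0.625), 0.5)
  expect_equal(ligover:::g_hy(0.9), 1.0)
  expect_equal(ligover:::g_hy(c(1, 0.8, 0.5)), c(2, 0, 0))
  # singleton clusters take c_p = 1
  solo <- hydrophobic_score(benzene_trio(spread_r = 5))
  expect_true(all(vapply(solo$clusters, `[[`, numeric(1), "c_p") == 1))
})

test_that("custom-feature score and simple scores follow the count formulas", {
  # four coincident custom centroids -> CF = 16
  ligs <- lapply(1:4, function(k) make_butane(paste0("b", k)))
  sys <- build_system(ligs, custom_atom_sets = stats::setNames(
    lapply(1:4, function(k) list(site = c(2L, 3L))),
    vapply(ligs, `[[`, "", "id")))
  ov <- new_overlay(sys, lapply(ligs, function(l)
    list(conf = 1L, coords = l$conformers[[1]])))
  expect_equal(custom_feature_score(ov)$CF, 16, tolerance = 1e-9)
  # beyond the f ramp the contribution is zero
  ligs2 <- lapply(1:2, function(k) make_butane(paste0("b", k)))
  sys2 <- build_system(ligs2, custom_atom_sets = stats::setNames(
    lapply(1:2, function(k) list(site = c(2L, 3L))),
    vapply(ligs2, `[[`, "", "id")))
  st <- lapply(1:2, function(k) {
    xyz <- ligs2[[k]]$conformers[[1]]
    if (k == 2) xyz <- sweep(xyz, 2, c(0, 0, 1.3), "+")
    list(conf = 1L, coords = xyz)
  })
  ov2 <- new_overlay(sys2, st)
  cf2 <- custom_feature_score(ov2)
  # every cluster contribution is exactly N^2 f(n_p), and the f ramp is
  # zero at and beyond 1.25 A^2
  for (cl in cf2$clusters)
    expect_equal(cl$contribution, cl$N^2 * ligover:::f_hy(cl$spread),
                 tolerance = 1e-12)
  expect_identical(ligover:::f_hy(c(1.25, 3)), c(0, 0))
  # no custom features -> 0
  expect_equal(custom_feature_score(nitrile_trio())$CF, 0)
  # simple scores: squared cluster sizes, no factors
  ss <- simple_scores(benzene_trio())
  expect_equal(unname(ss["HY_simple"]), 9)
  ss2 <- simple_scores(nitrile_trio())
  expect_equal(unname(ss2["HB_simple"]), 9)
  # with all geometric factors ideal, HB equals its simple atom term plus
  # the (equal-count) virtual-point term
  hb <- hbond_score(nitrile_trio(0))
  expect_equal(hb$HB, 2 * unname(ss2["HB_simple"]), tolerance = 1e-9)
})

test_that("strain energy obeys the worst-clash exemption rules", {
  # rigid benzene: no rotors, no clashes
  sys <- build_system(list(make_benzene()))
  ov <- new_overlay(sys, list(list(conf = 1L,
                                   coords = sys$ligands[[1]]$conformers[[1]])))
  expect_equal(energy_score(ov), 0)
  # two distant pentane-chain atoms forced together: one clash
  chain <- new_ligand("strained", rep("C", 5),
                      data.frame(i = 1:4, j = 2:5, order = 1),
                      list(rbind(c(0, 0, 0), c(1.5, 0.1, 0), c(2.2, 1.4, 0),
                                 c(1.5, 2.6, 0.1), c(0.1, 2.4, 0))))
  sysc <- build_system(list(chain))
  ovc <- new_overlay(sysc, list(list(conf = 1L,
                                     coords = chain$conformers[[1]])))
  # atoms 1 and 5 are ~2.4 A apart (clash at 0.85-scaled radii): energies
  # computed with and without the exemption differ by exactly that worst pair
  e_with <- ligover:::ligand_strain(chain, chain$conformers[[1]],
                                    sysc$atom_types[[1]], sysc$vdw,
                                    sysc$torsion_params, 0.85, 150)
  e_keep <- ligover:::ligand_strain(chain, chain$conformers[[1]],
                                    sysc$atom_types[[1]], sysc$vdw,
                                    sysc$torsion_params, 0.85, 0)
  expect_gt(e_keep, e_with)   # threshold 0 keeps every clash
  expect_gte(e_with, 0)
  # energy of any supplied conformer is finite and non-negative
  fix <- toy_fixture()
  e <- energy_score(true_toy_overlay(fix))
  expect_true(is.finite(e))
  expect_gte(e, 0)
})

test_that("union volume matches closed forms and converges with the grid", {
  # single carbon sphere
  v1 <- ligover:::grid_union_volume(rbind(c(0, 0, 0)), 1.7, 0.5)
  expect_lt(abs(v1 - 4 / 3 * pi * 1.7^3) / (4 / 3 * pi * 1.7^3), 0.02)
  # two-sphere union with lens-overlap closed form
  r <- 1.7; d <- 1.5
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * r * d) / (12 * d)
  vref <- 2 * (4 / 3 * pi * r^3) - lens
  v2 <- ligover:::grid_union_volume(rbind(c(0, 0, 0), c(d, 0, 0)),
                                    c(r, r), 0.5)
  expect_lt(abs(v2 - vref) / vref, 0.02)
  # union idempotence: duplicated atoms add nothing
  v_dup <- ligover:::grid_union_volume(rbind(c(0, 0, 0), c(0, 0, 0)),
                                       c(1.7, 1.7), 0.5)
  expect_equal(v_dup, v1)
  # far-apart union is additive
  v_far <- ligover:::grid_union_volume(rbind(c(0, 0, 0), c(30, 0, 0)),
                                       c(1.7, 1.7), 0.5)
  expect_equal(v_far, 2 * v1, tolerance = 0.01)
  # halving the grid changes the toy-overlay volume by under 1 percent
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  va <- volume_score(ov, grid = 0.5)
  vb <- volume_score(ov, grid = 0.25)
  expect_lt(abs(va - vb) / va, 0.01)
})

test_that("HB/HY/CF are invariant under rigid motion and monotone in spread", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  hb0 <- hbond_score(ov)$HB
  hy0 <- hydrophobic_score(ov)$HY
  tf <- ligover:::rotation_about_axis(c(1, 2, 3), c(2, 1, 5), 73)
  moved <- new_overlay(fix$sys, lapply(ov$states, function(st) {
    st$coords <- apply_transform(st$coords, tf)
    st
  }))
  expect_equal(hbond_score(moved)$HB, hb0, tolerance = 1e-6)
  expect_equal(hydrophobic_score(moved)$HY, hy0, tolerance = 1e-6)
  # tightening members toward the centroid never lowers the ramp factors
  spreads <- seq(0, 1.4, by = 0.2)
  expect_true(all(diff(ligover:::f_hb(spreads)) <= 1e-12))
  expect_true(all(diff(ligover:::f_hy(spreads)) <= 1e-12))
  hb_vals <- vapply(c(0, 0.3, 0.6), function(r)
    hbond_score(nitrile_trio(sqrt(max(r, 1e-9))))$HB, numeric(1))
  expect_true(all(diff(hb_vals) <= 1e-9))
})
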