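# Feature assignment, hydrophobe perception, fitting and virtual points.

test_that("donor/acceptor assignment follows the default definitions", {
  ph <- make_phenol()
  fts <- assign_features(ph)
  kinds <- vapply(fts, `[[`, "", "kind")
  atoms <- vapply(fts, `[[`, integer(1), "atom")
  # hydroxyl oxygen is both donor and acceptor
  expect_true(any(kinds == "donor" & atoms == 7L))
  expect_true(any(kinds == "acceptor" & atoms == 7L))
  # phenyl CH is never a donor; pyrimidine C2-H is (weak)
  expect_false(any(kinds == "donor" & atoms %in% 1:6))
  pyr <- new_ligand("pyrimidine", c("N", "C", "N", "C", "C", "C"),
                    data.frame(i = 1:6, j = c(2:6, 1),
                               order = c(2, 1, 2, 1, 2, 1)),
                    list(hex_ring_xyz()))
  fp <- assign_features(pyr)
  don <- Filter(function(f) f$kind == "donor", fp)
  expect_length(don, 1L)
  expect_identical(don[[1]]$atom, 2L)
  expect_identical(don[[1]]$strength, "weak")
  # exclusion removes features from the excluded atoms
  none <- assign_features(ph, excluded_atoms = 7L)
  expect_false(any(vapply(none, function(f) f$atom %in% 7L, logical(1))))
  expect_error(assign_features(ph, custom_atom_sets = list(x = 99L)),
               "missing atom")
})

test_that("feature assignment is conformation-independent", {
  fix <- toy_fixture()
  lig <- fix$ts$ligands[[1]]
  f1 <- ligand_features(lig)
  lig2 <- lig; lig2$conformers <- rev(lig$conformers)
  f2 <- ligand_features(lig2)
  expect_identical(lapply(f1, `[[`, "atoms"), lapply(f2, `[[`, "atoms"))
  expect_identical(vapply(f1, `[[`, "", "kind"), vapply(f2, `[[`, "", "kind"))
})

test_that("hydrophobe perception classifies rings, tBu/CF3 and segments", {
  hb <- perceive_hydrophobes(make_benzene())
  expect_length(hb, 1L)
  expect_identical(hb[[1]]$kind, "hydrophobe_dir")
  # saturated ring is non-directional
  chex <- new_ligand("cyclohexane", rep("C", 6),
                     data.frame(i = 1:6, j = c(2:6, 1), order = 1),
                     list(hex_ring_xyz(1.54)))
  expect_identical(perceive_hydrophobes(chex)[[1]]$kind, "hydrophobe_nondir")
  # neopentane: central C + 3 methyls = t-butyl group
  neo <- new_ligand("neopentane", rep("C", 5),
                    data.frame(i = rep(1, 4), j = 2:5, order = 1),
                    list(rbind(c(0, 0, 0), c(1.5, 0, 0), c(-0.5, 1.4, 0),
                               c(-0.5, -0.7, 1.2), c(-0.5, -0.7, -1.2))))
  tb <- Filter(function(f) f$name == "t-butyl", perceive_hydrophobes(neo))
  expect_length(tb, 1L)
  # chain segmentation: octane 4+4, hexane 3+3 (minimum size variance)
  mk_chain <- function(n) new_ligand(paste0("C", n), rep("C", n),
    data.frame(i = seq_len(n - 1), j = 2:n, order = 1),
    list(cbind(seq(0, 1.4 * (n - 1), length.out = n), rep(c(0, .5), length.out = n), 0)))
  sizes <- function(lig) sort(vapply(perceive_hydrophobes(lig),
                                     function(f) length(f$atoms), integer(1)))
  expect_identical(sizes(mk_chain(8)), c(4L, 4L))
  expect_identical(sizes(mk_chain(6)), c(3L, 3L))
  # segmentation oracle: chosen sizes minimise variance over all
  # compositions into parts of <= 4
  for (n in 5:9) {
    got <- sizes(mk_chain(n))
    all_parts <- ligover:::compositions_upto(n, 4L)
    best_var <- min(vapply(all_parts, function(p)
      if (length(p) > 1) stats::var(p) else 0, numeric(1)))
    got_var <- if (length(got) > 1) stats::var(got) else 0
    expect_equal(got_var, best_var, tolerance = 1e-12)
    expect_equal(sum(got), n)   # partition covers every atom exactly once
  }
})

test_that("fitting points sit on atoms, centroids and +/-1 A normals", {
  benz <- make_benzene()
  fts <- ligand_features(benz)
  fp <- place_fitting_points(fts, benz$conformers[[1]], use_normals = TRUE)
  expect_identical(nrow(fp$xyz), 3L)
  cen <- fp$xyz[fp$meta$role == "hydrophobe_centroid", ]
  expect_equal(cen, c(0, 0, 0), tolerance = 1e-9)
  for (role in c("hydrophobe_normal_plus", "hydrophobe_normal_minus"))
    expect_equal(sqrt(sum((fp$xyz[fp$meta$role == role, ] - cen)^2)), 1,
                 tolerance = 1e-6)
  expect_identical(nrow(place_fitting_points(fts, benz$conformers[[1]],
                                             use_normals = FALSE)$xyz), 1L)
  # carbonyl O acceptor point coincides with the O atom
  arm <- make_swing_arm("arm")
  afts <- ligand_features(arm)
  afp <- place_fitting_points(afts, arm$conformers[[1]])
  acc <- which(afp$meta$kind == "acceptor")
  expect_equal(afp$xyz[acc[1], ], arm$conformers[[1]][1, ], tolerance = 1e-12)
})

test_that("virtual points respect hydrogen-bond geometry classes", {
  hbd <- 2.9
  # nitrile: one point on the sp axis
  nit <- make_nitrile("n1")
  f <- Filter(function(x) x$kind == "acceptor", ligand_features(nit))[[1]]
  vp <- virtual_points(f, nit, nit$conformers[[1]], hb_distance = hbd)
  expect_identical(nrow(vp), 1L)
  expect_equal(sqrt(sum((vp[1, ] - nit$conformers[[1]][3, ])^2)), hbd,
               tolerance = 1e-9)
  # collinear with the C#N axis
  d <- vp[1, ] - nit$conformers[[1]][2, ]
  expect_equal(abs(sum(d * c(1, 0, 0))) / sqrt(sum(d^2)), 1,
               tolerance = 1e-9)
  # carbonyl: in-plane arc at the hb distance
  arm <- make_swing_arm("a2")
  f <- Filter(function(x) x$kind == "acceptor" && x$atom == 1L,
              ligand_features(arm))[[1]]
  vp <- virtual_points(f, arm, arm$conformers[[1]], hb_distance = hbd)
  expect_gte(nrow(vp), 3L)
  expect_true(all(abs(sqrt(rowSums(sweep(vp, 2,
                                         arm$conformers[[1]][1, ])^2)) -
                        hbd) < 1e-6))
  expect_true(all(abs(vp[, 3]) < 1e-6))  # sp2 plane is z = 0 here
  # cone: n points with equal adjacent angular spacing
  ac <- new_ligand("acetate", c("C", "C", "O", "O"),
                   data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                              order = c(1, 2, 1)),
                   list(rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0.6, 1.05, 0),
                              c(0.6, -1.05, 0))),
                   charges = c(0L, 0L, 0L, -1L))
  f <- Filter(function(x) x$kind == "acceptor" && x$atom == 4L,
              ligand_features(ac))[[1]]
  vp <- virtual_points(f, ac, ac$conformers[[1]], hb_distance = hbd,
                       n_points = 12L)
  expect_identical(nrow(vp), 12L)
  expect_true(all(abs(sqrt(rowSums(sweep(vp, 2, ac$conformers[[1]][4, ])^2)) -
                        hbd) < 1e-6))
  centre <- colMeans(vp)
  vecs <- sweep(vp, 2, centre)
  angs <- vapply(1:12, function(k) {
    a <- vecs[k, ]; b <- vecs[(k %% 12) + 1, ]
    acos(min(max(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
  }, numeric(1))
  expect_lt(diff(range(angs)), 1e-6)
  # missing local frame is a named error
  lone <- new_ligand("lone", "O", data.frame(i = integer(0), j = integer(0),
                                             order = integer(0))[0, ],
                     list(rbind(c(0, 0, 0))))
  lf <- ligover:::new_feature("acceptor", atoms = 1L, atom = 1L,
                              strength = "medium", geometry = "cone")
  expect_error(virtual_points(lf, lone, lone$conformers[[1]]),
               "no neighbours")
})
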