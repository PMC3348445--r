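# Triplet counting, canonical frames, fingerprints and the greedy search.

test_that("triplet types are counted and ranked by (L, P-bar)", {
  fix <- toy_fixture()
  sys <- fix$sys
  ranked <- enumerate_and_rank_triplet_types(sys, sys$config$bins_a)
  expect_true(all(diff(ranked$L) <= 0))
  # within equal L, P-bar is non-increasing
  for (l in unique(ranked$L)) {
    pb <- ranked$P_bar[ranked$L == l]
    expect_true(all(diff(pb) <= 1e-12))
  }
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  # M = number of types occurring in all ligands; those occupy the top ranks
  M <- attr(ranked, "M")
  expect_true(all(ranked$L[seq_len(M)] == sys$nlig))
  # exhaustive-count oracle: recount L and P-bar per type directly
  for (r in seq_len(min(3, nrow(ranked)))) {
    code <- ranked$code[r]
    per_lig <- vapply(seq_len(sys$nlig), function(li) {
      confs <- sys$fp[[li]]
      hits <- vapply(seq_along(confs), function(k) {
        tris <- ligover:::conformer_triplets(confs[[k]], FALSE,
                                             sys$config$bins_a)
        any(vapply(tris, `[[`, "", "code") == code)
      }, logical(1))
      mean(hits)
    }, numeric(1))
    expect_equal(ranked$P_bar[r], mean(per_lig), tolerance = 1e-12)
    expect_identical(ranked$L[r], sum(per_lig > 0))
  }
  # two identical rigid ligands: every type has L = 2 and P-bar = 1
  ligs <- lapply(c("x", "y"), make_swing_arm)
  sys2 <- build_system(ligs)
  r2 <- enumerate_and_rank_triplet_types(sys2, sys2$config$bins_a)
  expect_true(all(r2$L == 2L))
  expect_true(all(abs(r2$P_bar - 1) < 1e-12))
})

test_that("distance bins drop out-of-range triplets", {
  bins <- c(0.5, 3.0, 5.0)
  expect_identical(distance_bin(c(0.4, 0.5, 2.9, 3.0, 4.9, 5.0, 7), bins),
                   c(NA, 1L, 1L, 2L, 2L, 2L, NA))
})

test_that("canonical frames satisfy the placement rules", {
  set.seed(55)
  for (rep in 1:20) {
    p <- matrix(rnorm(9, sd = 3), 3, 3)
    if (ligover:::triangle_height(p) < 0.2) next
    tf <- canonical_frame(p)
    q <- apply_transform(p, tf)
    expect_lt(max(abs(colMeans(q))), 1e-9)          # centroid at origin
    expect_lt(abs(q[1, 2]), 1e-9); expect_lt(abs(q[1, 3]), 1e-9)
    expect_gt(q[1, 1], 0)                           # point 1 on +x
    expect_gte(q[2, 2], -1e-12)                     # point 2: y >= 0
    expect_lt(abs(q[2, 3]), 1e-9)                   # ... in the xy plane
    expect_equal(det(tf$R), 1, tolerance = 1e-9)
  }
  expect_error(canonical_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("canonical ordering puts acceptors before donors before hydrophobes", {
  binm <- matrix(1L, 3, 3)
  to <- ligover:::triplet_orderings(c("donor", "acceptor", "hydrophobe"), binm)
  for (p in to$orderings) expect_identical(p[1], 2L)  # the acceptor
  # equilateral all-acceptor triplet: full symmetry, 6 valid orderings
  to6 <- ligover:::triplet_orderings(rep("acceptor", 3), binm)
  expect_length(to6$orderings, 6L)
  # distinct bins: unique ordering satisfying d23 <= d13 <= d12
  bd <- matrix(0L, 3, 3)
  bd[1, 2] <- bd[2, 1] <- 3L; bd[1, 3] <- bd[3, 1] <- 2L
  bd[2, 3] <- bd[3, 2] <- 1L
  tod <- ligover:::triplet_orderings(rep("acceptor", 3), bd)
  expect_length(tod$orderings, 1L)
  expect_identical(tod$orderings[[1]], c(1L, 2L, 3L))
})

test_that("fingerprints hash non-base points with and without smearing", {
  ligs <- lapply(c("x", "y"), make_swing_arm)
  # swing-arm has 4 eligible points (2 acceptors? no: O acceptor, N donor,
  # segment) -- build both smeared and plain fingerprints on its top type
  for (smear in c(TRUE, FALSE)) {
    sys <- build_system(ligs, config = list(smear = smear))
    ranked <- enumerate_and_rank_triplet_types(sys, sys$config$bins_a)
    fp <- build_fingerprint(sys, ranked$code[1], sys$config$bins_a)
    expect_s3_class(fp, "alignment_fingerprint")
    expect_true(all(colSums(fp$bits) > 0))  # empty columns eliminated
    # rows with a single non-base point set 7 bits (smear) or 1 (plain)
    n_nonbase <- vapply(fp$rows, function(r) nrow(r$xyz), integer(1))
    ones <- rowSums(fp$bits)
    if (any(n_nonbase == 1L))
      expect_true(all(ones[n_nonbase == 1L] <= if (smear) 7L else 1L))
    if (!smear) expect_true(all(ones <= n_nonbase))
  }
})

test_that("fingerprint rows are invariant to rigid motion of a conformer", {
  lig1 <- make_swing_arm("x")
  lig2 <- make_swing_arm("y")
  tf <- ligover:::rotation_about_axis(c(0, 1, 0), c(3, 2, 1), 67)
  lig2$conformers[[1]] <- apply_transform(lig2$conformers[[1]], tf)
  sys <- build_system(list(lig1, lig2))
  ranked <- enumerate_and_rank_triplet_types(sys, sys$config$bins_a)
  expect_true(all(ranked$L == 2L))  # typing is frame-invariant
  fp <- build_fingerprint(sys, ranked$code[1], sys$config$bins_a)
  rl <- vapply(fp$rows, `[[`, integer(1), "ligand")
  r1 <- which(rl == 1L)[1]; r2 <- which(rl == 2L)[1]
  expect_identical(fp$bits[r1, ], fp$bits[r2, ])
})

# A miniature fingerprint whose rows can be enumerated exhaustively.
tiny_fingerprint <- function(nlig = 3L, rows_per_lig = 3L, ncol = 12L,
                             density = 0.35) {
  rows <- list(); bits <- list()
  for (li in seq_len(nlig)) for (r in seq_len(rows_per_lig)) {
    rows[[length(rows) + 1L]] <- list(ligand = li, conf = r,
                                      base_points = c(1L, 2L, 3L))
    bits[[length(bits) + 1L]] <- runif(ncol) < density
  }
  structure(list(bits = do.call(rbind, bits), rows = rows, colmap = NULL,
                 type_code = "tiny", grid = NULL),
            class = "alignment_fingerprint")
}

exhaustive_best_B <- function(fp, w = 2L) {
  rl <- vapply(fp$rows, `[[`, integer(1), "ligand")
  ligsets <- split(seq_along(fp$rows), rl)
  combos <- expand.grid(ligsets, KEEP.OUT.ATTRS = FALSE)
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    sel <- as.integer(combos[r, ])
    andv <- apply(fp$bits[sel, , drop = FALSE], 2, all)
    orv <- apply(fp$bits[sel, , drop = FALSE], 2, any)
    best <- max(best, w * sum(andv) - sum(orv))
  }
  best
}

test_that("greedy search scores B = wA - O and nears the exhaustive optimum", {
  # direct arithmetic: two identical rows give A = O, B = (w-1) A
  fp0 <- tiny_fingerprint(2L, 1L)
  fp0$bits[2, ] <- fp0$bits[1, ]
  fake_sys <- list(nlig = 2L, config = list(p_per_fingerprint = 1L, w = 2L))
  sol <- greedy_search(fp0, fake_sys, P = 1L, w = 2L)
  expect_equal(sol[[1]]$B, (2 - 1) * sum(fp0$bits[1, ]))
  # random tiny instances: greedy never beats exhaustive, usually matches
  set.seed(77)
  n_match <- 0L; n_tot <- 60L
  for (rep in seq_len(n_tot)) {
    fp <- tiny_fingerprint()
    fake_sys <- list(nlig = 3L, config = list(p_per_fingerprint = 9L, w = 2L))
    sols <- greedy_search(fp, fake_sys, P = 9L, w = 2L)
    gb <- max(vapply(sols, `[[`, numeric(1), "B"))
    eb <- exhaustive_best_B(fp)
    expect_lte(gb, eb)
    if (gb == eb) n_match <- n_match + 1L
    # every emitted B at least matches a random row combination on average
  }
  expect_gte(n_match / n_tot, 0.9)
})

test_that("generation pools both bin schemes and recovers planted triplets", {
  fix <- toy_fixture()
  set.seed(5)
  pool <- generate_overlays(fix$sys)
  st <- attr(pool, "stats")
  expect_lte(st$pool_size,
             2 * fix$sys$config$n_max * fix$sys$config$p_per_fingerprint)
  expect_gte(st$fingerprints, 1L)
  # at least one chromosome decodes to the planted overlay (base triplet
  # superimposes the planted features within the fingerprint grid)
  ok <- FALSE
  for (s in pool) {
    ov <- try(decode_chromosome(s$chromosome, fix$sys), silent = TRUE)
    if (inherits(ov, "try-error")) next
    sc <- score_against_truth(ov, fix$ts$truth)
    if (all(unlist(sc$R) < 1.5)) { ok <- TRUE; break }
  }
  expect_true(ok)
  # no shared triplet type: two far-apart-featured ligands
  small <- make_nitrile("a")
  big <- make_swing_arm("b")
  sys2 <- build_system(list(small, big))
  expect_error(generate_overlays(sys2), "stepwise|no common base triplet")
})

test_that("constrained generation superimposes the constraint points", {
  fix <- toy_fixture()
  ligs <- fix$ts$ligands
  # constrain on the amine nitrogen of each toy ligand
  sets <- stats::setNames(lapply(ligs, function(l)
    list(`constraint:amine` = 8L)), vapply(ligs, `[[`, "", "id"))
  sys <- build_system(ligs, config = list(n_max = 4L,
                                          p_per_fingerprint = 10L),
                      custom_atom_sets = sets)
  set.seed(9)
  pool <- constrained_generation(sys)
  expect_gt(length(pool), 0L)
  h <- sys$config$grid_spacing
  for (s in pool[seq_len(min(25, length(pool)))]) {
    ov <- try(decode_chromosome(s$chromosome, sys), silent = TRUE)
    if (inherits(ov, "try-error")) next
    pts <- overlay_points(ov, kinds = "constraint")
    expect_identical(nrow(pts$xyz), 3L)
    expect_lt(max(stats::dist(pts$xyz)), 2 * h)
  }
  # a ligand without the constraint feature is an error
  sets2 <- sets; sets2[[1]] <- list()
  sys2 <- build_system(ligs, custom_atom_sets = sets2)
  expect_error(generate_overlays(sys2, constraint = TRUE),
               "constraint feature on every ligand")
})

test_that("supermolecule merging averages close points, keeps distant ones", {
  fix <- toy_fixture()
  ov <- true_toy_overlay(fix)
  sm <- merge_to_supermolecule(list(ov))
  expect_s3_class(sm, "supermolecule")
  expect_length(sm$fp, 1L)
  # merged point count at least matches the largest single ligand
  per_lig <- vapply(ov$fp, function(f)
    sum(f$meta$role %in% c("atom_site", "hydrophobe_centroid",
                           "custom_centroid")), integer(1))
  expect_gte(nrow(sm$fp[[1]]$meta), max(per_lig))
  # planted coincident features merged into single points (3 contributors)
  expect_true(any(sm$fp[[1]]$meta$n_merged == 3L))
  # two same-kind points 2 A apart are never merged
  a <- make_nitrile("p", origin = c(0, 0, 0))
  b <- make_nitrile("q", origin = c(2, 0, 0))
  sysn <- build_system(list(a, b))
  ovn <- new_overlay(sysn, lapply(list(a, b), function(l)
    list(conf = 1L, coords = l$conformers[[1]])))
  smn <- merge_to_supermolecule(list(ovn))
  acc <- smn$fp[[1]]$meta$kind == "acceptor"
  expect_identical(sum(acc), 2L)
  # coincident acceptors merge to the midpoint
  c2 <- make_nitrile("r", origin = c(0.6, 0, 0))
  sys2 <- build_system(list(a, c2))
  ov2 <- new_overlay(sys2, lapply(list(a, c2), function(l)
    list(conf = 1L, coords = l$conformers[[1]])))
  sm2 <- merge_to_supermolecule(list(ov2))
  acc2 <- which(sm2$fp[[1]]$meta$kind == "acceptor")
  expect_length(acc2, 1L)
  expect_equal(sm2$fp[[1]]$xyz[acc2, ], c(0.3, 0, 0), tolerance = 1e-9)
})
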