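# Shared fixture builders. Everything is constructed in code; nothing is
# read from disk except via the package's own writers.

hex_ring_xyz <- function(r = 1.39) {
  t(sapply(0:5, function(k) c(r * cos(k * pi / 3), r * sin(k * pi / 3), 0)))
}

make_benzene <- function(id = "benzene") {
  new_ligand(id, rep("C", 6),
             data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
             list(hex_ring_xyz()))
}

make_butane <- function(id = "butane") {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(3.5, 1.5, 0.2))
  new_ligand(id, rep("C", 4), data.frame(i = 1:3, j = 2:4, order = 1),
             list(xyz))
}

# CH3-C#N with the nitrile N at `origin`
make_nitrile <- function(id, origin = c(0, 0, 0), axis = c(1, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  xyz <- rbind(origin - 2.7 * u, origin - 1.2 * u, origin)
  new_ligand(id, c("C", "C", "N"),
             data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 3)),
             list(xyz))
}

# phenol with explicit hydroxyl H
make_phenol <- function(id = "phenol") {
  xyz <- rbind(hex_ring_xyz(), c(2.75, 0, 0), c(3.3, 0.8, 0))
  new_ligand(id, c(rep("C", 6), "O", "H"),
             data.frame(i = c(1:6, 1, 7), j = c(2:6, 1, 7, 8),
                        order = c(2, 1, 2, 1, 2, 1, 1, 1)),
             list(xyz))
}

# a ketone arm with an amine: one rotatable bond (C2-C3); four fitting
# points (carbonyl O acceptor, amine N donor, two methyl segments)
make_swing_arm <- function(id, torsion = NULL) {
  xyz <- rbind(c(-1.1, 0.6, 0),     # O (=C)
               c(0, 0, 0),          # C2 sp2
               c(1.5, 0, 0),        # C3 sp3
               c(2.1, 1.35, 0),     # N
               c(1.8, 1.9, 0.75),   # H
               c(3.05, 1.3, -0.1),  # H
               c(2.1, -0.8, 1.1),   # C7 methyl on C3
               c(-0.75, -1.3, 0))   # C8 methyl on C2 (in the sp2 plane)
  lig <- new_ligand(id, c("O", "C", "C", "N", "H", "H", "C", "C"),
                    data.frame(i = c(1, 2, 3, 4, 4, 3, 2),
                               j = c(2, 3, 4, 5, 6, 7, 8),
                               order = c(2, 1, 1, 1, 1, 1, 1)),
                    list(xyz))
  if (!is.null(torsion)) {
    rots <- perceive_rotatable_bonds(lig)
    lig$conformers[[1]] <- drive_torsions(xyz, rots, torsion)
  }
  lig
}

# cached default toy set + small-search system shared across test files
toy_cache <- new.env()
toy_fixture <- function() {
  if (is.null(toy_cache$ts)) {
    toy_cache$ts <- make_toy_set(toy_spec())
    toy_cache$sys <- build_system(
      toy_cache$ts$ligands,
      config = list(n_max = 6L, p_per_fingerprint = 20L))
  }
  list(ts = toy_cache$ts, sys = toy_cache$sys)
}

true_toy_overlay <- function(fix) {
  new_overlay(fix$sys, lapply(seq_along(fix$ts$ligands), function(k)
    list(conf = fix$ts$truth$conformers[k],
         coords = fix$ts$truth$coords[[k]])))
}

# independent Kabsch oracle: Horn's closed-form quaternion method
horn_rmsd <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(src))
}

# a ring + off-axis amine + benzyl-ether arm tipped with a nitrile: the
# arm torsion about the ring-O bond defines two conformer families that
# rearrange several probe atoms (D_G > 0.2 between families) while the
# mapped features stay put
make_flex_ligand <- function(id) {
  ring <- hex_ring_xyz()
  u2 <- ring[2, ] / sqrt(sum(ring[2, ]^2))
  Ca <- ring[2, ] + 1.50 * u2
  nd <- c(0.2, 0.55, 0.81); nd <- nd / sqrt(sum(nd^2))
  N <- Ca + 1.47 * nd
  H1 <- N + 1.01 * c(0.55, 0.45, 0.7)
  H2 <- N + 1.01 * c(0.2, -0.3, -0.93)
  Oe <- ring[4, ] + 1.36 * ring[4, ] / sqrt(sum(ring[4, ]^2))
  C1 <- Oe + 1.43 * c(-0.62, 0.71, 0.33)
  r2dir <- c(-0.55, 0.45, 0.7); r2dir <- r2dir / sqrt(sum(r2dir^2))
  r2cen <- C1 + 2.89 * r2dir
  b1 <- r2dir; b2 <- c(-b1[2], b1[1], 0); b2 <- b2 / sqrt(sum(b2^2))
  ring2 <- t(sapply(0:5, function(k)
    r2cen + 1.39 * (cos(k * pi / 3 + pi) * b1 + sin(k * pi / 3 + pi) * b2)))
  u16 <- (ring2[4, ] - r2cen) / 1.39
  Cn <- ring2[4, ] + 1.43 * u16
  Nn <- Cn + 1.16 * u16
  elements <- c(rep("C", 6), "C", "N", "H", "H", "O", "C", rep("C", 6),
                "C", "N")
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 2, 7, 8, 8, 4, 11, 12, 13, 14, 15, 16, 17, 18,
          16, 19),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18,
          13, 19, 20),
    order = c(2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 2, 1, 2, 1, 2, 1, 1, 3))
  new_ligand(id, elements, bonds,
             list(rbind(ring, Ca, N, H1, H2, Oe, C1, ring2, Cn, Nn)))
}

# the two family reference overlays of a flex-ligand pair: as built, and
# with the arm torsion (about the ring-O bond) flipped by 180 degrees
flex_family_refs <- function(sys) {
  rots <- sys$rotors[[1]]
  arm <- which(vapply(rots, function(rb)
    all(sort(c(rb$i, rb$j)) == c(4L, 11L)), logical(1)))
  base_t <- measure_torsions(sys$ligands[[1]]$conformers[[1]], rots)
  flip_t <- base_t
  flip_t[arm] <- ((flip_t[arm] + 180 + 180) %% 360) - 180
  mk <- function(tv) new_overlay(sys, lapply(seq_len(sys$nlig), function(li)
    list(conf = 1L,
         coords = drive_torsions(sys$ligands[[li]]$conformers[[1]],
                                 sys$rotors[[li]], tv))))
  list(a = mk(base_t), b = mk(flip_t))
}
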