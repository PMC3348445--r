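## Synthetic toy-ligand generator.
##
## Builds small para-disubstituted benzene scaffolds carrying an amine donor
## and a carbonyl acceptor, so that every ligand realises the same planted
## pharmacophore (donor, acceptor, ring hydrophobe) in one "true" conformer.
## Decoy substituents (a ring methyl, an anisole-type ether acceptor)
## distinguish the ligands, and conformers are enumerated on a torsion grid
## so the true binding conformer is guaranteed present. The generator
## returns the ground truth (true overlay, pharmacophore-point groups)
## needed for recovery scoring.

#' Specification of a synthetic toy set
#'
#' @param n_ligands 2 to 4 (default 3).
#' @param planted_kinds which planted points all ligands share; a spec with
#'   fewer than three planted points is emitted with a "stepwise required"
#'   truth flag.
#' @param grid_step torsion-grid step in degrees (default 120, so the true
#'   conformer is one of the enumerated grid points).
#' @param decoys add distinguishing decoy substituents (default TRUE).
#' @param seed integer seed controlling the (deterministic) construction.
#' @export
toy_spec <- function(n_ligands = 3L,
                     planted_kinds = c("donor", "acceptor", "hydrophobe"),
                     grid_step = 120, decoys = TRUE, seed = 1L) {
  stopifnot(n_ligands >= 2L, n_ligands <= 4L,
            all(planted_kinds %in% c("donor", "acceptor", "hydrophobe")))
  structure(list(n_ligands = as.integer(n_ligands),
                 planted_kinds = planted_kinds, grid_step = grid_step,
                 decoys = isTRUE(decoys), seed = as.integer(seed)),
            class = "toy_spec")
}

## Scaffold geometry (Angstrom). Ring centred at the origin in the xy
## plane; amine chain off ring atom 1 (+x), carbonyl off the para atom.
toy_scaffold <- function(variant = 1L) {
  ring <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
  Ca <- c(2.89, 0, 0)
  N <- Ca + 1.47 * c(cos(70.5 * DEG), sin(70.5 * DEG), 0)
  H1 <- N + 1.01 * unit(c(0.9, 0.35, 0.35))
  H2 <- N + 1.01 * unit(c(0.15, -0.25, 0.95))
  Cc <- c(-2.89, 0, 0)
  O <- Cc + 1.23 * c(-0.5, 0.866, 0)
  elements <- c(rep("C", 6), "C", "N", "H", "H", "C", "O")
  coords <- rbind(ring, Ca, N, H1, H2, Cc, O)
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 8, 4, 11),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12),
    order = c(2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 1, 2))
  if (variant == 2L) {           # ring methyl decoy on atom 2
    coords <- rbind(coords, ring[2, ] + 1.50 * unit(ring[2, ]))
    elements <- c(elements, "C")
    bonds <- rbind(bonds, data.frame(i = 2, j = 13, order = 1))
  } else if (variant == 3L) {    # anisole-type ether decoy on atom 5
    Oe <- ring[5, ] + 1.36 * unit(ring[5, ])
    Cm <- Oe + 1.43 * unit(Oe + c(0.3, -1.2, 0.4))
    coords <- rbind(coords, Oe, Cm)
    elements <- c(elements, "O", "C")
    bonds <- rbind(bonds, data.frame(i = c(5, 13), j = c(13, 14),
                                     order = 1))
  } else if (variant == 4L) {    # both decoys
    coords <- rbind(coords, ring[2, ] + 1.50 * unit(ring[2, ]))
    Oe <- ring[5, ] + 1.36 * unit(ring[5, ])
    Cm <- Oe + 1.43 * unit(Oe + c(0.3, -1.2, 0.4))
    coords <- rbind(coords, Oe, Cm)
    elements <- c(elements, "C", "O", "C")
    bonds <- rbind(bonds, data.frame(i = c(2, 5, 14), j = c(13, 14, 15),
                                     order = 1))
  }
  list(elements = elements, coords = coords, bonds = bonds,
       donor_atom = 8L, acceptor_atom = 12L, ring_atoms = 1:6)
}

#' Build a synthetic toy set with a known true overlay
#'
#' @param spec a [toy_spec()].
#' @param dir optional directory; when given, one SD file per ligand plus a
#'   `truth.json` are written there.
#' @return List with `ligands` (multi-conformer, true conformer included in
#'   the grid), `truth` (planted pharmacophore-point groups with per-ligand
#'   atoms and true positions, true conformer indices and coordinates,
#'   `stepwise_required` flag) and, when written, `files`.
#' @export
make_toy_set <- function(spec = toy_spec(), dir = NULL) {
  rules <- default_rotatable_rules()
  ligands <- list()
  truth_states <- list()
  two_point <- length(spec$planted_kinds) < 3L
  for (k in seq_len(spec$n_ligands)) {
    variant <- if (spec$decoys) k else 1L
    sc <- toy_scaffold(variant)
    coords <- sc$coords
    if (two_point && k > 1L) {
      # only donor and acceptor are planted: spin each ligand about the
      # N-O axis so the ring centroids do not coincide across ligands
      tf <- rotation_about_axis(coords[sc$donor_atom, ],
                                coords[sc$acceptor_atom, ], 70 * (k - 1L))
      fixed <- c(sc$donor_atom, sc$acceptor_atom)
      move <- setdiff(seq_len(nrow(coords)), fixed)
      coords[move, ] <- apply_transform(coords[move, , drop = FALSE], tf)
    }
    lig1 <- new_ligand(sprintf("toy%d", k), sc$elements, sc$bonds,
                       list(coords))
    rots <- perceive_rotatable_bonds(lig1, rules)
    base <- measure_torsions(coords, rots)
    offs <- expand.grid(rep(list(c(-spec$grid_step, 0, spec$grid_step)),
                            length(rots)))
    confs <- lapply(seq_len(nrow(offs)), function(r) {
      vals <- ((base + as.numeric(offs[r, ]) + 180) %% 360) - 180
      drive_torsions(coords, rots, vals)
    })
    true_conf <- which(rowSums(abs(offs)) == 0)[1]
    lig <- new_ligand(sprintf("toy%d", k), sc$elements, sc$bonds, confs)
    ligands[[k]] <- lig
    truth_states[[k]] <- list(conf = true_conf, coords = coords,
                              donor_atom = sc$donor_atom,
                              acceptor_atom = sc$acceptor_atom,
                              ring_atoms = sc$ring_atoms)
  }
  groups <- list()
  if ("donor" %in% spec$planted_kinds)
    groups$donor <- list(kind = "donor",
      atoms = lapply(truth_states, function(s) s$donor_atom))
  if ("acceptor" %in% spec$planted_kinds)
    groups$acceptor <- list(kind = "acceptor",
      atoms = lapply(truth_states, function(s) s$acceptor_atom))
  if ("hydrophobe" %in% spec$planted_kinds)
    groups$hydrophobe <- list(kind = "hydrophobe",
      atoms = lapply(truth_states, function(s) s$ring_atoms))
  for (g in names(groups))
    groups[[g]]$positions <- lapply(seq_along(truth_states), function(k)
      group_position(truth_states[[k]]$coords, groups[[g]]$atoms[[k]]))
  truth <- list(groups = groups,
                conformers = vapply(truth_states, `[[`, integer(1), "conf"),
                coords = lapply(truth_states, `[[`, "coords"),
                stepwise_required = two_point)
  out <- list(ligands = ligands, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_along(ligands), function(k) {
      f <- file.path(dir, sprintf("toy%d.sdf", k))
      write_ligands(ligands[[k]], f)
      f
    }, character(1))
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(schema = "ligover-truth/1",
           stepwise_required = truth$stepwise_required,
           conformers = truth$conformers,
           groups = lapply(truth$groups, function(g) list(
             kind = g$kind, atoms = g$atoms,
             positions = lapply(g$positions, as.numeric)))),
      tj, auto_unbox = TRUE, digits = NA)
    out$files <- c(files, tj)
  }
  out
}

## A group's representative position: the atom itself for donor/acceptor
## (single atom), the centroid dummy for hydrophobes.
group_position <- function(coords, atoms) {
  if (length(atoms) == 1L) coords[atoms, ] else
    colMeans(coords[atoms, , drop = FALSE])
}

#' Score a predicted overlay against the planted truth
#'
#' For each pharmacophore-point group i, R_i is the rmsd after
#' least-squares fitting the group's true positions (donor/acceptor atoms,
#' hydrophobe-centroid dummies; one per ligand) onto the corresponding
#' positions in the predicted overlay. R_total uses the union of all group
#' positions in a single fit. Small R_i for every group means the feature
#' mapping is correct; a small R_total as well means the conformations also
#' match.
#'
#' @param overlay predicted `overlay` (same ligand order as the toy set).
#' @param truth the `truth` element from [make_toy_set()].
#' @return List with `R` (named per group, NA when a group is missing from
#'   the prediction) and `R_total`.
#' @export
score_against_truth <- function(overlay, truth) {
  nlig <- length(truth$coords)
  if (length(overlay$states) != nlig)
    stop("prediction and truth cover different ligand sets")
  Rs <- numeric(0)
  all_true <- list(); all_pred <- list()
  for (g in names(truth$groups)) {
    grp <- truth$groups[[g]]
    true_pts <- do.call(rbind, grp$positions)
    pred_pts <- t(vapply(seq_len(nlig), function(k) {
      atoms <- grp$atoms[[k]]
      cs <- overlay$states[[k]]$coords
      if (any(unlist(atoms) > nrow(cs))) return(c(NA_real_, NA, NA))
      group_position(cs, unlist(atoms))
    }, numeric(3)))
    if (anyNA(pred_pts)) { Rs[g] <- NA_real_; next }
    Rs[g] <- kabsch_fit(true_pts, pred_pts)$rmsd
    all_true[[g]] <- true_pts; all_pred[[g]] <- pred_pts
  }
  R_total <- if (length(all_true))
    kabsch_fit(do.call(rbind, all_true), do.call(rbind, all_pred))$rmsd
  else NA_real_
  list(R = Rs, R_total = R_total)
}
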