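## The ligand system: shared, precomputed context for a set of ligands.
##
## Features, rotatable bonds and per-conformer fitting points are computed
## once and shared (via an environment) by every overlay built from the set.

#' Default run configuration
#'
#' All tunable parameters with their standard values: distance-bin schemes,
#' fingerprint grid 1.5 A, volume grid 0.5 A, at most 25 fingerprints per bin
#' scheme, 200 solutions per fingerprint, AND-weight w = 2, Pareto rank
#' threshold 5, best-30 percent score constraints on V and HB, at most 20
#' final solutions with minimum consensus dissimilarity 0.05.
#' @export
default_config <- function() {
  list(
    bins_a = c(0.5, 3.0, 5.0, 7.0, 9.0, 11.0, 13.0),
    bins_b = c(0.5, 3.5, 6.0, 8.5, 11.5, 13.5),
    grid_spacing = 1.5,
    smear = TRUE,
    n_max = 25L,
    p_per_fingerprint = 200L,
    w = 2L,
    use_normals = FALSE,
    triplet_kinds = c("donor", "acceptor", "hydrophobe_dir",
                      "hydrophobe_nondir", "constraint"),
    volume_grid = 0.5,
    hb_distance = 2.9,
    vp_n_points = 12L,
    vp_arc_points = 5L,
    vp_cone_half_angle = 60,
    cluster_dist = 1.5,
    pareto_rank_max = 5L,
    constraint_percentile = 30,
    max_solutions = 20L,
    min_dissimilarity = 0.05,
    objectives = c("V", "HB", "HY"),
    seed = 1L
  )
}

#' Build a ligand system
#'
#' Precomputes features, rotatable bonds and fitting points for every
#' conformer of every ligand. The returned environment is shared by all
#' overlays of the set.
#'
#' @param ligands list of `ligand` objects (see [read_ligands()]).
#' @param config see [default_config()]; partial lists are merged over the
#'   defaults.
#' @param feature_defs,rotatable_rules definition files or lists; shipped
#'   defaults when NULL.
#' @param excluded_atoms,custom_atom_sets per-ligand lists keyed by ligand
#'   id (see [assign_features()]).
#' @export
build_system <- function(ligands, config = list(), feature_defs = NULL,
                         rotatable_rules = NULL,
                         excluded_atoms = list(), custom_atom_sets = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(feature_defs)) feature_defs <- default_feature_defs()
  if (is.null(rotatable_rules)) rotatable_rules <- default_rotatable_rules()
  sys <- new.env(parent = emptyenv())
  sys$ligands <- ligands
  sys$config <- cfg
  sys$nlig <- length(ligands)
  sys$ids <- vapply(ligands, `[[`, "", "id")
  sys$features <- lapply(ligands, function(lig)
    ligand_features(lig, feature_defs,
                    excluded_atoms = excluded_atoms[[lig$id]] %||% integer(0),
                    custom_atom_sets = custom_atom_sets[[lig$id]] %||% list()))
  sys$rotors <- lapply(ligands, perceive_rotatable_bonds,
                       rules = rotatable_rules)
  sys$fp <- lapply(seq_along(ligands), function(li)
    lapply(ligands[[li]]$conformers, function(xyz)
      place_fitting_points(sys$features[[li]], xyz,
                           use_normals = cfg$use_normals)))
  sys$vdw <- utils::read.csv(pkg_extdata("tripos_minimal.csv"))
  sys$torsion_params <- utils::read.csv(pkg_extdata("tripos_torsions.csv"))
  sys$atom_types <- lapply(ligands, tripos_atom_types)
  class(sys) <- c("ligand_system", "environment")
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Locate a shipped data file (works from a source checkout too).
pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "ligover")
  if (nzchar(p)) p else file.path("inst", "extdata", file)
}

#' @export
print.ligand_system <- function(x, ...) {
  cat(sprintf("<ligand system: %d ligands (%s), %s conformers>\n", x$nlig,
              paste(x$ids, collapse = ", "),
              paste(vapply(x$ligands, function(l) length(l$conformers),
                           integer(1)), collapse = "/")))
  invisible(x)
}

## Simple Tripos-style atom typing from element + bond orders.
tripos_atom_types <- function(lig) {
  vapply(seq_len(lig$natoms), function(a) {
    el <- lig$elements[a]
    sel <- lig$bonds$i == a | lig$bonds$j == a
    ords <- lig$bonds$order[sel]; arom <- any(lig$bonds$aromatic[sel])
    switch(el,
      C = if (arom) "C.ar" else if (any(ords == 3)) "C.1"
          else if (any(ords == 2)) "C.2" else "C.3",
      N = if (arom) "N.ar" else if (lig$charges[a] > 0) "N.4"
          else if (any(ords == 3)) "N.1"
          else if (any(ords == 2)) "N.2" else "N.3",
      O = if (lig$charges[a] < 0) "O.co2"
          else if (any(ords == 2)) "O.2" else "O.3",
      S = if (any(ords == 2)) "S.2" else "S.3",
      P = "P.3",
      el)
  }, character(1))
}

#' Construct an overlay
#'
#' An overlay is one positioned conformation per ligand of a system; fitting
#' points in the overlay frame are cached on construction.
#'
#' @param system from [build_system()].
#' @param states list (one per ligand) of `list(conf = conformer index,
#'   coords = n x 3 matrix)`.
#' @param chromosome optional provenance.
#' @export
new_overlay <- function(system, states, chromosome = NULL) {
  fps <- lapply(seq_along(states), function(li)
    place_fitting_points(system$features[[li]], states[[li]]$coords,
                         use_normals = system$config$use_normals))
  structure(list(system = system, states = states, fp = fps,
                 chromosome = chromosome), class = "overlay")
}

#' @export
print.overlay <- function(x, ...) {
  sc <- attr(x, "scores")
  cat(sprintf("<overlay of %d ligands%s>\n", length(x$states),
              if (is.null(sc)) "" else paste0(": ",
                paste(sprintf("%s=%.2f", names(sc), sc), collapse = " "))))
  invisible(x)
}

## All fitting points of an overlay as one table.
overlay_points <- function(overlay, roles = NULL, kinds = NULL) {
  xs <- list(); meta <- list()
  for (li in seq_along(overlay$fp)) {
    f <- overlay$fp[[li]]
    keep <- rep(TRUE, nrow(f$meta))
    if (!is.null(roles)) keep <- keep & f$meta$role %in% roles
    if (!is.null(kinds)) keep <- keep & f$meta$kind %in% kinds
    if (!any(keep)) next
    xs[[length(xs) + 1L]] <- f$xyz[keep, , drop = FALSE]
    mm <- f$meta[keep, , drop = FALSE]
    mm$ligand <- li
    mm$point <- which(keep)   # fitting-point index within the ligand
    meta[[length(meta) + 1L]] <- mm
  }
  if (!length(xs)) return(list(xyz = matrix(numeric(0), 0, 3),
                               meta = data.frame()))
  list(xyz = do.call(rbind, xs), meta = do.call(rbind, meta))
}
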