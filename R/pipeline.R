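## End-user orchestration: the full generate -> filter (-> refine/multiply)
## pipeline with reproducible seeding, stage-level logging and a run
## manifest, plus exporters for solution sets (SD with score tags, JSON,
## TSV dissimilarity matrices and MDS coordinates).

#' Run the overlay pipeline
#'
#' Builds the ligand system, generates the chromosome pool with the
#' alignment-fingerprint algorithm, filters it to a ranked diverse solution
#' set, and optionally writes all artifacts (solutions JSON, per-solution SD
#' files, manifest) to `out_dir`. All randomness is governed by
#' `config$seed`; a rerun with the same inputs and config is
#' digest-identical.
#'
#' @param ligands list of `ligand` objects or paths to SD files.
#' @param config partial [default_config()] override list.
#' @param constraint use constrained generation (see [generate_overlays()]).
#' @param refine also anneal each selected solution with
#'   [refine_overlay()] using `refine_config`.
#' @param refine_config an [anneal_config()].
#' @param out_dir optional output directory.
#' @param ... passed to [build_system()] (feature_defs, rotatable_rules,
#'   excluded_atoms, custom_atom_sets).
#' @return The `solution_set`, with the manifest in attribute `"manifest"`.
#' @export
run_pipeline <- function(ligands, config = list(), constraint = FALSE,
                         refine = FALSE, refine_config = anneal_config(),
                         out_dir = NULL, ...) {
  input_digest <- NULL
  if (is.character(ligands)) {
    input_digest <- tools::md5sum(ligands)
    ligands <- read_ligands(ligands)
  }
  system <- build_system(ligands, config, ...)
  cfg <- system$config
  set.seed(cfg$seed)
  message(sprintf("system: %d ligands, %s conformers", system$nlig,
                  paste(vapply(ligands, function(l) length(l$conformers),
                               integer(1)), collapse = "/")))
  pool <- generate_overlays(system, constraint = constraint)
  gs <- attr(pool, "stats")
  message(sprintf("generation: %d fingerprints, pool %d",
                  gs$fingerprints, gs$pool_size))
  sols <- filter_overlays(system, pool)
  fs <- attr(sols, "stats")
  message(sprintf("filtering: %d rank survivors, %d selected",
                  fs$rank_survivors, fs$selected))
  if (refine) {
    for (i in seq_along(sols)) {
      rf <- refine_overlay(sols[[i]]$overlay, refine_config)
      sols[[i]]$overlay <- rf$overlay
      sols[[i]]$chromosome <- rf$chromosome %||% sols[[i]]$chromosome
      sols[[i]]$F_refined <- rf$F
    }
  }
  manifest <- list(
    package = "ligover",
    version = as.character(utils::packageVersion("ligover")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    inputs = if (is.null(input_digest)) ligand_digests(ligands)
             else as.list(input_digest),
    generation = gs,
    filtering = fs)
  attr(sols, "manifest") <- manifest
  if (!is.null(out_dir)) write_solution_set(sols, system, out_dir)
  sols
}

ligand_digests <- function(ligands) {
  lapply(ligands, function(l) {
    con <- textConnection(paste(c(l$elements, unlist(l$conformers)),
                                collapse = ","))
    on.exit(close(con))
    as.character(sum(utf8ToInt(paste(l$id, l$natoms,
                                     signif(sum(unlist(l$conformers)), 12)))))
  })
}

#' Write a solution set to disk
#'
#' Emits `solutions.json` (chromosomes, scores, ranks, schema-versioned),
#' one multi-molecule SD file per solution with per-molecule score tags,
#' and `manifest.json`.
#'
#' @param solutions a `solution_set`.
#' @param system the ligand system the solutions belong to.
#' @param dir output directory (created if needed).
#' @export
write_solution_set <- function(solutions, system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(
    schema = "ligover-solutions/1",
    objectives = attr(solutions, "objectives"),
    solutions = lapply(seq_along(solutions), function(i) {
      s <- solutions[[i]]
      list(index = i, scores = as.list(s$scores),
           pareto_rank = s$pareto_rank, borda = s$borda,
           chromosome = jsonlite::fromJSON(
             chromosomes_to_json(s$chromosome),
             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)$solutions[[1]])
    }))
  jsonlite::write_json(doc, file.path(dir, "solutions.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(solutions))
    export_overlay_sd(solutions[[i]]$overlay,
                      file.path(dir, sprintf("solution_%02d.sdf", i)),
                      scores = solutions[[i]]$scores)
  mf <- attr(solutions, "manifest")
  if (!is.null(mf))
    jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export an overlay as a multi-molecule SD file
#'
#' One record per ligand, positioned in the overlay frame, with the score
#' vector attached as SD data fields.
#'
#' @param overlay an `overlay`.
#' @param path output SD file.
#' @param scores optional named numeric vector written as data fields.
#' @export
export_overlay_sd <- function(overlay, path, scores = NULL) {
  sys <- overlay$system
  ligs <- lapply(seq_len(sys$nlig), function(li) {
    lig <- sys$ligands[[li]]
    lig$conformers <- list(overlay$states[[li]]$coords)
    lig
  })
  data <- if (is.null(scores)) NULL else
    as.list(stats::setNames(sprintf("%.4f", scores), names(scores)))
  write_ligands(ligs, path, data = data)
}

#' Compare the overlays of a solution set
#'
#' Writes the three dissimilarity matrices (D_P, D_G, D_C) as TSV and a
#' SMACOF embedding (per coefficient) as TSV with the objective scores
#' appended for colouring.
#'
#' @param solutions a `solution_set`.
#' @param dir output directory.
#' @param dims embedding dimensionality (2).
#' @return Invisibly, a list with the matrices and embeddings.
#' @export
compare_solutions <- function(solutions, dir = NULL, dims = 2L) {
  out <- list()
  scores <- do.call(rbind, lapply(solutions, `[[`, "scores"))
  for (coef in c("D_P", "D_G", "D_C")) {
    m <- dissimilarity_matrix(solutions, coef)
    emb <- mds_map(m, dims = dims)
    out[[coef]] <- list(matrix = m, mds = emb)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(m, file.path(dir, paste0(coef, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      tab <- data.frame(solution = seq_len(nrow(emb$coords)), emb$coords)
      names(tab)[-1] <- paste0("dim", seq_len(dims))
      tab <- cbind(tab, scores)
      utils::write.table(tab, file.path(dir, paste0("mds_", coef, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out)
}

#' Plot a solution-set embedding
#'
#' Scatter plot of the 2D SMACOF embedding under the chosen coefficient,
#' points shaded by an objective score.
#'
#' @param x a `solution_set`.
#' @param coefficient "D_C", "D_P" or "D_G".
#' @param colour_by objective name (default first objective).
#' @param ... passed to [graphics::plot()].
#' @export
plot.solution_set <- function(x, coefficient = "D_C", colour_by = NULL,
                              ...) {
  m <- dissimilarity_matrix(x, coefficient)
  emb <- mds_map(m, dims = 2L)
  scores <- do.call(rbind, lapply(x, `[[`, "scores"))
  if (is.null(colour_by)) colour_by <- colnames(scores)[1]
  v <- scores[, colour_by]
  pal <- grDevices::hcl.colors(16, "viridis")
  col <- pal[cut(v, breaks = 16, labels = FALSE, include.lowest = TRUE)]
  graphics::plot(emb$coords[, 1], emb$coords[, 2], pch = 19, col = col,
                 xlab = "dimension 1", ylab = "dimension 2",
                 main = sprintf("overlay map (%s, coloured by %s)",
                                coefficient, colour_by), ...)
  graphics::text(emb$coords[, 1], emb$coords[, 2],
                 labels = seq_along(x), pos = 3, cex = 0.7)
  invisible(emb)
}
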