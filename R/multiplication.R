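## Overlay multiplication: a multi-objective genetic algorithm exploring
## alternative ligand conformations under a fixed feature mapping. The
## mapping table extracted from a seed overlay is conserved in every
## chromosome; variation comes from torsion mutations, single-ligand torsion
## crossovers and small rigid-body mutations. Selection is Pareto-based on
## (V, HB, HY, E) with niching on a crude squared-distance-matrix
## dissimilarity to preserve geometric diversity.

#' MOGA configuration
#'
#' @param population,children population size and children per generation
#'   (both 150).
#' @param generations number of generations (default 100).
#' @param p_torsion_mutation,p_torsion_crossover,p_rigid_mutation operator
#'   probabilities (0.4 / 0.3 / 0.3).
#' @param tournament_size parent-selection tournament (2).
#' @param niche_threshold crude-dissimilarity radius defining a niche
#'   (1.0 A^2) and `niche_capacity` chromosomes allowed per niche (2).
#' @param torsion_step,translate_step,rotate_step rigid/torsion move
#'   magnitudes as in refinement.
#' @param seed integer seed.
#' @export
moga_config <- function(population = 150L, children = 150L,
                        generations = 100L, p_torsion_mutation = 0.4,
                        p_torsion_crossover = 0.3, p_rigid_mutation = 0.3,
                        tournament_size = 2L, niche_threshold = 1.0,
                        niche_capacity = 2L, torsion_step = 30,
                        translate_step = 0.25, rotate_step = 5, seed = 1L) {
  stopifnot(population > 0L, children > 0L)
  list(population = population, children = children,
       generations = generations,
       p_ops = c(torsion_mutation = p_torsion_mutation,
                 torsion_crossover = p_torsion_crossover,
                 rigid_mutation = p_rigid_mutation),
       tournament_size = tournament_size, niche_threshold = niche_threshold,
       niche_capacity = niche_capacity, torsion_step = torsion_step,
       translate_step = translate_step, rotate_step = rotate_step,
       seed = seed)
}

#' Build a mapping table from an overlay's pharmacophore
#'
#' One column per pharmacophore point (full and partial) found by cluster
#' analysis of the overlay's fitting points, with missing markers where a
#' ligand does not contribute. The table decodes back to the source
#' overlay's geometry.
#'
#' @param overlay an `overlay`.
#' @param min_ligands minimum contributors per point (default 2).
#' @return An integer mapping matrix (ligands x points, NA = missing).
#' @export
build_mapping_from_overlay <- function(overlay, min_ligands = 2L) {
  pharm <- extract_pharmacophore(overlay, min_ligands)
  if (!length(pharm))
    stop("overlay has no pharmacophore points; nothing to preserve")
  nlig <- length(overlay$states)
  mapping <- matrix(NA_integer_, nlig, length(pharm))
  for (p in seq_along(pharm)) {
    con <- pharm[[p]]$contributors
    mapping[con$ligand, p] <- con$point
  }
  if (ncol(mapping) < 3L || is.null(placement_order(mapping)))
    stop("pharmacophore mapping is not decodable (need >= 3 shared columns)")
  mapping
}

#' Crude overlay dissimilarity
#'
#' Mean absolute difference between corresponding elements of the two
#' overlays' squared-distance matrices over the probe atoms (one per
#' feature per ligand). Zero for identical overlays and invariant to rigid
#' motion of a whole overlay.
#'
#' @param a,b overlays of the same ligand set.
#' @param probes optional precomputed [probe_atoms()] list.
#' @export
crude_dissimilarity <- function(a, b, probes = NULL) {
  sys <- a$system
  if (is.null(probes)) probes <- probe_atoms(sys)
  pts <- function(ov) do.call(rbind, lapply(seq_len(sys$nlig), function(li)
    ov$states[[li]]$coords[probes[[li]], , drop = FALSE]))
  da <- as.matrix(stats::dist(pts(a)))^2
  db <- as.matrix(stats::dist(pts(b)))^2
  mean(abs(da - db))
}

#' Multiply an overlay
#'
#' Searches for other overlays with the same feature mapping but different
#' ligand conformations. A population of chromosomes sharing the seed's
#' mapping table (and conformer indices) but randomised torsions is evolved:
#' children are produced by single-torsion mutation, single-ligand torsion
#' crossover or single-ligand rigid-body mutation (parents by tournament
#' selection); parents and children are merged, Pareto-ranked on V, HB, HY
#' and E, and the next population filled by rank with niche capping.
#'
#' @param overlay seed `overlay` (its chromosome supplies the conformer
#'   indices).
#' @param config a [moga_config()].
#' @return A `solution_set` of the final non-dominated overlays (all of
#'   which carry the seed's mapping table).
#' @export
multiply_overlay <- function(overlay, config = moga_config()) {
  sys <- overlay$system
  nlig <- sys$nlig
  set.seed(config$seed)
  mapping <- build_mapping_from_overlay(overlay)
  conformers <- if (!is.null(overlay$chromosome))
    overlay$chromosome$conformers else
    vapply(overlay$states, `[[`, integer(1), "conf")
  probes <- probe_atoms(sys)
  objectives <- c("V", "HB", "HY", "E")
  nrot <- vapply(sys$rotors, length, integer(1))
  flexible <- any(nrot > 0L)

  random_torsions <- function() lapply(seq_len(nlig), function(li) {
    if (nrot[li] == 0L) return(numeric(0))
    vapply(sys$rotors[[li]], function(rb) {
      if (is.null(rb$range)) stats::runif(1, -180, 180)
      else random_in_range(rb$range)
    }, numeric(1))
  })
  evaluate <- function(ch) {
    ov <- tryCatch(decode_chromosome(ch, sys), error = function(e) NULL,
                   torsion_range_error = function(e) NULL)
    if (is.null(ov)) return(NULL)
    list(chromosome = ch, overlay = ov,
         scores = as.numeric(score_overlay(ov, objectives)))
  }
  make_chrom <- function(torsions, rigid = NULL)
    new_chromosome(conformers, mapping, torsions = torsions, rigid = rigid)

  if (!flexible) {
    # no variation operators applicable: the seed is the whole population
    seed_ind <- evaluate(make_chrom(NULL))
    sol <- list(list(chromosome = seed_ind$chromosome,
                     overlay = seed_ind$overlay,
                     scores = stats::setNames(seed_ind$scores, objectives),
                     pareto_rank = 1L, borda = length(objectives)))
    return(structure(sol, class = "solution_set",
                     stats = list(generations = 0L), objectives = objectives))
  }

  pop <- list()
  attempts <- 0L
  while (length(pop) < config$population && attempts < config$population * 20L) {
    attempts <- attempts + 1L
    ind <- evaluate(make_chrom(random_torsions()))
    if (!is.null(ind)) pop[[length(pop) + 1L]] <- ind
  }
  if (!length(pop)) stop("could not build a feasible initial population")
  scores_mat <- function(inds) {
    m <- do.call(rbind, lapply(inds, `[[`, "scores"))
    colnames(m) <- objectives
    m
  }
  ranks <- pareto_rank(scores_mat(pop))
  for (gen in seq_len(config$generations)) {
    children <- list()
    while (length(children) < config$children) {
      op <- sample(names(config$p_ops), 1L, prob = config$p_ops)
      p1 <- tournament(ranks, config$tournament_size)
      child <- NULL
      if (op == "torsion_mutation") {
        ch <- pop[[p1]]$chromosome
        li <- sample(which(nrot > 0L), 1L)
        k <- sample(nrot[li], 1L)
        tor <- ch$torsions
        rb <- sys$rotors[[li]][[k]]
        tor[[li]][k] <- if (is.null(rb$range)) stats::runif(1, -180, 180)
                        else random_in_range(rb$range)
        child <- make_chrom(tor, ch$rigid)
      } else if (op == "torsion_crossover") {
        p2 <- tournament(ranks, config$tournament_size)
        ch1 <- pop[[p1]]$chromosome; ch2 <- pop[[p2]]$chromosome
        li <- sample(which(nrot > 0L), 1L)
        tor <- ch1$torsions
        tor[[li]] <- ch2$torsions[[li]]
        child <- make_chrom(tor, ch1$rigid)
      } else {
        ch <- pop[[p1]]$chromosome
        li <- sample(nlig, 1L)
        rigid <- ch$rigid %||% rep(list(numeric(6)), nlig)
        rigid <- lapply(rigid, function(r) if (length(r)) r else numeric(6))
        delta <- c(stats::runif(3, -config$rotate_step, config$rotate_step),
                   stats::runif(3, -config$translate_step,
                                config$translate_step))
        rigid[[li]] <- rigid[[li]] + delta
        child <- make_chrom(ch$torsions, rigid)
      }
      ind <- evaluate(child)
      if (!is.null(ind)) children[[length(children) + 1L]] <- ind
    }
    merged <- c(pop, children)
    mranks <- pareto_rank(scores_mat(merged))
    ord <- order(mranks, seq_along(merged))
    nextpop <- list(); nranks <- integer(0)
    for (i in ord) {
      if (length(nextpop) >= config$population) break
      in_niche <- sum(vapply(nextpop, function(x)
        crude_dissimilarity(merged[[i]]$overlay, x$overlay, probes) <
          config$niche_threshold, logical(1)))
      if (in_niche >= config$niche_capacity) next
      nextpop[[length(nextpop) + 1L]] <- merged[[i]]
      nranks <- c(nranks, mranks[i])
    }
    pop <- nextpop
    ranks <- pareto_rank(scores_mat(pop))
  }
  final <- which(ranks == 1L)
  sm <- scores_mat(pop)
  tallies <- borda_tally(sm[final, , drop = FALSE])
  ord <- order(tallies, final)
  sols <- lapply(ord, function(r) list(
    chromosome = pop[[final[r]]]$chromosome,
    overlay = pop[[final[r]]]$overlay,
    scores = stats::setNames(pop[[final[r]]]$scores, objectives),
    pareto_rank = 1L, borda = tallies[r]))
  structure(sols, class = "solution_set",
            stats = list(generations = config$generations,
                         population = length(pop)),
            objectives = objectives)
}

tournament <- function(ranks, size) {
  cand <- sample(length(ranks), min(size, length(ranks)))
  cand[which.min(ranks[cand])]
}

random_in_range <- function(range) {
  span <- (range[2] - range[1]) %% 360
  v <- range[1] + stats::runif(1, 0, span)
  ((v + 180) %% 360) - 180
}
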