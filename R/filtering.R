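## Overlay filtering: Fonseca-Fleming Pareto ranking with score
## constraints, Borda tallies, and greedy diversity selection.

#' Fonseca-Fleming Pareto ranks
#'
#' Rank = 1 + number of dominating solutions. One solution dominates
#' another when it is better on at least one objective and worse on none.
#' When score constraints are active, a solution breaking any constraint is
#' additionally dominated by every solution that breaks none.
#'
#' @param scores matrix (solutions x objectives) with named columns.
#' @param minimise logical per objective; defaults follow the objective
#'   names (V, E minimised; HB, HY, CF maximised).
#' @param constraints list of `list(objective, mode = "percentile" |
#'   "absolute", bound)`; a percentile bound of 30 keeps the best 30
#'   percent of that objective.
#' @return Integer ranks (best = 1).
#' @export
pareto_rank <- function(scores, minimise = NULL, constraints = list()) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(minimise)) minimise <- default_minimise(colnames(scores))
  breaks <- constraint_breakers(scores, minimise, constraints)
  sgn <- ifelse(minimise, 1, -1)  # smaller-adjusted is better
  adj <- sweep(scores, 2, sgn, "*")
  ranks <- integer(n)
  for (i in seq_len(n)) {
    dom <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (breaks[i] && !breaks[j]) { dom <- dom + 1L; next }
      if (breaks[j] && !breaks[i]) next
      le <- all(adj[j, ] <= adj[i, ] + 1e-12)
      lt <- any(adj[j, ] < adj[i, ] - 1e-12)
      if (le && lt) dom <- dom + 1L
    }
    ranks[i] <- 1L + dom
  }
  ranks
}

default_minimise <- function(objectives) {
  m <- OBJECTIVE_MINIMISE[objectives]
  m[is.na(m)] <- FALSE
  unname(m)
}

## Which solutions break a constraint. Percentile bounds use the
## nearest-rank method in the favourable direction: "best 30 percent" keeps
## the ceil(0.3 n) best-scoring solutions' threshold value.
constraint_breakers <- function(scores, minimise, constraints) {
  n <- nrow(scores)
  breaks <- rep(FALSE, n)
  for (con in constraints) {
    obj <- con$objective
    if (!obj %in% colnames(scores)) stop("constraint on unknown objective ", obj)
    v <- scores[, obj]
    minim <- minimise[match(obj, colnames(scores))]
    if (identical(con$mode, "percentile")) {
      k <- max(1L, ceiling(con$bound / 100 * n))
      sorted <- sort(v, decreasing = !minim)
      thr <- sorted[k]
      breaks <- breaks | (if (minim) v > thr + 1e-12 else v < thr - 1e-12)
    } else {
      breaks <- breaks | (if (minim) v > con$bound else v < con$bound)
    }
  }
  breaks
}

#' Borda tallies
#'
#' Per objective, solutions are ranked (best = 1, ties share the average
#' rank); the tally is the sum of ranks across objectives. Smaller is
#' better, and tallies are invariant to the order of the solutions.
#'
#' @inheritParams pareto_rank
#' @export
borda_tally <- function(scores, minimise = NULL) {
  scores <- as.matrix(scores)
  if (is.null(minimise)) minimise <- default_minimise(colnames(scores))
  tallies <- numeric(nrow(scores))
  for (k in seq_len(ncol(scores))) {
    v <- if (minimise[k]) scores[, k] else -scores[, k]
    tallies <- tallies + rank(v, ties.method = "average")
  }
  tallies
}

#' Greedy diversity selection
#'
#' Accepts the best-tallied survivor, drops everything within
#' `min_dissim` of an accepted solution, and repeats until `max_n` overlays
#' are chosen or the candidates are exhausted.
#'
#' @param order_ candidate indices in preference order (best first).
#' @param dissim function(i, j) or a precomputed dissimilarity matrix.
#' @param max_n maximum number accepted (default 20).
#' @param min_dissim rejection threshold (default 0.05).
#' @return Accepted indices, in acceptance order.
#' @export
select_diverse <- function(order_, dissim, max_n = 20L, min_dissim = 0.05) {
  dfun <- if (is.matrix(dissim)) function(i, j) dissim[i, j] else dissim
  accepted <- integer(0)
  for (i in order_) {
    if (length(accepted) >= max_n) break
    if (length(accepted) &&
        any(vapply(accepted, function(j) dfun(i, j), numeric(1)) <
            min_dissim)) next
    accepted <- c(accepted, i)
  }
  accepted
}

#' Filter a generated pool into a ranked, diverse solution set
#'
#' Decodes and scores every chromosome (conformers as supplied, no torsion
#' adjustment), Pareto-ranks with the configured percentile constraints
#' (best 30 percent of V and of HB by default), rejects ranks above the
#' threshold (5), orders survivors by Borda tally and greedily selects a
#' diverse subset using the consensus dissimilarity D_C.
#'
#' @param system from [build_system()].
#' @param pool from [generate_overlays()].
#' @param objectives default from config: V, HB, HY (energy is excluded
#'   because generated conformations come straight from the user's
#'   conformers).
#' @return A `solution_set`: list of solutions (`chromosome`, `overlay`,
#'   `scores`, `pareto_rank`, `borda`), filter statistics in attribute
#'   `"stats"`.
#' @export
filter_overlays <- function(system, pool,
                            objectives = system$config$objectives) {
  cfg <- system$config
  overlays <- list(); chroms <- list(); keep <- logical(length(pool))
  for (s in seq_along(pool)) {
    ov <- try(decode_chromosome(pool[[s]]$chromosome, system), silent = TRUE)
    if (inherits(ov, "try-error")) next
    keep[s] <- TRUE
    overlays[[length(overlays) + 1L]] <- ov
    chroms[[length(chroms) + 1L]] <- pool[[s]]$chromosome
  }
  if (!length(overlays)) stop("no decodable chromosome in the pool")
  scores <- t(vapply(overlays, function(ov)
    as.numeric(score_overlay(ov, objectives)), numeric(length(objectives))))
  colnames(scores) <- objectives
  constraints <- list()
  if ("V" %in% objectives)
    constraints <- c(constraints, list(list(objective = "V",
      mode = "percentile", bound = cfg$constraint_percentile)))
  if ("HB" %in% objectives)
    constraints <- c(constraints, list(list(objective = "HB",
      mode = "percentile", bound = cfg$constraint_percentile)))
  pr <- pareto_rank(scores, constraints = constraints)
  surv <- which(pr <= cfg$pareto_rank_max)
  tallies <- borda_tally(scores[surv, , drop = FALSE])
  ord <- surv[order(tallies, surv)]
  dc_cache <- new.env(parent = emptyenv())
  dfun <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(dc_cache[[key]])) return(dc_cache[[key]])
    v <- consensus_dissimilarity(overlays[[i]], overlays[[j]])$D_C
    dc_cache[[key]] <- v
    v
  }
  chosen <- select_diverse(ord, dfun, cfg$max_solutions, cfg$min_dissimilarity)
  sols <- lapply(chosen, function(i) list(
    chromosome = chroms[[i]], overlay = overlays[[i]],
    scores = scores[i, ], pareto_rank = pr[i],
    borda = tallies[match(i, surv)]))
  structure(sols, class = "solution_set",
            stats = list(pool = length(pool), decoded = sum(keep),
                         rank_survivors = length(surv),
                         selected = length(chosen)),
            objectives = objectives)
}

#' @export
print.solution_set <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf("<solution set: %d overlays (pool %d, rank survivors %d)>\n",
              length(x), st$pool %||% NA, st$rank_survivors %||% NA))
  invisible(x)
}

#' @export
summary.solution_set <- function(object, ...) {
  df <- do.call(rbind, lapply(seq_along(object), function(i) {
    s <- object[[i]]
    data.frame(solution = i, t(s$scores), pareto_rank = s$pareto_rank,
               borda = s$borda)
  }))
  df
}
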