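## Overlay refinement by simulated annealing under the combined cost
## F = HB - 0.5 V + HY - 0.3 E (maximised). Each step changes one ligand
## torsion or applies a small rigid-body move to one ligand; the best state
## visited is returned, so the reported F never decreases.

#' Annealing configuration
#'
#' @param t0 initial temperature (default 0.5; refinement starts low since
#'   the aim is local improvement, not exploration).
#' @param cooling geometric cooling factor per level (0.95).
#' @param moves_per_level moves at each temperature (100).
#' @param levels temperature levels (50).
#' @param max_consecutive_rejections early stop (500).
#' @param torsion_step,translate_step,rotate_step move magnitudes: uniform
#'   +/- 30 degrees, +/- 0.25 A per axis, +/- 5 degrees about a random axis
#'   through the ligand centroid.
#' @param weights Eq-style cost weights on (HB, V, HY, E).
#' @param seed integer seed.
#' @export
anneal_config <- function(t0 = 0.5, cooling = 0.95, moves_per_level = 100L,
                          levels = 50L, max_consecutive_rejections = 500L,
                          torsion_step = 30, translate_step = 0.25,
                          rotate_step = 5,
                          weights = c(HB = 1, V = -0.5, HY = 1, E = -0.3),
                          seed = 1L) {
  stopifnot(cooling > 0, cooling < 1)
  list(t0 = t0, cooling = cooling, moves_per_level = moves_per_level,
       levels = levels,
       max_consecutive_rejections = max_consecutive_rejections,
       torsion_step = torsion_step, translate_step = translate_step,
       rotate_step = rotate_step, weights = weights, seed = seed)
}

#' Combined refinement cost
#'
#' @param overlay an `overlay`.
#' @param weights named weights on HB, V, HY, E.
#' @export
refine_cost <- function(overlay,
                        weights = c(HB = 1, V = -0.5, HY = 1, E = -0.3)) {
  sc <- score_overlay(overlay, names(weights))
  sum(weights * as.numeric(sc[names(weights)]))
}

#' Refine an overlay by simulated annealing
#'
#' Metropolis acceptance on the change in F; torsion moves respect the
#' allowed ranges (out-of-range proposals are vetoed); rigid moves act
#' about the ligand centroid. With no rotatable bonds and rigid moves
#' disabled the input is returned unchanged with a message.
#'
#' @param overlay an `overlay` (typically from [filter_overlays()]).
#' @param config an [anneal_config()].
#' @param rigid_moves allow rigid-body moves (default TRUE).
#' @return List: `overlay` (best state), `F` (its cost), `F_in`, `trace`
#'   (best-F trajectory per level) and `chromosome` (the refined state with
#'   rigid-body terms, serialisable via [chromosomes_to_json()]).
#' @export
refine_overlay <- function(overlay, config = anneal_config(),
                           rigid_moves = TRUE) {
  sys <- overlay$system
  nlig <- sys$nlig
  nrot <- vapply(sys$rotors, length, integer(1))
  if (all(nrot == 0L) && !rigid_moves) {
    message("no rotatable bonds and rigid moves disabled; overlay unchanged")
    return(list(overlay = overlay, F = refine_cost(overlay, config$weights),
                F_in = refine_cost(overlay, config$weights),
                trace = numeric(0), chromosome = overlay$chromosome))
  }
  set.seed(config$seed)
  coords <- lapply(overlay$states, `[[`, "coords")
  cur <- overlay
  Fcur <- refine_cost(cur, config$weights)
  F_in <- Fcur
  best <- cur; Fbest <- Fcur
  temp <- config$t0
  consec_rej <- 0L
  trace <- numeric(0)
  rebuild <- function(coords) {
    new_overlay(sys, lapply(seq_len(nlig), function(li)
      list(conf = overlay$states[[li]]$conf, coords = coords[[li]])),
      chromosome = overlay$chromosome)
  }
  for (lev in seq_len(config$levels)) {
    for (mv in seq_len(config$moves_per_level)) {
      li <- sample(nlig, 1L)
      move_types <- c(if (nrot[li] > 0L) "torsion",
                      if (rigid_moves) c("translate", "rotate"))
      if (is.null(move_types)) next
      type <- sample(move_types, 1L)
      newc <- coords
      if (type == "torsion") {
        k <- sample(nrot[li], 1L)
        vals <- rep(NA_real_, nrot[li])
        curtor <- measure_torsion(coords[[li]], sys$rotors[[li]][[k]]$quartet)
        prop <- curtor + stats::runif(1, -config$torsion_step,
                                      config$torsion_step)
        prop <- ((prop + 180) %% 360) - 180
        vals[k] <- prop
        moved <- tryCatch(drive_torsions(coords[[li]], sys$rotors[[li]], vals),
                          torsion_range_error = function(e) NULL)
        if (is.null(moved)) { consec_rej <- consec_rej + 1L; next }
        newc[[li]] <- moved
      } else if (type == "translate") {
        newc[[li]] <- sweep(coords[[li]], 2,
                            stats::runif(3, -config$translate_step,
                                         config$translate_step), "+")
      } else {
        cen <- colMeans(coords[[li]])
        ax <- unit(stats::rnorm(3))
        tf <- rotation_about_axis(cen, cen + ax,
                                  stats::runif(1, -config$rotate_step,
                                               config$rotate_step))
        newc[[li]] <- apply_transform(coords[[li]], tf)
      }
      cand <- rebuild(newc)
      Fcand <- refine_cost(cand, config$weights)
      dF <- Fcand - Fcur
      if (dF >= 0 || stats::runif(1) < exp(dF / max(temp, 1e-12))) {
        coords <- newc; cur <- cand; Fcur <- Fcand
        consec_rej <- 0L
        if (Fcur > Fbest) { best <- cur; Fbest <- Fcur }
      } else consec_rej <- consec_rej + 1L
      if (consec_rej >= config$max_consecutive_rejections) break
    }
    trace <- c(trace, Fbest)
    if (consec_rej >= config$max_consecutive_rejections) break
    temp <- temp * config$cooling
  }
  chrom <- refined_chromosome(overlay, best)
  list(overlay = best, F = Fbest, F_in = F_in, trace = trace,
       chromosome = chrom)
}

## Decompose R = Rz(g) Ry(b) Rx(a) into intrinsic x-y-z Euler angles
## (degrees).
euler_from_matrix <- function(R) {
  b <- asin(max(min(-R[3, 1], 1), -1))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal: fold everything into a
    a <- atan2(-R[2, 3], R[2, 2])
    g <- 0
  }
  c(a, b, g) / DEG
}

## Express a refined overlay as the source chromosome plus per-ligand
## rigid-body terms (and updated torsions) so it stays serialisable.
refined_chromosome <- function(source_overlay, refined) {
  sys <- source_overlay$system
  ch <- source_overlay$chromosome
  if (is.null(ch)) return(NULL)
  torsions <- lapply(seq_len(sys$nlig), function(li) {
    rots <- sys$rotors[[li]]
    if (!length(rots)) return(numeric(0))
    measure_torsions(refined$states[[li]]$coords, rots)
  })
  base <- decode_chromosome(new_chromosome(ch$conformers, ch$mapping,
                                           torsions = torsions), sys)
  rigid <- lapply(seq_len(sys$nlig), function(li) {
    tf <- kabsch_fit(base$states[[li]]$coords, refined$states[[li]]$coords)
    cen <- colMeans(base$states[[li]]$coords)
    trans <- tf$t - cen + as.vector(tf$R %*% cen)
    c(euler_from_matrix(tf$R), trans)
  })
  new_chromosome(ch$conformers, ch$mapping, torsions = torsions,
                 rigid = rigid)
}
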