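## Rotatable-bond perception and torsion driving.
##
## Which acyclic single bonds count as rotatable is controlled by a rules
## file of SMARTS patterns; exclusion rules (methyl groups) and allowed
## torsion ranges (esters held within 5 degrees of trans) are expressed the
## same way. Torsion driving rotates the side of the bond with fewer atoms
## (ties broken by the lower minimum atom index); any consistent convention
## gives the same overlays up to rigid motion.

#' Default rotatable-bond rules
#'
#' Reads the rules shipped in `inst/extdata/rotatable_rules.yaml`: a generic
#' acyclic-single-bond rule, a methyl exclusion, and an ester rule that
#' constrains the O=C-O-C torsion to trans +/- 5 degrees.
#' @export
default_rotatable_rules <- function() {
  yaml::read_yaml(pkg_extdata("rotatable_rules.yaml"))$rules
}

load_rotatable_rules <- function(rules) {
  if (is.character(rules) && length(rules) == 1L)
    rules <- yaml::read_yaml(rules)$rules
  for (r in rules) {
    if (is.null(r$smarts)) stop("rotatable rule without smarts")
    smarts_pattern(r$smarts)  # validates at load time
  }
  rules
}

#' Perceive rotatable bonds
#'
#' Every acyclic, non-aromatic single bond matching an inclusion rule and not
#' matching an exclusion rule is returned, with its torsion-defining quartet,
#' optional allowed range and the set of atoms that move when it is driven.
#'
#' @param ligand a `ligand`.
#' @param rules list of rules (each `list(smarts, bond_atoms, torsion_atoms,
#'   min_deg, max_deg, exclude)`) or a path to a YAML rules file; defaults to
#'   the shipped rules.
#' @return List of `rotatable_bond` objects: `i`, `j` (fixed-side and
#'   moving-side bond atoms), `quartet` (a-b-c-d with c,d on the moving
#'   side), `range` (NULL or c(min, max) degrees, possibly wrapping), and
#'   `moving` (atom indices rotated by [drive_torsions()]).
#' @export
perceive_rotatable_bonds <- function(ligand, rules = default_rotatable_rules()) {
  rules <- load_rotatable_rules(rules)
  bond_key <- function(i, j) paste(min(i, j), max(i, j))
  include <- list(); excluded <- character(0); ranged <- list()
  for (r in rules) {
    m <- smarts_match(ligand, r$smarts, unique = FALSE)
    if (!nrow(m)) next
    ba <- if (is.null(r$bond_atoms)) c(1L, 2L) else as.integer(r$bond_atoms)
    for (row in seq_len(nrow(m))) {
      bi <- m[row, ba[1]]; bj <- m[row, ba[2]]
      key <- bond_key(bi, bj)
      if (isTRUE(r$exclude)) { excluded <- c(excluded, key); next }
      if (!is.null(r$min_deg)) {
        q <- if (is.null(r$torsion_atoms)) NULL else m[row, as.integer(r$torsion_atoms)]
        ranged[[key]] <- list(range = c(r$min_deg, r$max_deg), quartet = q)
      } else include[[key]] <- c(bi, bj)
    }
  }
  # ranged rules imply inclusion
  for (key in names(ranged)) if (is.null(include[[key]]))
    include[[key]] <- ranged[[key]]$quartet[2:3]
  out <- list()
  for (key in setdiff(names(include), excluded)) {
    ij <- include[[key]]
    bi <- ij[1]; bj <- ij[2]
    sel <- which((ligand$bonds$i == bi & ligand$bonds$j == bj) |
                 (ligand$bonds$i == bj & ligand$bonds$j == bi))
    if (!length(sel)) next
    if (ligand$bonds$order[sel] != 1L || ligand$bonds$aromatic[sel]) next
    if (ligand$bond_in_ring[sel]) next
    side_i <- reachable_side(ligand, from = bi, blocked = bj)
    side_j <- reachable_side(ligand, from = bj, blocked = bi)
    move_j <- length(side_j) < length(side_i) ||
      (length(side_j) == length(side_i) && min(side_j) < min(side_i))
    fixed_atom <- if (move_j) bi else bj
    moving_atom <- if (move_j) bj else bi
    moving <- if (move_j) side_j else side_i
    a <- anchor_neighbour(ligand, fixed_atom, moving_atom)
    d <- anchor_neighbour(ligand, moving_atom, fixed_atom)
    if (is.na(a) || is.na(d)) next   # terminal: no torsion to define
    rng <- ranged[[key]]
    quartet <- c(a, fixed_atom, moving_atom, d)
    if (!is.null(rng) && !is.null(rng$quartet)) {
      q <- rng$quartet
      # orient the rule's quartet to our fixed->moving convention
      if (q[2] == moving_atom) q <- rev(q)
      quartet <- q
    }
    out[[length(out) + 1L]] <-
      structure(list(i = fixed_atom, j = moving_atom, quartet = quartet,
                     range = if (is.null(rng)) NULL else as.numeric(rng$range),
                     moving = sort(moving)),
                class = "rotatable_bond")
  }
  # deterministic order: by bond atom indices
  if (length(out))
    out <- out[order(vapply(out, function(b) min(b$i, b$j) * 1000 +
                              max(b$i, b$j), numeric(1)))]
  out
}

anchor_neighbour <- function(lig, atom, not) {
  nb <- setdiff(heavy_neighbours(lig, atom), not)
  if (!length(nb)) NA_integer_ else min(nb)
}

reachable_side <- function(lig, from, blocked) {
  seen <- logical(lig$natoms); seen[blocked] <- TRUE
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, lig$adj[[v]][!seen[lig$adj[[v]]]])
  }
  seen[blocked] <- FALSE
  which(seen)
}

torsion_range_error <- function(msg) {
  structure(class = c("torsion_range_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Drive rotatable bonds to requested torsion values
#'
#' Returns coordinates in which each measured torsion equals its requested
#' value; atoms on the fixed side of every bond are unmoved. Requests outside
#' a bond's allowed range raise a `torsion_range_error`, the rejection signal
#' used by the annealing and genetic stages to veto moves.
#'
#' @param coords n x 3 coordinate matrix.
#' @param rotatable_bonds from [perceive_rotatable_bonds()].
#' @param values numeric vector, degrees, one per rotatable bond; NA entries
#'   leave that bond untouched.
#' @export
drive_torsions <- function(coords, rotatable_bonds, values) {
  if (length(values) != length(rotatable_bonds))
    stop("need one torsion value per rotatable bond")
  for (k in seq_along(rotatable_bonds)) {
    target <- values[k]
    if (is.na(target)) next
    rb <- rotatable_bonds[[k]]
    if (!is.null(rb$range) && !ang_in_range(target, rb$range[1], rb$range[2]))
      stop(torsion_range_error(sprintf(
        "torsion %d: %.1f deg outside allowed range [%.1f, %.1f]",
        k, target, rb$range[1], rb$range[2])))
    cur <- measure_torsion(coords, rb$quartet)
    delta <- target - cur
    if (abs(delta) < 1e-10) next
    tf <- rotation_about_axis(coords[rb$i, ], coords[rb$j, ], delta)
    newc <- coords
    newc[rb$moving, ] <- apply_transform(coords[rb$moving, , drop = FALSE], tf)
    if (ang_diff(measure_torsion(newc, rb$quartet), target) > 1e-6) {
      tf <- rotation_about_axis(coords[rb$i, ], coords[rb$j, ], -delta)
      newc <- coords
      newc[rb$moving, ] <- apply_transform(coords[rb$moving, , drop = FALSE], tf)
    }
    coords <- newc
  }
  coords
}

#' Measure the torsions of all rotatable bonds
#' @export
measure_torsions <- function(coords, rotatable_bonds) {
  vapply(rotatable_bonds, function(rb) measure_torsion(coords, rb$quartet),
         numeric(1))
}
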