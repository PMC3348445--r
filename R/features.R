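## Chemical features and fitting points.
##
## Donors, acceptors and custom features are assigned by SMARTS definitions;
## hydrophobes are perceived by built-in rules (rings of size <= 7, t-butyl
## and -CF3 groups, amide/C=C/C=N/N=N linkages, and segmentation of the
## remaining hydrophobic portions into pieces of up to four atoms). Each
## feature is represented by fitting points: donor/acceptor points sit on the
## heavy atom itself, hydrophobes get a centroid point and (optionally, for
## directional hydrophobes) two points on the plane normal at 1 Angstrom.
##
## Feature assignment is topological, so a ligand has one feature list valid
## for every conformer; only fitting-point coordinates depend on the
## conformer. Segmentation tie-breaks that need coordinates use the first
## conformer as the reference.

FEATURE_KINDS <- c("donor", "acceptor", "hydrophobe_dir", "hydrophobe_nondir",
                   "custom", "constraint")

#' Default feature definitions
#'
#' Reads `inst/extdata/feature_defs.yaml`: ionised N donors and O acceptors
#' are strong, neutral N/O groups medium, thiol/activated C-H donors and
#' thiocarbonyl S acceptors weak; each carries a hydrogen-bond geometry
#' class used for virtual-point placement.
#' @export
default_feature_defs <- function() {
  yaml::read_yaml(pkg_extdata("feature_defs.yaml"))$features
}

load_feature_defs <- function(defs) {
  if (is.character(defs) && length(defs) == 1L)
    defs <- yaml::read_yaml(defs)$features
  for (d in defs) {
    if (is.null(d$smarts) || is.null(d$kind)) stop("malformed feature def")
    smarts_pattern(d$smarts)  # validate SMARTS at load time
    if (d$kind %in% c("donor", "acceptor") &&
        (is.null(d$strength) || is.null(d$geometry)))
      stop("donor/acceptor definition '", d$name,
           "' must carry strength and geometry")
  }
  defs
}

new_feature <- function(kind, atoms, atom = NA_integer_, strength = NA,
                        geometry = NA, name = kind, directional = NA) {
  structure(list(kind = kind, atoms = as.integer(atoms),
                 atom = as.integer(atom), strength = strength,
                 geometry = geometry, name = name, directional = directional),
            class = "ligover_feature")
}

#' Assign donor, acceptor, custom and constraint features
#'
#' Every SMARTS match of a definition that does not touch an excluded atom
#' yields a feature; for each kind the first matching definition per atom
#' wins. Atoms matching both a donor and an acceptor definition (hydroxyl
#' oxygens) receive both features. Hand-picked custom atom sets become
#' features verbatim.
#'
#' @param ligand a `ligand`.
#' @param feature_defs definitions (list or YAML path); default shipped set.
#' @param excluded_atoms atom indices never given features (e.g. a
#'   solubilising group).
#' @param custom_atom_sets named list of atom-index vectors; names become
#'   feature names. Use kind "constraint" by prefixing the name with
#'   "constraint:".
#' @return List of features (donors, then acceptors, then customs, ordered
#'   by atom index within kind).
#' @export
assign_features <- function(ligand, feature_defs = default_feature_defs(),
                            excluded_atoms = integer(0),
                            custom_atom_sets = list()) {
  defs <- load_feature_defs(feature_defs)
  if (length(excluded_atoms) && any(excluded_atoms > ligand$natoms))
    stop("excluded atom index out of range for ligand ", ligand$id)
  out <- list()
  for (want in c("donor", "acceptor")) {
    taken <- integer(0)
    for (d in defs) {
      if (d$kind != want) next
      m <- smarts_match(ligand, d$smarts, unique = FALSE)
      if (!nrow(m)) next
      fa_col <- if (is.null(d$atom)) 1L else as.integer(d$atom)
      for (row in seq_len(nrow(m))) {
        if (any(m[row, ] %in% excluded_atoms)) next
        fa <- m[row, fa_col]
        if (fa %in% taken) next
        taken <- c(taken, fa)
        out[[length(out) + 1L]] <-
          new_feature(want, atoms = fa, atom = fa, strength = d$strength,
                      geometry = d$geometry, name = d$name)
      }
    }
  }
  for (d in defs) {
    if (!d$kind %in% c("custom", "constraint")) next
    m <- smarts_match(ligand, d$smarts, unique = TRUE)
    for (row in seq_len(nrow(m))) {
      if (any(m[row, ] %in% excluded_atoms)) next
      out[[length(out) + 1L]] <-
        new_feature(d$kind, atoms = m[row, ], name = d$name)
    }
  }
  for (nm in names(custom_atom_sets)) {
    atoms <- as.integer(custom_atom_sets[[nm]])
    if (any(atoms < 1L | atoms > ligand$natoms))
      stop("custom atom set '", nm, "' references a missing atom in ligand ",
           ligand$id)
    kind <- if (startsWith(nm, "constraint:")) "constraint" else "custom"
    out[[length(out) + 1L]] <- new_feature(kind, atoms = atoms,
                                           name = sub("^constraint:", "", nm))
  }
  ord <- order(match(vapply(out, `[[`, "", "kind"), FEATURE_KINDS),
               vapply(out, function(f) min(f$atoms), integer(1)))
  out[ord]
}

delocalisable <- function(lig, a) {
  if (lig$aromatic[a]) return(TRUE)
  sel <- (lig$bonds$i == a | lig$bonds$j == a)
  any(lig$bonds$order[sel] >= 2)
}

is_halogen <- function(el) el %in% c("F", "Cl", "Br", "I")

#' Perceive hydrophobic features
#'
#' Rings of size <= 7 become one hydrophobe each, directional when at least
#' three ring atoms are delocalisable (aromatic or doubly bonded). t-Butyl
#' and -CF3 groups are non-directional hydrophobes. Acyclic amide, C=C, C=N
#' and N=N linkages are directional. Remaining hydrophobic atoms (carbons,
#' with their halogens, not adjacent to charged or hydrogen-bonding
#' heteroatoms) are partitioned into segments of up to four atoms, choosing
#' the segmentation with the most uniform segment sizes (then the most
#' uniform centroid spacing in the reference conformer).
#'
#' @param ligand a `ligand`.
#' @param ref_conformer conformer index used for spacing tie-breaks only.
#' @export
perceive_hydrophobes <- function(ligand, ref_conformer = 1L) {
  lig <- ligand
  used <- logical(lig$natoms)
  out <- list()
  add <- function(atoms, directional, name) {
    out[[length(out) + 1L]] <<- new_feature(
      if (directional) "hydrophobe_dir" else "hydrophobe_nondir",
      atoms = atoms, name = name, directional = directional)
  }
  # rings of size <= 7
  for (r in lig$rings) {
    if (length(r) > 7L) next
    ndeloc <- sum(vapply(r, function(a) delocalisable(lig, a), logical(1)))
    add(r, ndeloc >= 3L, "ring")
    used[r] <- TRUE
  }
  # t-butyl / -CF3: sp3 carbon with three identical terminal CH3 or F
  for (c0 in which(lig$elements == "C" & !used)) {
    nb <- heavy_neighbours(lig, c0)
    term <- nb[vapply(nb, function(a) length(heavy_neighbours(lig, a)) == 1L,
                      logical(1))]
    me <- term[lig$elements[term] == "C" & !used[term]]
    fl <- term[lig$elements[term] == "F"]
    if (length(me) >= 3L) { add(c(c0, me[1:3]), FALSE, "t-butyl")
                            used[c(c0, me[1:3])] <- TRUE }
    else if (length(fl) >= 3L) { add(c(c0, fl[1:3]), FALSE, "CF3")
                                 used[c(c0, fl[1:3])] <- TRUE }
  }
  # acyclic directional linkages: amide, C=C, C=N, N=N
  link_pats <- list(amide = "[NX3][CX3]=[OX1]", `C=C` = "[CX3]=[CX3]",
                    `C=N` = "[CX3]=[NX2]", `N=N` = "[NX2]=[NX2]")
  for (nm in names(link_pats)) {
    m <- smarts_match(lig, link_pats[[nm]], unique = TRUE)
    for (row in seq_len(nrow(m))) {
      core <- m[row, ]
      if (any(lig$in_ring[core]) || any(used[core])) next
      # plane atoms: the linkage plus heavy neighbours of its sp2 atoms
      ext <- unique(c(core, unlist(lapply(core, function(a)
        heavy_neighbours(lig, a)))))
      add(ext, TRUE, nm)
      used[core] <- TRUE
    }
  }
  # remaining hydrophobic portions -> segments of up to 4 atoms
  hydrophobic <- vapply(seq_len(lig$natoms), function(a) {
    if (used[a] || lig$elements[a] != "C") return(FALSE)
    nb <- lig$adj[[a]]
    if (any(lig$charges[nb] != 0)) return(FALSE)
    het <- nb[!lig$elements[nb] %in% c("C", "H") & !is_halogen(lig$elements[nb])]
    length(het) == 0L
  }, logical(1))
  comp <- connected_components(lig, which(hydrophobic))
  ref <- lig$conformers[[ref_conformer]]
  for (atoms in comp) {
    path <- dfs_path_order(lig, atoms)
    for (seg in best_segmentation(path, ref)) {
      members <- seg
      # attach halogens riding on segment carbons
      hal <- unlist(lapply(seg, function(a) {
        nb <- heavy_neighbours(lig, a); nb[is_halogen(lig$elements[nb])]
      }))
      add(sort(unique(c(members, hal))), FALSE, "segment")
    }
  }
  out
}

connected_components <- function(lig, atoms) {
  comps <- list(); left <- atoms
  while (length(left)) {
    seen <- c(); stack <- left[1]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, intersect(lig$adj[[v]], setdiff(left, seen)))
    }
    comps[[length(comps) + 1L]] <- sort(seen)
    left <- setdiff(left, seen)
  }
  comps
}

## Order component atoms along a DFS walk starting from a terminal atom, so
## consecutive runs form chemically contiguous segments.
dfs_path_order <- function(lig, atoms) {
  deg <- vapply(atoms, function(a) length(intersect(lig$adj[[a]], atoms)),
                integer(1))
  start <- atoms[which(deg == min(deg))[1]]
  seen <- integer(0); stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    nxt <- setdiff(intersect(lig$adj[[v]], atoms), seen)
    stack <- c(stack, rev(sort(nxt)))
  }
  seen
}

## All ordered partitions of the walk into consecutive segments of <= 4
## atoms; pick minimal size variance, then fewest segments, then most
## uniform centroid spacing in the reference conformer.
best_segmentation <- function(path, ref_coords, max_size = 4L) {
  n <- length(path)
  if (n == 0L) return(list())
  parts <- compositions_upto(n, max_size)
  score <- lapply(parts, function(sizes) {
    segs <- split(path, rep(seq_along(sizes), sizes))
    sv <- if (length(sizes) > 1) stats::var(sizes) else 0
    sp <- 0
    if (length(segs) > 2) {
      cents <- t(vapply(segs, function(s)
        colMeans(ref_coords[s, , drop = FALSE]), numeric(3)))
      gaps <- sqrt(rowSums((cents[-1, , drop = FALSE] -
                            cents[-nrow(cents), , drop = FALSE])^2))
      sp <- stats::var(gaps)
    }
    c(sv, length(sizes), sp)
  })
  key <- vapply(score, function(s) s[1] * 1e6 + s[2] * 1e3 + s[3], numeric(1))
  sizes <- parts[[which.min(key)]]
  unname(split(path, rep(seq_along(sizes), sizes)))
}

compositions_upto <- function(n, k) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(n, k)))
    for (rest in compositions_upto(n - first, k))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}

#' All features of a ligand
#'
#' Convenience wrapper combining [assign_features()] and
#' [perceive_hydrophobes()] in the package's canonical feature order.
#' @inheritParams assign_features
#' @export
ligand_features <- function(ligand, feature_defs = default_feature_defs(),
                            excluded_atoms = integer(0),
                            custom_atom_sets = list()) {
  feats <- c(assign_features(ligand, feature_defs, excluded_atoms,
                             custom_atom_sets),
             perceive_hydrophobes(ligand))
  ord <- order(match(vapply(feats, `[[`, "", "kind"), FEATURE_KINDS),
               vapply(feats, function(f) min(f$atoms), integer(1)))
  feats[ord]
}

plane_normal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  sv <- svd(c0, nu = 0)
  sv$v[, 3]
}

#' Place fitting points for a set of features
#'
#' Donor/acceptor points coincide with the heavy atom; hydrophobes get their
#' centroid (plus two points at +/- 1 Angstrom along the least-squares plane
#' normal for directional hydrophobes when `use_normals`); custom and
#' constraint features get the centroid of their member atoms.
#'
#' @param features list from [ligand_features()].
#' @param coords conformer coordinates (n x 3).
#' @param use_normals include hydrophobe normal points (default FALSE).
#' @return List with `xyz` (m x 3 matrix) and `meta` (data frame: `kind`,
#'   `role`, `feature` index, `atom`, `strength`). Row order is stable
#'   across conformers of the same ligand.
#' @export
place_fitting_points <- function(features, coords, use_normals = FALSE) {
  xyz <- list(); meta <- list()
  push <- function(p, kind, role, fi, atom = NA_integer_, strength = NA) {
    xyz[[length(xyz) + 1L]] <<- p
    meta[[length(meta) + 1L]] <<- data.frame(
      kind = kind, role = role, feature = fi, atom = atom,
      strength = if (is.null(strength) || is.na(strength)) NA_character_
                 else strength,
      stringsAsFactors = FALSE)
  }
  for (fi in seq_along(features)) {
    f <- features[[fi]]
    if (f$kind %in% c("donor", "acceptor")) {
      push(coords[f$atom, ], f$kind, "atom_site", fi, f$atom, f$strength)
    } else if (f$kind %in% c("hydrophobe_dir", "hydrophobe_nondir")) {
      pts <- coords[f$atoms, , drop = FALSE]
      cen <- colMeans(pts)
      push(cen, f$kind, "hydrophobe_centroid", fi)
      if (f$kind == "hydrophobe_dir" && use_normals) {
        nrm <- plane_normal(pts)
        push(cen + nrm, f$kind, "hydrophobe_normal_plus", fi)
        push(cen - nrm, f$kind, "hydrophobe_normal_minus", fi)
      }
    } else {
      push(colMeans(coords[f$atoms, , drop = FALSE]), f$kind,
           "custom_centroid", fi)
    }
  }
  list(xyz = do.call(rbind, xyz), meta = do.call(rbind, meta))
}

#' Virtual points for a donor or acceptor
#'
#' Places hypothetical positions of the complementary protein atom at
#' `hb_distance` from the feature atom: one point on the axis for linear
#' groups (nitrile), one along the lone-pair bisector for trigonal groups
#' with two neighbours, an in-plane arc spanning the two sp2 lone-pair
#' directions plus intermediates for planar groups (carbonyl), and points
#' evenly spaced around the base of a cone for cone classes (ionised
#' phosphate-type oxygen, sp3 O/N). Donors with explicit hydrogens instead
#' get one point along each X-H direction.
#'
#' @param feature a donor/acceptor feature.
#' @param ligand,coords the ligand and conformer coordinates.
#' @param hb_distance hydrogen-bond distance, Angstrom (default 2.9).
#' @param n_points points around a cone base (default 12).
#' @param arc_points points across a planar arc (default 5).
#' @param cone_half_angle degrees (default 60).
#' @return Matrix of virtual-point coordinates (possibly 1 row).
#' @export
virtual_points <- function(feature, ligand, coords, hb_distance = 2.9,
                           n_points = 12L, arc_points = 5L,
                           cone_half_angle = 60) {
  a <- feature$atom
  p <- coords[a, ]
  nb <- heavy_neighbours(ligand, a)
  hs <- ligand$adj[[a]][ligand$elements[ligand$adj[[a]]] == "H"]
  if (feature$kind == "donor" && length(hs)) {
    dirs <- t(vapply(hs, function(h) unit(coords[h, ] - p), numeric(3)))
    return(sweep(dirs * hb_distance, 2, p, "+"))
  }
  if (!length(nb))
    stop("virtual_points: atom ", a, " of ligand ", ligand$id,
         " has no neighbours to define a local frame")
  geom <- feature$geometry
  if (is.null(geom) || is.na(geom)) geom <- "none"
  if (geom == "none") return(matrix(numeric(0), 0, 3))
  if (geom == "linear") {
    ax <- unit(p - coords[nb[1], ])
    return(rbind(p + hb_distance * ax))
  }
  if (geom == "trigonal" && length(nb) >= 2) {
    ax <- unit(-(unit(coords[nb[1], ] - p) + unit(coords[nb[2], ] - p)))
    return(rbind(p + hb_distance * ax))
  }
  if (geom %in% c("trigonal", "planar_arc")) {
    # sp2 plane from the neighbour and its substituents
    c1 <- nb[1]
    ring <- unique(c(a, c1, heavy_neighbours(ligand, c1)))
    if (length(ring) < 3)
      stop("virtual_points: cannot define sp2 plane at atom ", a,
           " of ligand ", ligand$id)
    nrm <- plane_normal(coords[ring, , drop = FALSE])
    base <- unit(p - coords[c1, ])
    angs <- seq(-60, 60, length.out = max(arc_points, 2L))
    pts <- t(vapply(angs, function(th) {
      tf <- rotation_about_axis(p, p + nrm, th)
      p + hb_distance * as.vector((tf$R %*% base))
    }, numeric(3)))
    return(pts)
  }
  # cone / tetrahedral_cone
  ax <- unit(-rowsum_dirs(coords, p, nb))
  basis <- orthobasis(ax)
  th0 <- cone_half_angle * DEG
  angs <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  pts <- t(vapply(angs, function(phi) {
    dirv <- cos(th0) * ax + sin(th0) * (cos(phi) * basis$u + sin(phi) * basis$v)
    p + hb_distance * dirv
  }, numeric(3)))
  pts
}

unit <- function(v) v / sqrt(sum(v^2))

rowsum_dirs <- function(coords, p, nb) {
  dirs <- vapply(nb, function(b) unit(coords[b, ] - p), numeric(3))
  v <- rowSums(rbind(dirs))
  if (sqrt(sum(v^2)) < 1e-8) {
    # symmetric neighbours: fall back to the plane normal
    v <- plane_normal(coords[c(nb, nb[1]), , drop = FALSE])
  }
  unit(v)
}

orthobasis <- function(ax) {
  e <- diag(3)[, which.min(abs(ax))]
  u <- unit(e - sum(e * ax) * ax)
  v <- c(ax[2] * u[3] - ax[3] * u[2],
         ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  list(u = u, v = v)
}
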