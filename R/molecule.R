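## Ligand data model and SD file I/O.
##
## A ligand is a molecule with a fixed topology (elements, charges, bonds)
## and one or more conformers (coordinate sets). SD files are parsed with
## ChemmineR; consecutive records sharing a title are treated as conformers
## of one ligand (the common multi-conformer SD dialect). Formal charges use
## the classic atom-block charge code, which ChemmineR exposes.

CHARGE_CODE_TO_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                           `5` = -1L, `6` = -2L, `7` = -3L, `0` = 0L)
CHARGE_TO_CODE <- function(q) {
  code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
            `-1` = 5L, `-2` = 6L, `-3` = 7L)
  unname(code[as.character(q)])
}

STANDARD_VALENCE <- list(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                         P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

#' Construct a ligand
#'
#' @param id molecule title.
#' @param elements character vector of element symbols.
#' @param charges integer formal charges (default all 0).
#' @param bonds data frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3) and `aromatic` (logical). Aromatic bonds may also be
#'   given as order 4 with `aromatic` omitted.
#' @param conformers list of n x 3 coordinate matrices (Angstrom).
#' @return A `ligand` object with perceived rings, aromaticity and implicit
#'   hydrogen counts.
#' @export
new_ligand <- function(id, elements, bonds, conformers, charges = NULL) {
  n <- length(elements)
  if (is.null(charges)) charges <- integer(n)
  bonds <- as.data.frame(bonds)
  if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4
  bonds$order[bonds$order == 4] <- 1L   # order used only for valence math
  stopifnot(all(bonds$i >= 1), all(bonds$j <= n), all(bonds$i != bonds$j))
  conformers <- lapply(conformers, function(x) {
    x <- rbind(x)
    if (nrow(x) != n) stop("conformer atom count mismatch")
    dimnames(x) <- NULL
    x
  })
  lig <- structure(list(id = id, elements = elements,
                        charges = as.integer(charges), bonds = bonds,
                        conformers = conformers, natoms = n),
                   class = "ligand")
  lig <- perceive_rings(lig)
  lig <- perceive_aromaticity(lig)
  lig$implicit_h <- implicit_h_counts(lig)
  lig$adj <- adjacency_list(lig)
  lig
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand '%s': %d atoms, %d bonds, %d conformer%s>\n",
              x$id, x$natoms, nrow(x$bonds), length(x$conformers),
              if (length(x$conformers) == 1) "" else "s"))
  invisible(x)
}

adjacency_list <- function(lig) {
  adj <- vector("list", lig$natoms)
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

heavy_neighbours <- function(lig, a) {
  nb <- lig$adj[[a]]
  nb[lig$elements[nb] != "H"]
}

## Smallest rings (<= max_size) found by per-bond shortest-cycle search.
perceive_rings <- function(lig, max_size = 8L) {
  n <- lig$natoms
  adj <- adjacency_list(lig)
  rings <- list()
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    # BFS from j to i avoiding the bond i-j
    prev <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    dist[j] <- 0L; queue <- j
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if ((v == j && u == i) || (v == i && u == j)) next
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L; prev[u] <- v
          if (u != i) queue <- c(queue, u)
        }
      }
    }
    if (!is.na(dist[i]) && dist[i] + 1L <= max_size) {
      path <- i
      while (path[length(path)] != j) path <- c(path, prev[path[length(path)]])
      rings[[length(rings) + 1L]] <- sort(path)
    }
  }
  lig$rings <- unique(rings)
  ring_atoms <- unique(unlist(lig$rings))
  lig$in_ring <- seq_len(lig$natoms) %in% ring_atoms
  bkey <- paste(pmin(lig$bonds$i, lig$bonds$j), pmax(lig$bonds$i, lig$bonds$j))
  ring_bkeys <- unlist(lapply(lig$rings, function(r) {
    # bond in ring if both atoms in ring and bonded
    sub <- lig$bonds[lig$bonds$i %in% r & lig$bonds$j %in% r, , drop = FALSE]
    paste(pmin(sub$i, sub$j), pmax(sub$i, sub$j))
  }))
  lig$bond_in_ring <- bkey %in% ring_bkeys
  lig
}

## Aromaticity: trusted from the file (bond flagged aromatic / order 4), plus
## perception of Kekule 5/6-rings of C/N with alternating single/double bonds.
perceive_aromaticity <- function(lig) {
  arom_bond <- lig$bonds$aromatic
  for (r in lig$rings) {
    if (!length(r) %in% c(5L, 6L)) next
    if (!all(lig$elements[r] %in% c("C", "N"))) next
    sel <- lig$bonds$i %in% r & lig$bonds$j %in% r
    ords <- lig$bonds$order[sel]
    if (length(r) == 6L && sum(ords == 2) == 3 && sum(ords == 1) == 3 &&
        !any(lig$bonds$aromatic[sel])) {
      # check alternation: every ring atom has exactly one ring double bond
      dbl <- lig$bonds[sel & lig$bonds$order == 2, , drop = FALSE]
      cnt <- table(factor(c(dbl$i, dbl$j), levels = r))
      if (all(cnt == 1)) arom_bond[sel] <- TRUE
    }
  }
  lig$bonds$aromatic <- arom_bond
  arom_atoms <- unique(c(lig$bonds$i[arom_bond], lig$bonds$j[arom_bond]))
  lig$aromatic <- seq_len(lig$natoms) %in% arom_atoms
  lig
}

implicit_h_counts <- function(lig) {
  n <- lig$natoms
  bsum <- numeric(n)
  for (k in seq_len(nrow(lig$bonds))) {
    o <- if (lig$bonds$aromatic[k]) 1.5 else lig$bonds$order[k]
    bsum[lig$bonds$i[k]] <- bsum[lig$bonds$i[k]] + o
    bsum[lig$bonds$j[k]] <- bsum[lig$bonds$j[k]] + o
  }
  vapply(seq_len(n), function(a) {
    el <- lig$elements[a]
    val <- STANDARD_VALENCE[[el]]
    if (is.null(val)) return(0L)
    # charge adjustment: N+ gains a bond slot, O-/N- lose one
    val <- val + lig$charges[a] * (if (el %in% c("N", "O", "S", "P")) 1L else 0L)
    need <- ceiling(bsum[a] - 1e-9)
    v <- val[val >= need]
    if (!length(v)) return(0L)
    as.integer(min(v) - need)
  }, integer(1))
}

## Total hydrogen count (explicit + implicit) on atom a.
total_h <- function(lig, a) {
  sum(lig$elements[lig$adj[[a]]] == "H") + lig$implicit_h[a]
}

topology_signature <- function(elements, charges, bonds) {
  b <- bonds[order(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)), ]
  paste(paste(elements, charges, collapse = ";"),
        paste(pmin(b$i, b$j), pmax(b$i, b$j), b$order, b$aromatic,
              collapse = ";"), sep = "|")
}

#' Read ligands from SD (V2000) or MOL2 files
#'
#' Each file may contain several molecules; consecutive records with the same
#' title are grouped as conformers of a single ligand. All conformers of one
#' ligand must agree exactly on topology (elements, charges, bond graph);
#' a mismatch is a hard error naming the ligand.
#'
#' @param paths character vector of file paths.
#' @param format "sd" (default) or "mol2". MOL2 input is converted to SD with
#'   the `obabel` command-line tool, which must be on the PATH.
#' @return List of [new_ligand()] objects, one per distinct title, conformers
#'   in file order.
#' @export
read_ligands <- function(paths, format = c("sd", "mol2")) {
  format <- match.arg(format)
  if (format == "mol2") {
    paths <- vapply(paths, function(p) {
      out <- tempfile(fileext = ".sdf")
      status <- system2("obabel", c(shQuote(p), "-osdf", "-O", shQuote(out)),
                        stdout = FALSE, stderr = FALSE)
      if (status != 0 || !file.exists(out))
        stop("MOL2 conversion failed for ", p, " (is obabel installed?)")
      out
    }, character(1))
  }
  recs <- list()
  for (p in paths) {
    sset <- suppressWarnings(ChemmineR::read.SDFset(p))
    if (length(sset) == 0) stop("empty or unparsable SD file: ", p)
    for (k in seq_along(sset)) recs[[length(recs) + 1L]] <- sset[[k]]
  }
  titles <- vapply(recs, function(s) {
    h <- ChemmineR::header(s)
    t <- h[["Molecule_Name"]]
    if (is.null(t) || is.na(t)) t <- h[[1]]
    trimws(t)
  }, character(1))
  grp <- cumsum(c(TRUE, titles[-1] != titles[-length(titles)]))
  ligands <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    parsed <- lapply(recs[idx], parse_sdf_record)
    sig <- vapply(parsed, function(x)
      topology_signature(x$elements, x$charges, x$bonds), character(1))
    if (length(unique(sig)) != 1)
      stop("topology mismatch between conformers of ligand '", titles[idx[1]],
           "'")
    first <- parsed[[1]]
    ligands[[length(ligands) + 1L]] <-
      new_ligand(id = titles[idx[1]], elements = first$elements,
                 charges = first$charges, bonds = first$bonds,
                 conformers = lapply(parsed, `[[`, "coords"))
  }
  ligands
}

parse_sdf_record <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  codes <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charges <- unname(CHARGE_CODE_TO_CHARGE[as.character(codes)])
  charges[is.na(charges)] <- 0L
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  bonds$aromatic <- bonds$order == 4L
  bonds$order[bonds$aromatic] <- 1L
  list(elements = elements, charges = charges, bonds = bonds, coords = coords)
}

#' Write ligands to an SD (V2000) file
#'
#' One record per conformer, grouped by ligand, titles preserved, so the file
#' round-trips through [read_ligands()]. Optional per-record data fields may
#' be supplied (used when exporting scored overlays).
#'
#' @param ligands list of `ligand` objects.
#' @param path output file.
#' @param data optional named character vector (or list of one vector per
#'   ligand) written as SD data fields on every record.
#' @export
write_ligands <- function(ligands, path, data = NULL) {
  if (inherits(ligands, "ligand")) ligands <- list(ligands)
  sdfs <- list()
  for (li in seq_along(ligands)) {
    lig <- ligands[[li]]
    dat <- if (is.null(data)) character(0)
           else if (is.list(data)) data[[li]] else data
    for (ci in seq_along(lig$conformers))
      sdfs[[length(sdfs) + 1L]] <- as_sdf_record(lig, ci, dat)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(unlist(sdfs), con)
  invisible(path)
}

## Format one V2000 record. The fixed-width connection table is assembled
## here (writer only; parsing is done by ChemmineR).
as_sdf_record <- function(lig, conf_index, data = character(0)) {
  xyz <- lig$conformers[[conf_index]]
  n <- lig$natoms; nb <- nrow(lig$bonds)
  lines <- c(lig$id, "  ligover", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    code <- CHARGE_TO_CODE(max(min(lig$charges[a], 3L), -3L))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
      xyz[a, 1], xyz[a, 2], xyz[a, 3], lig$elements[a], code))
  }
  ords <- ifelse(lig$bonds$aromatic, 4L, lig$bonds$order)
  for (k in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0", lig$bonds$i[k], lig$bonds$j[k],
                              ords[k]))
  lines <- c(lines, "M  END")
  if (length(data))
    for (nm in names(data))
      lines <- c(lines, sprintf("> <%s>", nm), as.character(data[[nm]]), "")
  c(lines, "$$$$")
}

## A positioned conformation: ligand + conformer index + live coordinates
## (possibly torsion-driven and rigid-body moved).
new_conformation <- function(ligand, conformer_index = 1L, coords = NULL,
                             torsions = NULL) {
  if (is.null(coords)) coords <- ligand$conformers[[conformer_index]]
  structure(list(ligand = ligand, conformer_index = conformer_index,
                 coords = coords, torsions = torsions),
            class = "conformation")
}
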