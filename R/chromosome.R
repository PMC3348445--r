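## Chromosomes: compact overlay encodings.
##
## A chromosome fully defines the conformation, position and orientation of
## every ligand: a conformer index and optional torsion values per ligand, a
## shared mapping table matching fitting points across ligands, and optional
## rigid-body terms (three intrinsic x-y-z Euler angles about the ligand
## centroid, then a translation). Decoding places the first ligand as
## supplied and least-squares fits each subsequent ligand's mapped fitting
## points onto the running per-column centroids of the ligands already
## placed.

#' Construct a chromosome
#'
#' @param conformers integer vector, one conformer index per ligand.
#' @param mapping integer matrix (ligands x columns) of fitting-point
#'   indices, NA for missing entries; at least 3 columns.
#' @param torsions optional list (per ligand) of torsion values in degrees,
#'   or NULL to use conformers directly.
#' @param rigid optional list (per ligand) of c(rx, ry, rz, tx, ty, tz)
#'   (degrees, Angstrom), or NULL.
#' @export
new_chromosome <- function(conformers, mapping, torsions = NULL,
                           rigid = NULL) {
  mapping <- as.matrix(mapping)
  storage.mode(mapping) <- "integer"
  nlig <- length(conformers)
  if (nrow(mapping) != nlig) stop("mapping table must have one row per ligand")
  if (ncol(mapping) < 3L) stop("mapping table needs at least 3 columns")
  structure(list(conformers = as.integer(conformers), mapping = mapping,
                 torsions = torsions, rigid = rigid),
            class = "chromosome")
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("<chromosome: %d ligands, %d mapping columns%s%s>\n",
              length(x$conformers), ncol(x$mapping),
              if (is.null(x$torsions)) "" else ", torsions",
              if (is.null(x$rigid)) "" else ", rigid-body terms"))
  invisible(x)
}

validate_chromosome <- function(chromosome, system) {
  nlig <- system$nlig
  if (length(chromosome$conformers) != nlig)
    stop("chromosome ligand count mismatch")
  for (li in seq_len(nlig)) {
    k <- chromosome$conformers[li]
    if (is.na(k) || k < 1L || k > length(system$ligands[[li]]$conformers))
      stop("invalid conformer index for ligand ", system$ids[li])
    npts <- nrow(system$fp[[li]][[1]]$meta)
    row <- chromosome$mapping[li, ]
    if (any(!is.na(row) & (row < 1L | row > npts)))
      stop("mapping table references a missing fitting point of ligand ",
           system$ids[li])
    if (!is.null(chromosome$torsions) &&
        !is.null(chromosome$torsions[[li]]) &&
        length(chromosome$torsions[[li]]) != length(system$rotors[[li]]))
      stop("torsion count mismatch for ligand ", system$ids[li])
  }
  invisible(TRUE)
}

## Greedy placement order over a (possibly incomplete) mapping table:
## start from the pair sharing the most complete columns, then add ligands
## by descending count of columns shared with placed material (>= 3
## required). Returns the ligand order or NULL when no order exists.
placement_order <- function(mapping) {
  nlig <- nrow(mapping)
  if (nlig == 1L) return(1L)
  has <- !is.na(mapping)
  shared <- matrix(0L, nlig, nlig)
  for (i in seq_len(nlig - 1L)) for (j in seq(i + 1L, nlig))
    shared[i, j] <- shared[j, i] <- sum(has[i, ] & has[j, ])
  best <- which(shared == max(shared), arr.ind = TRUE)[1, ]
  if (shared[best[1], best[2]] < 3L) return(NULL)
  order_ <- sort(as.integer(best))
  while (length(order_) < nlig) {
    rest <- setdiff(seq_len(nlig), order_)
    usable <- vapply(rest, function(li)
      sum(has[li, ] & colSums(has[order_, , drop = FALSE]) > 0L), integer(1))
    if (max(usable) < 3L) return(NULL)
    order_ <- c(order_, rest[which.max(usable)])
  }
  order_
}

#' Decode a chromosome into an overlay
#'
#' Conformations are built (driving torsions when present), then ligands are
#' placed in a greedy order: the first as supplied, each subsequent one by
#' Kabsch-fitting its mapped fitting points onto the per-column centroids of
#' the already-placed ligands (missing entries skipped column-wise). Rigid-
#' body terms, when present, are applied afterwards. Identical chromosomes
#' decode to identical coordinates.
#'
#' @param chromosome a `chromosome`.
#' @param system from [build_system()].
#' @return An `overlay`.
#' @export
decode_chromosome <- function(chromosome, system) {
  validate_chromosome(chromosome, system)
  nlig <- system$nlig
  states <- vector("list", nlig)
  fps <- vector("list", nlig)
  for (li in seq_len(nlig)) {
    k <- chromosome$conformers[li]
    coords <- system$ligands[[li]]$conformers[[k]]
    tor <- if (is.null(chromosome$torsions)) NULL else chromosome$torsions[[li]]
    if (!is.null(tor) && length(tor))
      coords <- drive_torsions(coords, system$rotors[[li]], tor)
    states[[li]] <- list(conf = k, coords = coords)
    fps[[li]] <- if (is.null(tor) || !length(tor))
      system$fp[[li]][[k]]
    else place_fitting_points(system$features[[li]], coords,
                              use_normals = system$config$use_normals)
  }
  ord <- placement_order(chromosome$mapping)
  if (is.null(ord))
    stop("invalid chromosome: no ligand ordering allows placement ",
         "(need >= 3 shared mapping columns)")
  placed <- ord[1]
  for (li in ord[-1]) {
    cols <- which(!is.na(chromosome$mapping[li, ]))
    src <- list(); dst <- list()
    for (cc in cols) {
      contrib <- placed[!is.na(chromosome$mapping[placed, cc])]
      if (!length(contrib)) next
      target <- colMeans(do.call(rbind, lapply(contrib, function(pj)
        fps[[pj]]$xyz[chromosome$mapping[pj, cc], , drop = FALSE])))
      src[[length(src) + 1L]] <- fps[[li]]$xyz[chromosome$mapping[li, cc], ]
      dst[[length(dst) + 1L]] <- target
    }
    if (length(src) < 3L)
      stop("invalid chromosome: ligand ", system$ids[li],
           " shares fewer than 3 usable mapping columns")
    tf <- kabsch_fit(do.call(rbind, src), do.call(rbind, dst))
    states[[li]]$coords <- apply_transform(states[[li]]$coords, tf)
    fps[[li]]$xyz <- apply_transform(fps[[li]]$xyz, tf)
    placed <- c(placed, li)
  }
  if (!is.null(chromosome$rigid)) {
    for (li in seq_len(nlig)) {
      rg <- chromosome$rigid[[li]]
      if (is.null(rg) || all(rg == 0)) next
      centre <- colMeans(states[[li]]$coords)
      tf <- euler_xyz_transform(rg[1:3], centre = centre,
                                translation = rg[4:6])
      states[[li]]$coords <- apply_transform(states[[li]]$coords, tf)
    }
  }
  new_overlay(system, states, chromosome = chromosome)
}

#' Serialise chromosomes to JSON and back
#'
#' Field-exact round trip for persistent storage of solution sets; the
#' schema is versioned.
#' @param chromosomes a `chromosome` or list of them.
#' @param path optional file; when NULL the JSON string is returned.
#' @export
chromosomes_to_json <- function(chromosomes, path = NULL) {
  if (inherits(chromosomes, "chromosome")) chromosomes <- list(chromosomes)
  doc <- list(schema = "ligover-chromosome/1",
              solutions = lapply(chromosomes, function(ch) list(
                conformers = ch$conformers,
                mapping = apply(ch$mapping, 1, function(r)
                  ifelse(is.na(r), -1L, r), simplify = FALSE),
                torsions = ch$torsions,
                rigid = ch$rigid)))
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname chromosomes_to_json
#' @param json a JSON string or file path produced by [chromosomes_to_json()].
#' @export
chromosomes_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$schema, "ligover-chromosome/1"))
    stop("unrecognised chromosome schema")
  lapply(doc$solutions, function(s) {
    mapping <- do.call(rbind, lapply(s$mapping, unlist))
    mapping[mapping < 0L] <- NA_integer_
    new_chromosome(conformers = unlist(s$conformers), mapping = mapping,
                   torsions = if (is.null(s$torsions)) NULL
                              else lapply(s$torsions, unlist),
                   rigid = if (is.null(s$rigid)) NULL
                           else lapply(s$rigid, unlist))
  })
}

## Deduplication key: mapping table + conformer indices (+ torsions).
chromosome_key <- function(ch) {
  paste(paste(ch$conformers, collapse = ","),
        paste(ifelse(is.na(ch$mapping), "x", ch$mapping), collapse = ","),
        if (is.null(ch$torsions)) "" else
          paste(round(unlist(ch$torsions), 1), collapse = ","),
        sep = "|")
}
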