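#' Read a (possibly multi-MODEL) PDB file
#'
#' Parses a PDB file into a \linkS4class{Trajectory} with one frame per
#' MODEL (a file without MODEL records yields one frame). Elements come from
#' columns 77-78 when present, otherwise from atom-name heuristics. Alternate
#' locations are resolved by policy; water residues (HOH/WAT/TIP3/SOL) are
#' dropped unless \code{keepWaters}. Insertion codes are rejected: author
#' residue numbering is authoritative and silently merging inserted residues
#' would corrupt sequence separations.
#'
#' @param path PDB file path.
#' @param altlocPolicy \code{"occupancy"} keeps the highest-occupancy
#'   alternate (ties: first encountered); \code{"first"} keeps the first.
#' @param keepWaters keep water residues (default FALSE).
#' @param replicateId replicate label attached to the trajectory.
#' @param backboneSet atom names treated as backbone.
#' @return a \linkS4class{Trajectory}
#' @export
readPDB <- function(path, altlocPolicy = c("occupancy", "first"),
                    keepWaters = FALSE, replicateId = basename(path),
                    backboneSet = .BACKBONE_SET) {
  altlocPolicy <- match.arg(altlocPolicy)
  if (!file.exists(path)) stop(sprintf("cannot read PDB file: %s", path))
  .validatePDBLines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop(sprintf("no ATOM/HETATM records in %s", path))
  if (any(!is.na(a$insert) & nzchar(a$insert))) {
    stop(sprintf("insertion codes present in %s: not supported", path))
  }
  xyz <- pdb$xyz                       # nFrames x (3 * nAtoms)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)

  keep <- rep(TRUE, nrow(a))
  if (!keepWaters) {
    keep <- keep & !(a$resid %in% c("HOH", "WAT", "TIP3", "SOL"))
  }
  keep <- keep & .resolveAltloc(a, altlocPolicy)
  if (!any(keep)) stop(sprintf("no atoms left after filtering in %s", path))
  a <- a[keep, , drop = FALSE]
  xyz <- xyz[, as.vector(rbind(3L * which(keep) - 2L,
                               3L * which(keep) - 1L,
                               3L * which(keep))), drop = FALSE]

  element <- a$elesy
  miss <- is.na(element) | !nzchar(trimws(element))
  if (any(miss)) {
    element[miss] <- mapply(inferElement, a$elety[miss], a$resid[miss])
  }
  element <- trimws(element)

  topo <- Topology(
    data.frame(serial = a$eleno, name = a$elety, element = element,
               chain = ifelse(is.na(a$chain), " ", a$chain),
               resno = a$resno, resname = a$resid, stringsAsFactors = FALSE),
    backboneSet = backboneSet
  )
  nAtoms <- nrow(a)
  nFr <- nrow(xyz)
  co <- array(NA_real_, dim = c(nAtoms, 3L, nFr))
  for (f in seq_len(nFr)) {
    co[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  new("Trajectory", topology = topo, coords = co, replicateId = replicateId)
}

# Raw-line sanity scan: MODEL blocks must contain identical numbers of
# coordinate records (bio3d only warns, producing misaligned frames).
.validatePDBLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isCoord <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isCoord)) stop(sprintf("no ATOM/HETATM records in %s", path))
  starts <- which(rec == "MODEL ")
  if (length(starts) > 1L) {
    model_id <- findInterval(which(isCoord), starts)
    counts <- tabulate(model_id, nbins = length(starts))
    if (length(unique(counts[counts > 0])) > 1L) {
      stop(sprintf("inconsistent atom counts across MODELs in %s: %s",
                   path, paste(counts, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

# TRUE for atoms to keep under the alternate-location policy.
.resolveAltloc <- function(a, policy) {
  alt <- a$alt
  hasAlt <- !is.na(alt) & nzchar(alt)
  keep <- rep(TRUE, nrow(a))
  if (!any(hasAlt)) return(keep)
  key <- paste(a$chain, a$resno, a$resid, a$elety)
  for (k in unique(key[hasAlt])) {
    idx <- which(key == k)
    if (length(idx) == 1L) next
    sel <- if (policy == "occupancy") {
      occ <- ifelse(is.na(a$o[idx]), 1, a$o[idx])
      idx[which.max(occ)]            # which.max: first on ties
    } else {
      idx[1L]
    }
    keep[setdiff(idx, sel)] <- FALSE
  }
  keep
}

#' Read and concatenate trajectory files over a known topology
#'
#' Frames from each file are appended in path order. Every file must match
#' the topology's atom count.
#'
#' @param topology a \linkS4class{Topology}.
#' @param paths character vector of multi-MODEL PDB paths.
#' @param replicateId replicate label for the combined trajectory.
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(topology, paths, replicateId = "rep1") {
  if (!length(paths)) stop("empty frame list")
  frames <- lapply(paths, function(p) {
    tr <- readPDB(p)
    if (atomCount(tr) != atomCount(topology)) {
      stop(sprintf("atom count mismatch in %s: %d vs topology %d",
                   p, atomCount(tr), atomCount(topology)))
    }
    tr@coords
  })
  co <- array(unlist(frames), dim = c(atomCount(topology), 3L,
                                      sum(vapply(frames, function(x) dim(x)[3], 1L))))
  new("Trajectory", topology = topology, coords = co, replicateId = replicateId)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Fixed-width PDB records; coordinates at 3 decimals (the format's field
#' precision).
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param path output file path
#' @return invisibly, the path
#' @export
writePDB <- function(trajectory, path) {
  a <- atoms(trajectory)
  recname <- ifelse(a$resname %in% .STANDARD_AA, "ATOM  ", "HETATM")
  con <- file(path, "w")
  on.exit(close(con))
  nFr <- nFrames(trajectory)
  for (f in seq_len(nFr)) {
    xyz <- trajectory@coords[, , f]
    if (nFr > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      recname, a$serial %% 100000L, .padAtomName(a$name), " ", a$resname,
      a$chain, a$resno, " ", xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(a$element, 1, 2)), con)
    if (nFr > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# PDB atom-name column convention: names of 1-3 characters for one-letter
# elements start in column 14.
.padAtomName <- function(name) {
  ifelse(nchar(name) >= 4L, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a point cloud as an XYZ file
#'
#' @param points n x 3 matrix of coordinates (Angstrom)
#' @param path output path
#' @param element element symbol for the pseudo-atoms
#' @param comment comment line
#' @return invisibly, the path
#' @export
writeXYZ <- function(points, path, element = "C", comment = "point cloud") {
  points <- as.matrix(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(points)), comment), con)
  writeLines(sprintf("%s %12.6f %12.6f %12.6f", element,
                     points[, 1], points[, 2], points[, 3]), con)
  invisible(path)
}

#' Write a results table as CSV
#'
#' Deterministic output: header row, floats at 6 significant digits, rows
#' ordered by pair label then frame index when those columns are present.
#'
#' @param records data.frame of results
#' @param path output path
#' @return invisibly, the path
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records)
  ord <- intersect(c("pair", "pair_label", "replicate", "frame", "frame_index"),
                   names(records))
  if (length(ord)) {
    records <- records[do.call(order, records[ord]), , drop = FALSE]
  }
  isNum <- vapply(records, is.double, TRUE)
  records[isNum] <- lapply(records[isNum], signif, digits = 6L)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
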