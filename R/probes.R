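#' Select atoms of a residue or residue name
#'
#' @param topology a \linkS4class{Topology}
#' @param chain,resno residue identity; either both given, or neither
#' @param resname 3-letter residue name selecting all matching residues
#' @param heavyOnly drop hydrogens (default TRUE)
#' @return integer vector of atom row indices
#' @export
selectAtoms <- function(topology, chain = NULL, resno = NULL, resname = NULL,
                        heavyOnly = TRUE) {
  a <- topology@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (!is.null(resno)) keep <- keep & a$resno == resno
  if (!is.null(resname)) keep <- keep & a$resname == resname
  if (heavyOnly) keep <- keep & !a$isHydrogen
  idx <- which(keep)
  if (!length(idx)) stop("empty atom selection")
  idx
}

#' Minimum ligand-residue distance per frame
#'
#' For every frame, the minimum Euclidean distance between any heavy atom of
#' the ligand selection and any heavy atom of the target residue (hydrogens
#' never participate). Symmetric in the two selections and invariant under
#' rigid motions of a frame.
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param ligandIdx,targetIdx integer atom index vectors (see
#'   \code{\link{selectAtoms}}); hydrogens are removed again defensively
#' @return numeric vector of per-frame distances (Angstrom)
#' @export
minDistanceSeries <- function(trajectory, ligandIdx, targetIdx) {
  topo <- trajectory@topology
  ligandIdx <- ligandIdx[!topo@atoms$isHydrogen[ligandIdx]]
  targetIdx <- targetIdx[!topo@atoms$isHydrogen[targetIdx]]
  if (!length(ligandIdx) || !length(targetIdx)) stop("empty atom selection")
  co <- trajectory@coords
  best <- rep(Inf, nFrames(trajectory))
  for (i in ligandIdx) {
    for (j in targetIdx) {
      diff <- co[i, , , drop = FALSE] - co[j, , , drop = FALSE]
      d <- sqrt(colSums(matrix(diff, nrow = 3L)^2))
      best <- pmin(best, d)
    }
  }
  best
}

# coords array -> bio3d xyz matrix (frames x 3N, interleaved x,y,z)
.asXYZMatrix <- function(co) {
  t(matrix(aperm(co, c(2L, 1L, 3L)), nrow = 3L * dim(co)[1]))
}

#' Ligand occupancy cloud after superposition
#'
#' Least-squares (Kabsch) superposition of every frame onto the first frame
#' of the first replicate, using the alignment selection (by default the
#' C-alpha atoms of all standard protein residues); the ligand heavy-atom
#' positions of all superposed frames are then pooled into one point cloud.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of replicates over
#'   a common topology
#' @param ligandIdx heavy-atom indices of the ligand selection
#' @param alignIdx atom indices used for superposition (>= 3, non-collinear);
#'   default: all protein C-alpha atoms
#' @param refXYZ optional explicit reference frame (\code{nAtoms x 3}
#'   matrix); default: the first frame of the first replicate
#' @return matrix (nFrames * nLigandAtoms) x 3 of pooled positions, with a
#'   \code{frame} attribute giving each point's source frame
#' @export
occupancyCloud <- function(trajectories, ligandIdx, alignIdx = NULL,
                           refXYZ = NULL) {
  trajectories <- .asTrajectoryList(trajectories)
  topo <- trajectories[[1]]@topology
  a <- topo@atoms
  if (is.null(alignIdx)) {
    alignIdx <- which(a$name == "CA" & a$resname %in% .STANDARD_AA)
  }
  if (length(alignIdx) < 3L) stop("alignment selection needs >= 3 atoms")
  ligandIdx <- ligandIdx[!a$isHydrogen[ligandIdx]]
  if (!length(ligandIdx)) stop("empty ligand selection")

  ref <- if (is.null(refXYZ)) trajectories[[1]]@coords[, , 1] else as.matrix(refXYZ)
  if (nrow(ref) != nrow(a)) stop("reference frame atom count mismatch")
  refA <- ref[alignIdx, , drop = FALSE]
  sv <- svd(scale(refA, scale = FALSE))$d
  if (length(sv) < 2L || sv[2] < 1e-6 * max(sv[1], 1)) {
    stop("degenerate (collinear) alignment selection")
  }
  fixedXYZ <- as.vector(t(ref))
  inds <- bio3d::atom2xyz(alignIdx)

  pts <- list()
  frames <- integer(0)
  off <- 0L
  for (tr in trajectories) {
    mob <- .asXYZMatrix(tr@coords)
    fitted <- bio3d::fit.xyz(fixed = fixedXYZ, mobile = mob,
                             fixed.inds = inds, mobile.inds = inds)
    if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
    for (f in seq_len(nrow(fitted))) {
      xyz <- matrix(fitted[f, ], ncol = 3L, byrow = TRUE)
      pts[[length(pts) + 1L]] <- xyz[ligandIdx, , drop = FALSE]
      frames <- c(frames, rep(off + f, length(ligandIdx)))
    }
    off <- off + nFrames(tr)
  }
  cloud <- do.call(rbind, pts)
  colnames(cloud) <- c("x", "y", "z")
  attr(cloud, "frame") <- frames
  cloud
}

#' Channel bottleneck radius per frame (axis-sweep estimator)
#'
#' A simplified tunnel estimator: points are sampled along a straight axis
#' from the start-residue centroid; the free radius at a point is the
#' smallest (distance to any heavy atom centre minus its van-der-Waals
#' radius), floored at zero and capped; the per-frame bottleneck is the
#' minimum free radius along the path. Points narrower than the probe radius
#' mark the tunnel as closed in that frame (the bottleneck is reported
#' regardless). This is a declared approximation of full Voronoi-based tunnel
#' search: it assumes the tunnel is straight and its axis known, and it is
#' validated against analytic cylinder fixtures only.
#'
#' @param trajectory a \linkS4class{Trajectory}
#' @param start start residue, list with \code{chain}, \code{resno}
#' @param direction length-3 axis direction (need not be normalised); or
#'   supply \code{end} instead
#' @param end optional end residue (list with \code{chain}, \code{resno});
#'   the axis then runs from the start centroid towards the end centroid
#' @param step axial sampling step, Angstrom (default 0.5)
#' @param pathLength swept length, Angstrom (default 30)
#' @param probeRadius probe radius marking closure, Angstrom (default 0.9)
#' @param cap maximum reported free radius, Angstrom (default 5)
#' @param vdwRadii named radii table (default \code{\link{bondiRadii}})
#' @param excludeStart drop the start residue's own atoms from the sweep
#'   (the probe starts inside it); default TRUE
#' @return a \linkS4class{ChannelProfile}
#' @export
bottleneckSeries <- function(trajectory, start, direction = NULL, end = NULL,
                             step = 0.5, pathLength = 30, probeRadius = 0.9,
                             cap = 5.0, vdwRadii = bondiRadii(),
                             excludeStart = TRUE) {
  if (step <= 0) stop("step must be positive")
  topo <- trajectory@topology
  startIdx <- heavyAtoms(topo, start$chain, start$resno)
  if (!length(startIdx)) stop("start residue has no heavy atoms")

  atomIdx <- which(!topo@atoms$isHydrogen)
  if (excludeStart) atomIdx <- setdiff(atomIdx, residueAtomIndices(topo, start$chain, start$resno))
  if (!length(atomIdx)) stop("no atoms to sweep against")
  el <- topo@atoms$element[atomIdx]
  unknown <- setdiff(unique(el), names(vdwRadii))
  if (length(unknown)) {
    stop(sprintf("no vdW radius for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  radii <- vdwRadii[el]

  nFr <- nFrames(trajectory)
  tvals <- seq(0, pathLength, by = step)
  radiiOut <- numeric(nFr)
  closed <- logical(nFr)
  for (f in seq_len(nFr)) {
    xyz <- trajectory@coords[, , f]
    origin <- colMeans(xyz[startIdx, , drop = FALSE])
    dir <- if (!is.null(end)) {
      endIdx <- heavyAtoms(topo, end$chain, end$resno)
      colMeans(xyz[endIdx, , drop = FALSE]) - origin
    } else if (!is.null(direction)) {
      as.numeric(direction)
    } else {
      stop("supply either a direction vector or an end residue")
    }
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) stop("zero-length axis")
    dir <- dir / nrm
    pts <- outer(tvals, dir) + rep(origin, each = length(tvals))
    at <- xyz[atomIdx, , drop = FALSE]
    d2 <- outer(rowSums(pts^2), rowSums(at^2), "+") - 2 * tcrossprod(pts, at)
    free <- sqrt(pmax(d2, 0)) - rep(radii, each = length(tvals))
    freeAtPoint <- pmin(apply(free, 1L, min), cap)
    radiiOut[f] <- max(0, min(freeAtPoint))
    closed[f] <- any(freeAtPoint < probeRadius)
  }
  new("ChannelProfile", radii = radiiOut, closed = closed,
      probeRadius = probeRadius, step = step, cap = cap,
      startLabel = sprintf("%s:%d", start$chain, start$resno))
}

#' Bottleneck radii of a channel profile
#' @param x a \linkS4class{ChannelProfile}
#' @export
setGeneric("bottleneckRadii", function(x) standardGeneric("bottleneckRadii"))

#' @rdname bottleneckRadii
#' @export
setMethod("bottleneckRadii", "ChannelProfile", function(x) x@radii)

setMethod("show", "ChannelProfile", function(object) {
  cat(sprintf(
    "ChannelProfile from %s: %d frames, bottleneck %.2f-%.2f A (probe %.2f A)\n",
    object@startLabel, length(object@radii), min(object@radii),
    max(object@radii), object@probeRadius))
})

#' Fraction of water-permissive frames
#'
#' Fraction of frames whose bottleneck radius strictly exceeds the water
#' probe radius; above 1.4 Angstrom a tunnel is taken to permit water
#' passage.
#'
#' @param profile a \linkS4class{ChannelProfile}
#' @param rWater water probe radius, Angstrom (default 1.4)
#' @return fraction in [0, 1]
#' @export
permissiveFraction <- function(profile, rWater = 1.4) {
  mean(profile@radii > rWater)
}
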