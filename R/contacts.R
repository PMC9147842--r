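#' Bondi van-der-Waals radii
#'
#' The de-facto standard radii (Angstrom) used by the contact criterion:
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 (D treated as H), plus
#' common halogens. User-supplied tables override these.
#'
#' @return named numeric vector, element symbol to radius
#' @export
bondiRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, D = 1.20,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
}

#' Construct a van-der-Waals contact criterion
#'
#' @param vdwRadii named radii table (Angstrom); defaults to
#'   \code{\link{bondiRadii}}
#' @param epsilon slack added to the radius sum (Angstrom, default 0.25)
#' @param heavyOnly restrict to heavy atoms (default TRUE)
#' @return a \linkS4class{ContactSpec}
#' @export
ContactSpec <- function(vdwRadii = bondiRadii(), epsilon = 0.25,
                        heavyOnly = TRUE) {
  new("ContactSpec", vdwRadii = vdwRadii, epsilon = epsilon,
      heavyOnly = heavyOnly)
}

# radii for a set of atom rows; error on unknown element (no silent default)
.atomRadii <- function(topology, idx, spec) {
  el <- topology@atoms$element[idx]
  unknown <- setdiff(unique(el), names(spec@vdwRadii))
  if (length(unknown)) {
    stop(sprintf("no vdW radius for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  spec@vdwRadii[el]
}

.contactSelections <- function(topology, a, b, spec) {
  if (identical(a$chain, b$chain) && a$resno == b$resno) {
    stop("the two residues must be distinct")
  }
  pick <- function(r) {
    idx <- residueAtomIndices(topology, r$chain, r$resno)
    if (spec@heavyOnly) idx <- idx[!topology@atoms$isHydrogen[idx]]
    idx
  }
  list(idxA = pick(a), idxB = pick(b))
}

#' Van-der-Waals contact between two residues in one frame
#'
#' TRUE when any qualifying atom pair has centre distance strictly less than
#' the sum of the two van-der-Waals radii plus the slack \code{epsilon}; a
#' distance exactly at the bound is not a contact.
#'
#' @param xyz frame coordinates, \code{nAtoms x 3} matrix
#' @param topology a \linkS4class{Topology}
#' @param a,b residue identities (lists with \code{chain}, \code{resno})
#' @param spec a \linkS4class{ContactSpec}
#' @return logical flag
#' @export
vdwContact <- function(xyz, topology, a, b, spec = ContactSpec()) {
  sel <- .contactSelections(topology, a, b, spec)
  if (!length(sel$idxA) || !length(sel$idxB)) return(FALSE)
  rA <- .atomRadii(topology, sel$idxA, spec)
  rB <- .atomRadii(topology, sel$idxB, spec)
  A <- xyz[sel$idxA, , drop = FALSE]
  B <- xyz[sel$idxB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  bound <- outer(rA, rB, "+") + spec@epsilon
  any(sqrt(pmax(d2, 0)) < bound)
}

# Per-frame contact flags for one pair across all frames of one trajectory.
.contactFrames <- function(trajectory, a, b, spec) {
  topo <- trajectory@topology
  sel <- .contactSelections(topo, a, b, spec)
  nFr <- nFrames(trajectory)
  if (!length(sel$idxA) || !length(sel$idxB)) return(rep(FALSE, nFr))
  rA <- .atomRadii(topo, sel$idxA, spec)
  rB <- .atomRadii(topo, sel$idxB, spec)
  co <- trajectory@coords
  hit <- rep(FALSE, nFr)
  for (i in seq_along(sel$idxA)) {
    for (j in seq_along(sel$idxB)) {
      diff <- co[sel$idxA[i], , , drop = FALSE] -
              co[sel$idxB[j], , , drop = FALSE]
      d <- sqrt(colSums(matrix(diff, nrow = 3L)^2))
      hit <- hit | (d < rA[i] + rB[j] + spec@epsilon)
    }
  }
  hit
}

#' Contact fraction of a residue pair over replicate trajectories
#'
#' Fraction of frames, pooled across all replicates, in which the pair is in
#' van-der-Waals contact. Pooling mirrors reporting contact occupancy over
#' the concatenated simulation time of independent repetitions.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of replicates
#' @param a,b residue identities (lists with \code{chain}, \code{resno})
#' @param spec a \linkS4class{ContactSpec}
#' @return fraction in [0, 1]
#' @export
contactFraction <- function(trajectories, a, b, spec = ContactSpec()) {
  trajectories <- .asTrajectoryList(trajectories)
  hits <- unlist(lapply(trajectories, .contactFrames, a = a, b = b,
                        spec = spec))
  if (!length(hits)) stop("zero total frames")
  mean(hits)
}

#' Average contact fractions for a condition
#'
#' Applies \code{\link{contactFraction}} to every pair of a registry.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of replicates
#' @param pairs a \linkS4class{PairSet}
#' @param bwMap a \linkS4class{BWMap}
#' @param spec a \linkS4class{ContactSpec}
#' @param condition condition label
#' @return an \linkS4class{ACFTable}
#' @export
acfTable <- function(trajectories, pairs, bwMap, spec = ContactSpec(),
                     condition = "condition") {
  trajectories <- .asTrajectoryList(trajectories)
  topo <- trajectories[[1]]@topology
  total <- sum(vapply(trajectories, nFrames, 1L))
  p <- pairs@pairs
  rows <- lapply(seq_len(nrow(p)), function(k) {
    rp <- resolvePair(p$labelA[k], p$labelB[k], bwMap, topo)
    data.frame(pair = rp$label,
               fraction = contactFraction(trajectories, rp$a, rp$b, spec),
               nFrames = total, stringsAsFactors = FALSE)
  })
  new("ACFTable", condition = condition, fractions = do.call(rbind, rows))
}

#' Condition label and fractions of an ACFTable
#' @param x an \linkS4class{ACFTable}
#' @export
setGeneric("acfFractions", function(x) standardGeneric("acfFractions"))

#' @rdname acfFractions
#' @export
setMethod("acfFractions", "ACFTable", function(x) x@fractions)

setMethod("show", "ACFTable", function(object) {
  cat(sprintf("ACFTable '%s': %d pairs over %d frames\n", object@condition,
              nrow(object@fractions),
              if (nrow(object@fractions)) object@fractions$nFrames[1] else 0L))
})

.acfLookup <- function(acf, pairLabels) {
  f <- acf@fractions
  missing <- setdiff(pairLabels, f$pair)
  if (length(missing)) {
    stop(sprintf("pair(s) missing from ACF table '%s': %s", acf@condition,
                 paste(missing, collapse = ", ")))
  }
  stats::setNames(f$fraction[match(pairLabels, f$pair)], pairLabels)
}

#' Global-effect metric between apo and ligand-bound contact fractions
#'
#' Sums the squared per-pair differences between the reference and
#' ligand-bound average contact fractions, separately over the pairs
#' expected to gain contacts upon activation (\code{gePlus}) and those
#' expected to lose them (\code{geMinus}). With \code{rooted = TRUE} the
#' Euclidean norm of the difference vector is reported instead of its
#' squared norm.
#'
#' @param acfApo,acfLig \linkS4class{ACFTable}s covering all pairs of both
#'   sets
#' @param pairsPlus,pairsMinus \linkS4class{PairSet}s (or character vectors
#'   of pair labels) for the gain and loss sums
#' @param rooted report the square-rooted (Euclidean) variant
#' @return a \linkS4class{GEResult}
#' @export
geMetric <- function(acfApo, acfLig, pairsPlus, pairsMinus, rooted = FALSE) {
  labels <- function(ps) {
    if (is(ps, "PairSet")) pairLabel(ps@pairs$labelA, ps@pairs$labelB)
    else as.character(ps)
  }
  lp <- labels(pairsPlus)
  lm <- labels(pairsMinus)
  sq <- function(labs) {
    if (!length(labs)) return(0)
    d <- .acfLookup(acfApo, labs) - .acfLookup(acfLig, labs)
    sum(d^2)
  }
  gp <- sq(lp)
  gm <- sq(lm)
  if (rooted) { gp <- sqrt(gp); gm <- sqrt(gm) }
  new("GEResult", gePlus = gp, geMinus = gm, rooted = rooted,
      pairsPlus = lp, pairsMinus = lm)
}

#' @describeIn geMetric accessors for the two global-effect values
#' @param x a \linkS4class{GEResult}
#' @export
setGeneric("gePlus", function(x) standardGeneric("gePlus"))

#' @rdname geMetric
#' @export
setMethod("gePlus", "GEResult", function(x) x@gePlus)

#' @rdname geMetric
#' @export
setGeneric("geMinus", function(x) standardGeneric("geMinus"))

#' @rdname geMetric
#' @export
setMethod("geMinus", "GEResult", function(x) x@geMinus)

setMethod("show", "GEResult", function(object) {
  cat(sprintf("GEResult (%s): GE+ = %.4g over %d pairs, GE- = %.4g over %d pairs\n",
              if (object@rooted) "rooted" else "sum of squares",
              object@gePlus, length(object@pairsPlus),
              object@geMinus, length(object@pairsMinus)))
})
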