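#' Residue-residue contact score parameters
#'
#' @param rMin,rMax distance bounds of the piecewise-linear kernel (Angstrom)
#' @param nearSequenceThreshold residue separation at or below which backbone
#'   atoms of both residues are excluded from the score
#' @return an \linkS4class{RRCSParams}
#' @export
RRCSParams <- function(rMin = 3.23, rMax = 4.63, nearSequenceThreshold = 4L) {
  new("RRCSParams", rMin = rMin, rMax = rMax,
      nearSequenceThreshold = as.integer(nearSequenceThreshold))
}

#' Per-atom-pair distance score
#'
#' Piecewise-linear contact kernel: 1 at or below \code{rMin}, 0 at or above
#' \code{rMax}, and \eqn{(r_{max} - r) / (r_{max} - r_{min})} in between.
#' Continuous and non-increasing in the distance.
#'
#' @param r distance(s), Angstrom; must be finite and non-negative
#' @param params an \linkS4class{RRCSParams}
#' @return score(s) in [0, 1]
#' @export
deltaScore <- function(r, params = RRCSParams()) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("distances must be finite and non-negative")
  }
  pmin(1, pmax(0, (params@rMax - r) / (params@rMax - params@rMin)))
}

# Heavy-atom index pair for a residue pair, applying the backbone-exclusion
# rule: same-chain pairs within nearSequenceThreshold positions lose the
# backbone atoms of BOTH residues; cross-chain pairs are always "far".
.rrcsSelections <- function(topology, a, b, params) {
  sameChain <- identical(a$chain, b$chain)
  if (sameChain && a$resno == b$resno) stop("the two residues must be distinct")
  near <- sameChain && abs(a$resno - b$resno) <= params@nearSequenceThreshold
  list(idxA = heavyAtoms(topology, a$chain, a$resno, excludeBackbone = near),
       idxB = heavyAtoms(topology, b$chain, b$resno, excludeBackbone = near))
}

#' Residue-residue contact score for one frame
#'
#' Unweighted sum of \code{\link{deltaScore}} over the heavy-atom
#' cross-product of the two residues. For residues on the same chain within
#' \code{nearSequenceThreshold} sequence positions, backbone atoms of both
#' residues are excluded so that trivially persistent backbone contacts of
#' sequence neighbours do not dominate the score. Symmetric in residue order.
#'
#' @param xyz frame coordinates, \code{nAtoms x 3} matrix (Angstrom)
#' @param topology a \linkS4class{Topology}
#' @param a,b residue identities, each a list with \code{chain} and
#'   \code{resno}
#' @param params an \linkS4class{RRCSParams}
#' @return the score, a non-negative real
#' @export
rrcsPairFrame <- function(xyz, topology, a, b, params = RRCSParams()) {
  sel <- .rrcsSelections(topology, a, b, params)
  if (!length(sel$idxA) || !length(sel$idxB)) return(0)
  A <- xyz[sel$idxA, , drop = FALSE]
  B <- xyz[sel$idxB, , drop = FALSE]
  if (anyNA(A) || anyNA(B)) stop("missing coordinates for pair atoms")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sum(deltaScore(sqrt(pmax(d2, 0)), params))
}

#' RRCS time series over trajectories
#'
#' Computes a per-frame contact-score series for every pair in the registry
#' and every replicate trajectory, sampling frames at the given stride
#' starting from the first frame.
#'
#' @param trajectories a \linkS4class{Trajectory} or list of replicate
#'   trajectories over a common topology
#' @param pairs a \linkS4class{PairSet}
#' @param bwMap a \linkS4class{BWMap} resolving the pair labels
#' @param params an \linkS4class{RRCSParams}
#' @param stride positive frame sampling stride
#' @return data.frame with columns \code{pair_label}, \code{replicate},
#'   \code{frame_index} (0-based original frame index), \code{rrcs}
#' @export
rrcsSeries <- function(trajectories, pairs, bwMap, params = RRCSParams(),
                       stride = 1L) {
  trajectories <- .asTrajectoryList(trajectories)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be a positive integer")
  out <- list()
  for (tr in trajectories) {
    nFr <- nFrames(tr)
    if (stride > 1L && stride >= nFr) {
      stop(sprintf("stride %d too large for %d frames", stride, nFr))
    }
    sel <- seq.int(1L, nFr, by = stride)
    for (k in seq_len(nrow(pairs@pairs))) {
      rp <- resolvePair(pairs@pairs$labelA[k], pairs@pairs$labelB[k],
                        bwMap, tr@topology)
      scores <- .rrcsFrames(tr, rp$a, rp$b, params, sel)
      out[[length(out) + 1L]] <- data.frame(
        pair_label = rp$label, replicate = tr@replicateId,
        frame_index = sel - 1L, rrcs = scores, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Vectorised per-frame scores for one pair across selected frames.
.rrcsFrames <- function(trajectory, a, b, params, frameSel) {
  sel <- .rrcsSelections(trajectory@topology, a, b, params)
  if (!length(sel$idxA) || !length(sel$idxB)) {
    return(rep(0, length(frameSel)))
  }
  co <- trajectory@coords
  scores <- numeric(length(frameSel))
  for (i in sel$idxA) {
    for (j in sel$idxB) {
      diff <- co[i, , frameSel, drop = FALSE] - co[j, , frameSel, drop = FALSE]
      d <- sqrt(colSums(matrix(diff, nrow = 3L)^2))
      scores <- scores + deltaScore(d, params)
    }
  }
  scores
}

.asTrajectoryList <- function(trajectories) {
  if (is(trajectories, "Trajectory")) return(list(trajectories))
  if (!length(trajectories) || !all(vapply(trajectories, is, TRUE, "Trajectory"))) {
    stop("expected a Trajectory or a non-empty list of Trajectory objects")
  }
  trajectories
}

#' Pooled RRCS histogram
#'
#' Pools score values across all rows of a series table (typically all
#' replicates of one condition) into left-closed, right-open bins starting
#' at 0.
#'
#' @param series data.frame as returned by \code{\link{rrcsSeries}}
#' @param binWidth positive bin width (default 0.25 score units)
#' @param condition condition label carried into the result
#' @return data.frame with columns \code{binStart}, \code{binEnd},
#'   \code{count} and attributes \code{condition}, \code{binWidth}
#' @export
rrcsHistogram <- function(series, binWidth = 0.25, condition = "condition") {
  if (binWidth <= 0) stop("binWidth must be positive")
  x <- series$rrcs
  if (!length(x)) stop("empty series")
  nBins <- max(1L, floor(max(x) / binWidth) + 1L)
  bin <- pmin(floor(x / binWidth), nBins - 1L) + 1L
  counts <- tabulate(bin, nbins = nBins)
  out <- data.frame(binStart = (seq_len(nBins) - 1L) * binWidth,
                    binEnd = seq_len(nBins) * binWidth,
                    count = counts)
  attr(out, "condition") <- condition
  attr(out, "binWidth") <- binWidth
  out
}

#' Classify pairs as increased, decreased or unaffected
#'
#' For each pair, the condition mean is the mean of per-replicate mean
#' scores; the verdict compares the ligand-minus-apo difference against a
#' symmetric threshold.
#'
#' @param apo,lig series tables (\code{\link{rrcsSeries}}) for the reference
#'   and ligand-bound conditions; must cover the same pair labels
#' @param threshold non-negative verdict threshold on the mean difference
#'   (default 0.2 score units, small against the unit step of a single
#'   atom-pair contact)
#' @return data.frame with columns \code{pair_label}, \code{meanApo},
#'   \code{meanLig}, \code{delta}, \code{verdict}
#' @export
classifyPairs <- function(apo, lig, threshold = 0.2) {
  if (threshold < 0) stop("threshold must be >= 0")
  mApo <- .conditionMeans(apo)
  mLig <- .conditionMeans(lig)
  if (!setequal(names(mApo), names(mLig))) {
    stop("apo and ligand series must cover the same pair labels")
  }
  labs <- sort(names(mApo))
  delta <- mLig[labs] - mApo[labs]
  verdict <- ifelse(delta >= threshold, "increased",
                    ifelse(delta <= -threshold, "decreased", "unaffected"))
  data.frame(pair_label = labs, meanApo = unname(mApo[labs]),
             meanLig = unname(mLig[labs]), delta = unname(delta),
             verdict = unname(verdict), stringsAsFactors = FALSE)
}

# mean of per-replicate means, per pair label
.conditionMeans <- function(series) {
  repMeans <- stats::aggregate(rrcs ~ pair_label + replicate, data = series,
                               FUN = mean)
  out <- stats::aggregate(rrcs ~ pair_label, data = repMeans, FUN = mean)
  stats::setNames(out$rrcs, out$pair_label)
}
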