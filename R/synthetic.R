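GENERATOR_VERSION <- "1.0"

# Side-chain/backbone atom templates by heavy-atom count. The anchor atom
# (CB) realises the pair's reference distance; remaining atoms sit at fixed
# offsets on the far side of the anchor so that the anchor pair always
# dominates the inter-residue distance.
.SYN_TEMPLATES <- list(
  c("CB"),
  c("CB", "CG"),
  c("N", "CA", "CB"),
  c("N", "CA", "C", "CB"),
  c("N", "CA", "C", "O", "CB")
)
.SYN_ELEMENT <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C", CG = "C")
# offsets (Angstrom) relative to the anchor, all with non-positive x so a
# residue's atoms never extend towards its partner
.SYN_OFFSETS <- rbind(
  N  = c(-1.2,  0.8,  0.0),
  CA = c(-0.8, -0.5,  0.3),
  C  = c(-1.5, -0.9, -0.4),
  O  = c(-2.0,  0.5,  0.2),
  CB = c( 0.0,  0.0,  0.0),
  CG = c(-0.9,  0.4, -0.7)
)

#' Specify a synthetic two-state contact system
#'
#' Each designated pair is realised as two residues whose reference
#' (anchor-anchor) distance follows a two-state Markov chain between
#' \code{dContact} and \code{dApart} with stationary contact-state occupancy
#' \code{f}, isotropic per-atom Gaussian jitter \code{sigma} and mean
#' contact-state dwell time \code{meanDwell} frames. Sequence separations
#' both within and beyond the backbone-exclusion window are represented by
#' default (separations alternate 2 and 10 across pairs).
#'
#' @param nFrames frames to generate (>= 10)
#' @param seed integer seed; generation is bit-reproducible
#' @param f stationary contact fraction(s) in (0, 1), recycled across pairs
#' @param nPairs number of designated pairs
#' @param dContact,dApart contact/apart reference distances (Angstrom)
#' @param sigma per-atom isotropic jitter standard deviation (Angstrom)
#' @param meanDwell mean dwell time of the contact state (frames)
#' @param separation residue-sequence separations, recycled (default
#'   alternates 2 and 10)
#' @param nAtomsA,nAtomsB heavy atoms per residue (1-5), recycled
#' @param condition condition label
#' @return a \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(nFrames, seed, f, nPairs = length(f),
                          dContact = 3.0, dApart = 8.0, sigma = 0.1,
                          meanDwell = 20, separation = NULL,
                          nAtomsA = NULL, nAtomsB = NULL,
                          condition = "APO") {
  if (is.null(separation)) separation <- rep(c(2L, 10L), length.out = nPairs)
  if (is.null(nAtomsA)) nAtomsA <- rep(c(5L, 1L, 3L, 2L, 4L), length.out = nPairs)
  if (is.null(nAtomsB)) nAtomsB <- rep(c(5L, 1L, 2L, 4L, 3L), length.out = nPairs)
  ps <- data.frame(
    label = sprintf("1.%dx2.%d", 40L + seq_len(nPairs), 40L + seq_len(nPairs)),
    f = rep_len(f, nPairs),
    dContact = rep_len(dContact, nPairs),
    dApart = rep_len(dApart, nPairs),
    sigma = rep_len(sigma, nPairs),
    meanDwell = rep_len(meanDwell, nPairs),
    separation = as.integer(rep_len(separation, nPairs)),
    nAtomsA = as.integer(rep_len(nAtomsA, nPairs)),
    nAtomsB = as.integer(rep_len(nAtomsB, nPairs)),
    stringsAsFactors = FALSE)
  new("SyntheticSpec", nFrames = as.integer(nFrames), seed = as.integer(seed),
      pairSpecs = ps, condition = condition)
}

# Two-state Markov chain with stationary contact occupancy f and mean
# contact dwell meanDwell frames; returns logical vector (TRUE = contact).
.markovStates <- function(n, f, meanDwell) {
  pLeave <- 1 / meanDwell                  # contact -> apart
  pEnter <- f / (1 - f) * pLeave           # apart -> contact
  if (pEnter > 1) {
    stop(sprintf("contact fraction %.3f unreachable at meanDwell %.1f", f, meanDwell))
  }
  s <- logical(n)
  s[1] <- stats::runif(1) < f              # start from stationarity
  u <- stats::runif(n - 1L)
  for (t in seq_len(n - 1L)) {
    s[t + 1L] <- if (s[t]) u[t] >= pLeave else u[t] < pEnter
  }
  s
}

# Independent naive contact-score oracle used for manifest ground truth:
# plain double loop with its own kernel arithmetic, deliberately not sharing
# code with the scoring engine.
.oracleRRCS <- function(xyzA, xyzB, rMin = 3.23, rMax = 4.63) {
  s <- 0
  for (i in seq_len(nrow(xyzA))) {
    for (j in seq_len(nrow(xyzB))) {
      r <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
      s <- s + if (r <= rMin) 1 else if (r >= rMax) 0 else (rMax - r) / (rMax - rMin)
    }
  }
  s
}

#' Generate a synthetic two-state pair trajectory
#'
#' Builds a small multi-residue topology realising every pair of \code{spec}
#' (plus two distant scaffold residues that contribute nothing to any
#' score), then simulates per-frame coordinates: each pair's anchor-anchor
#' distance follows its two-state Markov chain, with isotropic Gaussian
#' jitter applied per atom. All randomness derives from \code{spec}'s single
#' seed; regeneration is bit-identical.
#'
#' The manifest records, per pair, the designed stationary contact fraction,
#' the realised fraction of frames spent in the contact state, and the mean
#' contact score of the generated coordinates computed by an independent
#' brute-force oracle (not by the scoring engine).
#'
#' @param spec a \linkS4class{SyntheticSpec}
#' @return list with elements \code{trajectory} (\linkS4class{Trajectory}),
#'   \code{manifest} (list), \code{bwMap} (\linkS4class{BWMap}) and
#'   \code{pairs} (\linkS4class{PairSet}) describing the generated system
#' @export
generatePairSystem <- function(spec) {
  validObject(spec)
  ps <- spec@pairSpecs
  nP <- nrow(ps)
  nFr <- spec@nFrames

  # --- topology -----------------------------------------------------------
  atomRows <- list()
  bwRows <- list()
  serial <- 0L
  resnames <- rep_len(.STANDARD_AA, 2L * nP + 2L)
  pairInfo <- vector("list", nP)
  for (k in seq_len(nP)) {
    baseRes <- 100L * k
    yOff <- 60 * (k - 1L)
    tplA <- .SYN_TEMPLATES[[ps$nAtomsA[k]]]
    tplB <- .SYN_TEMPLATES[[ps$nAtomsB[k]]]
    rowsA <- data.frame(serial = serial + seq_along(tplA), name = tplA,
                        element = unname(.SYN_ELEMENT[tplA]), chain = "A",
                        resno = baseRes, resname = resnames[2L * k - 1L],
                        stringsAsFactors = FALSE)
    serial <- serial + length(tplA)
    rowsB <- data.frame(serial = serial + seq_along(tplB), name = tplB,
                        element = unname(.SYN_ELEMENT[tplB]), chain = "A",
                        resno = baseRes + ps$separation[k],
                        resname = resnames[2L * k],
                        stringsAsFactors = FALSE)
    serial <- serial + length(tplB)
    atomRows[[2L * k - 1L]] <- rowsA
    atomRows[[2L * k]] <- rowsB
    labs <- strsplit(ps$label[k], "x", fixed = TRUE)[[1]]
    bwRows[[2L * k - 1L]] <- data.frame(chain = "A", resno = baseRes,
                                        label = labs[1], stringsAsFactors = FALSE)
    bwRows[[2L * k]] <- data.frame(chain = "A", resno = baseRes + ps$separation[k],
                                   label = labs[2], stringsAsFactors = FALSE)
    pairInfo[[k]] <- list(k = k, yOff = yOff,
                          idxA = rowsA$serial, idxB = rowsB$serial,
                          tplA = tplA, tplB = tplB,
                          resA = baseRes, resB = baseRes + ps$separation[k])
  }
  # scaffold residues, > 20 A away from every pair region
  for (s in 1:2) {
    tpl <- .SYN_TEMPLATES[[5]]
    atomRows[[length(atomRows) + 1L]] <- data.frame(
      serial = serial + seq_along(tpl), name = tpl,
      element = unname(.SYN_ELEMENT[tpl]), chain = "S",
      resno = s, resname = resnames[2L * nP + s], stringsAsFactors = FALSE)
    serial <- serial + length(tpl)
  }
  atomTab <- do.call(rbind, atomRows)
  topo <- Topology(atomTab)
  nAtoms <- nrow(atomTab)

  # --- coordinates --------------------------------------------------------
  set.seed(spec@seed)
  co <- array(0, dim = c(nAtoms, 3L, nFr))
  manifestPairs <- vector("list", nP)
  for (k in seq_len(nP)) {
    pi <- pairInfo[[k]]
    states <- .markovStates(nFr, ps$f[k], ps$meanDwell[k])
    dRef <- ifelse(states, ps$dContact[k], ps$dApart[k])
    # residue A: anchor at (0, yOff, 0), offsets towards -x
    baseA <- .SYN_OFFSETS[pi$tplA, , drop = FALSE]
    baseA[, 2] <- baseA[, 2] + pi$yOff
    # residue B: anchor at (d, yOff, 0), offsets mirrored towards +x
    baseB <- .SYN_OFFSETS[pi$tplB, , drop = FALSE]
    baseB[, 1] <- -baseB[, 1]
    baseB[, 2] <- baseB[, 2] + pi$yOff
    nA <- length(pi$idxA); nB <- length(pi$idxB)
    jitter <- if (ps$sigma[k] > 0) {
      array(stats::rnorm(3L * (nA + nB) * nFr, sd = ps$sigma[k]),
            dim = c(nA + nB, 3L, nFr))
    } else {
      array(0, dim = c(nA + nB, 3L, nFr))
    }
    for (f in seq_len(nFr)) {
      xyzA <- baseA + jitter[seq_len(nA), , f, drop = TRUE]
      xyzB <- baseB + jitter[nA + seq_len(nB), , f, drop = TRUE]
      if (nA == 1L) xyzA <- matrix(xyzA, nrow = 1L)
      if (nB == 1L) xyzB <- matrix(xyzB, nrow = 1L)
      xyzB[, 1] <- xyzB[, 1] + dRef[f]
      co[pi$idxA, , f] <- xyzA
      co[pi$idxB, , f] <- xyzB
    }
    # manifest ground truth via the independent oracle; the score's
    # backbone-exclusion rule applies to sequence-near pairs
    near <- ps$separation[k] <= 4L
    oA <- pi$idxA[!(near & pi$tplA %in% c("N", "CA", "C", "O", "OXT"))]
    oB <- pi$idxB[!(near & pi$tplB %in% c("N", "CA", "C", "O", "OXT"))]
    meanScore <- mean(vapply(seq_len(nFr), function(f) {
      .oracleRRCS(matrix(co[oA, , f], ncol = 3L),
                  matrix(co[oB, , f], ncol = 3L))
    }, numeric(1)))
    manifestPairs[[k]] <- data.frame(
      label = ps$label[k], trueFraction = ps$f[k],
      stateFraction = mean(states), expectedMeanRRCS = meanScore,
      stringsAsFactors = FALSE)
  }
  # scaffold: static, far away on chain S
  scaffoldIdx <- which(atomTab$chain == "S")
  for (i in seq_along(scaffoldIdx)) {
    co[scaffoldIdx[i], 1, ] <- -40 - 5 * i
    co[scaffoldIdx[i], 2, ] <- -40
  }

  traj <- new("Trajectory", topology = topo, coords = co,
              replicateId = sprintf("%s-seed%d", spec@condition, spec@seed))
  manifest <- list(seed = spec@seed, condition = spec@condition,
                   nFrames = nFr, generator = GENERATOR_VERSION,
                   pairs = do.call(rbind, manifestPairs))
  bwMap <- new("BWMap", entries = do.call(rbind, bwRows))
  pairs <- PairSet(vapply(strsplit(ps$label, "x", fixed = TRUE), `[`, "", 1L),
                   vapply(strsplit(ps$label, "x", fixed = TRUE), `[`, "", 2L))
  list(trajectory = traj, manifest = manifest, bwMap = bwMap, pairs = pairs)
}

.oracleRRCSMatrix <- function(xyzA, xyzB) .oracleRRCS(xyzA, xyzB)

#' Generate a synthetic cylindrical channel
#'
#' A static single-frame cylinder of atoms around the z axis: \code{nRings}
#' rings of \code{atomsPerRing} atoms at radius \code{ringRadius}, spaced
#' \code{spacing} Angstrom apart, each ring one residue on chain C. The
#' analytic bottleneck radius of such a channel is
#' \code{ringRadius - vdW(element)}; the manifest records it as ground
#' truth.
#'
#' @param ringRadius ring radius, Angstrom; must exceed the element's vdW
#'   radius (otherwise the channel is geometrically closed)
#' @param nRings number of rings (residues)
#' @param atomsPerRing atoms per ring
#' @param element element symbol of the ring atoms (default C)
#' @param spacing axial ring spacing, Angstrom (default 1)
#' @param vdwRadii radii table used for the ground-truth bottleneck
#' @return list with \code{trajectory} and \code{manifest}
#' @export
generateChannelSystem <- function(ringRadius, nRings = 10L, atomsPerRing = 8L,
                                  element = "C", spacing = 1.0,
                                  vdwRadii = bondiRadii()) {
  if (!element %in% names(vdwRadii)) {
    stop(sprintf("no vdW radius for element %s", element))
  }
  rv <- vdwRadii[[element]]
  if (ringRadius <= rv) {
    stop(sprintf("ring radius %.2f <= vdW radius %.2f: channel closed",
                 ringRadius, rv))
  }
  ang <- 2 * pi * (seq_len(atomsPerRing) - 1L) / atomsPerRing
  rows <- list()
  xyz <- list()
  for (r in seq_len(nRings)) {
    rows[[r]] <- data.frame(
      serial = (r - 1L) * atomsPerRing + seq_len(atomsPerRing),
      name = paste0(element, seq_len(atomsPerRing)),
      element = element, chain = "C", resno = r, resname = "RNG",
      stringsAsFactors = FALSE)
    xyz[[r]] <- cbind(ringRadius * cos(ang), ringRadius * sin(ang),
                      (r - 1L) * spacing)
  }
  topo <- Topology(do.call(rbind, rows))
  co <- array(do.call(rbind, xyz), dim = c(nRings * atomsPerRing, 3L, 1L))
  traj <- new("Trajectory", topology = topo, coords = co,
              replicateId = "channel")
  manifest <- list(generator = GENERATOR_VERSION,
                   trueBottleneck = ringRadius - rv,
                   ringRadius = ringRadius, element = element,
                   nRings = nRings, atomsPerRing = atomsPerRing,
                   spacing = spacing)
  list(trajectory = traj, manifest = manifest)
}

#' Generate matched apo and ligand-bound synthetic conditions
#'
#' Both specs must imply the same topology (same pairs, separations and atom
#' counts); only the contact fractions (and dynamics parameters) may differ,
#' giving designed per-pair effect sizes with known expected classification
#' and global-effect outputs.
#'
#' @param apoSpec,ligSpec \linkS4class{SyntheticSpec}s for the two
#'   conditions
#' @return list with \code{apo}, \code{lig} (each as returned by
#'   \code{\link{generatePairSystem}}) and \code{pairs}, a
#'   \linkS4class{PairSet} annotated with the designed direction of change
#' @export
generateConditionPair <- function(apoSpec, ligSpec) {
  topoCols <- c("label", "separation", "nAtomsA", "nAtomsB")
  if (!identical(apoSpec@pairSpecs[topoCols], ligSpec@pairSpecs[topoCols]) ||
      apoSpec@nFrames != ligSpec@nFrames) {
    stop("apo and ligand specs imply different topologies")
  }
  apo <- generatePairSystem(apoSpec)
  lig <- generatePairSystem(ligSpec)
  dF <- ligSpec@pairSpecs$f - apoSpec@pairSpecs$f
  direction <- ifelse(dF > 1e-12, "increase",
                      ifelse(dF < -1e-12, "decrease", "unspecified"))
  labs <- strsplit(apoSpec@pairSpecs$label, "x", fixed = TRUE)
  pairs <- PairSet(vapply(labs, `[`, "", 1L), vapply(labs, `[`, "", 2L),
                   direction)
  list(apo = apo, lig = lig, pairs = pairs)
}
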