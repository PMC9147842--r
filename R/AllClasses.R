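#' @import methods
NULL

.BACKBONE_SET <- c("N", "CA", "C", "O", "OXT")

#' Topology of a molecular system
#'
#' Atom-level description of a molecular system: one row per atom with its
#' serial number, atom name, element symbol, chain identifier, author residue
#' number and residue name, plus derived hydrogen/backbone flags. Residues are
#' identified by the pair (chain, residue number); author (PDB) numbering is
#' authoritative throughout the package.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{chain}, \code{resno}, \code{resname},
#'   \code{isHydrogen}, \code{isBackbone}.
#' @slot backboneSet character vector of atom names treated as protein
#'   backbone (default \code{N, CA, C, O, OXT}).
#' @export
setClass("Topology",
  representation(atoms = "data.frame", backboneSet = "character"),
  prototype(backboneSet = .BACKBONE_SET)
)

setValidity("Topology", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("serial", "name", "element", "chain", "resno", "resname",
            "isHydrogen", "isBackbone")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) == 0L) msgs <- c(msgs, "topology has no atoms")
  if (anyNA(a$resno) || anyNA(a$chain)) {
    msgs <- c(msgs, "chain/resno must not contain NA")
  }
  bad_h <- a$isHydrogen != (a$element %in% c("H", "D"))
  if (any(bad_h)) msgs <- c(msgs, "isHydrogen inconsistent with element")
  bad_b <- a$isBackbone != (a$name %in% object@backboneSet)
  if (any(bad_b)) msgs <- c(msgs, "isBackbone inconsistent with backboneSet")
  # atom names unique within a residue (after altloc resolution)
  key <- paste(a$chain, a$resno, a$name)
  if (anyDuplicated(key)) {
    msgs <- c(msgs, "duplicate atom name within a residue")
  }
  # residue order nondecreasing in resno within each chain
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    if (is.unsorted(r)) {
      msgs <- c(msgs, sprintf("residue numbers not nondecreasing in chain %s", ch))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Coordinate ensemble over a fixed topology
#'
#' A trajectory couples a \linkS4class{Topology} with an ordered stack of
#' coordinate frames (Angstrom). Frames may carry simulation times and a
#' replicate label so that independent MD repetitions can be pooled downstream.
#'
#' @slot topology the \linkS4class{Topology}.
#' @slot coords numeric array \code{nAtoms x 3 x nFrames}, Angstrom.
#' @slot frameTimes numeric, simulation times in ns (length 0 if unknown).
#' @slot replicateId single character label for the replicate.
#' @export
setClass("Trajectory",
  representation(topology = "Topology", coords = "array",
                 frameTimes = "numeric", replicateId = "character"),
  prototype(frameTimes = numeric(0), replicateId = "rep1")
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3L || d[2] != 3L) {
    return("coords must be an nAtoms x 3 x nFrames array")
  }
  if (d[1] != nrow(object@topology@atoms)) {
    msgs <- c(msgs, "frame atom count does not match topology")
  }
  if (d[3] < 1L) msgs <- c(msgs, "trajectory has no frames")
  if (!all(is.finite(object@coords))) msgs <- c(msgs, "non-finite coordinates")
  if (length(object@frameTimes) &&
      length(object@frameTimes) != d[3]) {
    msgs <- c(msgs, "frameTimes length does not match frame count")
  }
  if (length(object@replicateId) != 1L) msgs <- c(msgs, "replicateId must be length 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Ballesteros-Weinstein label map
#'
#' Associates residues (chain, author residue number) with
#' Ballesteros-Weinstein generic labels \code{"H.NN"} (helix 1-8, position
#' relative to the most conserved residue of the helix, numbered 50).
#' Non-helical residues (loops) are representable with an explicit
#' \code{"x-"} prefix and are excluded from pathway analysis by default.
#'
#' @slot entries data.frame with columns \code{chain}, \code{resno},
#'   \code{label}.
#' @export
setClass("BWMap", representation(entries = "data.frame"))

.bw_label_ok <- function(label) {
  grepl("^[1-8]\\.[0-9]{1,3}$", label) | grepl("^x-", label)
}

setValidity("BWMap", function(object) {
  e <- object@entries
  if (!all(c("chain", "resno", "label") %in% names(e))) {
    return("entries must have columns chain, resno, label")
  }
  msgs <- character()
  bad <- !.bw_label_ok(e$label)
  if (any(bad)) {
    msgs <- c(msgs, paste("malformed BW label(s):",
                          paste(unique(e$label[bad]), collapse = ", ")))
  }
  if (anyDuplicated(paste(e$chain, e$resno))) msgs <- c(msgs, "duplicate residue")
  if (anyDuplicated(paste(e$chain, e$label))) {
    msgs <- c(msgs, "duplicate label within a chain (map must be injective)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Registry of activation-pathway residue pairs
#'
#' An unordered set of Ballesteros-Weinstein label pairs, each annotated with
#' the direction of contact change expected upon receptor activation
#' (\code{"increase"}, \code{"decrease"} or \code{"unspecified"}).
#'
#' @slot pairs data.frame with columns \code{labelA}, \code{labelB},
#'   \code{direction}.
#' @export
setClass("PairSet", representation(pairs = "data.frame"))

setValidity("PairSet", function(object) {
  p <- object@pairs
  if (!all(c("labelA", "labelB", "direction") %in% names(p))) {
    return("pairs must have columns labelA, labelB, direction")
  }
  msgs <- character()
  if (any(p$labelA == p$labelB)) msgs <- c(msgs, "a pair must join two distinct labels")
  if (!all(p$direction %in% c("increase", "decrease", "unspecified"))) {
    msgs <- c(msgs, "direction must be increase, decrease or unspecified")
  }
  key <- apply(cbind(p$labelA, p$labelB), 1L,
               function(x) paste(sort(x), collapse = "|"))
  if (anyDuplicated(key)) msgs <- c(msgs, "duplicate unordered pair")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Parameters of the residue-residue contact score
#'
#' The per-atom-pair score is 1 below \code{rMin}, 0 above \code{rMax} and
#' linear in between. Backbone atoms of both residues are excluded from the
#' sum when the residues lie on the same chain within
#' \code{nearSequenceThreshold} positions of each other.
#'
#' @slot rMin lower distance bound, Angstrom (default 3.23).
#' @slot rMax upper distance bound, Angstrom (default 4.63).
#' @slot nearSequenceThreshold residue-separation cutoff for the backbone
#'   exclusion rule (default 4).
#' @export
setClass("RRCSParams",
  representation(rMin = "numeric", rMax = "numeric",
                 nearSequenceThreshold = "integer"),
  prototype(rMin = 3.23, rMax = 4.63, nearSequenceThreshold = 4L)
)

setValidity("RRCSParams", function(object) {
  if (length(object@rMin) != 1L || length(object@rMax) != 1L ||
      !is.finite(object@rMin) || !is.finite(object@rMax)) {
    return("rMin and rMax must be single finite numbers")
  }
  if (!(object@rMin > 0 && object@rMin < object@rMax)) {
    return("require 0 < rMin < rMax")
  }
  if (object@nearSequenceThreshold < 0L) return("nearSequenceThreshold must be >= 0")
  TRUE
})

#' Van-der-Waals contact criterion
#'
#' Two atoms are in contact when the distance between their centres is
#' strictly less than the sum of their van-der-Waals radii plus
#' \code{epsilon}. Radii default to the Bondi set; elements missing from the
#' table raise an error rather than receiving a silent default.
#'
#' @slot vdwRadii named numeric vector, element symbol to radius (Angstrom).
#' @slot epsilon slack distance added to the radius sum (default 0.25).
#' @slot heavyOnly consider heavy atoms only (default TRUE).
#' @export
setClass("ContactSpec",
  representation(vdwRadii = "numeric", epsilon = "numeric",
                 heavyOnly = "logical"),
  prototype(epsilon = 0.25, heavyOnly = TRUE)
)

setValidity("ContactSpec", function(object) {
  if (is.null(names(object@vdwRadii)) || any(!nzchar(names(object@vdwRadii)))) {
    return("vdwRadii must be a named vector (element symbols)")
  }
  if (any(object@vdwRadii <= 0)) return("all vdW radii must be > 0")
  if (length(object@epsilon) != 1L || object@epsilon < 0) {
    return("epsilon must be a single value >= 0")
  }
  TRUE
})

#' Average contact fractions for one condition
#'
#' Per-pair share of trajectory frames (pooled across replicates) in which
#' the residue pair is in van-der-Waals contact.
#'
#' @slot condition condition label (e.g. \code{"APO"} or a ligand name).
#' @slot fractions data.frame with columns \code{pair}, \code{fraction},
#'   \code{nFrames}.
#' @export
setClass("ACFTable",
  representation(condition = "character", fractions = "data.frame")
)

setValidity("ACFTable", function(object) {
  f <- object@fractions
  if (!all(c("pair", "fraction", "nFrames") %in% names(f))) {
    return("fractions must have columns pair, fraction, nFrames")
  }
  msgs <- character()
  if (any(f$fraction < 0 | f$fraction > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (anyDuplicated(f$pair)) msgs <- c(msgs, "each pair must appear exactly once")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Global-effect metric result
#'
#' Sums of squared contact-fraction differences between a reference (apo) and
#' a ligand-bound condition, taken separately over the pairs expected to gain
#' (\code{gePlus}) and lose (\code{geMinus}) contacts upon activation.
#'
#' @slot gePlus global effect over the gain set.
#' @slot geMinus global effect over the loss set.
#' @slot rooted whether the Euclidean (square-rooted) variant was used.
#' @slot pairsPlus,pairsMinus the pair labels each sum ran over.
#' @export
setClass("GEResult",
  representation(gePlus = "numeric", geMinus = "numeric", rooted = "logical",
                 pairsPlus = "character", pairsMinus = "character"),
  prototype(rooted = FALSE)
)

setValidity("GEResult", function(object) {
  if (object@gePlus < 0 || object@geMinus < 0) return("GE values must be >= 0")
  TRUE
})

#' Per-frame channel bottleneck profile
#'
#' The narrowest free radius along a probe axis through the receptor,
#' evaluated per frame, together with the sampling parameters used.
#'
#' @slot radii per-frame bottleneck radius, Angstrom (capped at \code{cap}).
#' @slot closed per-frame flag: TRUE when any axis point falls below the probe
#'   radius.
#' @slot probeRadius probe radius (Angstrom) marking a tunnel as closed.
#' @slot step axial sampling step (Angstrom).
#' @slot cap maximum reported free radius (Angstrom).
#' @slot startLabel label of the start residue.
#' @export
setClass("ChannelProfile",
  representation(radii = "numeric", closed = "logical", probeRadius = "numeric",
                 step = "numeric", cap = "numeric", startLabel = "character")
)

setValidity("ChannelProfile", function(object) {
  if (length(object@radii) == 0L) return("profile has no frames")
  if (any(object@radii < 0)) return("radii must be >= 0")
  if (any(object@radii > object@cap + 1e-9)) return("radii must not exceed cap")
  if (length(object@closed) != length(object@radii)) {
    return("closed must be parallel to radii")
  }
  TRUE
})

#' Specification of a synthetic two-state contact system
#'
#' Describes a desk-scale trajectory in which designated residue pairs follow
#' a two-state (contact/apart) Markov distance process with prescribed
#' stationary contact fraction, contact/apart reference distances, isotropic
#' Gaussian jitter and mean dwell time. Used to generate ground-truth data for
#' validating every stage of the contact pipeline.
#'
#' @slot nFrames number of frames to generate (>= 10).
#' @slot seed integer seed; regeneration from the same spec is bit-identical.
#' @slot pairSpecs data.frame with columns \code{label}, \code{f},
#'   \code{dContact}, \code{dApart}, \code{sigma}, \code{meanDwell},
#'   \code{separation}, \code{nAtomsA}, \code{nAtomsB}.
#' @slot condition condition label (e.g. \code{"APO"} or \code{"LIG"}).
#' @export
setClass("SyntheticSpec",
  representation(nFrames = "integer", seed = "integer",
                 pairSpecs = "data.frame", condition = "character"),
  prototype(condition = "APO")
)

setValidity("SyntheticSpec", function(object) {
  p <- object@pairSpecs
  need <- c("label", "f", "dContact", "dApart", "sigma", "meanDwell",
            "separation", "nAtomsA", "nAtomsB")
  if (!all(need %in% names(p))) {
    return(paste("pairSpecs must have columns:", paste(need, collapse = ", ")))
  }
  msgs <- character()
  if (object@nFrames < 10L) msgs <- c(msgs, "nFrames must be >= 10")
  if (any(p$f <= 0 | p$f >= 1)) msgs <- c(msgs, "contact fractions must lie in (0, 1)")
  if (any(p$dContact >= p$dApart)) msgs <- c(msgs, "dContact must be < dApart")
  if (any(p$sigma < 0)) msgs <- c(msgs, "jitter sigma must be >= 0")
  if (any(p$meanDwell < 1)) msgs <- c(msgs, "meanDwell must be >= 1 frame")
  if (any(p$nAtomsA < 1 | p$nAtomsA > 5 | p$nAtomsB < 1 | p$nAtomsB > 5)) {
    msgs <- c(msgs, "residues carry 1-5 heavy atoms")
  }
  if (anyDuplicated(p$label)) msgs <- c(msgs, "duplicate pair label")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Validated end-to-end run configuration
#'
#' Holds everything \code{\link{runPipeline}} needs: per-condition trajectory
#' paths, the BW map and pair registry, scoring parameters, strides and
#' thresholds, the output directory and a seed echoed into the provenance
#' block.
#'
#' @slot conditions named list: condition label -> character vector of
#'   trajectory paths (one path per replicate).
#' @slot reference label of the reference (apo) condition.
#' @slot bwMap the \linkS4class{BWMap}.
#' @slot pairs the \linkS4class{PairSet}.
#' @slot rrcsParams \linkS4class{RRCSParams}.
#' @slot contactSpec \linkS4class{ContactSpec}.
#' @slot stride frame sampling stride for RRCS series.
#' @slot threshold verdict threshold on the mean-RRCS difference.
#' @slot outDir output directory.
#' @slot seed integer seed recorded in provenance.
#' @slot writeFigures whether to render histogram figures.
#' @export
setClass("RunConfig",
  representation(conditions = "list", reference = "character",
                 bwMap = "BWMap", pairs = "PairSet",
                 rrcsParams = "RRCSParams", contactSpec = "ContactSpec",
                 stride = "integer", threshold = "numeric",
                 outDir = "character", seed = "integer",
                 writeFigures = "logical"),
  prototype(stride = 1L, threshold = 0.2, seed = 1L, writeFigures = FALSE)
)
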