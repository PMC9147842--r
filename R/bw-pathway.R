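#' Load a Ballesteros-Weinstein map from a two-column TSV
#'
#' Expected format: one entry per line, \code{chain:resnum<TAB>label}, where
#' label is \code{"H.NN"} (helix 1-8) or an explicit \code{"x-"}-prefixed
#' non-helical label. Validation rejects malformed labels, duplicate residues
#' and duplicate labels within a chain.
#'
#' @param path TSV file path
#' @return a \linkS4class{BWMap}
#' @export
loadBWMap <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("BW map file must have two tab-separated columns")
  spec <- trimws(tab[[1]])
  parts <- strsplit(spec, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("malformed residue spec(s): %s",
                 paste(spec[bad], collapse = ", ")))
  }
  new("BWMap", entries = data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    label = trimws(tab[[2]]),
    stringsAsFactors = FALSE))
}

#' Default Ballesteros-Weinstein map for the human M1 muscarinic receptor
#'
#' Built from published residue/label correspondences for human M1 (chain A,
#' author numbering): e.g. Asp71 is 2.50 (sodium pocket), Trp378 is 6.48
#' (tryptophan toggle), Asp122/Arg123 are 3.49/3.50 (DRY motif), Tyr418 is
#' 7.53 (tyrosine toggle). Positions 1.49 (Gly42) and 2.43 (Leu64) are filled
#' in by the within-helix offset that defines BW numbering (positions are
#' consecutive along a helix), anchored at 1.53 = Val46 and 2.50 = Asp71.
#'
#' @return a \linkS4class{BWMap}
#' @export
defaultBWMap <- function() {
  loadBWMap(system.file("extdata", "m1_bw_map.tsv",
                        package = "MicroswitchMD", mustWork = TRUE))
}

#' Look up a Ballesteros-Weinstein label
#'
#' @param map a \linkS4class{BWMap}
#' @param chain chain identifier
#' @param resno author residue number
#' @return the label, or an error if unmapped
#' @export
bwLookup <- function(map, chain, resno) {
  e <- map@entries
  hit <- which(e$chain == chain & e$resno == resno)
  if (!length(hit)) stop(sprintf("residue %s:%d has no BW label", chain, resno))
  e$label[hit]
}

# Inverse lookup: label -> (chain, resno); label must be mapped.
.bwResidue <- function(map, label) {
  e <- map@entries
  hit <- which(e$label == label)
  if (!length(hit)) stop(sprintf("BW label %s not present in map", label))
  if (length(hit) > 1L) {
    stop(sprintf("BW label %s maps to multiple chains; disambiguate the map", label))
  }
  list(chain = e$chain[hit], resno = e$resno[hit])
}

#' Canonical unordered pair label
#'
#' @param labelA,labelB BW labels
#' @return single string \code{"a x b"} with the two labels sorted
#' @export
pairLabel <- function(labelA, labelB) {
  paste(pmin(labelA, labelB), pmax(labelA, labelB), sep = "x")
}

#' Resolve a BW label pair against a topology
#'
#' Maps both labels to concrete residues and reports the quantities the
#' contact-score backbone rule needs: sequence separation and whether the two
#' residues share a chain.
#'
#' @param labelA,labelB BW labels
#' @param bwMap a \linkS4class{BWMap}
#' @param topology a \linkS4class{Topology}
#' @return list with elements \code{a}, \code{b} (each \code{chain},
#'   \code{resno}), \code{separation}, \code{sameChain}, \code{label}
#' @export
resolvePair <- function(labelA, labelB, bwMap, topology) {
  ra <- .bwResidue(bwMap, labelA)
  rb <- .bwResidue(bwMap, labelB)
  residueAtomIndices(topology, ra$chain, ra$resno)
  residueAtomIndices(topology, rb$chain, rb$resno)
  sameChain <- identical(ra$chain, rb$chain)
  list(a = ra, b = rb,
       separation = if (sameChain) abs(ra$resno - rb$resno) else NA_integer_,
       sameChain = sameChain,
       label = pairLabel(labelA, labelB))
}

#' Build a PairSet
#'
#' @param labelA,labelB character vectors of BW labels
#' @param direction expected contact-change direction upon activation
#' @return a \linkS4class{PairSet}
#' @export
PairSet <- function(labelA, labelB, direction = "unspecified") {
  new("PairSet", pairs = data.frame(
    labelA = labelA, labelB = labelB,
    direction = rep_len(direction, length(labelA)),
    stringsAsFactors = FALSE))
}

#' Load a residue-pair registry from a three-column TSV
#'
#' Format: \code{labelA<TAB>labelB<TAB>direction} with direction one of
#' \code{increase}, \code{decrease}, \code{unspecified}.
#'
#' @param path TSV file path
#' @return a \linkS4class{PairSet}
#' @export
loadPairSet <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("pair file must have three tab-separated columns")
  PairSet(trimws(tab[[1]]), trimws(tab[[2]]), trimws(tab[[3]]))
}

#' Default activation-pathway residue pairs
#'
#' The microswitch pairs reported to respond to agonist binding in muscarinic
#' receptors, with their expected direction of contact change upon
#' activation: gains at the toggle/sodium-pocket region (3.40x6.48,
#' 2.50x3.39, 7.50x7.55, 1.49x7.50) and losses at the DRY ionic lock, the
#' tyrosine-toggle environment and the hydrophobic lock (3.49x3.50,
#' 1.53x7.53, 3.46x6.37, 3.43x6.43, 2.43x7.53). The full 34-pair class-A
#' activation pathway is not enumerated here; supply it as an external pair
#' file when available.
#'
#' @return a \linkS4class{PairSet}
#' @export
defaultPathwayPairs <- function() {
  loadPairSet(system.file("extdata", "m1_pathway_pairs.tsv",
                          package = "MicroswitchMD", mustWork = TRUE))
}

setMethod("show", "BWMap", function(object) {
  cat(sprintf("BWMap: %d residue labels on chain(s) %s\n",
              nrow(object@entries),
              paste(unique(object@entries$chain), collapse = ", ")))
})

setMethod("show", "PairSet", function(object) {
  p <- object@pairs
  cat(sprintf("PairSet: %d pairs (%d increase, %d decrease, %d unspecified)\n",
              nrow(p), sum(p$direction == "increase"),
              sum(p$direction == "decrease"),
              sum(p$direction == "unspecified")))
})
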