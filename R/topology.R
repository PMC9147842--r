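#' Build a Topology from an atom table
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{chain}, \code{resno}, \code{resname}. Hydrogen and
#'   backbone flags are derived.
#' @param backboneSet atom names treated as backbone.
#' @return a \linkS4class{Topology}
#' @export
Topology <- function(atoms, backboneSet = .BACKBONE_SET) {
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$isHydrogen <- atoms$element %in% c("H", "D")
  atoms$isBackbone <- atoms$name %in% backboneSet
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms, backboneSet = backboneSet)
}

#' @describeIn Topology number of atoms
#' @param x,object a Topology
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname Topology
#' @export
setMethod("atomCount", "Topology", function(x) nrow(x@atoms))

#' @rdname Topology
#' @export
setMethod("atomCount", "Trajectory", function(x) nrow(x@topology@atoms))

#' Atom table accessor
#'
#' @param x a Topology or Trajectory
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' Residue table of a topology
#'
#' One row per residue, in topology order.
#'
#' @param x a Topology or Trajectory
#' @return data.frame with columns \code{chain}, \code{resno}, \code{resname},
#'   \code{nAtoms}
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname residues
#' @export
setMethod("residues", "Topology", function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, sep = ":")
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx],
             resname = a$resname[idx],
             nAtoms = as.integer(table(factor(key, levels = key[idx]))),
             stringsAsFactors = FALSE)
})

#' @rdname residues
#' @export
setMethod("residues", "Trajectory", function(x) residues(x@topology))

setMethod("show", "Topology", function(object) {
  r <- residues(object)
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              nrow(object@atoms), nrow(r), length(unique(r$chain))))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s': %d frames over ", object@replicateId,
              nFrames(object)))
  show(object@topology)
})

#' Frame count of a trajectory
#' @param x a Trajectory
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Coordinates accessor
#'
#' @param x a Trajectory
#' @param frame frame index; \code{NULL} returns the full array
#' @return an \code{nAtoms x 3} matrix, or the \code{nAtoms x 3 x nFrames}
#'   array when \code{frame} is \code{NULL}
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  x@coords[, , frame, drop = (length(frame) == 1L)]
})

# Row indices of a residue's atoms; errors if the residue is absent.
residueAtomIndices <- function(topology, chain, resno) {
  a <- topology@atoms
  idx <- which(a$chain == chain & a$resno == resno)
  if (!length(idx)) {
    stop(sprintf("residue %s:%s not found in topology", chain, resno))
  }
  idx
}

#' Heavy atoms of a residue
#'
#' Hydrogens (H/D) are always removed; backbone atoms are removed as well when
#' \code{excludeBackbone} is TRUE. May return an empty selection (glycine with
#' backbone excluded); contact scores over an empty selection are zero.
#'
#' @param topology a \linkS4class{Topology}
#' @param chain,resno residue identity (chain id, author residue number)
#' @param excludeBackbone drop backbone atoms too
#' @return integer vector of atom row indices into \code{atoms(topology)}
#' @export
heavyAtoms <- function(topology, chain, resno, excludeBackbone = FALSE) {
  idx <- residueAtomIndices(topology, chain, resno)
  a <- topology@atoms[idx, ]
  keep <- !a$isHydrogen
  if (excludeBackbone) keep <- keep & !a$isBackbone
  idx[keep]
}

# Element inference for PDB records lacking the element column.
# Strips digits and primes from the atom name, then matches a two-letter
# element if the name starts with one, else takes the first letter.
.TWO_LETTER_ELEMENTS <- c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "SE",
                          "CA", "CU", "NI", "CO")

inferElement <- function(name, resname = "") {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  if (!nzchar(nm)) return("X")
  two <- substr(nm, 1, 2)
  # CA/NA in protein residues are carbon/nitrogen atom names, not metals;
  # only treat them as elements for single-atom ion residues of the same name
  if (two %in% .TWO_LETTER_ELEMENTS && nchar(nm) == 2L) {
    if (!(two %in% c("CA", "NA")) || toupper(resname) %in% c("CA", "NA")) {
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    }
  }
  substr(nm, 1, 1)
}
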