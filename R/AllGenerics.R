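#' Number of frames in an ensemble
#' @param x a \linkS4class{StructureEnsemble}
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues
#' @param x a snapshot or ensemble
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom table accessor
#' @param x a snapshot or ensemble
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinate accessor
#' @param x a snapshot or ensemble
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Extract one frame of an ensemble as a snapshot
#' @param x a \linkS4class{StructureEnsemble}
#' @param i frame index
#' @export
setGeneric("getSnapshot", function(x, i) standardGeneric("getSnapshot"))

#' Residue table: one row per residue in order of appearance
#'
#' Returns a data.frame with columns \code{gindex} (0-based global residue
#' index), \code{chain}, \code{resid} (0-based within-chain index) and
#' \code{resname}.
#' @param x a snapshot or ensemble
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname nFrames
setMethod("nFrames", "StructureEnsemble", function(x) dim(x@coords)[3])

#' @rdname atoms
setMethod("atoms", "StructureSnapshot", function(x) x@atoms)
#' @rdname atoms
setMethod("atoms", "StructureEnsemble", function(x) x@atoms)

#' @rdname coords
setMethod("coords", "StructureSnapshot", function(x) x@coords)
#' @rdname coords
setMethod("coords", "StructureEnsemble", function(x) x@coords)

.residueTable <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "|")
  first <- !duplicated(key)
  data.frame(gindex = seq_len(sum(first)) - 1L,
             chain = atoms$chain[first],
             resid = atoms$resid[first],
             resname = atoms$resname[first],
             stringsAsFactors = FALSE)
}

## global residue index (0-based) per atom
.atomGindex <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "|")
  match(key, unique(key)) - 1L
}

#' @rdname residueTable
setMethod("residueTable", "StructureSnapshot", function(x) .residueTable(x@atoms))
#' @rdname residueTable
setMethod("residueTable", "StructureEnsemble", function(x) .residueTable(x@atoms))

#' @rdname nResidues
setMethod("nResidues", "StructureSnapshot",
          function(x) nrow(.residueTable(x@atoms)))
#' @rdname nResidues
setMethod("nResidues", "StructureEnsemble",
          function(x) nrow(.residueTable(x@atoms)))

#' @rdname getSnapshot
setMethod("getSnapshot", "StructureEnsemble", function(x, i) {
  stopifnot(i >= 1L, i <= nFrames(x))
  new("StructureSnapshot", atoms = x@atoms,
      coords = x@coords[, , i, drop = TRUE])
})

#' Construct label accessor
#' @param x a \linkS4class{StructureEnsemble}
#' @export
constructLabel <- function(x) x@construct

#' Region accessor for a DomainAnnotation
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param name region name, e.g. "S6"
#' @return integer vector of within-chain residue indices
#' @export
region <- function(annotation, name) {
  r <- annotation@regions[[name]]
  if (is.null(r)) stop("region '", name, "' not present in annotation")
  r
}

#' Preceding subunit in the declared counter-clockwise chain cycle
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param chain chain id
#' @export
precedingChain <- function(annotation, chain) {
  cyc <- annotation@chainOrder
  k <- match(chain, cyc)
  if (is.na(k)) stop("chain '", chain, "' not in chainOrder")
  cyc[if (k == 1L) length(cyc) else k - 1L]
}
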