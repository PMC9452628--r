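## Domain annotation: named residue ranges (VSD, S4, PD, S6, CL, CNBD, HCND,
## selectivity filter, upper pore, gate, insertion site) plus the explicit
## subunit cycle. All indices are internal 0-based within-chain positions;
## numberingOffset maps them onto the author numbering of the structure.

#' Construct a DomainAnnotation
#'
#' @param regions named list of integer vectors (within-chain residue indices).
#' @param gateResidues integer vector of gate residues (subset of S6).
#' @param insertionSite integer(2): the residue pair flanking the insertion.
#' @param chainOrder character vector: subunit cycle, counter-clockwise as
#'   viewed from the extracellular side.
#' @param numberingOffset integer: internal index + offset = author numbering.
#' @return a \linkS4class{DomainAnnotation}
#' @export
domainAnnotation <- function(regions = list(), gateResidues = integer(0),
                             insertionSite = integer(0),
                             chainOrder = character(0),
                             numberingOffset = 0L) {
  regions <- lapply(regions, function(r) as.integer(sort(unique(r))))
  new("DomainAnnotation", regions = regions,
      gateResidues = as.integer(gateResidues),
      insertionSite = as.integer(insertionSite),
      chainOrder = as.character(chainOrder),
      numberingOffset = as.integer(numberingOffset))
}

.rangeToVector <- function(x, name) {
  if (is.list(x) && !is.null(x$from)) return(seq.int(x$from, x$to))
  if (is.list(x)) return(unlist(lapply(x, .rangeToVector, name = name)))
  if (is.numeric(x)) return(as.integer(x))
  stop("cannot interpret residue range for region '", name, "'")
}

#' Read a DomainAnnotation from a YAML config file
#'
#' Expected keys: \code{regions} (name -> \code{\{from, to\}} range, list of
#' ranges, or explicit index vector), and optionally \code{gate_residues},
#' \code{insertion_site}, \code{chain_order}, \code{numbering_offset}.
#'
#' @param path path to a YAML file.
#' @return a \linkS4class{DomainAnnotation}
#' @export
readDomainAnnotation <- function(path) {
  cfg <- yaml::read_yaml(path)
  regions <- list()
  for (nm in names(cfg$regions))
    regions[[nm]] <- .rangeToVector(cfg$regions[[nm]], nm)
  domainAnnotation(regions = regions,
                   gateResidues = as.integer(cfg$gate_residues %||% integer(0)),
                   insertionSite = as.integer(cfg$insertion_site %||% integer(0)),
                   chainOrder = as.character(cfg$chain_order %||% character(0)),
                   numberingOffset = as.integer(cfg$numbering_offset %||% 0L))
}

#' Map internal residue indices to author numbering
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param resid internal within-chain residue indices
#' @export
authorNumbering <- function(annotation, resid) {
  as.integer(resid) + annotation@numberingOffset
}

`%||%` <- function(a, b) if (is.null(a)) b else a
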