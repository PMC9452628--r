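## Assembly of the body-bar constraint network for one snapshot at one
## hydrogen-bond energy cutoff. Bodies are atoms; bar multiplicities follow
## the body-bar convention of the FIRST/CNA lineage: locked covalent bonds 6,
## rotatable covalent bonds 5, retained hydrogen bonds 5 (attached between
## donor and acceptor heavy atoms), hydrophobic tethers 2.

#' Build a constraint network
#'
#' Only hydrogen bonds with \code{energy <= eCut} are retained, so lowering
#' \code{eCut} along a dilution trajectory removes constraints monotonically.
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param bonds hydrogen-bond table from \code{\link{detectHydrogenBonds}}.
#' @param tethers tether table from \code{\link{detectHydrophobicTethers}}.
#' @param eCut hydrogen-bond energy cutoff, kcal/mol (must be <= 0).
#' @param covalent optional precomputed \code{covalentBonds(snapshot)} table.
#' @return a \linkS4class{ConstraintNetwork}.
#' @export
buildNetwork <- function(snapshot, bonds = detectHydrogenBonds(snapshot),
                         tethers = detectHydrophobicTethers(snapshot),
                         eCut = 0, covalent = covalentBonds(snapshot)) {
  if (eCut > 0) stop("eCut must be <= 0 kcal/mol")
  nc <- nrow(covalent)
  cov <- data.frame(
    a = covalent$a, b = covalent$b,
    mult = ifelse(covalent$locked, 6L, 5L),
    kind = ifelse(covalent$locked, "covalent-locked", "covalent-rotatable"),
    energy = rep(NA_real_, nc), stringsAsFactors = FALSE)
  keep <- which(bonds$energy <= eCut)
  hb <- data.frame(
    a = pmin(bonds$donor[keep], bonds$acceptor[keep]),
    b = pmax(bonds$donor[keep], bonds$acceptor[keep]),
    mult = rep(5L, length(keep)), kind = rep("hbond", length(keep)),
    energy = bonds$energy[keep], stringsAsFactors = FALSE)
  nt <- nrow(tethers)
  ht <- data.frame(
    a = tethers$a, b = tethers$b, mult = rep(2L, nt),
    kind = rep("hydrophobic", nt), energy = rep(NA_real_, nt),
    stringsAsFactors = FALSE)
  bars <- rbind(cov, hb, ht)
  rownames(bars) <- NULL
  new("ConstraintNetwork", nBodies = nrow(snapshot@atoms), bars = bars,
      eCut = eCut)
}

#' Export a constraint network as a delimited edge list
#' @param network a \linkS4class{ConstraintNetwork}
#' @param path output path (TSV with header)
#' @export
writeNetwork <- function(network, path) {
  write.table(network@bars, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Import a constraint network from a delimited edge list
#' @param path TSV written by \code{\link{writeNetwork}}
#' @param nBodies number of bodies; defaults to the largest endpoint index
#' @export
readNetwork <- function(path, nBodies = NULL) {
  bars <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  bars$mult <- as.integer(bars$mult)
  if (is.null(nBodies)) nBodies <- max(bars$a, bars$b)
  new("ConstraintNetwork", nBodies = as.integer(nBodies), bars = bars,
      eCut = if (any(bars$kind == "hbond"))
        max(bars$energy[bars$kind == "hbond"]) else NA_real_)
}
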