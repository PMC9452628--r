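## Rigid-cluster decomposition and hydrogen-bond dilution.

#' Default energy-cutoff grid for constraint dilution
#'
#' -0.1 to -6.0 kcal/mol in 0.1 steps (strictly decreasing), the customary
#' dilution range for protein constraint networks.
#' @export
defaultEcutGrid <- function() -seq(0.1, 6.0, by = 0.1)

#' Rigid-cluster decomposition of a constraint network
#'
#' Runs the (6,6) body-bar pebble game: every body carries 6 pebbles, a bar of
#' multiplicity m is inserted as m copies, each accepted if 7 pebbles can be
#' gathered on its endpoints. Rigid clusters are the maximal body sets with no
#' remaining relative motion; floppy modes count the internal degrees of
#' freedom, with 6 trivial DOF subtracted once per connected component.
#'
#' @param network a \linkS4class{ConstraintNetwork}.
#' @return a \linkS4class{RigidClusterDecomposition}.
#' @export
pebbleGame <- function(network) {
  bars <- network@bars
  if (nrow(bars) && !all(bars$mult %in% c(2L, 5L, 6L)))
    stop("bar multiplicities must be in {2, 5, 6}")
  res <- .pebbleGameCpp(network@nBodies, as.integer(bars$a),
                        as.integer(bars$b), as.integer(bars$mult))
  new("RigidClusterDecomposition",
      eCut = network@eCut,
      clusterOf = as.integer(res$clusterOf),
      nClusters = as.integer(res$nClusters),
      floppyModes = as.integer(res$floppyModes))
}

#' Constraint dilution: decompositions along an energy-cutoff grid
#'
#' Generates the trajectory of network states obtained by successively removing
#' hydrogen-bond constraints in the order of increasing strength: at each grid
#' value only bonds with \code{energy <= eCut} are retained, and the network is
#' decomposed into rigid clusters.
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param eCutGrid strictly decreasing vector of cutoffs, all <= 0, kcal/mol.
#' @param bonds,tethers,covalent optional precomputed constraint tables.
#' @return list of \linkS4class{RigidClusterDecomposition}, one per grid value.
#' @export
dilute <- function(snapshot, eCutGrid = defaultEcutGrid(),
                   bonds = detectHydrogenBonds(snapshot,
                                               covalent = covalent),
                   tethers = detectHydrophobicTethers(snapshot,
                                                      covalent = covalent),
                   covalent = covalentBonds(snapshot)) {
  if (!length(eCutGrid)) stop("eCutGrid must be non-empty")
  if (any(eCutGrid > 0)) stop("eCutGrid values must be <= 0")
  if (length(eCutGrid) > 1L && any(diff(eCutGrid) >= 0))
    stop("eCutGrid must be strictly decreasing")
  lapply(eCutGrid, function(ec)
    pebbleGame(buildNetwork(snapshot, bonds = bonds, tethers = tethers,
                            eCut = ec, covalent = covalent)))
}
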