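## Neighbor stability maps rc_ij and the chemical potential energies
## E_CNA / E_i,CNA / Delta E_i,CNA derived from a dilution trajectory.
##
## rc_ij = min{ E_cut | some rigid cluster contains residues i and j }, taken
## over the dilution grid, restricted to short-range contacts (>= 1 heavy-atom
## pair of the residue pair within 4.5 A, boundary inclusive). A residue
## belongs to a cluster when at least one of its heavy atoms does. Pairs that
## are never co-rigid carry the sentinel value one grid step above the grid
## maximum, so they contribute the weakest possible stability instead of
## being dropped from the sums.

## in-contact residue pairs (0-based global indices, i < j)
.contactPairs <- function(snapshot, cutoff = 4.5) {
  at <- snapshot@atoms
  xyz <- snapshot@coords
  gidx <- .atomGindex(at)
  hv <- which(at$heavy)
  p <- xyz[hv, , drop = FALSE]
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * p %*% t(p)
  hit <- which(upper.tri(d2) & d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  gi <- gidx[hv[hit[, 1]]]; gj <- gidx[hv[hit[, 2]]]
  keep <- gi != gj
  pr <- unique(data.frame(i = pmin(gi, gj)[keep], j = pmax(gi, gj)[keep]))
  pr[order(pr$i, pr$j), , drop = FALSE]
}

#' Neighbor stability map from a dilution trajectory
#'
#' @param dilution list of \linkS4class{RigidClusterDecomposition} as returned
#'   by \code{\link{dilute}} on the same snapshot (strictly decreasing E_cut).
#' @param snapshot the \linkS4class{StructureSnapshot} the dilution was
#'   computed on.
#' @param contactCutoff heavy-atom contact distance, Angstrom (inclusive).
#' @return a \linkS4class{StabilityMap}.
#' @export
stabilityMap <- function(dilution, snapshot, contactCutoff = 4.5) {
  grid <- vapply(dilution, function(d) d@eCut, numeric(1))
  step <- if (length(grid) > 1L) abs(grid[1] - grid[2]) else 0.1
  sentinel <- max(grid) + step
  pairs <- .contactPairs(snapshot, contactCutoff)
  at <- snapshot@atoms
  gidx <- .atomGindex(at)
  nres <- nrow(.residueTable(at))
  heavyByRes <- split(which(at$heavy), gidx[at$heavy])

  rc <- rep(sentinel, nrow(pairs))
  if (nrow(pairs)) {
    ## partitions only refine as E_cut decreases, so scan from the top of the
    ## grid and push rc down while the pair stays co-rigid
    alive <- rep(TRUE, nrow(pairs))
    for (k in seq_along(dilution)) {
      cl <- dilution[[k]]@clusterOf
      ## cluster-id sets per residue at this cutoff
      resClusters <- lapply(heavyByRes, function(ix) unique(cl[ix]))
      for (p in which(alive)) {
        ci <- resClusters[[as.character(pairs$i[p])]]
        cj <- resClusters[[as.character(pairs$j[p])]]
        if (length(intersect(ci, cj))) rc[p] <- grid[k]
        else alive[p] <- FALSE
      }
      if (!any(alive)) break
    }
  }
  new("StabilityMap",
      pairs = data.frame(i = pairs$i, j = pairs$j, rc = rc),
      nResidues = as.integer(nres), sentinel = sentinel, averaged = FALSE)
}

#' Average stability maps over the snapshots of an ensemble
#'
#' rc_ij is averaged over all snapshots; in snapshots where a pair is not in
#' contact it contributes the sentinel (no stable neighbour contact), so that
#' losing a contact in part of the ensemble reads as reduced stability rather
#' than dropping out of the average. Pairs never in contact in any snapshot
#' are absent from the result.
#'
#' @param maps list of per-snapshot \linkS4class{StabilityMap}s.
#' @return an ensemble-averaged \linkS4class{StabilityMap}.
#' @export
averageStabilityMaps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  nmap <- length(maps)
  sentinel <- maps[[1]]@sentinel
  allPairs <- do.call(rbind, lapply(maps, function(m) m@pairs))
  agg <- aggregate(rc ~ i + j, data = allPairs,
                   FUN = function(v) (sum(v) + (nmap - length(v)) * sentinel) / nmap)
  agg <- agg[order(agg$i, agg$j), ]
  rownames(agg) <- NULL
  new("StabilityMap", pairs = agg, nResidues = maps[[1]]@nResidues,
      sentinel = sentinel, averaged = TRUE)
}

#' Per-residue chemical potential energies from a stability map
#'
#' E_i = 1/2 sum_{j != i} rc_ij over in-contact neighbours, and
#' E_total = sum_{i < j} rc_ij; the pair-halving identity
#' sum_i E_i = E_total holds by construction.
#'
#' @param map a \linkS4class{StabilityMap}.
#' @return a \linkS4class{StabilityProfile}.
#' @export
stabilityProfile <- function(map) {
  n <- map@nResidues
  Ei <- numeric(n)
  p <- map@pairs
  if (nrow(p)) {
    for (k in seq_len(nrow(p))) {
      Ei[p$i[k] + 1L] <- Ei[p$i[k] + 1L] + p$rc[k] / 2
      Ei[p$j[k] + 1L] <- Ei[p$j[k] + 1L] + p$rc[k] / 2
    }
  }
  names(Ei) <- as.character(seq_len(n) - 1L)
  new("StabilityProfile", Ei = Ei, Etotal = sum(p$rc))
}

#' Ensemble stability profile for one ensemble
#'
#' Convenience chain: per-snapshot dilution -> stability map -> ensemble
#' average -> profile. \code{aggregation = "rc"} averages rc_ij over snapshots
#' before applying the per-residue sum (default); \code{"profile"} computes
#' per-snapshot profiles and averages the energies.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param eCutGrid dilution grid, see \code{\link{dilute}}.
#' @param contactCutoff heavy-atom contact distance, Angstrom.
#' @param aggregation "rc" or "profile".
#' @param frames optional subset of frame indices.
#' @return a \linkS4class{StabilityProfile}.
#' @export
ensembleStabilityProfile <- function(ensemble, eCutGrid = defaultEcutGrid(),
                                     contactCutoff = 4.5,
                                     aggregation = c("rc", "profile"),
                                     frames = seq_len(nFrames(ensemble))) {
  aggregation <- match.arg(aggregation)
  covalent <- covalentBonds(getSnapshot(ensemble, frames[1]))
  maps <- lapply(frames, function(m) {
    snap <- getSnapshot(ensemble, m)
    dil <- dilute(snap, eCutGrid, covalent = covalent)
    stabilityMap(dil, snap, contactCutoff)
  })
  if (aggregation == "rc") {
    stabilityProfile(averageStabilityMaps(maps))
  } else {
    profs <- lapply(maps, stabilityProfile)
    Ei <- rowMeans(vapply(profs, function(p) p@Ei,
                          numeric(length(profs[[1]]@Ei))))
    new("StabilityProfile", Ei = Ei, Etotal = sum(Ei))
  }
}

#' Reference-minus-construct stability differences with per-residue tests
#'
#' dE_i = mean_ref(E_i) - mean_construct(E_i), with a two-sided Welch unpaired
#' t-test per residue across the replicate profiles (subunits x runs).
#' Residues with p >= alpha are zeroed in the reported map; raw differences
#' are retained. Negative reported values mean the construct is destabilised.
#'
#' @param reference,construct lists of replicate E_i vectors (equal residue
#'   mapping; one numeric vector per subunit x run replicate).
#' @param alpha significance level.
#' @return a \linkS4class{DeltaStability}.
#' @export
deltaStability <- function(reference, construct, alpha = 0.05) {
  if (length(reference) < 2L || length(construct) < 2L)
    stop("need >= 2 replicates per group")
  refM <- do.call(cbind, reference)
  conM <- do.call(cbind, construct)
  if (nrow(refM) != nrow(conM))
    stop("reference and construct must share the residue mapping")
  nres <- nrow(refM)
  dE <- unname(rowMeans(refM) - rowMeans(conM))
  p <- vapply(seq_len(nres), function(i)
    unpairedT(refM[i, ], conM[i, ])["p"], numeric(1))
  sig <- !is.na(p) & p < alpha
  rep_ <- ifelse(sig, dE, 0)
  new("DeltaStability", residue = seq_len(nres) - 1L, dE = dE,
      dEReported = rep_, p = as.numeric(p), significant = sig, alpha = alpha)
}

#' Region average of a stability difference map
#'
#' Mean (and SD) of the reported dE_i over a residue region.
#'
#' @param delta a \linkS4class{DeltaStability}.
#' @param region integer vector of residue indices (same indexing as
#'   \code{delta@residue}).
#' @param reported use the significance-zeroed map (default) or raw dE.
#' @return named numeric: mean, sd, n.
#' @export
regionAverage <- function(delta, region, reported = TRUE) {
  if (!length(region)) stop("region must be non-empty")
  sel <- match(region, delta@residue)
  if (anyNA(sel)) stop("region contains residues outside the map")
  v <- if (reported) delta@dEReported[sel] else delta@dE[sel]
  c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0, n = length(v))
}

#' Write per-residue stability differences into the B-factor column of a PDB
#'
#' Visualisation helper: every atom of residue i gets dE_i as its B-factor.
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param values numeric vector over global residues (0-based order).
#' @param path output PDB path.
#' @export
writeBfactorPDB <- function(snapshot, values, path) {
  at <- snapshot@atoms
  gidx <- .atomGindex(at)
  xyz <- snapshot@coords
  lines <- vapply(seq_len(nrow(at)), function(i) {
    nm <- if (nchar(at$name[i]) >= 4L) substr(at$name[i], 1, 4) else
      sprintf(" %-3s", at$name[i])
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f          %2s",
            at$serial[i] %% 100000L, nm, at$resname[i], at$chain[i],
            at$resno[i] %% 10000L, xyz[i, 1], xyz[i, 2], xyz[i, 3],
            values[gidx[i] + 1L], at$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
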