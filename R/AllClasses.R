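#' @import methods
#' @importFrom stats sd coef predict t.test rnorm runif quantile approx
#'   residuals aggregate
#' @importFrom utils head tail read.table write.table
#' @useDynLib cnaflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Atom table column contract used throughout the package. Atoms live in a
## data.frame rather than one S4 object per atom: ensembles carry thousands of
## atoms and all algorithms are vectorised over this table.
.ATOM_COLS <- c("serial", "name", "element", "resid", "resname",
                "chain", "heavy")

#' StructureSnapshot: one conformation of a molecule
#'
#' A single structure snapshot: an atom table (identity, topology bookkeeping)
#' plus an \code{n x 3} coordinate matrix in Angstrom. \code{resid} is the
#' internal 0-based sequential residue index within each chain; the original
#' author/file numbering is kept in \code{resno} inside the atom table and a
#' \code{numberingOffset} in \linkS4class{DomainAnnotation} maps between the
#' two.
#'
#' @slot atoms data.frame with columns serial, name, element, resid, resname,
#'   chain, heavy (and resno: the residue number as read from file).
#' @slot coords numeric matrix, n_atoms x 3, Angstrom.
#' @slot frameTime numeric(0 or 1), snapshot time in ns (optional).
#' @export
setClass("StructureSnapshot",
  representation(atoms = "data.frame", coords = "matrix",
                 frameTime = "numeric"),
  prototype(frameTime = numeric(0)))

setValidity("StructureSnapshot", function(object) {
  a <- object@atoms
  if (nrow(a) < 1L) return("snapshot must contain at least one atom")
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atom table must have columns:",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(object@coords) != nrow(a) || ncol(object@coords) != 3L)
    return("coords must be an n_atoms x 3 matrix")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (any(!nzchar(a$element))) return("element symbols must be non-empty")
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  ## residue index non-decreasing within each chain
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    if (is.unsorted(r)) return(sprintf("resid not non-decreasing in chain %s", ch))
  }
  TRUE
})

#' StructureEnsemble: a fixed-topology set of snapshots
#'
#' All frames share one atom table; coordinates are an n_atoms x 3 x n_frames
#' array. Metadata records the construct label (e.g. "0G", "4G", "synthetic")
#' and a run identifier.
#'
#' @slot atoms shared atom table (see \linkS4class{StructureSnapshot}).
#' @slot coords numeric array n_atoms x 3 x n_frames, Angstrom.
#' @slot construct character(1) construct label.
#' @slot runId character(1) run identifier.
#' @export
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array",
                 construct = "character", runId = "character"),
  prototype(construct = "synthetic", runId = "run1"))

setValidity("StructureEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@atoms))
    return("coords first dimension must match atom count")
  if (d[3] < 1L) return("ensemble needs at least one frame")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' DomainAnnotation: named residue ranges and subunit topology
#'
#' Residue ranges use the internal 0-based within-chain index and apply to every
#' chain of a homomultimer. \code{chainOrder} lists chain IDs in the
#' counter-clockwise order viewed from the extracellular side, so "preceding
#' subunit" lookups are explicit declarations, never geometric inference.
#'
#' @slot regions named list; each element an integer vector of residue indices.
#' @slot gateResidues integer vector, subset of the S6 region.
#' @slot insertionSite integer(2), the residue pair flanking the insertion.
#' @slot chainOrder character vector, subunit cycle.
#' @slot numberingOffset integer(1), internal index + offset = author numbering.
#' @export
setClass("DomainAnnotation",
  representation(regions = "list", gateResidues = "integer",
                 insertionSite = "integer", chainOrder = "character",
                 numberingOffset = "integer"),
  prototype(regions = list(), gateResidues = integer(0),
            insertionSite = integer(0), chainOrder = character(0),
            numberingOffset = 0L))

setValidity("DomainAnnotation", function(object) {
  if (length(object@gateResidues) &&
      !is.null(object@regions$S6) &&
      !all(object@gateResidues %in% object@regions$S6))
    return("gateResidues must lie inside the S6 region")
  TRUE
})

#' ConstraintNetwork: bodies and bars for one snapshot at one cutoff
#'
#' Bodies are atoms (indexed 1..nBodies into the originating snapshot's atom
#' table); bars carry a multiplicity in {2, 5, 6} following the body-bar
#' convention: locked covalent bonds 6, rotatable covalent bonds and hydrogen
#' bonds 5, hydrophobic tethers 2.
#'
#' @slot nBodies integer(1).
#' @slot bars data.frame with columns a, b (1-based atom indices, a < b),
#'   mult (2, 5 or 6), kind ("covalent-locked", "covalent-rotatable",
#'   "hbond", "hydrophobic"), energy (kcal/mol, NA unless kind == "hbond").
#' @slot eCut numeric(1), the hydrogen-bond energy cutoff used, kcal/mol.
#' @export
setClass("ConstraintNetwork",
  representation(nBodies = "integer", bars = "data.frame", eCut = "numeric"))

setValidity("ConstraintNetwork", function(object) {
  b <- object@bars
  if (nrow(b)) {
    if (!all(b$mult %in% c(2L, 5L, 6L)))
      return("bar multiplicities must be in {2, 5, 6}")
    if (any(b$a < 1L | b$b < 1L | b$a > object@nBodies | b$b > object@nBodies))
      return("bar endpoints must be bodies")
    if (any(b$kind == "hbond" & !is.finite(b$energy)))
      return("hbond bars must carry a finite energy")
  }
  TRUE
})

#' RigidClusterDecomposition: pebble-game output for one network
#'
#' @slot eCut numeric(1), kcal/mol (NA when the network was built directly).
#' @slot clusterOf integer vector, cluster id per body; ids are contiguous
#'   1..nClusters and canonicalised by lowest member index.
#' @slot nClusters integer(1).
#' @slot floppyModes integer(1), internal degrees of freedom (6 trivial DOF
#'   subtracted once per connected component of the bar graph).
#' @export
setClass("RigidClusterDecomposition",
  representation(eCut = "numeric", clusterOf = "integer",
                 nClusters = "integer", floppyModes = "integer"))

setValidity("RigidClusterDecomposition", function(object) {
  if (object@floppyModes < 0L) return("floppyModes must be >= 0")
  if (length(object@clusterOf) &&
      !identical(sort(unique(object@clusterOf)), seq_len(object@nClusters)))
    return("cluster ids must be contiguous 1..nClusters")
  TRUE
})

#' StabilityMap: residue-pair rigid-contact energies rc_ij
#'
#' Sparse symmetric storage: one row per unordered in-contact residue pair
#' (heavy-atom pair within the contact cutoff). \code{rc} is the lowest (most
#' negative) energy cutoff at which the pair still shares a rigid cluster;
#' pairs never co-rigid carry the sentinel (one grid step above the grid
#' maximum) so Eq.-style sums stay well defined.
#'
#' @slot pairs data.frame with columns i, j (0-based global residue indices,
#'   i < j) and rc (kcal/mol).
#' @slot nResidues integer(1).
#' @slot sentinel numeric(1), kcal/mol.
#' @slot averaged logical(1), TRUE for ensemble-averaged maps.
#' @export
setClass("StabilityMap",
  representation(pairs = "data.frame", nResidues = "integer",
                 sentinel = "numeric", averaged = "logical"),
  prototype(averaged = FALSE))

setValidity("StabilityMap", function(object) {
  p <- object@pairs
  if (nrow(p) && any(p$i >= p$j)) return("pairs must satisfy i < j")
  if (nrow(p) && any(p$rc > object@sentinel + 1e-12))
    return("rc values cannot exceed the sentinel")
  TRUE
})

#' StabilityProfile: per-residue chemical potential energies
#'
#' E_i = 1/2 sum_{j != i} rc_ij over in-contact neighbours; E_total =
#' sum_{i<j} rc_ij, so sum_i E_i == E_total by construction.
#'
#' @slot Ei numeric vector over residues (kcal/mol), names = residue index.
#' @slot Etotal numeric(1), kcal/mol.
#' @export
setClass("StabilityProfile",
  representation(Ei = "numeric", Etotal = "numeric"))

#' DeltaStability: reference-minus-construct stability differences
#'
#' dE_i = mean_ref(E_i) - mean_construct(E_i); negative values mean the
#' construct is destabilised at residue i. Residues whose Welch test does not
#' reach significance are zeroed in \code{dEReported} while raw differences
#' remain in \code{dE}.
#'
#' @slot residue integer vector (within-chain residue index).
#' @slot dE numeric vector, raw differences, kcal/mol.
#' @slot dEReported numeric vector, non-significant entries set to 0.
#' @slot p numeric vector of per-residue p-values.
#' @slot significant logical vector, p < alpha.
#' @slot alpha numeric(1).
#' @export
setClass("DeltaStability",
  representation(residue = "integer", dE = "numeric", dEReported = "numeric",
                 p = "numeric", significant = "logical", alpha = "numeric"))

setValidity("DeltaStability", function(object) {
  ok <- object@significant == (object@p < object@alpha)
  ok[is.na(object@p)] <- !object@significant[is.na(object@p)]
  if (!all(ok)) return("significant must equal p < alpha")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "StructureSnapshot", function(object) {
  a <- object@atoms
  cat(sprintf("StructureSnapshot: %d atoms, %d residues, %d chain(s)\n",
              nrow(a), nResidues(object), length(unique(a$chain))))
})

setMethod("show", "StructureEnsemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("StructureEnsemble '%s' (%s): %d frames x %d atoms\n",
              object@construct, object@runId, d[3], d[1]))
})

setMethod("show", "ConstraintNetwork", function(object) {
  tab <- table(object@bars$kind)
  cat(sprintf("ConstraintNetwork: %d bodies, %d bars (E_cut = %s)\n",
              object@nBodies, nrow(object@bars),
              ifelse(is.na(object@eCut), "none", format(object@eCut))))
  if (length(tab)) print(tab)
})

setMethod("show", "RigidClusterDecomposition", function(object) {
  cat(sprintf("RigidClusterDecomposition: %d clusters, %d floppy modes%s\n",
              object@nClusters, object@floppyModes,
              ifelse(is.na(object@eCut), "",
                     sprintf(" (E_cut = %g kcal/mol)", object@eCut))))
})

setMethod("show", "StabilityMap", function(object) {
  cat(sprintf("StabilityMap: %d residues, %d in-contact pairs (%s)\n",
              object@nResidues, nrow(object@pairs),
              ifelse(object@averaged, "ensemble-averaged", "single snapshot")))
})

setMethod("show", "StabilityProfile", function(object) {
  cat(sprintf("StabilityProfile: %d residues, E_total = %.3f kcal/mol\n",
              length(object@Ei), object@Etotal))
})

setMethod("show", "DeltaStability", function(object) {
  cat(sprintf("DeltaStability: %d residues, %d significant at alpha = %g\n",
              length(object@dE), sum(object@significant), object@alpha))
})

setMethod("show", "DomainAnnotation", function(object) {
  cat(sprintf("DomainAnnotation: %d regions [%s]; chain cycle: %s\n",
              length(object@regions),
              paste(names(object@regions), collapse = ", "),
              paste(object@chainOrder, collapse = " -> ")))
})
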