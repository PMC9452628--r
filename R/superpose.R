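## Rigid-body superposition of ensemble frames onto a reference. The
## least-squares rotation/translation itself is bio3d's Kabsch-type fit
## (fit.xyz); this layer handles atom selection and the package containers.

## atom indices (1-based) for a residue selection; selection is a vector of
## within-chain residue indices applied to all chains
.selectionIndices <- function(atoms, selection,
                              what = c("backbone", "heavy", "calpha", "all")) {
  what <- match.arg(what)
  sel <- atoms$resid %in% selection
  sel <- sel & switch(what,
    backbone = atoms$name %in% c("N", "CA", "C", "O") & atoms$heavy,
    heavy = atoms$heavy,
    calpha = atoms$name == "CA",
    all = TRUE)
  which(sel)
}

#' Superpose all frames of an ensemble onto a reference
#'
#' Each frame is rigid-body transformed (least-squares rotation plus
#' translation) so that the RMSD of the selection atoms to the reference is
#' minimal; the transformation is applied to all atoms, so internal distances
#' are untouched. The default selection atoms are the backbone heavy atoms of
#' the selected residues.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param selection integer vector of within-chain residue indices (applied to
#'   all chains), e.g. the pore-domain residues.
#' @param reference a \linkS4class{StructureSnapshot} sharing the ensemble's
#'   topology; defaults to frame 1.
#' @param what which atoms of the selected residues to fit on.
#' @return the superposed \linkS4class{StructureEnsemble}.
#' @export
superpose <- function(ensemble, selection,
                      reference = getSnapshot(ensemble, 1L),
                      what = c("backbone", "heavy", "calpha", "all")) {
  what <- match.arg(what)
  if (!length(selection)) stop("selection must be non-empty")
  if (nrow(reference@atoms) != nrow(ensemble@atoms))
    stop("reference does not share the ensemble topology")
  idx <- .selectionIndices(ensemble@atoms, selection, what)
  if (length(idx) < 3L) stop("need at least 3 selection atoms")
  refsel <- reference@coords[idx, , drop = FALSE]
  ctr <- sweep(refsel, 2, colMeans(refsel))
  if (qr(ctr)$rank < 2L)
    stop("selection atoms are collinear; superposition is underdetermined")

  nfr <- nFrames(ensemble); na <- nrow(ensemble@atoms)
  mob <- matrix(NA_real_, nfr, 3L * na)
  for (m in seq_len(nfr)) mob[m, ] <- as.numeric(t(ensemble@coords[, , m]))
  fixed <- as.numeric(t(reference@coords))
  xyzind <- as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mob,
                           fixed.inds = xyzind, mobile.inds = xyzind)
  out <- ensemble@coords
  for (m in seq_len(nfr)) out[, , m] <- matrix(fitted[m, ], ncol = 3L, byrow = TRUE)
  ensemble@coords <- out
  ensemble
}

#' RMSD of a selection between a snapshot and a reference
#' @param snapshot,reference \linkS4class{StructureSnapshot}s of equal topology
#' @param selection residue selection as in \code{\link{superpose}}
#' @param what atom subset, see \code{\link{superpose}}
#' @export
selectionRMSD <- function(snapshot, reference, selection,
                          what = c("backbone", "heavy", "calpha", "all")) {
  what <- match.arg(what)
  idx <- .selectionIndices(snapshot@atoms, selection, what)
  d <- snapshot@coords[idx, , drop = FALSE] -
    reference@coords[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
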