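## Ensemble geometry observables: residue-wise RMSF after superposition,
## vertical inter-domain displacement d_z, helix kink angles, and residue-pair
## contact counts.

#' Residue-wise root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2) of each residue's representative
#' position (C-alpha by default) about its time average. The ensemble is
#' assumed superposed (see \code{\link{superpose}}); RMSF is then invariant to
#' any further global rigid motion applied uniformly to all frames.
#'
#' @param ensemble a (superposed) \linkS4class{StructureEnsemble}.
#' @param representative "calpha" (residue-wise convention) or "heavy"
#'   (average over all heavy-atom RMSFs of the residue).
#' @return data.frame with gindex, chain, resid and rmsf (Angstrom).
#' @export
rmsf <- function(ensemble, representative = c("calpha", "heavy")) {
  representative <- match.arg(representative)
  at <- ensemble@atoms
  gidx <- .atomGindex(at)
  xyz <- ensemble@coords
  atomRmsf <- function(ix) {
    ## per-atom rmsf, then average over the selected atoms of the residue
    vapply(ix, function(i) {
      m <- t(xyz[i, , ])                     # n_frames x 3
      mu <- colMeans(m)
      sqrt(mean(rowSums(sweep(m, 2, mu)^2)))
    }, numeric(1))
  }
  rt <- .residueTable(at)
  val <- vapply(seq_len(nrow(rt)), function(g) {
    ix <- which(gidx == g - 1L &
                  (if (representative == "calpha") at$name == "CA" else at$heavy))
    if (!length(ix)) return(NA_real_)
    mean(atomRmsf(ix))
  }, numeric(1))
  data.frame(gindex = rt$gindex, chain = rt$chain, resid = rt$resid,
             rmsf = val)
}

## mass table for mass-weighted centres of mass (standard atomic masses)
.MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974)

.zCOM <- function(snapshot, atomIdx) {
  m <- .MASSES[snapshot@atoms$element[atomIdx]]
  m[is.na(m)] <- 12
  sum(m * snapshot@coords[atomIdx, 3]) / sum(m)
}

#' Vertical CL displacement d_z per subunit
#'
#' For each subunit s: d_z = z_COM(four C-terminal S6 residues of s) -
#' z_COM(C-linker of the counter-clockwise preceding subunit), mass-weighted
#' over heavy atoms. The structure must be oriented with the membrane normal
#' along z.
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param annotation a \linkS4class{DomainAnnotation} providing regions
#'   \code{S6} and \code{CL} and the chain cycle.
#' @return named numeric vector, one d_z (Angstrom) per chain.
#' @export
dzDisplacement <- function(snapshot, annotation) {
  at <- snapshot@atoms
  s6 <- annotation@regions$S6
  cl <- annotation@regions$CL
  if (is.null(s6) || is.null(cl))
    stop("annotation must provide S6 and CL regions")
  s6tail <- tail(sort(s6), 4L)
  chains <- annotation@chainOrder
  if (!length(chains)) chains <- unique(at$chain)
  vapply(chains, function(ch) {
    prev <- precedingChain(annotation, ch)
    ixA <- which(at$chain == ch & at$resid %in% s6tail & at$heavy)
    ixB <- which(at$chain == prev & at$resid %in% cl & at$heavy)
    if (!length(ixA) || !length(ixB))
      stop("annotation ranges select no atoms for chain ", ch)
    .zCOM(snapshot, ixA) - .zCOM(snapshot, ixB)
  }, numeric(1))
}

## Helix axis from C-alpha positions, oriented from the first to the last
## residue (N to C). Second differences of consecutive CA positions of an
## ideal helix lie exactly in the plane perpendicular to the axis, so the
## averaged cross product of consecutive second differences recovers the axis
## without the phase/finite-length bias of a principal-component fit. Falls
## back to the principal component when the second differences degenerate
## (near-collinear CA trace).
.helixAxis <- function(xyz) {
  n <- nrow(xyz)
  nc <- xyz[n, ] - xyz[1, ]
  ## Running [1,1,1]/3 smoothing of the CA trace: a linear filter maps a helix
  ## onto a coaxial helix of much smaller radius (factor |1 + 2 cos w|/3,
  ## about 0.23 for an alpha helix) while leaving the axis untouched, so the
  ## principal component of the smoothed trace is nearly free of the
  ## phase/finite-length bias of a raw PCA fit and averages the noise down.
  smooth1 <- function(x) {
    m <- nrow(x)
    (x[1:(m - 2L), , drop = FALSE] + x[2:(m - 1L), , drop = FALSE] +
       x[3:m, , drop = FALSE]) / 3
  }
  s <- xyz
  passes <- if (n >= 8L) 2L else if (n >= 6L) 1L else 0L
  for (k in seq_len(passes)) s <- smooth1(s)
  ctr <- sweep(s, 2, colMeans(s))
  sv <- svd(ctr)
  if (sv$d[1] < 1e-8)
    stop("degenerate helix: C-alpha coordinates carry no principal axis")
  ax <- sv$v[, 1]
  if (sum(ax * nc) < 0) ax <- -ax
  ax
}

#' Kink angle between two helices
#'
#' Helix axes are estimated from the C-alpha trace of each residue range
#' (averaged cross products of consecutive second differences, which is exact
#' for ideal helices; principal-component fallback for degenerate traces),
#' oriented N to C; the kink is the angle between the two axis directions
#' (0 degrees = collinear continuation).
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param helixA,helixB residue index vectors (within-chain).
#' @param chain chain id to evaluate (default: first chain).
#' @return angle in degrees.
#' @export
kinkAngle <- function(snapshot, helixA, helixB,
                      chain = snapshot@atoms$chain[1]) {
  at <- snapshot@atoms
  getCA <- function(range) {
    ix <- which(at$chain == chain & at$resid %in% range & at$name == "CA")
    if (length(ix) < 6L)
      stop("helix range needs >= 6 C-alpha atoms in chain ", chain)
    snapshot@coords[ix, , drop = FALSE][order(at$resid[ix]), , drop = FALSE]
  }
  xa <- getCA(helixA); xb <- getCA(helixB)
  for (x in list(xa, xb))
    if (svd(sweep(x, 2, colMeans(x)))$d[1] < 1e-6)
      stop("degenerate helix: C-alpha coordinates carry no principal axis")
  axA <- .helixAxis(xa); axB <- .helixAxis(xb)
  cosang <- sum(axA * axB)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Count residue-pair contacts between two groups
#'
#' Number of residue pairs (a in A, b in B) with at least one heavy-atom pair
#' within the cutoff (inclusive).
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param groupA,groupB data.frames with columns chain, resid (or integer
#'   residue vectors applied to all chains).
#' @param cutoff Angstrom, default 4.5.
#' @return integer contact count.
#' @export
countContacts <- function(snapshot, groupA, groupB, cutoff = 4.5) {
  at <- snapshot@atoms
  select <- function(g) {
    if (is.data.frame(g)) {
      which(paste(at$chain, at$resid) %in% paste(g$chain, g$resid) & at$heavy)
    } else which(at$resid %in% g & at$heavy)
  }
  ixA <- select(groupA); ixB <- select(groupB)
  keyA <- paste(at$chain[ixA], at$resid[ixA])
  keyB <- paste(at$chain[ixB], at$resid[ixB])
  if (length(intersect(unique(keyA), unique(keyB))))
    stop("contact groups must be disjoint")
  if (!length(ixA) || !length(ixB)) return(0L)
  pa <- snapshot@coords[ixA, , drop = FALSE]
  pb <- snapshot@coords[ixB, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  hit <- d2 <= cutoff^2 + 1e-9
  if (!any(hit)) return(0L)
  pairs <- unique(data.frame(a = keyA[which(hit, arr.ind = TRUE)[, 1]],
                             b = keyB[which(hit, arr.ind = TRUE)[, 2]]))
  nrow(pairs)
}
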