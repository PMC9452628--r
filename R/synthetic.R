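## Synthetic-data generators with known ground truth. The structural
## generator builds idealised C_n-symmetric multimers of poly-alanine helices
## (full backbone, C-beta, amide hydrogens at ideal in-plane positions) whose
## inter-helix junction is a tunable flexible hinge, emulating the contrast
## between a rigid helix-helix junction and one loosened by glycine
## insertions. Trace generators forward-simulate the Boltzmann, exponential
## and Hill models with additive i.i.d. Gaussian noise. Every generator is a
## pure function of its arguments including the seed.

## ---- ideal backbone construction (natural extension reference frame) ------

.cross3 <- function(u, v)
  c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])

.unit <- function(v) v / sqrt(sum(v^2))

## place atom D given positions A, B, C, bond length r(C-D), bond angle
## B-C-D (deg) and torsion A-B-C-D (deg)
.placeAtom <- function(a, b, c_, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d_local <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c_ + cbind(bc, m, n) %*% d_local
}

## ideal-geometry poly-alanine chain from phi/psi lists; returns atom-table
## fields and coordinates. Atoms per residue: N, (H), CA, CB, C, O.
.buildChain <- function(phi, psi, omega = 180) {
  nres <- length(phi)
  stopifnot(length(psi) == nres)
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7

  pos <- list()   # per residue: N, CA, C
  ## seed the first three backbone atoms
  N1 <- c(0, 0, 0)
  CA1 <- c(bN_CA, 0, 0)
  ang <- aN_CA_C * pi / 180
  C1 <- CA1 + bCA_C * c(-cos(ang), sin(ang), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(nres - 1L) + 1L) {
    pr <- pos[[i - 1L]]
    N <- .placeAtom(pr$N, pr$CA, pr$C, bC_N, aCA_C_N, psi[i - 1L])
    CA <- .placeAtom(pr$CA, pr$C, N, bN_CA, aC_N_CA, omega)
    C <- .placeAtom(pr$C, N, CA, bCA_C, aN_CA_C, phi[i])
    pos[[i]] <- list(N = N, CA = CA, C = C)
  }

  name <- character(0); coords <- NULL; resid <- integer(0)
  for (i in seq_len(nres)) {
    p <- pos[[i]]
    ## carbonyl O: trans to the next N (torsion N-CA-C-O = psi + 180)
    O <- .placeAtom(p$N, p$CA, p$C, 1.231, 120.5, psi[i] + 180)
    ## C-beta: tetrahedral substituent on CA
    b1 <- .unit(p$N - p$CA); b2 <- .unit(p$C - p$CA)
    v <- -.unit(b1 + b2); w <- .unit(.cross3(b1, b2))
    CB <- p$CA + 1.53 * .unit(0.605 * v + 0.796 * w)
    atomsHere <- list(N = p$N)
    if (i > 1L) {
      ## amide H: in the peptide plane, trans bisector of C(i-1) and CA
      Cprev <- pos[[i - 1L]]$C
      u <- .unit(.unit(p$CA - p$N) + .unit(Cprev - p$N))
      atomsHere$H <- p$N - 1.01 * u
    }
    atomsHere <- c(atomsHere, list(CA = p$CA, CB = CB, C = p$C, O = O))
    for (nm in names(atomsHere)) {
      name <- c(name, nm)
      coords <- rbind(coords, as.numeric(atomsHere[[nm]]))
      resid <- c(resid, i - 1L)
    }
  }
  list(name = name, coords = coords, resid = resid)
}

## rotation matrix about unit axis by angle (deg)
.rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## align a coordinate block so its CA principal axis points along +z
.alignToZ <- function(coords, caIdx) {
  ca <- coords[caIdx, , drop = FALSE]
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  ## rotation taking ax -> z
  z <- c(0, 0, 1)
  v <- .cross3(ax, z); s <- sqrt(sum(v^2)); cth <- sum(ax * z)
  R <- if (s < 1e-12) diag(3) * sign(cth) else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * (1 - cth) / s^2
  }
  sweep(coords, 2, ctr) %*% t(R)
}

#' Generate a hinged C_n-symmetric multimer ensemble with known ground truth
#'
#' Builds one idealised poly-alanine chain of two consecutive alpha-helices
#' (the pre-hinge helix stands in for S6, the post-hinge helix for the
#' C-linker A'-helix), replicates it with C_n symmetry about the z axis, and
#' samples frames in which the junction is a flexible hinge: the backbone
#' torsions of the two residues at the junction are perturbed per frame by
#' wrapped-normal angles with SD \code{hingeFlexibility}, which both bends
#' the post-hinge helix (bend amplitude grows with the SD) and frays the
#' hydrogen bonds spanning the junction, as a floppy linker does. The
#' post-hinge segment is additionally shifted along z by
#' \code{plantedDzShift}, and optionally jittered with Gaussian coordinate
#' noise. With \code{hingeFlexibility = 0}, \code{plantedDzShift = 0} and
#' \code{noise = 0} all frames are identical.
#'
#' @param nChains number of subunits (default 4).
#' @param helixLengths integer(2): residues in the pre- and post-hinge helix.
#' @param hingeFlexibility angular SD of the hinge bend, degrees.
#' @param plantedDzShift downward z-shift of the post-hinge segment, Angstrom.
#' @param nFrames number of frames.
#' @param noise per-coordinate Gaussian jitter SD, Angstrom.
#' @param radius placement radius of the chains from the symmetry axis, A.
#' @param seed RNG seed (recorded in the ground-truth record).
#' @param construct,runId ensemble metadata labels.
#' @return list with \code{ensemble} (a \linkS4class{StructureEnsemble}),
#'   \code{annotation} (a \linkS4class{DomainAnnotation} declaring S6 =
#'   pre-hinge helix, CL = post-hinge helix and the chain cycle) and
#'   \code{truth} (the generator parameters).
#' @export
generateHingedMultimer <- function(nChains = 4L, helixLengths = c(12L, 12L),
                                   hingeFlexibility = 0, plantedDzShift = 0,
                                   nFrames = 1L, noise = 0, radius = 12,
                                   seed = 1L, construct = "synthetic",
                                   runId = "run1") {
  stopifnot(nChains >= 1L, nFrames >= 1L, hingeFlexibility >= 0,
            all(helixLengths >= 6L))
  set.seed(seed)
  nres <- sum(helixLengths)
  hinge <- helixLengths[1] - 1L           # 0-based index of last pre-hinge res
  phi0 <- rep(-57, nres); psi0 <- rep(-47, nres)
  ch <- .buildChain(phi = phi0, psi = psi0)
  ## rigid-body frame of the base chain: pre-hinge CA axis to +z
  caIdx <- which(ch$name == "CA")
  preCA <- caIdx[ch$resid[caIdx] <= hinge]
  alignRef <- function(coords) .alignToZ(coords, preCA)
  base <- alignRef(ch$coords)

  natoms <- nrow(base)
  name <- rep(ch$name, nChains)
  resid <- rep(ch$resid, nChains)
  chainIds <- LETTERS[seq_len(nChains)]
  chain <- rep(chainIds, each = natoms)
  element <- substr(name, 1, 1)
  resname <- rep("ALA", natoms * nChains)

  place <- function(coords, k) {
    Rz <- .rotationMatrix(c(0, 0, 1), (k - 1L) * 360 / nChains)
    (coords + matrix(c(radius, 0, 0), natoms, 3, byrow = TRUE)) %*% t(Rz)
  }

  postSel <- ch$resid > hinge
  hingeRes <- c(hinge, hinge + 1L)        # torsions perturbed at the junction
  wrap <- function(x) ((x + 180) %% 360) - 180

  arr <- array(NA_real_, dim = c(natoms * nChains, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    for (k in seq_len(nChains)) {
      if (hingeFlexibility > 0) {
        phi <- phi0; psi <- psi0
        jit <- wrap(rnorm(2 * length(hingeRes), 0, hingeFlexibility))
        phi[hingeRes + 1L] <- phi[hingeRes + 1L] + jit[seq_along(hingeRes)]
        psi[hingeRes + 1L] <- psi[hingeRes + 1L] +
          jit[seq_along(hingeRes) + length(hingeRes)]
        x <- alignRef(.buildChain(phi = phi, psi = psi)$coords)
      } else {
        x <- base
      }
      if (plantedDzShift != 0)
        x[postSel, 3] <- x[postSel, 3] - plantedDzShift
      x <- place(x, k)
      if (noise > 0)
        x <- x + matrix(rnorm(length(x), 0, noise), nrow(x), 3)
      arr[((k - 1L) * natoms + 1L):(k * natoms), , f] <- x
    }
  }

  snap <- .makeSnapshot(name = name, element = element, resname = resname,
                        chain = chain, resid = resid,
                        coords = arr[, , 1, drop = TRUE])
  ensemble <- .makeEnsemble(snap, arr, construct = construct, runId = runId)
  annotation <- domainAnnotation(
    regions = list(S6 = 0:hinge, CL = (hinge + 1L):(nres - 1L)),
    insertionSite = c(hinge, hinge + 1L),
    chainOrder = chainIds)
  truth <- list(nChains = nChains, helixLengths = helixLengths,
                hingeSite = hinge, hingeFlexibility = hingeFlexibility,
                plantedDzShift = plantedDzShift, nFrames = nFrames,
                noise = noise, radius = radius, seed = seed)
  list(ensemble = ensemble, annotation = annotation, truth = truth)
}

#' Write a ground-truth sidecar file (key = value text)
#' @param truth named list of scalar ground-truth values
#' @param path output path
#' @export
writeGroundTruth <- function(truth, path) {
  writeLines(sprintf("%s = %s", names(truth),
                     vapply(truth, function(v) paste(format(v), collapse = ","),
                            character(1))), path)
  invisible(path)
}

## ---- gating / binding data generators --------------------------------------

#' Generate a steady-state activation curve from the Boltzmann model
#'
#' @param vHalf,zDelta,relImaxSatV model parameters (mV, -, -).
#' @param voltages voltage protocol, mV (default -150 to -70 in 10 mV steps).
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param constants see \code{\link{physicalConstants}}.
#' @return data.frame V, relI plus a "truth" attribute.
#' @export
generateActivationCurve <- function(vHalf = -119.6, zDelta = 4,
                                    relImaxSatV = 1,
                                    voltages = seq(-150, -70, by = 10),
                                    noiseSd = 0, seed = 1L,
                                    constants = physicalConstants()) {
  set.seed(seed)
  relI <- boltzmannModel(voltages, vHalf, zDelta, relImaxSatV, constants) +
    rnorm(length(voltages), 0, noiseSd)
  out <- data.frame(V = voltages, relI = relI)
  attr(out, "truth") <- list(vHalf = vHalf, zDelta = zDelta,
                             relImaxSatV = relImaxSatV, noiseSd = noiseSd,
                             seed = seed)
  out
}

#' Generate an exponential activation trace
#'
#' I(t) = Iinf - A exp(-(t - delay)/tau) for t >= delay; flat at the
#' pre-delay level before.
#'
#' @param tau time constant, ms.
#' @param A amplitude.
#' @param delay initial delay, ms.
#' @param Iinf steady-state current.
#' @param tMax,dt trace length and sampling interval, ms.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return data.frame t, I plus a "truth" attribute.
#' @export
generateActivationTrace <- function(tau = 120, A = 1, delay = 20, Iinf = 1,
                                    tMax = 600, dt = 1, noiseSd = 0,
                                    seed = 1L) {
  t <- seq(0, tMax, by = dt)
  I <- ifelse(t < delay, Iinf - A, Iinf - A * exp(-(t - delay) / tau))
  set.seed(seed)
  I <- I + rnorm(length(t), 0, noiseSd)
  out <- data.frame(t = t, I = I)
  attr(out, "truth") <- list(tau = tau, A = A, delay = delay, Iinf = Iinf,
                             noiseSd = noiseSd, seed = seed)
  out
}

#' Generate a concentration-binding curve from the Hill model
#'
#' @param bc50 half-maximum binding concentration, uM.
#' @param hB Hill coefficient.
#' @param concentrations ligand concentrations, uM.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return data.frame x, relF plus a "truth" attribute.
#' @export
generateBindingCurve <- function(bc50 = 0.51, hB = 1.4,
                                 concentrations = c(0.05, 0.1, 0.25, 0.5,
                                                    1, 2.5),
                                 noiseSd = 0, seed = 1L) {
  set.seed(seed)
  relF <- hillModel(concentrations, bc50, hB) +
    rnorm(length(concentrations), 0, noiseSd)
  out <- data.frame(x = concentrations, relF = relF)
  attr(out, "truth") <- list(bc50 = bc50, hB = hB, noiseSd = noiseSd,
                             seed = seed)
  out
}

#' Generate a synthetic two-channel binding image
#'
#' The red channel carries the free-dye field; the green channel carries
#' \code{k} times the free-dye field plus the planted bound amplitude inside
#' the patch mask, plus optional noise and channel offsets.
#'
#' @param boundAmplitude planted bound-signal amplitude (>= 0).
#' @param k green/red free-dye scaling factor.
#' @param dim image dimensions (rows, cols).
#' @param noiseSd per-pixel Gaussian noise SD.
#' @param offsets numeric(2): additive green and red channel offsets.
#' @param seed RNG seed.
#' @return list with green, red, bathMask, patchMask, borderMask and truth.
#' @export
generateBindingImage <- function(boundAmplitude = 1, k = 2,
                                 dim = c(40L, 40L), noiseSd = 0,
                                 offsets = c(green = 0, red = 0),
                                 seed = 1L) {
  stopifnot(boundAmplitude >= 0)
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  border <- row <= 3 | row > nr - 3 | col <= 3 | col > nc - 3
  ## smooth free-dye field, zero on the signal-free border
  free <- (1 + 0.3 * sin(row / 5) + 0.2 * cos(col / 7)) * !border
  ctr <- c(nr, nc) / 2
  patch <- (row - ctr[1])^2 + (col - ctr[2])^2 <= 6^2
  bath <- !border & !patch
  red <- free + offsets["red"] + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
  green <- k * free + boundAmplitude * patch + offsets["green"] +
    matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
  list(green = green, red = red, bathMask = bath, patchMask = patch,
       borderMask = border,
       truth = list(boundAmplitude = boundAmplitude, k = k,
                    noiseSd = noiseSd, seed = seed))
}
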