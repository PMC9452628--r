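## Fixtures built in code: toy PDB text, ideal helices and strands, bent
## two-helix chains, and random body-bar networks.

toyPDBLines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "END")

## same three atoms without the element column (inference path)
toyPDBLinesNoElement <- function()
  sub("           [NC]$", "", toyPDBLines()[1:3])

writeToyEnsemblePDB <- function(path, nModels = 5L, nAtoms = 10L,
                                jitter = 0.05, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(nAtoms * 3, sd = 3), nAtoms, 3)
  out <- character(0)
  for (m in seq_len(nModels)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    x <- base + matrix(rnorm(nAtoms * 3, sd = jitter), nAtoms, 3)
    out <- c(out, vapply(seq_len(nAtoms), function(i)
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i, i, x[i, 1], x[i, 2], x[i, 3]), character(1)))
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  path
}

## snapshot from bare coordinates: one single-atom residue per row.
## name/resname chosen so the covalent templates accept them (CB of ALA is a
## carbon, SD of MET a sulfur).
pointCloudSnapshot <- function(coords, elements = rep("C", nrow(coords))) {
  name <- ifelse(elements == "S", "SD", "CB")
  resname <- ifelse(elements == "S", "MET", "ALA")
  cnaflex:::.makeSnapshot(name = name, element = elements, resname = resname,
                          chain = rep("A", nrow(coords)),
                          resid = seq_len(nrow(coords)) - 1L,
                          coords = coords)
}

## ideal poly-alanine chain snapshot (N, H, CA, CB, C, O per residue)
helixSnapshot <- function(nres, phi = rep(-57, nres), psi = rep(-47, nres),
                          chain = "A") {
  ch <- cnaflex:::.buildChain(phi = phi, psi = psi)
  x <- cnaflex:::.alignToZ(ch$coords, which(ch$name == "CA"))
  cnaflex:::.makeSnapshot(name = ch$name, element = substr(ch$name, 1, 1),
                          resname = rep("ALA", length(ch$name)),
                          chain = rep(chain, length(ch$name)),
                          resid = ch$resid, coords = x)
}

## two coaxial-or-bent ideal helices in one chain; bend applied about the
## hinge C-alpha, optional coordinate noise
bentHelixSnapshot <- function(angle, noise = 0, seed = 1L, nres = 28L,
                              hinge = 13L) {
  set.seed(seed)
  ch <- cnaflex:::.buildChain(phi = rep(-57, nres), psi = rep(-47, nres))
  x <- cnaflex:::.alignToZ(ch$coords, which(ch$name == "CA"))
  post <- ch$resid > hinge
  hingeCA <- which(ch$name == "CA" & ch$resid == hinge)
  R <- cnaflex:::.rotationMatrix(c(1, 0, 0), angle)
  pivot <- x[hingeCA, ]
  x[post, ] <- sweep(sweep(x[post, , drop = FALSE], 2, pivot) %*% t(R),
                     2, pivot, "+")
  if (noise > 0) x <- x + matrix(rnorm(length(x), 0, noise), nrow(x), 3)
  cnaflex:::.makeSnapshot(name = ch$name, element = substr(ch$name, 1, 1),
                          resname = rep("ALA", length(ch$name)),
                          chain = rep("A", length(ch$name)),
                          resid = ch$resid, coords = x)
}

## antiparallel two-strand beta sheet (placement found once by a ladder scan;
## interior residues of both strands form the canonical bridge pattern)
betaSheetSnapshot <- function(nres = 8L) {
  s <- cnaflex:::.buildChain(phi = rep(-139, nres), psi = rep(135, nres))
  x1 <- cnaflex:::.alignToZ(s$coords, which(s$name == "CA"))
  R <- cnaflex:::.rotationMatrix(c(1, 0, 0), 180)
  x2 <- x1 %*% t(R)
  x2[, 1] <- x2[, 1] + 3.8
  x2[, 3] <- x2[, 3] - 2.25
  n <- length(s$name)
  cnaflex:::.makeSnapshot(name = c(s$name, s$name),
                          element = substr(c(s$name, s$name), 1, 1),
                          resname = rep("ALA", 2L * n),
                          chain = rep(c("A", "B"), each = n),
                          resid = c(s$resid, s$resid),
                          coords = rbind(x1, x2))
}

## random body-bar network as a ConstraintNetwork (multiplicities from 2/5/6)
randomNetwork <- function(nBodies, seed) {
  set.seed(seed)
  m <- sample.int(nBodies + 4L, 1L)
  a <- integer(0); b <- integer(0)
  for (k in seq_len(m)) {
    pr <- sample.int(nBodies, 2L)
    a <- c(a, min(pr)); b <- c(b, max(pr))
  }
  keep <- !duplicated(paste(a, b))
  a <- a[keep]; b <- b[keep]
  bars <- data.frame(a = a, b = b,
                     mult = sample(c(2L, 5L, 6L), length(a), replace = TRUE),
                     kind = "covalent-rotatable", energy = NA_real_)
  new("ConstraintNetwork", nBodies = as.integer(nBodies), bars = bars,
      eCut = NA_real_)
}

## canonical form of a partition vector (relabel by first appearance)
canonicalPartition <- function(p) match(p, unique(p))

## A donor-hydrogen-acceptor triple in ideal geometry: linear D-H...A at the
## equilibrium distance, acceptor base at the trigonal angle, so the angular
## factor is exactly 1 and the energy is the radial minimum -V0.
idealTripleSnapshot <- function(dDA = 2.8) {
  coords <- rbind(
    c(dDA, 0, 0),                                 # N  (donor, res 0)
    c(dDA - 1.0, 0, 0),                           # H
    c(0, 0, 0),                                   # O  (acceptor, res 2)
    1.23 * c(cos(2*pi/3), sin(2*pi/3), 0))        # C  (acceptor base)
  cnaflex:::.makeSnapshot(name = c("N", "H", "O", "C"),
                          element = c("N", "H", "O", "C"),
                          resname = rep("ALA", 4),
                          chain = rep("A", 4),
                          resid = c(0L, 0L, 2L, 2L),
                          coords = coords)
}
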