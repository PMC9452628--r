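## Kabsch-Sander-style secondary-structure assignment. Backbone N-H...O=C
## hydrogen bonds are scored with the electrostatic energy
##   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
## (bond if E < -0.5); n-turns at i -> i+3/4/5 define 3-10/alpha/pi helices,
## bridges define beta structure, with label precedence H > E > G > I > T.

.KS_CUTOFF <- -0.5

## backbone atom coordinate lookup per residue; reconstructs the amide H from
## the preceding peptide unit when it is absent (standard virtual placement
## H = N + unit(C_prev - O_prev)).
.backboneFrames <- function(snapshot) {
  at <- snapshot@atoms
  gidx <- .atomGindex(at)
  rt <- .residueTable(at)
  n <- nrow(rt)
  get <- function(g, nm) {
    ix <- which(gidx == g & at$name == nm)
    if (length(ix)) snapshot@coords[ix[1], ] else NULL
  }
  frames <- vector("list", n)
  for (g in seq_len(n) - 1L) {
    f <- list(N = get(g, "N"), CA = get(g, "CA"), C = get(g, "C"),
              O = get(g, "O"), H = get(g, "H"),
              chain = rt$chain[g + 1L], resname = rt$resname[g + 1L])
    if (is.null(f$H)) {
      ## any hydrogen bonded to N counts as the amide H
      ix <- which(gidx == g & !at$heavy)
      if (length(ix) && !is.null(f$N)) {
        d2 <- colSums((t(snapshot@coords[ix, , drop = FALSE]) - f$N)^2)
        if (min(d2) <= 1.25^2) f$H <- snapshot@coords[ix[which.min(d2)], ]
      }
    }
    frames[[g + 1L]] <- f
  }
  ## virtual H from previous residue where still missing (not PRO, not chain
  ## start)
  if (n < 2L) return(frames)
  for (g in 2:n) {
    f <- frames[[g]]; fp <- frames[[g - 1L]]
    if (is.null(f$H) && f$resname != "PRO" && identical(f$chain, fp$chain) &&
        !is.null(f$N) && !is.null(fp$C) && !is.null(fp$O)) {
      d <- fp$C - fp$O
      frames[[g]]$H <- f$N + d / sqrt(sum(d^2))
    }
  }
  frames
}

## Kabsch-Sander H-bond energy matrix: E[i, j] = energy of N-H(i) ... O=C(j)
.ksEnergies <- function(frames) {
  n <- length(frames)
  E <- matrix(NA_real_, n, n)
  dist1 <- function(a, b) sqrt(sum((a - b)^2))
  for (i in seq_len(n)) {
    fi <- frames[[i]]
    if (is.null(fi$N) || is.null(fi$H)) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      fj <- frames[[j]]
      if (is.null(fj$C) || is.null(fj$O)) next
      rON <- dist1(fj$O, fi$N); rCH <- dist1(fj$C, fi$H)
      rOH <- dist1(fj$O, fi$H); rCN <- dist1(fj$C, fi$N)
      if (rON > 7) next  # beyond any plausible bond; keeps the scan local
      E[i, j] <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Assign secondary structure per residue
#'
#' Labels: H (alpha helix), G (3-10 helix), I (pi helix), E (beta strand),
#' T (turn), C (coil); precedence H > E > G > I > T. Residues with missing
#' backbone atoms are labelled C with a warning.
#'
#' @param snapshot a \linkS4class{StructureSnapshot} with backbone
#'   N, CA, C, O atoms.
#' @return character vector of labels, one per residue (global order).
#' @export
assignSecondaryStructure <- function(snapshot) {
  frames <- .backboneFrames(snapshot)
  n <- length(frames)
  missing_ <- vapply(frames, function(f)
    is.null(f$N) || is.null(f$CA) || is.null(f$C) || is.null(f$O), logical(1))
  if (any(missing_))
    warning(sum(missing_), " residue(s) with missing backbone atoms ",
            "labelled C")
  E <- .ksEnergies(frames)
  hb <- !is.na(E) & E < .KS_CUTOFF   # hb[i, j]: NH(i) donates to CO(j)

  ## n-turns: turn_k(i) <=> CO(i) accepts from NH(i+k), same chain
  turn <- function(k) {
    v <- logical(n)
    idx <- seq_len(n - k)
    v[idx] <- hb[cbind(idx + k, idx)] &
      vapply(idx, function(i)
        identical(frames[[i]]$chain, frames[[i + k]]$chain), logical(1))
    v
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  lab <- rep("C", n)
  markHelix <- function(tv, k, code) {
    for (i in which(tv)) {
      if (i > 1L && tv[i - 1L]) {
        span <- i:(i + k - 1L)
        span <- span[span <= n]
        lab[span][lab[span] == "C"] <<- code
      }
    }
  }
  ## precedence encoded by assignment order onto still-unlabelled residues:
  ## alpha first, then beta below, then 3-10, pi, turns
  markHelix(t4, 4L, "H")

  ## bridges (parallel / antiparallel) -> E
  isE <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3L) next
    par <- (i > 1L && j <= n && .safeHB(hb, i - 1L, j) && .safeHB(hb, j, i + 1L)) ||
           (.safeHB(hb, j - 1L, i) && .safeHB(hb, i, j + 1L))
    anti <- (.safeHB(hb, i, j) && .safeHB(hb, j, i)) ||
            (.safeHB(hb, i - 1L, j + 1L) && .safeHB(hb, j - 1L, i + 1L))
    if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
  }
  lab[isE & lab == "C"] <- "E"

  markHelix(t3, 3L, "G")
  markHelix(t5, 5L, "I")

  turnRes <- logical(n)
  for (k in 3:5) {
    tv <- list(t3, t4, t5)[[k - 2L]]
    for (i in which(tv)) {
      span <- (i + 1L):(i + k - 1L)
      turnRes[span[span <= n]] <- TRUE
    }
  }
  lab[turnRes & lab == "C"] <- "T"
  lab[missing_] <- "C"
  lab
}

.safeHB <- function(hb, i, j) {
  n <- nrow(hb)
  i >= 1L && j >= 1L && i <= n && j <= n && hb[i, j]
}

#' Secondary-structure content of a region across an ensemble
#'
#' Fraction of (residue, frame) cells labelled H/G/I/E; turns and bends are
#' not counted as secondary structure. The SEM is computed across chains
#' (subunits).
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param regionResidues within-chain residue indices defining the region.
#' @param frames optional frame subset.
#' @return named numeric: fraction, sem, n cells.
#' @export
ssContent <- function(ensemble, regionResidues,
                      frames = seq_len(nFrames(ensemble))) {
  if (!length(regionResidues)) stop("region must be non-empty")
  at <- ensemble@atoms
  rt <- .residueTable(at)
  sel <- rt$resid %in% regionResidues
  if (!any(sel)) stop("region selects no residues")
  chains <- unique(rt$chain[sel])
  perChain <- matrix(NA_real_, length(chains), length(frames))
  for (fk in seq_along(frames)) {
    lab <- assignSecondaryStructure(getSnapshot(ensemble, frames[fk]))
    struct <- lab %in% c("H", "G", "I", "E")
    for (ck in seq_along(chains)) {
      ix <- which(sel & rt$chain == chains[ck])
      perChain[ck, fk] <- mean(struct[ix])
    }
  }
  chainMeans <- rowMeans(perChain)
  c(fraction = mean(chainMeans),
    sem = if (length(chains) > 1L) sd(chainMeans) / sqrt(length(chains)) else NA_real_,
    n = sum(sel) * length(frames))
}
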