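## Hydrogen-bond and salt-bridge detection with Mayo-type energies, following
## the convention of the FIRST software family: candidate D-H...A triples pass
## geometric screens and are scored with
##   E_HB = V0 * [5 (d0/d)^12 - 6 (d0/d)^10] * F(theta, phi, gamma)
## with V0 = 8 kcal/mol, d0 = 2.8 A, d the donor-acceptor distance, and F a
## hybridisation-dependent angular factor. Salt bridges between charged groups
## are scored with the radial term only, using a longer equilibrium distance.
## Only attractive bonds (E_HB < 0) are kept.

#' Default hydrogen-bond detection parameters
#'
#' Geometric screens and energy-model constants. All distances in Angstrom,
#' angles in degrees, energies in kcal/mol.
#'
#' @param V0 well depth of the radial term.
#' @param d0 equilibrium donor-acceptor distance.
#' @param d0SaltBridge equilibrium distance for the salt-bridge variant.
#' @param maxHA maximum H...A distance.
#' @param maxDA maximum donor-acceptor distance.
#' @param maxDASalt maximum donor-acceptor distance for salt bridges.
#' @param minAngleDHA minimum D-H...A angle, degrees.
#' @return a named list of parameters.
#' @export
hbondParams <- function(V0 = 8, d0 = 2.8, d0SaltBridge = 3.287,
                        maxHA = 2.6, maxDA = 3.6, maxDASalt = 3.8,
                        minAngleDHA = 100) {
  list(V0 = V0, d0 = d0, d0SaltBridge = d0SaltBridge, maxHA = maxHA,
       maxDA = maxDA, maxDASalt = maxDASalt, minAngleDHA = minAngleDHA)
}

.angle <- function(a, b, c) {
  ## angle at b in degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.radialTerm <- function(d, V0, d0) V0 * (5 * (d0 / d)^12 - 6 * (d0 / d)^10)

## angular factor; theta = D-H...A angle (deg), phi = H...A-B angle at the
## acceptor (deg), gamma = angle between the donor and acceptor sp2 plane
## normals folded to [0, 90] (deg). Hybridisation cases use the standard
## cosine forms; the common prefactor cos^2(theta) exp(-(pi-theta)^6) damps
## non-linear geometries.
.angularFactor <- function(theta, phi, gamma, donorSp2, acceptorSp2) {
  th <- theta * pi / 180
  base <- cos(th)^2 * exp(-(pi - th)^6)
  dev <- function(deg) cos((phi - deg) * pi / 180)^2
  if (!donorSp2 && !acceptorSp2) base * dev(109.5)
  else if (!donorSp2 && acceptorSp2) base * dev(120)
  else if (donorSp2 && !acceptorSp2) base * dev(109.5)
  else base * dev(120) * cos(gamma * pi / 180)^2
}

## unit normal of the plane through atom `center` and its (first two) bonded
## heavy neighbours; NULL when underdetermined
.planeNormal <- function(xyz, center, neighbours) {
  if (length(neighbours) < 2L) return(NULL)
  u <- xyz[neighbours[1], ] - xyz[center, ]
  v <- xyz[neighbours[2], ] - xyz[center, ]
  nrm <- c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])
  len <- sqrt(sum(nrm^2))
  if (len < 1e-8) return(NULL)
  nrm / len
}

#' Detect hydrogen bonds (including salt bridges) in a snapshot
#'
#' Donors are N/O/S heavy atoms with a covalently attached hydrogen; acceptors
#' are the template-declared N/O/S acceptors (nitrogen acceptors only when
#' unprotonated). Candidate D-H...A triples must pass the geometric screens in
#' \code{params}; each survivor is scored with the Mayo-type energy and kept if
#' E_HB < 0. Pairs of atoms in oppositely charged groups are detected as salt
#' bridges and scored with the salt-bridge radial variant.
#'
#' @param snapshot a \linkS4class{StructureSnapshot} with hydrogens present.
#' @param params see \code{\link{hbondParams}}.
#' @param covalent optional precomputed \code{covalentBonds(snapshot)} table.
#' @return data.frame with columns donor, hydrogen, acceptor (atom indices;
#'   hydrogen is NA for salt bridges), energy (kcal/mol, < 0) and saltBridge.
#' @export
detectHydrogenBonds <- function(snapshot, params = hbondParams(),
                                covalent = covalentBonds(snapshot)) {
  at <- snapshot@atoms
  xyz <- snapshot@coords
  n <- nrow(at)
  gidx <- .atomGindex(at)

  ## adjacency from covalent bonds
  nbr <- vector("list", n)
  for (k in seq_len(nrow(covalent))) {
    a <- covalent$a[k]; b <- covalent$b[k]
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  bondedKey <- c(paste(covalent$a, covalent$b), paste(covalent$b, covalent$a))

  hasH <- vapply(seq_len(n), function(i)
    any(!at$heavy[nbr[[i]]]), logical(1))

  isDonor <- at$heavy & at$element %in% c("N", "O", "S") & hasH
  ## chain-start nitrogens legitimately lack an amide H; do not warn on them
  chainStart <- !duplicated(at$chain) | (gidx == ave(gidx, at$chain,
                                                     FUN = min))
  skippedDonors <- at$heavy & at$element %in% c("N", "O", "S") &
    !hasH & at$name == "N" & at$resname != "PRO" & !chainStart
  if (any(skippedDonors))
    warning(sum(skippedDonors), " backbone nitrogen donor(s) without a ",
            "hydrogen were skipped")

  accOK <- vapply(seq_len(n), function(i) {
    nm <- at$name[i]; rn <- at$resname[i]
    nm %in% .ACCEPTOR_ATOMS$backbone ||
      nm %in% (.ACCEPTOR_ATOMS[[rn]] %||% character(0))
  }, logical(1))
  ## nitrogen acceptors only when unprotonated
  isAcceptor <- at$heavy & accOK & !(at$element == "N" & hasH)

  isPos <- vapply(seq_len(n), function(i)
    at$name[i] %in% (.POSITIVE_ATOMS[[at$resname[i]]] %||% character(0)),
    logical(1))
  isNeg <- vapply(seq_len(n), function(i)
    at$name[i] %in% (.NEGATIVE_ATOMS[[at$resname[i]]] %||% character(0)),
    logical(1))

  sp2 <- .isSp2(at$resname, at$name)
  donors <- which(isDonor)
  acceptors <- which(isAcceptor | isNeg)
  out <- list()

  if (!length(donors) || !length(acceptors))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), energy = numeric(0),
                      saltBridge = logical(0)))

  ## vectorised distance prefilter over all donor/acceptor pairs
  dmat <- sqrt(outer(rowSums(xyz[donors, , drop = FALSE]^2),
                     rowSums(xyz[acceptors, , drop = FALSE]^2), "+") -
               2 * xyz[donors, , drop = FALSE] %*%
                 t(xyz[acceptors, , drop = FALSE]))
  cand <- which(dmat <= params$maxDASalt, arr.ind = TRUE)

  for (k in seq_len(nrow(cand))) {
    d <- donors[cand[k, 1]]; acc <- acceptors[cand[k, 2]]
    {
      hyds <- nbr[[d]][!at$heavy[nbr[[d]]]]
      salt <- isPos[d]
      if (acc == d || gidx[acc] == gidx[d]) next
      if (paste(d, acc) %in% bondedKey) next
      dDA <- dmat[cand[k, 1], cand[k, 2]]
      isSB <- salt && isNeg[acc]
      if (dDA > (if (isSB) params$maxDASalt else params$maxDA)) next

      if (isSB) {
        e <- .radialTerm(dDA, params$V0, params$d0SaltBridge)
        if (e < 0)
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = NA_integer_, acceptor = acc,
            energy = e, saltBridge = TRUE)
        next
      }
      if (!isAcceptor[acc]) next

      ## best hydrogen for this D...A pair
      best <- NULL
      for (h in hyds) {
        dHA <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
        if (dHA > params$maxHA) next
        theta <- .angle(xyz[d, ], xyz[h, ], xyz[acc, ])
        if (theta < params$minAngleDHA) next
        base <- nbr[[acc]][at$heavy[nbr[[acc]]]]
        phi <- if (length(base)) .angle(xyz[h, ], xyz[acc, ], xyz[base[1], ])
               else if (sp2[acc]) 120 else 109.5
        gamma <- 0
        if (sp2[d] && sp2[acc]) {
          nd <- .planeNormal(xyz, d, nbr[[d]][at$heavy[nbr[[d]]]])
          na_ <- .planeNormal(xyz, acc, base)
          if (!is.null(nd) && !is.null(na_)) {
            cg <- abs(sum(nd * na_))
            gamma <- acos(max(-1, min(1, cg))) * 180 / pi
          }
        }
        f <- .angularFactor(theta, phi, gamma, sp2[d], sp2[acc])
        e <- .radialTerm(dDA, params$V0, params$d0) * f
        if (is.null(best) || e < best$energy)
          best <- list(hydrogen = h, energy = e)
      }
      if (!is.null(best) && best$energy < 0)
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = best$hydrogen, acceptor = acc,
          energy = best$energy, saltBridge = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), energy = numeric(0),
                      saltBridge = logical(0)))
  do.call(rbind, out)
}
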