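## Residue templates for the 20 standard amino acids: heavy-atom covalent
## bonds, ring membership, sp2 centres, hydrogen-bond donor/acceptor roles and
## charged groups. Hydrogens are attached by distance (<= 1.25 A to the
## nearest heavy atom), which is robust against the many H naming schemes in
## MD-derived PDB files. Disulfides are detected by S-S distance.

.BACKBONE_BONDS <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))

.SIDECHAIN_BONDS <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","NE"),
             c("NE","CZ"), c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CA","CB"), c("CB","SG")),
  GLN = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","NE2")),
  GLU = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","OE2")),
  GLY = list(),
  HIS = list(c("CA","CB"), c("CB","CG"), c("CG","ND1"), c("CG","CD2"),
             c("ND1","CE1"), c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","CE"),
             c("CE","NZ")),
  MET = list(c("CA","CB"), c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = list(c("CA","CB"), c("CB","OG")),
  THR = list(c("CA","CB"), c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","NE1"), c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"),
             c("CE2","CZ2"), c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"),
             c("CZ","OH")),
  VAL = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2")))

## ring bonds (locked regardless of hybridisation; covers the sp3 PRO ring)
.RING_BONDS <- list(
  HIS = list(c("CG","ND1"), c("CG","CD2"), c("ND1","CE1"), c("CD2","NE2"),
             c("CE1","NE2")),
  PHE = list(c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"), c("CD2","CE2"),
             c("CE1","CZ"), c("CE2","CZ")),
  TYR = list(c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"), c("CD2","CE2"),
             c("CE1","CZ"), c("CE2","CZ")),
  TRP = list(c("CG","CD1"), c("CG","CD2"), c("CD1","NE1"), c("NE1","CE2"),
             c("CD2","CE2"), c("CD2","CE3"), c("CE2","CZ2"), c("CE3","CZ3"),
             c("CZ2","CH2"), c("CZ3","CH2")),
  PRO = list(c("N","CA"), c("CA","CB"), c("CB","CG"), c("CG","CD"),
             c("CD","N")))

## sp2 heavy atoms per residue (beyond the backbone N, C, O which are always
## sp2 in the amide); everything else defaults to sp3
.SP2_ATOMS <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  GLN = c("CD", "OE1", "NE2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"))

.BACKBONE_SP2 <- c("N", "C", "O", "OXT")

## hydrogen-bond acceptors: name -> TRUE per residue (N acceptors only if
## unprotonated, decided at detection time from attached hydrogens)
.ACCEPTOR_ATOMS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG")

## charged groups for salt-bridge detection
.POSITIVE_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                        HIS = c("ND1", "NE2"))
.NEGATIVE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.VDW_RADII <- c(C = 1.7, S = 1.8)

.isSp2 <- function(resname, name) {
  name %in% .BACKBONE_SP2 | mapply(function(rn, nm)
    nm %in% (.SP2_ATOMS[[rn]] %||% character(0)), resname, name,
    USE.NAMES = FALSE)
}

## Covalent bond list for a snapshot. Returns data.frame(a, b, locked) with
## 1-based atom indices, a < b. Errors on heavy sidechain atoms that the
## templates do not know (nonstandard residues).
covalentBonds <- function(snapshot) {
  at <- snapshot@atoms
  xyz <- snapshot@coords
  n <- nrow(at)
  gidx <- .atomGindex(at)
  a <- integer(0); b <- integer(0)

  known <- c("N","CA","C","O","OXT")
  bylab <- split(seq_len(n), gidx)
  for (res in bylab) {
    rn <- at$resname[res[1]]
    tmpl <- .SIDECHAIN_BONDS[[rn]]
    heavyNames <- at$name[res][at$heavy[res]]
    if (is.null(tmpl)) {
      if (any(!heavyNames %in% known))
        stop("no covalent template for residue '", rn, "'")
      tmpl <- list()
    } else {
      tnames <- unique(c(known, unlist(tmpl)))
      if (any(!heavyNames %in% tnames))
        stop("atom(s) ", paste(setdiff(heavyNames, tnames), collapse = ","),
             " of residue '", rn, "' not in covalent template")
    }
    bonds <- c(.BACKBONE_BONDS, tmpl)
    nm <- at$name[res]
    for (bd in bonds) {
      i <- res[match(bd[1], nm)]; j <- res[match(bd[2], nm)]
      if (!is.na(i) && !is.na(j)) { a <- c(a, i); b <- c(b, j) }
    }
  }

  ## peptide bonds: C(i) - N(i+1) within a chain, consecutive residues
  rt <- .residueTable(at)
  cIdx <- which(at$name == "C"); nIdx <- which(at$name == "N")
  for (k in cIdx) {
    g <- gidx[k]
    nxt <- nIdx[gidx[nIdx] == g + 1L & at$chain[nIdx] == at$chain[k]]
    if (length(nxt) == 1L && g + 2L <= nrow(rt) &&
        rt$resid[g + 2L] == rt$resid[g + 1L] + 1L) {
      a <- c(a, k); b <- c(b, nxt)
    }
  }

  ## hydrogens: attach to nearest heavy atom within 1.25 A
  hIdx <- which(!at$heavy)
  if (length(hIdx)) {
    heavyIdx <- which(at$heavy)
    for (h in hIdx) {
      d2 <- colSums((t(xyz[heavyIdx, , drop = FALSE]) - xyz[h, ])^2)
      j <- heavyIdx[which.min(d2)]
      if (d2[which.min(d2)] <= 1.25^2) { a <- c(a, h); b <- c(b, j) }
      ## unattached hydrogens are left free; detection warns about them
    }
  }

  ## disulfides: SG-SG <= 2.3 A, different residues
  sg <- which(at$name == "SG" & at$element == "S")
  if (length(sg) > 1L) {
    for (i in seq_along(sg)) for (j in seq_len(i - 1L)) {
      d <- sqrt(sum((xyz[sg[i], ] - xyz[sg[j], ])^2))
      if (d <= 2.3 && gidx[sg[i]] != gidx[sg[j]]) {
        a <- c(a, sg[j]); b <- c(b, sg[i])
      }
    }
  }

  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]

  ## locked bars: peptide bonds, sp2-sp2 bonds, ring bonds, bonds to terminal
  ## (degree-1) atoms -- rotation about an axis through a point atom is not a
  ## physical degree of freedom
  deg <- tabulate(c(lo, hi), nbins = n)
  sp2 <- .isSp2(at$resname, at$name) & at$heavy
  ringKey <- unlist(lapply(names(.RING_BONDS), function(rn)
    vapply(.RING_BONDS[[rn]], function(bd)
      paste(rn, paste(sort(bd), collapse = "-")), character(1))))
  bondKey <- paste(at$resname[lo],
                   paste(pmin(at$name[lo], at$name[hi]),
                         pmax(at$name[lo], at$name[hi]), sep = "-"))
  sameRes <- gidx[lo] == gidx[hi]
  isPeptide <- at$name[lo] %in% c("C", "N") & at$name[hi] %in% c("C", "N") &
    !sameRes
  locked <- isPeptide | (sp2[lo] & sp2[hi]) |
    (sameRes & bondKey %in% ringKey) |
    deg[lo] == 1L | deg[hi] == 1L

  data.frame(a = lo, b = hi, locked = locked)
}
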