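## Hydrophobic tethers: carbon/sulfur heavy-atom pairs from different residues
## within the sum of their van der Waals radii (C 1.7 A, S 1.8 A) plus an
## offset D_cut = 0.25 A. The boundary is inclusive (a C-C pair at exactly
## 3.65 A is a tether). Tethers model through-space hydrophobic contacts, so
## pairs connected through at most 3 covalent bonds (1-2, 1-3, 1-4
## neighbours, e.g. backbone C(i)-CA(i+1)) are excluded: such pairs are
## already angle/dihedral-coupled and tethering them would rigidify every
## polypeptide backbone irrespective of its hydrogen bonding.

#' Detect hydrophobic tethers in a snapshot
#'
#' @param snapshot a \linkS4class{StructureSnapshot}.
#' @param dcut offset added to the van der Waals radius sum, Angstrom.
#' @param covalent optional precomputed \code{covalentBonds(snapshot)} table.
#' @return data.frame with columns a, b (atom indices, a < b) and distance.
#' @export
detectHydrophobicTethers <- function(snapshot, dcut = 0.25,
                                     covalent = covalentBonds(snapshot)) {
  at <- snapshot@atoms
  xyz <- snapshot@coords
  idx <- which(at$heavy & at$element %in% c("C", "S"))
  empty <- data.frame(a = integer(0), b = integer(0), distance = numeric(0))
  if (length(idx) < 2L) return(empty)

  gidx <- .atomGindex(at)
  r <- .VDW_RADII[at$element[idx]]
  p <- xyz[idx, , drop = FALSE]
  maxCut <- max(r) * 2 + dcut

  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * p %*% t(p)
  d2[d2 < 0] <- 0
  cut <- outer(r, r, "+") + dcut
  hit <- which(upper.tri(d2) & sqrt(d2) <= cut + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)

  a <- idx[hit[, 1]]; b <- idx[hit[, 2]]
  keep <- gidx[a] != gidx[b]
  ## covalent-graph distance <= 3 bonds excludes the pair
  nAll <- nrow(at)
  adj <- vector("list", nAll)
  for (k in seq_len(nrow(covalent))) {
    adj[[covalent$a[k]]] <- c(adj[[covalent$a[k]]], covalent$b[k])
    adj[[covalent$b[k]]] <- c(adj[[covalent$b[k]]], covalent$a[k])
  }
  near3 <- function(u) {
    s1 <- adj[[u]]
    s2 <- unique(unlist(adj[s1]))
    s3 <- unique(unlist(adj[s2]))
    unique(c(s1, s2, s3))
  }
  cand <- unique(c(a[keep], b[keep]))
  nearOf <- setNames(lapply(cand, near3), cand)
  tooClose <- mapply(function(x, y)
    y %in% nearOf[[as.character(x)]], a, b)
  keep <- keep & !tooClose
  if (!any(keep)) return(empty)
  a <- a[keep]; b <- b[keep]
  data.frame(a = pmin(a, b), b = pmax(a, b),
             distance = sqrt(d2[hit])[keep])
}
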