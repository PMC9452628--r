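## Independent oracles used by the tests: numeric-rank generic rigidity
## matrix, quaternion-based least-squares superposition, and brute-force
## re-implementations of the constraint rules.

## Generic body-bar rigidity-matrix oracle: floppy modes and rigid-cluster
## partition from the numeric rank of randomly realised rigidity matrices.
## Each bar contributes one row per copy with random generic attachment
## points; co-rigidity of a body pair is tested by whether one additional
## generic bar raises the rank. Results are taken over several realisations
## to guard against accidental degeneracy.
rigidityMatrixOracle <- function(network, nRealisations = 3L, seed = 1L) {
  set.seed(seed)
  n <- network@nBodies
  bars <- network@bars
  pts <- lapply(seq_len(nRealisations), function(r) matrix(rnorm(n * 3), n, 3))
  cross3 <- function(u, v)
    c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])
  rowFor <- function(P, u, v) {
    pu <- P[u, ] + rnorm(3, 0, 0.3); pv <- P[v, ] + rnorm(3, 0, 0.3)
    d <- pu - pv
    row <- numeric(6 * n)
    row[(6*u-5):(6*u-3)] <- d;  row[(6*u-2):(6*u)] <- cross3(pu, d)
    row[(6*v-5):(6*v-3)] <- -d; row[(6*v-2):(6*v)] <- -cross3(pv, d)
    row
  }
  rankOf <- function(P, extra = NULL) {
    rows <- list()
    for (k in seq_len(nrow(bars)))
      for (cc in seq_len(bars$mult[k]))
        rows[[length(rows) + 1L]] <- rowFor(P, bars$a[k], bars$b[k])
    if (!is.null(extra))
      rows[[length(rows) + 1L]] <- rowFor(P, extra[1], extra[2])
    if (!length(rows)) return(0L)
    qr(do.call(rbind, rows))$rank
  }
  baseRank <- max(vapply(pts, function(P) rankOf(P), integer(1)))

  ## connected components of the bar graph
  par <- seq_len(n)
  find <- function(x) { while (par[x] != x) x <- par[x]; x }
  for (k in seq_len(nrow(bars))) {
    ra <- find(bars$a[k]); rb <- find(bars$b[k])
    if (ra != rb) par[rb] <- ra
  }
  ncomp <- length(unique(vapply(seq_len(n), find, integer(1))))
  floppy <- 6L * n - 6L * ncomp - baseRank

  ## cluster partition: all pairs, co-rigid iff an extra generic bar never
  ## raises the rank
  par2 <- seq_len(n)
  find2 <- function(x) { while (par2[x] != x) x <- par2[x]; x }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (find2(i) == find2(j)) next
    ranks <- vapply(pts, function(P) rankOf(P, c(i, j)), integer(1))
    if (all(ranks == baseRank)) {
      ra <- find2(i); rb <- find2(j)
      if (ra != rb) par2[rb] <- ra
    }
  }
  part <- vapply(seq_len(n), find2, integer(1))
  list(floppyModes = floppy, partition = match(part, unique(part)),
       rank = baseRank)
}

## Horn's closed-form quaternion solution for least-squares superposition;
## returns the RMSD of y onto x after the optimal rigid transformation.
quaternionRMSD <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  X <- sweep(x, 2, cx); Y <- sweep(y, 2, cy)
  S <- t(Y) %*% X
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1,1] + S[2,2] + S[3,3]
  N[1, 2] <- N[2, 1] <- S[2,3] - S[3,2]
  N[1, 3] <- N[3, 1] <- S[3,1] - S[1,3]
  N[1, 4] <- N[4, 1] <- S[1,2] - S[2,1]
  N[2, 2] <- S[1,1] - S[2,2] - S[3,3]
  N[2, 3] <- N[3, 2] <- S[1,2] + S[2,1]
  N[2, 4] <- N[4, 2] <- S[1,3] + S[3,1]
  N[3, 3] <- -S[1,1] + S[2,2] - S[3,3]
  N[3, 4] <- N[4, 3] <- S[2,3] + S[3,2]
  N[4, 4] <- -S[1,1] - S[2,2] + S[3,3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; v <- q[2:4]
  R <- diag(3) * (w^2 - sum(v^2)) + 2 * (v %*% t(v)) +
    2 * w * matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  Yr <- Y %*% t(R)
  sqrt(mean(rowSums((Yr - X)^2)))
}

## Brute-force Mayo-type hydrogen-bond scan over all D-H...A triples,
## written directly from the energy definitions (radial term, hybridisation
## cosine factors, geometric screens).
bruteForceHBonds <- function(snapshot, params = hbondParams()) {
  at <- snapshot@atoms
  xyz <- snapshot@coords
  cov <- cnaflex:::covalentBonds(snapshot)
  n <- nrow(at)
  adj <- vector("list", n)
  for (k in seq_len(nrow(cov))) {
    adj[[cov$a[k]]] <- c(adj[[cov$a[k]]], cov$b[k])
    adj[[cov$b[k]]] <- c(adj[[cov$b[k]]], cov$a[k])
  }
  gidx <- cnaflex:::.atomGindex(at)
  sp2 <- cnaflex:::.isSp2(at$resname, at$name)
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(max(-1, min(1, sum(u*v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  res <- list()
  for (d in seq_len(n)) {
    if (!at$heavy[d] || !(at$element[d] %in% c("N", "O", "S"))) next
    hyds <- adj[[d]][!at$heavy[adj[[d]]]]
    if (!length(hyds)) next
    for (acc in seq_len(n)) {
      if (acc == d || gidx[acc] == gidx[d]) next
      nm <- at$name[acc]; rn <- at$resname[acc]
      accTab <- c(cnaflex:::.ACCEPTOR_ATOMS$backbone,
                  cnaflex:::.ACCEPTOR_ATOMS[[rn]])
      if (!(nm %in% accTab)) next
      if (at$element[acc] == "N" && any(!at$heavy[adj[[acc]]])) next
      if (acc %in% adj[[d]]) next
      dDA <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (dDA > params$maxDA) next
      bestE <- NA; bestH <- NA
      for (h in hyds) {
        dHA <- sqrt(sum((xyz[h, ] - xyz[acc, ])^2))
        if (dHA > params$maxHA) next
        theta <- ang(xyz[d, ], xyz[h, ], xyz[acc, ])
        if (theta < params$minAngleDHA) next
        base <- adj[[acc]][at$heavy[adj[[acc]]]]
        phi <- if (length(base)) ang(xyz[h, ], xyz[acc, ], xyz[base[1], ])
               else if (sp2[acc]) 120 else 109.5
        gamma <- 0
        if (sp2[d] && sp2[acc]) {
          pn <- function(center, nbrs) {
            if (length(nbrs) < 2L) return(NULL)
            u <- xyz[nbrs[1], ] - xyz[center, ]
            v <- xyz[nbrs[2], ] - xyz[center, ]
            w <- c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
            if (sqrt(sum(w^2)) < 1e-8) NULL else w / sqrt(sum(w^2))
          }
          nd <- pn(d, adj[[d]][at$heavy[adj[[d]]]])
          na_ <- pn(acc, base)
          if (!is.null(nd) && !is.null(na_))
            gamma <- acos(max(-1, min(1, abs(sum(nd * na_))))) * 180 / pi
        }
        thr <- theta * pi / 180
        fbase <- cos(thr)^2 * exp(-(pi - thr)^6)
        fang <- if (!sp2[d] && !sp2[acc]) fbase * cos((phi - 109.5)*pi/180)^2
          else if (!sp2[d] && sp2[acc]) fbase * cos((phi - 120)*pi/180)^2
          else if (sp2[d] && !sp2[acc]) fbase * cos((phi - 109.5)*pi/180)^2
          else fbase * cos((phi - 120)*pi/180)^2 * cos(gamma*pi/180)^2
        e <- params$V0 * (5 * (params$d0/dDA)^12 - 6 * (params$d0/dDA)^10) * fang
        if (is.na(bestE) || e < bestE) { bestE <- e; bestH <- h }
      }
      if (!is.na(bestE) && bestE < 0)
        res[[length(res) + 1L]] <- data.frame(donor = d, hydrogen = bestH,
                                              acceptor = acc, energy = bestE)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), energy = numeric(0)))
  do.call(rbind, res)
}
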