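test_that("body-bar counting on minimal networks", {
  one <- new("ConstraintNetwork", nBodies = 1L,
             bars = data.frame(a = integer(0), b = integer(0),
                               mult = integer(0), kind = character(0),
                               energy = numeric(0)), eCut = NA_real_)
  d <- pebbleGame(one)
  expect_equal(d@nClusters, 1L)
  expect_equal(d@floppyModes, 0L)

  two6 <- new("ConstraintNetwork", nBodies = 2L,
              bars = data.frame(a = 1L, b = 2L, mult = 6L,
                                kind = "covalent-locked", energy = NA_real_),
              eCut = NA_real_)
  d6 <- pebbleGame(two6)
  expect_equal(d6@nClusters, 1L)
  expect_equal(d6@floppyModes, 0L)

  two5 <- new("ConstraintNetwork", nBodies = 2L,
              bars = data.frame(a = 1L, b = 2L, mult = 5L,
                                kind = "covalent-rotatable",
                                energy = NA_real_), eCut = NA_real_)
  d5 <- pebbleGame(two5)
  expect_equal(d5@nClusters, 2L)          # a hinge: no shared rigid cluster
  expect_equal(d5@floppyModes, 1L)        # one internal DOF
})

test_that("invalid bar multiplicities are rejected", {
  bad <- new("ConstraintNetwork", nBodies = 2L,
             bars = data.frame(a = 1L, b = 2L, mult = 6L,
                               kind = "covalent-locked", energy = NA_real_),
             eCut = NA_real_)
  bad@bars$mult <- 4L
  expect_error(pebbleGame(bad), "multiplicities")
})

test_that("pebble game matches the generic rigidity-matrix oracle", {
  ## the full 200-network comparison runs in the acceptance suite; this is a
  ## fast regression slice over the same generator
  for (seed in 1:40) {
    net <- randomNetwork(nBodies = sample(2:10, 1), seed = seed)
    dec <- pebbleGame(net)
    orc <- rigidityMatrixOracle(net, seed = seed + 1000L)
    expect_equal(dec@floppyModes, orc$floppyModes,
                 info = sprintf("seed %d floppy", seed))
    expect_equal(canonicalPartition(dec@clusterOf),
                 canonicalPartition(orc$partition),
                 info = sprintf("seed %d partition", seed))
  }
})

test_that("decomposition is invariant to bar insertion order", {
  set.seed(77)
  net <- randomNetwork(nBodies = 9L, seed = 42)
  ref <- pebbleGame(net)
  for (rep_ in 1:5) {
    perm <- sample.int(nrow(net@bars))
    shuffled <- net
    shuffled@bars <- net@bars[perm, ]
    got <- pebbleGame(shuffled)
    expect_equal(got@clusterOf, ref@clusterOf)
    expect_equal(got@floppyModes, ref@floppyModes)
  }
})

test_that("adding a bar within a connected network never increases floppy modes", {
  ## (joining two disconnected components is different: it merges their
  ## trivial-motion counts and legitimately exposes relative DOF)
  set.seed(5)
  for (rep_ in 1:20) {
    net <- randomNetwork(nBodies = 8L, seed = rep_ + 300L)
    ## connect with a backbone chain of rotatable bars
    chain <- data.frame(a = 1:7, b = 2:8, mult = 5L,
                        kind = "covalent-rotatable", energy = NA_real_)
    net@bars <- unique(rbind(net@bars, chain))
    base <- pebbleGame(net)@floppyModes
    pr <- sample.int(8L, 2L)
    aug <- net
    aug@bars <- rbind(net@bars,
                      data.frame(a = min(pr), b = max(pr), mult = 2L,
                                 kind = "hydrophobic", energy = NA_real_))
    expect_lte(pebbleGame(aug)@floppyModes, base)
  }
})

test_that("dilution with one grid value equals a direct pebble game", {
  snap <- helixSnapshot(8L)
  cov <- cnaflex:::covalentBonds(snap)
  bonds <- suppressWarnings(detectHydrogenBonds(snap, covalent = cov))
  tet <- detectHydrophobicTethers(snap, covalent = cov)
  dil <- dilute(snap, eCutGrid = -1, bonds = bonds, tethers = tet,
                covalent = cov)
  direct <- pebbleGame(buildNetwork(snap, bonds, tet, eCut = -1,
                                    covalent = cov))
  expect_equal(dil[[1]]@clusterOf, direct@clusterOf)
  expect_equal(dil[[1]]@floppyModes, direct@floppyModes)
  expect_error(dilute(snap, eCutGrid = numeric(0)), "non-empty")
  expect_error(dilute(snap, eCutGrid = c(-2, -1)), "decreasing")
})

test_that("cluster partitions only refine along the dilution", {
  snap <- helixSnapshot(10L)
  grid <- -seq(0.5, 5, by = 0.5)
  dil <- suppressWarnings(dilute(snap, grid))
  nclus <- vapply(dil, function(d) d@nClusters, integer(1))
  expect_true(all(diff(nclus) >= 0))       # monotone fragmentation
  for (k in 2:length(dil)) {
    lo <- dil[[k]]@clusterOf; hi <- dil[[k - 1]]@clusterOf
    ## every cluster at the lower cutoff sits inside one cluster above
    expect_true(all(tapply(hi, lo, function(v) length(unique(v))) == 1L))
  }
})

test_that("stability map obeys the inclusive contact rule and grid bounds", {
  ## two single-atom residues at exactly 4.5 A, rigidly connected
  snap <- pointCloudSnapshot(rbind(c(0, 0, 0), c(4.5, 0, 0)))
  dil <- list(new("RigidClusterDecomposition", eCut = -0.1,
                  clusterOf = c(1L, 1L), nClusters = 1L, floppyModes = 0L),
              new("RigidClusterDecomposition", eCut = -6,
                  clusterOf = c(1L, 1L), nClusters = 1L, floppyModes = 0L))
  sm <- stabilityMap(dil, snap)
  expect_equal(nrow(sm@pairs), 1L)          # 4.5 A boundary is a contact
  expect_equal(sm@pairs$rc, -6)             # co-rigid at every cutoff
  ## just beyond the boundary: no contact pair
  snap2 <- pointCloudSnapshot(rbind(c(0, 0, 0), c(4.51, 0, 0)))
  expect_equal(nrow(stabilityMap(dil, snap2)@pairs), 0L)
  ## never co-rigid: sentinel one step above the grid maximum
  dil2 <- list(new("RigidClusterDecomposition", eCut = -0.1,
                   clusterOf = c(1L, 2L), nClusters = 2L, floppyModes = 6L),
               new("RigidClusterDecomposition", eCut = -0.2,
                   clusterOf = c(1L, 2L), nClusters = 2L, floppyModes = 6L))
  sm2 <- stabilityMap(dil2, snap)
  expect_equal(sm2@pairs$rc, 0)
  expect_equal(sm2@sentinel, 0)
})

test_that("rc map equals a brute-force (pair, cutoff) scan on the helix", {
  snap <- helixSnapshot(8L)
  grid <- -seq(0.5, 5, by = 0.5)
  dil <- suppressWarnings(dilute(snap, grid))
  sm <- stabilityMap(dil, snap)
  at <- atoms(snap); gidx <- cnaflex:::.atomGindex(at)
  xyz <- coords(snap)
  heavyByRes <- split(which(at$heavy), gidx[at$heavy])
  nres <- nResidues(snap)
  for (i in 0:(nres - 2L)) for (j in (i + 1L):(nres - 1L)) {
    hi <- heavyByRes[[as.character(i)]]; hj <- heavyByRes[[as.character(j)]]
    dmin <- min(sqrt(outer(rowSums(xyz[hi, , drop = FALSE]^2),
                           rowSums(xyz[hj, , drop = FALSE]^2), "+") -
                     2 * xyz[hi, , drop = FALSE] %*%
                       t(xyz[hj, , drop = FALSE])))
    inContact <- dmin <= 4.5
    row <- sm@pairs[sm@pairs$i == i & sm@pairs$j == j, ]
    expect_equal(nrow(row), as.integer(inContact))
    if (!inContact) next
    coRigid <- vapply(seq_along(grid), function(k) {
      cl <- dil[[k]]@clusterOf
      length(intersect(unique(cl[hi]), unique(cl[hj]))) > 0L
    }, logical(1))
    rcBrute <- if (any(coRigid)) min(grid[coRigid]) else sm@sentinel
    expect_equal(row$rc, rcBrute)
  }
  ## symmetry is structural: stored as i < j with a unique row per pair
  expect_true(all(sm@pairs$i < sm@pairs$j))
  expect_false(any(duplicated(sm@pairs[, c("i", "j")])))
})

test_that("profile halving identity: sum_i E_i equals E_total", {
  ## direct application on a residue with contacts at -2 and -4 kcal/mol
  sm <- new("StabilityMap",
            pairs = data.frame(i = c(0L, 0L), j = c(1L, 2L), rc = c(-2, -4)),
            nResidues = 4L, sentinel = 0, averaged = FALSE)
  pr <- stabilityProfile(sm)
  expect_equal(unname(pr@Ei[1]), -3)        # (-2 + -4)/2
  expect_equal(unname(pr@Ei[4]), 0)         # no contacts
  expect_equal(sum(pr@Ei), pr@Etotal, tolerance = 1e-12)
  ## random sparse maps
  set.seed(8)
  for (rep_ in 1:10) {
    n <- 12L
    pairs <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
    pairs <- pairs[pairs$i < pairs$j, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.3, ]
    pairs$rc <- -runif(nrow(pairs), 0, 6)
    smr <- new("StabilityMap", pairs = pairs, nResidues = n, sentinel = 0,
               averaged = FALSE)
    prr <- stabilityProfile(smr)
    expect_equal(sum(prr@Ei), prr@Etotal, tolerance = 1e-9)
  }
})

test_that("delta-stability conventions: zero null, sign, and exact p-values", {
  ## identical groups: nothing significant, all differences zero
  reps <- lapply(1:4, function(k) setNames(rep(-3, 6), 0:5))
  d0 <- deltaStability(reps, reps)
  expect_equal(d0@dE, rep(0, 6))
  expect_false(any(d0@significant))
  ## construct shifted +5.5 with tiny variance: destabilised => negative dE
  set.seed(12)
  ref <- lapply(1:4, function(k) setNames(rnorm(6, -10, 0.01), 0:5))
  con <- lapply(1:4, function(k) setNames(rnorm(6, -4.5, 0.01), 0:5))
  d <- deltaStability(ref, con)
  expect_true(all(d@dE < -5.3 & d@dE > -5.7))
  expect_true(all(d@significant))
  expect_equal(d@dEReported, d@dE)
  ## p-values equal the direct Welch formula
  refM <- do.call(cbind, ref); conM <- do.call(cbind, con)
  for (i in 1:6) {
    a <- refM[i, ]; b <- conM[i, ]
    s2a <- var(a) / length(a); s2b <- var(b) / length(b)
    tstat <- (mean(a) - mean(b)) / sqrt(s2a + s2b)
    df <- (s2a + s2b)^2 / (s2a^2 / (length(a) - 1) + s2b^2 / (length(b) - 1))
    pWant <- 2 * pt(-abs(tstat), df)
    expect_equal(d@p[i], pWant, tolerance = 1e-9)
  }
  expect_error(deltaStability(ref[1], con), ">= 2 replicates")
})

test_that("region averages reduce correctly", {
  d <- new("DeltaStability", residue = 0:5, dE = c(1, -2, 3, 0, 0, 0),
           dEReported = c(1, -2, 3, 0, 0, 0), p = rep(0.01, 6),
           significant = rep(TRUE, 6), alpha = 0.05)
  one <- regionAverage(d, 1L)
  expect_equal(unname(one["mean"]), -2)
  expect_equal(unname(one["sd"]), 0)
  expect_equal(unname(regionAverage(d, 3:5)["mean"]), 0)
  r <- regionAverage(d, 0:2)
  expect_equal(unname(r["mean"]), mean(c(1, -2, 3)))
  expect_equal(unname(r["sd"]), sd(c(1, -2, 3)))
  expect_error(regionAverage(d, 10L), "outside")
  expect_error(regionAverage(d, integer(0)), "non-empty")
})

test_that("both ensemble aggregation orders are internally consistent", {
  g <- generateHingedMultimer(nChains = 1L, helixLengths = c(8L, 8L),
                              hingeFlexibility = 12, nFrames = 4L, seed = 3)
  grid <- -seq(0.5, 5, by = 0.5)
  suppressWarnings({
    pRC <- ensembleStabilityProfile(g$ensemble, grid, aggregation = "rc")
    pPr <- ensembleStabilityProfile(g$ensemble, grid, aggregation = "profile")
  })
  expect_equal(length(pRC@Ei), length(pPr@Ei))
  expect_equal(sum(pRC@Ei), pRC@Etotal, tolerance = 1e-9)
  expect_equal(sum(pPr@Ei), pPr@Etotal, tolerance = 1e-9)
})
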