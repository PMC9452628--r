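test_that("RMSF: zero for static ensembles, analytic for an oscillator", {
  snap <- helixSnapshot(8L)
  n <- nrow(coords(snap))
  arr <- array(rep(coords(snap), 5), c(n, 3, 5))
  ens <- cnaflex:::.makeEnsemble(snap, arr)
  expect_true(all(rmsf(ens)$rmsf == 0))

  ## one CA alternating between +a and -a along x
  a <- 1.7
  one <- pointCloudSnapshot(matrix(c(0, 0, 0), 1, 3))
  one@atoms$name <- "CA"
  osc <- array(0, c(1, 3, 4))
  osc[1, 1, ] <- c(a, -a, a, -a)
  ensO <- cnaflex:::.makeEnsemble(one, osc)
  expect_equal(rmsf(ensO)$rmsf, a, tolerance = 1e-12)
})

test_that("RMSF equals the brute-force two-pass computation", {
  set.seed(14)
  snap <- helixSnapshot(6L)
  n <- nrow(coords(snap))
  arr <- array(rep(coords(snap), 8), c(n, 3, 8)) +
    array(rnorm(n * 3 * 8, sd = 0.4), c(n, 3, 8))
  ens <- cnaflex:::.makeEnsemble(snap, arr)
  got <- rmsf(ens)
  caIdx <- which(atoms(ens)$name == "CA")
  gidx <- cnaflex:::.atomGindex(atoms(ens))
  for (k in seq_along(caIdx)) {
    m <- t(arr[caIdx[k], , ])
    mu <- colMeans(m)
    want <- sqrt(mean(rowSums(sweep(m, 2, mu)^2)))
    expect_equal(got$rmsf[got$gindex == gidx[caIdx[k]]], want,
                 tolerance = 1e-9)
  }
})

test_that("RMSF is invariant to a uniform global rigid motion", {
  set.seed(15)
  g <- generateHingedMultimer(nChains = 2L, helixLengths = c(8L, 8L),
                              hingeFlexibility = 10, nFrames = 6L, seed = 2)
  ens <- g$ensemble
  base <- rmsf(ens)$rmsf
  R <- cnaflex:::.rotationMatrix(rnorm(3), 73)
  shift <- c(4, -2, 9)
  moved <- ens
  for (m in seq_len(nFrames(ens)))
    moved@coords[, , m] <- ens@coords[, , m] %*% t(R) +
      matrix(shift, nrow(atoms(ens)), 3, byrow = TRUE)
  expect_equal(rmsf(moved)$rmsf, base, tolerance = 1e-9)
})

test_that("d_z displacement: zero baseline, translation covariance, COM math", {
  g <- generateHingedMultimer(nChains = 4L, helixLengths = c(8L, 8L),
                              nFrames = 1L, seed = 4)
  snap <- getSnapshot(g$ensemble, 1)
  ann <- g$annotation
  base <- dzDisplacement(snap, ann)
  ## translate the CL group of every chain down by 2.3 A -> every dz + 2.3
  at <- atoms(snap)
  cl <- region(ann, "CL")
  moved <- snap
  sel <- at$resid %in% cl
  moved@coords[sel, 3] <- snap@coords[sel, 3] - 2.3
  expect_equal(dzDisplacement(moved, ann), base + 2.3, tolerance = 1e-9)
  ## x/y translations leave dz unchanged
  movedXY <- snap
  movedXY@coords[sel, 1:2] <- snap@coords[sel, 1:2] + 11
  expect_equal(dzDisplacement(movedXY, ann), base, tolerance = 1e-9)
  ## hand-computed mass-weighted difference for one chain
  s6tail <- tail(sort(region(ann, "S6")), 4L)
  m <- cnaflex:::.MASSES
  ixA <- which(at$chain == "A" & at$resid %in% s6tail & at$heavy)
  prev <- precedingChain(ann, "A")
  ixB <- which(at$chain == prev & at$resid %in% cl & at$heavy)
  zc <- function(ix) sum(m[at$element[ix]] * snap@coords[ix, 3]) /
    sum(m[at$element[ix]])
  expect_equal(unname(base["A"]), zc(ixA) - zc(ixB), tolerance = 1e-12)
  ## all atoms at identical z -> dz = 0
  flat <- snap
  flat@coords[, 3] <- 5
  expect_equal(unname(dzDisplacement(flat, ann)), rep(0, 4), tolerance = 1e-12)
})

test_that("kink angle recovers constructed geometries", {
  rangeA <- 1:12; rangeB <- 16:27
  expect_lt(abs(kinkAngle(bentHelixSnapshot(0), rangeA, rangeB)), 1)
  expect_lt(abs(kinkAngle(bentHelixSnapshot(90), rangeA, rangeB) - 90), 1)
  for (seed in 1:5) {
    got30 <- kinkAngle(bentHelixSnapshot(30, noise = 0.1, seed = seed),
                       rangeA, rangeB)
    expect_lt(abs(got30 - 30), 2)
  }
})

test_that("kink angle is rotation invariant and symmetric in its ranges", {
  snap <- bentHelixSnapshot(35, noise = 0.05, seed = 7)
  a <- kinkAngle(snap, 1:12, 16:27)
  rot <- snap
  R <- cnaflex:::.rotationMatrix(c(1, 2, -1), 141)
  rot@coords <- snap@coords %*% t(R) + matrix(c(3, -8, 2), nrow(snap@coords),
                                              3, byrow = TRUE)
  expect_equal(kinkAngle(rot, 1:12, 16:27), a, tolerance = 1e-6)
  ## swapping ranges flips both N->C orientations, preserving the angle
  expect_equal(kinkAngle(snap, 16:27, 1:12), a, tolerance = 1e-6)
  expect_error(kinkAngle(snap, 1:3, 16:27), ">= 6")
})

test_that("contact counts: trivial cases and exhaustive enumeration", {
  far <- pointCloudSnapshot(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(countContacts(far, 0L, 1L), 0L)
  near <- pointCloudSnapshot(rbind(c(0, 0, 0), c(4.0, 0, 0)))
  expect_equal(countContacts(near, 0L, 1L), 1L)
  expect_error(countContacts(near, 0:1, 1L), "disjoint")

  set.seed(16)
  coords <- matrix(rnorm(60, sd = 4), 20, 3)
  snap <- pointCloudSnapshot(coords)
  ga <- 0:9; gb <- 10:19
  got <- countContacts(snap, ga, gb, cutoff = 4.5)
  want <- 0L
  for (i in 1:10) for (j in 11:20)
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 4.5) want <- want + 1L
  expect_equal(got, want)
  ## monotone in the cutoff
  cuts <- c(2, 4.5, 6, 9)
  counts <- vapply(cuts, function(cc) countContacts(snap, ga, gb, cc),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("secondary structure: canonical helix, extended chain, beta sheet", {
  lab <- suppressWarnings(assignSecondaryStructure(helixSnapshot(12L)))
  expect_true(all(lab[3:10] == "H"))
  ext <- helixSnapshot(10L, phi = rep(-139, 10), psi = rep(135, 10))
  labE <- suppressWarnings(assignSecondaryStructure(ext))
  expect_false(any(labE %in% c("H", "E")))

  sheet <- betaSheetSnapshot(8L)
  labS <- suppressWarnings(assignSecondaryStructure(sheet))
  ## hand-traced ladder: interior residues of both strands pair up
  expect_true(all(labS[c(3:6, 11:14)] == "E"))
  expect_false(any(labS == "H"))
})

test_that("beta-sheet labels match the hand-traced hydrogen-bond ladder", {
  sheet <- betaSheetSnapshot(8L)
  frames <- cnaflex:::.backboneFrames(sheet)
  E <- cnaflex:::.ksEnergies(frames)
  hb <- !is.na(E) & E < -0.5
  ## antiparallel bridges (i, j): HB(i,j) & HB(j,i) or the offset form
  n <- length(frames)
  bridged <- logical(n)
  for (i in 1:n) for (j in 1:n) {
    if (abs(i - j) < 3) next
    anti1 <- hb[i, j] && hb[j, i]
    anti2 <- (i > 1 && j < n && hb[i - 1, j + 1]) &&
             (j > 1 && i < n && hb[j - 1, i + 1])
    if (anti1 || anti2) { bridged[i] <- TRUE; bridged[j] <- TRUE }
  }
  labS <- suppressWarnings(assignSecondaryStructure(sheet))
  expect_equal(labS == "E", bridged)
})

test_that("secondary-structure content reduces to planted fractions", {
  snap <- helixSnapshot(12L)
  n <- nrow(coords(snap))
  arr <- array(rep(coords(snap), 3), c(n, 3, 3))
  ens <- cnaflex:::.makeEnsemble(snap, arr)
  lab <- suppressWarnings(assignSecondaryStructure(snap))
  helixRes <- which(lab == "H") - 1L
  coilRes <- setdiff(0:11, helixRes)
  expect_equal(unname(suppressWarnings(
    ssContent(ens, helixRes))["fraction"]), 1.0)
  expect_equal(unname(suppressWarnings(
    ssContent(ens, coilRes))["fraction"]), 0.0)
  ## mixed region with a known planted composition
  mix <- c(helixRes[1:3], coilRes[1])
  expect_equal(unname(suppressWarnings(ssContent(ens, mix))["fraction"]),
               0.75)
  expect_error(ssContent(ens, integer(0)), "non-empty")
})
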