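test_that("Boltzmann fit recovers noiseless generator parameters", {
  cur <- generateActivationCurve(vHalf = -119.6, zDelta = 3.2,
                                 relImaxSatV = 0.95, noiseSd = 0, seed = 1)
  f <- fitBoltzmann(cur$V, cur$relI)
  expect_equal(f$vHalf, -119.6, tolerance = 0.01)
  expect_equal(f$zDelta, 3.2, tolerance = 1e-3)
  expect_equal(f$relImaxSatV, 0.95, tolerance = 1e-3)
  ## midpoint identity of the returned fit
  mid <- boltzmannModel(f$vHalf, f$vHalf, f$zDelta, f$relImaxSatV)
  expect_equal(mid, 0.5 * f$relImaxSatV, tolerance = 1e-9)
})

test_that("Boltzmann fit is scale covariant and guards its preconditions", {
  cur <- generateActivationCurve(noiseSd = 0, seed = 2)
  f1 <- fitBoltzmann(cur$V, cur$relI)
  f2 <- fitBoltzmann(cur$V, 2 * cur$relI)
  expect_equal(f2$vHalf, f1$vHalf, tolerance = 1e-6)
  expect_equal(f2$zDelta, f1$zDelta, tolerance = 1e-6)
  expect_equal(f2$relImaxSatV, 2 * f1$relImaxSatV, tolerance = 1e-6)
  flat <- cur[cur$relI > 0.9, ]
  expect_error(fitBoltzmann(flat$V, flat$relI))
})

test_that("per-recording fitting averages parameters with SEMs", {
  recs <- lapply(1:5, function(s) {
    cur <- generateActivationCurve(noiseSd = 0.02, seed = s)
    data.frame(V = cur$V, relI = cur$relI)
  })
  set_ <- fitBoltzmannSet(recs)
  expect_equal(nrow(set_$summary), 3L)
  vh <- vapply(set_$fits, function(f) f$vHalf, numeric(1))
  expect_equal(set_$summary$mean[set_$summary$parameter == "vHalf"], mean(vh))
  expect_equal(set_$summary$sem[set_$summary$parameter == "vHalf"],
               sd(vh) / sqrt(5))
})

test_that("exponential fit recovers tau and flags degenerate traces", {
  tr <- generateActivationTrace(tau = 120, delay = 20, noiseSd = 0, seed = 3)
  f <- fitActivationExponential(tr$t, tr$I)
  expect_equal(f$tau, 120, tolerance = 0.1)
  expect_equal(f$delayUsed, 20, tolerance = 1.5)
  flat <- data.frame(t = 0:100, I = rep(2.5, 101))
  expect_error(fitActivationExponential(flat$t, flat$I), "steady state")
  ## scale covariance: rescaling I rescales A, leaves tau
  f2 <- fitActivationExponential(tr$t, 3 * tr$I)
  expect_equal(f2$tau, f$tau, tolerance = 1e-6)
  expect_equal(f2$A, 3 * f$A, tolerance = 1e-6)
})

test_that("exponential residuals match a grid+polish oracle", {
  tr <- generateActivationTrace(tau = 80, delay = 10, noiseSd = 0.01,
                                seed = 4)
  f <- fitActivationExponential(tr$t, tr$I, delay = 10)
  ## oracle: tau grid, linear LS for (Iinf, A) at each tau, then polish
  sel <- tr$t >= 10
  ts <- tr$t[sel]; Is <- tr$I[sel]
  rssOf <- function(tau) {
    basis <- exp(-(ts - 10) / tau)
    fit <- lm.fit(cbind(1, basis), Is)
    sum(fit$residuals^2)
  }
  coarse <- vapply(seq(5, 400, by = 2.5), rssOf, numeric(1))
  tau0 <- seq(5, 400, by = 2.5)[which.min(coarse)]
  opt <- optimize(rssOf, c(tau0 - 5, tau0 + 5))
  expect_equal(f$residualNorm^2, opt$objective, tolerance = 1e-6)
})

test_that("Hill fit: half-maximum identity and exact noiseless recovery", {
  bc <- generateBindingCurve(bc50 = 0.51, hB = 1.4, noiseSd = 0, seed = 5)
  f <- fitHill(bc$x, bc$relF)
  expect_equal(f$bc50, 0.51, tolerance = 1e-6)
  expect_equal(f$hB, 1.4, tolerance = 1e-6)
  expect_equal(hillModel(f$bc50, f$bc50, f$hB), 0.5, tolerance = 1e-9)
  expect_error(fitHill(bc$x, rep(0.99, nrow(bc))), "saturated")
  expect_error(fitHill(bc$x, rep(0.01, nrow(bc))), "all-zero")
})

test_that("bound-fluorescence extraction removes the free-dye signal", {
  ## free dye only: bound signal vanishes
  img0 <- generateBindingImage(boundAmplitude = 0, k = 1.8, noiseSd = 0,
                               seed = 6)
  ex0 <- extractBoundFluorescence(img0$green, img0$red, img0$bathMask,
                                  img0$patchMask, img0$borderMask)
  expect_lt(abs(ex0$F), 1e-9)
  ## planted amplitude recovered within 1 percent
  img <- generateBindingImage(boundAmplitude = 0.8, k = 2.3, noiseSd = 0,
                              seed = 7)
  ex <- extractBoundFluorescence(img$green, img$red, img$bathMask,
                                 img$patchMask, img$borderMask)
  expect_equal(ex$F, 0.8, tolerance = 0.01)
  ## channel offsets are removed via the border estimate
  imgOff <- generateBindingImage(boundAmplitude = 0.8, k = 2.3, noiseSd = 0,
                                 offsets = c(green = 7, red = 4), seed = 7)
  exOff <- extractBoundFluorescence(imgOff$green, imgOff$red, imgOff$bathMask,
                                    imgOff$patchMask, imgOff$borderMask)
  expect_equal(exOff$F, 0.8, tolerance = 0.01)
  expect_error(extractBoundFluorescence(img$green, img$red,
                                        img$bathMask, img$bathMask),
               "disjoint")
})

test_that("gain changes cancel in F/F_max normalisation", {
  mk <- function(gain) {
    img <- generateBindingImage(boundAmplitude = 0.5, k = 2, noiseSd = 0,
                                seed = 8)
    sat <- generateBindingImage(boundAmplitude = 1.5, k = 2, noiseSd = 0,
                                seed = 9)
    boundFluorescenceSeries(
      greenFrames = list(gain * img$green, gain * sat$green),
      redFrames = list(gain * img$red, gain * sat$red),
      bathMask = img$bathMask, patchMask = img$patchMask,
      referenceFrames = 2L, borderMask = img$borderMask)
  }
  expect_equal(mk(1)$relF, mk(2)$relF, tolerance = 1e-9)
})

test_that("grand mean/SEM performs two-level averaging", {
  vals <- as.numeric(outer(1:4, 1:5))        # subunit x run grid
  sub <- rep(1:4, 5); run <- rep(1:5, each = 4)
  gm <- grandMeanSem(vals, sub, run)
  runMeans <- tapply(vals, run, mean)
  expect_equal(unname(gm["mean"]), mean(runMeans))
  expect_equal(unname(gm["sem"]), sd(runMeans) / sqrt(5))
  ## identical values: SEM 0
  expect_equal(unname(grandMeanSem(rep(3, 20), sub, run)["sem"]), 0)
  ## permuting subunits within runs changes nothing
  perm <- unlist(lapply(split(seq_along(vals), run), sample))
  gm2 <- grandMeanSem(vals[perm], sub, run)  # same run structure
  expect_equal(gm2["mean"], gm["mean"])
  ## single run: SEM undefined
  expect_true(is.na(grandMeanSem(1:4, 1:4, rep(1, 4))["sem"]))
})

test_that("unpaired Welch test: edge cases and textbook agreement", {
  expect_equal(unname(unpairedT(rep(2, 5), rep(2, 5))["p"]), 1)
  a <- c(12.1, 11.8, 12.4, 12.0, 11.9)
  b <- c(10.9, 11.2, 11.0, 11.4, 11.1)
  got <- unpairedT(a, b)
  s2a <- var(a) / 5; s2b <- var(b) / 5
  tWant <- (mean(a) - mean(b)) / sqrt(s2a + s2b)
  dfW <- (s2a + s2b)^2 / (s2a^2 / 4 + s2b^2 / 4)
  expect_equal(unname(got["t"]), tWant, tolerance = 1e-9)
  expect_equal(unname(got["p"]), 2 * pt(-abs(tWant), dfW), tolerance = 1e-9)
  expect_error(unpairedT(1, 1:3), ">= 2")
})
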