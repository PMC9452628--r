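## Parametric fits of gating and binding data: the Boltzmann steady-state
## activation relation, single-exponential activation kinetics, and the Hill
## binding curve. All fits are Levenberg-Marquardt nonlinear least squares
## (minpack.lm::nlsLM) with robust automatic starting values.

#' Physical constants used by the Boltzmann relation
#'
#' @param temperature temperature in Kelvin (default 295, room temperature).
#' @return list with F (C/mol), R (J/(mol K)) and T (K).
#' @export
physicalConstants <- function(temperature = 295) {
  list(F = 96485, R = 8.314, T = temperature)
}

#' Boltzmann steady-state activation model
#'
#' rel_I(V) = relImaxSatV / (1 + exp(zDelta * F * (V - vHalf) / (R * T))),
#' with V and vHalf in mV. For hyperpolarisation-activated channels
#' (zDelta > 0) the relative current saturates at strongly negative voltages.
#'
#' @param V voltage, mV.
#' @param vHalf half-maximum activation voltage, mV.
#' @param zDelta effective gating charge.
#' @param relImaxSatV relative current at saturating voltage.
#' @param constants see \code{\link{physicalConstants}}.
#' @export
boltzmannModel <- function(V, vHalf, zDelta, relImaxSatV = 1,
                           constants = physicalConstants()) {
  relImaxSatV / (1 + exp(zDelta * constants$F * (V - vHalf) * 1e-3 /
                           (constants$R * constants$T)))
}

#' Fit the Boltzmann activation relation to one recording
#'
#' @param V voltage vector, mV.
#' @param relI relative current vector (same length, >= 4 points spanning at
#'   least 0.3 of the full range).
#' @param constants see \code{\link{physicalConstants}}.
#' @param start optional named list overriding the automatic starting values.
#' @return list of class \code{"boltzmannFit"}: estimates vHalf (mV), zDelta,
#'   relImaxSatV, their standard errors, and the residual norm.
#' @export
fitBoltzmann <- function(V, relI, constants = physicalConstants(),
                         start = NULL) {
  stopifnot(length(V) == length(relI))
  if (length(V) < 4L) stop("need >= 4 points to fit")
  if (max(relI) - min(relI) < 0.3)
    stop("curve does not span its midpoint (range < 0.3)")
  half <- (max(relI) + min(relI)) / 2
  s <- list(vHalf = V[which.min(abs(relI - half))], zDelta = 4,
            relImaxSatV = max(relI))
  s[names(start)] <- start
  df <- data.frame(V = V, relI = relI)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      relI ~ boltzmannModel(V, vHalf, zDelta, relImaxSatV, constants),
      data = df, start = s,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(vHalf = unname(cf["vHalf"]), zDelta = unname(cf["zDelta"]),
                 relImaxSatV = unname(cf["relImaxSatV"]),
                 se = se, residualNorm = sqrt(sum(residuals(fit)^2)),
                 constants = constants, fit = fit),
            class = "boltzmannFit")
}

#' Fit Boltzmann relations per recording and summarise
#'
#' Recordings are fitted individually and the parameter estimates averaged
#' (mean +/- SEM), matching the per-recording convention of patch-clamp
#' steady-state analyses.
#'
#' @param recordings list of data.frames with columns V, relI.
#' @param constants see \code{\link{physicalConstants}}.
#' @return list with per-recording fits and a summary data.frame.
#' @export
fitBoltzmannSet <- function(recordings, constants = physicalConstants()) {
  fits <- lapply(recordings, function(r)
    fitBoltzmann(r$V, r$relI, constants))
  par <- vapply(fits, function(f)
    c(f$vHalf, f$zDelta, f$relImaxSatV), numeric(3))
  summ <- data.frame(
    parameter = c("vHalf", "zDelta", "relImaxSatV"),
    mean = rowMeans(par),
    sem = apply(par, 1, sd) / sqrt(ncol(par)))
  list(fits = fits, summary = summ)
}

#' Estimate the activation delay of a current trace
#'
#' The latest time before the absolute slope first exceeds
#' \code{fraction} of its maximum.
#'
#' @param t time vector, ms (strictly increasing).
#' @param I current vector.
#' @param fraction slope threshold fraction (default 0.1).
#' @export
estimateDelay <- function(t, I, fraction = 0.1) {
  s <- abs(diff(I) / diff(t))
  k <- which(s > fraction * max(s))[1]
  if (is.na(k) || k == 1L) t[1] else t[k]
}

#' Fit a single-exponential activation time course
#'
#' Activation currents relax towards a steady state, so the fitted model is
#' I(t) = Iinf - A * exp(-(t - delay)/tau) for t >= delay; tau is the same
#' relaxation constant as in the decaying-exponential parameterisation.
#'
#' @param t time vector, ms (strictly increasing).
#' @param I current vector (arbitrary scale).
#' @param delay fit-window start, ms; estimated from the slope threshold when
#'   NULL (see \code{\link{estimateDelay}}).
#' @return list of class \code{"expFit"}: tau (ms), A, Iinf, delayUsed,
#'   standard errors.
#' @export
fitActivationExponential <- function(t, I, delay = NULL) {
  stopifnot(length(t) == length(I))
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (is.null(delay)) delay <- estimateDelay(t, I)
  sel <- t >= delay
  if (sum(sel) < 4L) stop("fewer than 4 points after the delay")
  ts <- t[sel]; Is <- I[sel]
  if (max(Is) - min(Is) < 1e-9 * max(abs(Is), 1))
    stop("trace already at steady state: tau unidentifiable")
  ## 1/e-crossing initial tau
  Iinf0 <- Is[length(Is)]; A0 <- Iinf0 - Is[1]
  target <- Iinf0 - A0 / exp(1)
  k <- which(if (A0 > 0) Is >= target else Is <= target)[1]
  tau0 <- max(ts[ifelse(is.na(k), length(ts), k)] - delay, diff(range(ts)) / 10)
  df <- data.frame(ts = ts, Is = Is)
  fit <- tryCatch(
    minpack.lm::nlsLM(Is ~ Iinf - A * exp(-(ts - delay) / tau), data = df,
                      start = list(Iinf = Iinf0, A = A0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(tau = unname(cf["tau"]), A = unname(cf["A"]),
                 Iinf = unname(cf["Iinf"]), delayUsed = delay, se = se,
                 residualNorm = sqrt(sum(residuals(fit)^2)), fit = fit),
            class = "expFit")
}

#' Hill binding model
#'
#' relF(x) = 1 / (1 + (bc50 / x)^hB); relF(bc50) = 0.5.
#' @param x ligand concentration, uM.
#' @param bc50 concentration of half-maximum binding, uM.
#' @param hB Hill coefficient.
#' @export
hillModel <- function(x, bc50, hB) 1 / (1 + (bc50 / x)^hB)

#' Fit the Hill equation to a concentration-binding curve
#'
#' @param x concentration vector, uM (> 0, >= 4 values spanning bc50).
#' @param relF normalised fluorescence (bound fraction) vector.
#' @param start optional named list of starting values.
#' @return list of class \code{"hillFit"}: bc50 (uM), hB, standard errors.
#' @export
fitHill <- function(x, relF, start = NULL) {
  stopifnot(length(x) == length(relF), all(x > 0))
  if (length(x) < 4L) stop("need >= 4 concentrations")
  if (all(relF > 0.9)) stop("all-saturated data: bc50 not identifiable")
  if (all(relF < 0.1)) stop("all-zero data: bc50 not identifiable")
  ## interpolated half-maximum as bc50 start
  o <- order(x)
  bc0 <- tryCatch(approx(relF[o], x[o], xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(bc0)) bc0 <- exp(mean(log(x)))
  s <- list(bc50 = bc0, hB = 1.5)
  s[names(start)] <- start
  df <- data.frame(x = x, relF = relF)
  fit <- tryCatch(
    minpack.lm::nlsLM(relF ~ hillModel(x, bc50, hB), data = df, start = s,
                      lower = c(1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(bc50 = unname(cf["bc50"]), hB = unname(cf["hB"]), se = se,
                 residualNorm = sqrt(sum(residuals(fit)^2)), fit = fit),
            class = "hillFit")
}

#' @export
print.boltzmannFit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: vHalf = %.2f mV, zDelta = %.3f, plateau = %.3f\n",
              x$vHalf, x$zDelta, x$relImaxSatV))
  invisible(x)
}

#' @export
print.expFit <- function(x, ...) {
  cat(sprintf("Exponential fit: tau = %.2f ms (delay %.2f ms), A = %.3g\n",
              x$tau, x$delayUsed, x$A))
  invisible(x)
}

#' @export
print.hillFit <- function(x, ...) {
  cat(sprintf("Hill fit: bc50 = %.3f uM, hB = %.2f\n", x$bc50, x$hB))
  invisible(x)
}
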