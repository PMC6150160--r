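## Release-kinetics module: the four classical empirical release laws,
## least-squares fitting, R^2-based model selection, and assay-calibration
## helpers.
##
## Convention: time in hours; release expressed as percent of the drug load
## when constants are reported (so K0 is percent/hour, KH percent/sqrt(h),
## KP percent/h^n). The first-order constant K1 (per hour) sits inside an
## exponential and does not depend on the release scale.

.checkConstants <- function(model, constants) {
  if (!(length(model) == 1 && model %in% .kineticModels))
    .invalidArg(sprintf("unknown kinetic model '%s'; expected one of %s",
                        paste(model, collapse = ","),
                        paste(.kineticModels, collapse = ", ")))
  want <- .modelParams[[model]]
  got <- names(constants)
  if (is.null(got) || !setequal(got, want) || length(constants) != length(want))
    .invalidArg(sprintf("model '%s' requires exactly constants {%s}, got {%s}",
                        model, paste(want, collapse = ", "),
                        paste(got, collapse = ", ")))
  rates <- constants[setdiff(want, "n")]
  if (any(!is.finite(rates)) || any(rates <= 0))
    .invalidArg("rate constants must be positive and finite")
  if ("n" %in% want) {
    n <- constants[["n"]]
    if (!is.finite(n) || n <= 0 || n > 2)
      .invalidArg("release exponent n must lie in (0, 2]")
  }
  invisible(constants[want])
}

## Model formulas on the percent scale.
.releaseFun <- list(
  zero_order       = function(k, t) k[["K0"]] * t,
  first_order      = function(k, t) 100 * (1 - exp(-k[["K1"]] * t)),
  higuchi          = function(k, t) k[["KH"]] * sqrt(t),
  korsmeyer_peppas = function(k, t) k[["KP"]] * t^k[["n"]]
)

#' Predict cumulative release under a kinetic model
#'
#' Evaluates one of the four release laws at the given times: zero-order
#' `F = K0 t`, first-order `F = 100 (1 - e^(-K1 t))`, Higuchi
#' `F = KH sqrt(t)`, Korsmeyer-Peppas `F = KP t^n`. Release is returned in
#' percent of load, time is in hours, matching the convention under which
#' fitted constants are reported. All four laws pass through the origin, and
#' the first-order prediction stays below 100 for finite time.
#'
#' @param model one of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @param constants named numeric vector with exactly the model's parameters
#'   (`K0`, `K1`, `KH`, or `KP` and `n`); rates must be positive, `n` in
#'   `(0, 2]`.
#' @param t time in hours, non-negative.
#' @return Predicted cumulative release, percent of load.
#' @examples
#' predictRelease("zero_order", c(K0 = 0.246), t = 10)       # 2.46
#' predictRelease("korsmeyer_peppas", c(KP = 1.192, n = 0.650), t = 1)
#' @export
predictRelease <- function(model, constants, t) {
  k <- .checkConstants(model, constants)
  if (any(!is.finite(t)) || any(t < 0))
    .invalidArg("time must be finite and non-negative")
  unname(.releaseFun[[model]](k, t))
}

#' Determination coefficient of a fit
#'
#' `R^2 = 1 - SS_res / SS_tot`, at most 1, possibly negative for a model
#' worse than the mean.
#'
#' @param observed numeric vector of observations.
#' @param predicted numeric vector of model predictions, same length.
#' @return The determination coefficient.
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 3))   # 1
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    .invalidArg("observed and predicted must have equal length")
  if (length(observed) < 2)
    .invalidArg("at least 2 points are required")
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0)
    .invalidArg("zero total sum of squares: observed values are all identical")
  1 - sum((observed - predicted)^2) / ssTot
}

## Closed-form initializers from linearizations; used to start the nonlinear
## optimizer (and as multi-start perturbation centres).
.initFirstOrder <- function(t, y) {
  ok <- t > 0 & y > 0 & y < 100
  if (!any(ok)) return(0.1)
  k <- mean(-log(1 - y[ok] / 100) / t[ok])
  if (!is.finite(k) || k <= 0) 0.1 else k
}

.initKorsmeyerPeppas <- function(t, y) {
  ok <- t > 0 & y > 0
  if (sum(ok) < 2) return(c(KP = max(y, 1e-3), n = 0.5))
  fit <- stats::lm(log(y[ok]) ~ log(t[ok]))
  n0 <- min(max(unname(stats::coef(fit)[2]), 1e-3), 2)
  kp0 <- exp(unname(stats::coef(fit)[1]))
  if (!is.finite(kp0) || kp0 <= 0) kp0 <- max(y) / max(t)^n0
  c(KP = kp0, n = n0)
}

.nlsOnce <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Fit one kinetic model to a dissolution profile
#'
#' Least squares on the untransformed release scale. Zero-order and Higuchi
#' are through-origin linear regressions on `t` and `sqrt(t)`; first-order
#' and Korsmeyer-Peppas are bounded nonlinear least squares
#' (Levenberg-Marquardt) started from log-linear / log-log closed-form
#' estimates, with two additional deterministic perturbed restarts before a
#' non-convergence failure is declared. The reported R-squared is always
#' computed on the untransformed release scale so that models are compared
#' like-for-like.
#'
#' @param profile a [DissolutionProfile-class], or the time vector in hours
#'   when `released` is given.
#' @param model a kinetic model identifier.
#' @param released optional release values in percent of load (used with a
#'   numeric `profile` time vector; mainly for data already on the percent
#'   scale).
#' @return A [KineticFit-class] with constants on the percent/hour
#'   convention.
#' @examples
#' p <- simulateDissolution("higuchi", c(KH = 2.3), times = 1:12)
#' fitKineticModel(p, "higuchi")
#' @export
fitKineticModel <- function(profile, model, released = NULL) {
  if (is(profile, "DissolutionProfile")) {
    t <- profile@times
    y <- 100 * profile@released            # fit on the percent scale
  } else {
    t <- as.numeric(profile)
    y <- as.numeric(released)
    if (length(t) != length(y))
      .invalidArg("times and released values must have equal length")
  }
  if (!(length(model) == 1 && model %in% .kineticModels))
    .invalidArg(sprintf("unknown kinetic model '%s'", model))
  if (length(unique(t)) < 3)
    .invalidArg("at least 3 distinct time points are required")
  p <- .modelNParams[[model]]
  if (length(t) < p + 1)
    .invalidArg(sprintf("model '%s' needs at least %d points", model, p + 1))
  if (length(unique(y)) == 1)
    .fitFailure("degenerate profile: all release values are identical")

  if (model == "zero_order" || model == "higuchi") {
    x <- if (model == "zero_order") t else sqrt(t)
    k <- unname(stats::coef(stats::lm(y ~ 0 + x)))
    if (!is.finite(k) || k <= 0)
      .fitFailure(sprintf("'%s' fit produced a non-positive rate constant (%.3g)",
                          model, k))
    est <- stats::setNames(k, .modelParams[[model]])
  } else if (model == "first_order") {
    k0 <- .initFirstOrder(t, y)
    fit <- NULL
    for (mult in c(1, 0.5, 2)) {           # deterministic multi-start
      fit <- .nlsOnce(y ~ 100 * (1 - exp(-K1 * t)),
                      data = data.frame(t = t, y = y),
                      start = list(K1 = k0 * mult),
                      lower = 1e-12, upper = Inf)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      .fitFailure("first-order fit did not converge after 3 restarts")
    est <- c(K1 = unname(stats::coef(fit)[["K1"]]))
    if (est[["K1"]] <= 0)
      .fitFailure("first-order fit produced a non-positive rate constant")
  } else {                                  # korsmeyer_peppas
    s0 <- .initKorsmeyerPeppas(t, y)
    fit <- NULL
    for (mult in c(1, 0.5, 2)) {
      start <- list(KP = s0[["KP"]] * mult,
                    n = min(max(s0[["n"]] * mult, 0.05), 2))
      fit <- .nlsOnce(y ~ KP * t^n, data = data.frame(t = t, y = y),
                      start = start,
                      lower = c(1e-12, 1e-9), upper = c(Inf, 2))
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      .fitFailure("Korsmeyer-Peppas fit did not converge after 3 restarts")
    cf <- stats::coef(fit)
    est <- c(KP = unname(cf[["KP"]]), n = unname(cf[["n"]]))
    if (est[["KP"]] <= 0 || est[["n"]] <= 0 || est[["n"]] > 2)
      .fitFailure("Korsmeyer-Peppas fit left the admissible parameter region")
  }

  pred <- .releaseFun[[model]](est, t)
  new("KineticFit", model = model, constants = est,
      rSquared = rSquared(y, pred), residuals = y - pred, fitted = pred)
}

#' Fit all four release models to a profile
#'
#' Convenience wrapper returning one [KineticFit-class] per model; models
#' whose fit fails are dropped with a warning.
#'
#' @param profile a [DissolutionProfile-class].
#' @param models model identifiers to fit (default: all four).
#' @return A named list of [KineticFit-class] objects.
#' @export
fitAllModels <- function(profile, models = .kineticModels) {
  bad <- setdiff(models, .kineticModels)
  if (length(bad))
    .invalidArg(paste("unknown kinetic model(s):", paste(bad, collapse = ", ")))
  fits <- list()
  for (m in models) {
    f <- tryCatch(fitKineticModel(profile, m), error = function(e) {
      warning(sprintf("model '%s' failed to fit: %s", m, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[m]] <- f
  }
  fits
}

#' Select the best-fitting release model
#'
#' The winner is the fit with the maximal determination coefficient; exact
#' ties go to the model with fewer parameters (and then to the fixed model
#' order zero-order, first-order, Higuchi, Korsmeyer-Peppas, so selection is
#' deterministic).
#'
#' @param fits a list of at least two [KineticFit-class] objects with
#'   distinct models.
#' @return A [ModelSelection-class].
#' @examples
#' p <- simulateDissolution("korsmeyer_peppas", c(KP = 1.192, n = 0.65),
#'                          times = 1:12)
#' selectModel(fitAllModels(p))
#' @export
selectModel <- function(fits) {
  if (length(fits) < 2)
    .invalidArg("model selection needs at least 2 candidate fits")
  if (!all(vapply(fits, is, logical(1), class2 = "KineticFit")))
    .invalidArg("'fits' must be a list of KineticFit objects")
  ids <- vapply(fits, modelId, character(1))
  if (anyDuplicated(ids))
    .invalidArg("candidate fits must have distinct models")
  r2 <- vapply(fits, rSquaredValue, numeric(1))
  np <- .modelNParams[ids]
  ord <- order(-r2, np, match(ids, .kineticModels))
  new("ModelSelection", fits = unname(fits), best = unname(ids[ord[1]]),
      criterion = "max R²")
}

## ---- assay calibration ----------------------------------------------------

#' Fit a linear assay calibration line
#'
#' Ordinary least squares of response on concentration; `sigma` is the
#' residual standard deviation, used for detection limits.
#'
#' @param concentration known standard concentrations.
#' @param response measured assay responses (e.g. peak areas).
#' @return A [CalibrationLine-class].
#' @export
fitCalibration <- function(concentration, response) {
  if (length(concentration) != length(response) || length(response) < 3)
    .invalidArg("calibration needs >= 3 matched concentration/response pairs")
  fit <- stats::lm(response ~ concentration)
  cf <- stats::coef(fit)
  if (cf[["concentration"]] <= 0)
    .invalidArg("calibration slope must be positive for a valid assay")
  new("CalibrationLine", slope = unname(cf[["concentration"]]),
      intercept = unname(cf[["(Intercept)"]]),
      rSquared = summary(fit)$r.squared,
      sigma = stats::sigma(fit))
}

#' Detection and quantification limits of an assay
#'
#' ICH convention: `LOD = 3.3 sigma / S`, `LOQ = 10 sigma / S`, where
#' `sigma` is the residual (or blank) standard deviation of the response and
#' `S` the calibration slope. The LOQ/LOD ratio is always 10/3.3.
#'
#' @param sigma response standard deviation, >= 0, or a
#'   [CalibrationLine-class] (in which case `slope` is ignored).
#' @param slope calibration slope, > 0.
#' @return Named numeric `c(lod = ..., loq = ...)` in concentration units.
#' @examples
#' lodLoq(sigma = 1, slope = 10)   # lod 0.33, loq 1.0
#' @export
lodLoq <- function(sigma, slope = NULL) {
  if (is(sigma, "CalibrationLine")) {
    slope <- sigma@slope
    sigma <- sigma@sigma
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    .invalidArg("'sigma' must be a single non-negative value")
  if (!is.numeric(slope) || length(slope) != 1 || slope <= 0)
    .invalidArg("'slope' must be a single positive value")
  c(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}
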