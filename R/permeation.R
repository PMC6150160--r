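## Permeation module: steady-state flux from cumulative permeation series and
## the permeability coefficient Kp = J / (C * A).

## Least-squares slope/intercept/R^2 over a window of a cumulative series.
.windowFit <- function(t, y) {
  fit <- stats::lm(y ~ t)
  cf <- stats::coef(fit)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / ssTot
  list(slope = unname(cf[["t"]]), intercept = unname(cf[["(Intercept)"]]),
       r2 = r2)
}

#' Steady-state flux of a permeation series
#'
#' Fits a straight line to the linear late phase of cumulative permeated
#' amount per area versus time. When no window is given, the longest
#' trailing window (ending at the last point, at least 3 points) whose
#' linear fit reaches `R^2 >= rsqMin` is used; if none qualifies, the
#' trailing half of the series is used. The lag time is the x-intercept of
#' the steady-state line, clamped at zero. A zero or negative slope yields a
#' flagged result and no permeability coefficient downstream.
#'
#' @param series a [PermeationSeries-class] with at least 4 points.
#' @param window optional integer indices of the points to use (>= 3).
#' @param rsqMin R-squared gate for automatic window selection (default
#'   0.99).
#' @return A list with `slope` (ug/cm^2/h), `intercept`, `lagTime` (h),
#'   `window` (integer indices), `r2` and `flagged`.
#' @examples
#' s <- simulatePermeation(slope = 5, lag = 1, times = 0:12,
#'                         donorConcentration = 4000)
#' steadyStateFlux(s)
#' @export
steadyStateFlux <- function(series, window = NULL, rsqMin = 0.99) {
  if (!is(series, "PermeationSeries"))
    .invalidArg("'series' must be a PermeationSeries")
  t <- series@times
  y <- series@cumulative
  n <- length(t)
  if (n < 4)
    .invalidArg("steady-state estimation needs at least 4 points")

  if (!is.null(window)) {
    window <- as.integer(window)
    if (any(window < 1 | window > n) || length(window) < 3)
      .invalidArg("window must index >= 3 existing points")
    idx <- sort(unique(window))
  } else {
    ## candidate windows all end at the last point; among those whose linear
    ## fit reaches the R^2 gate, take the best fit, preferring the longest
    ## window on (numerical) ties
    starts <- seq_len(n - 2)
    r2 <- vapply(starts, function(s) {
      f <- .windowFit(t[s:n], y[s:n])
      if (is.finite(f$r2)) f$r2 else -Inf
    }, numeric(1))
    ok <- which(r2 >= rsqMin)
    if (length(ok)) {
      best <- ok[r2[ok] >= max(r2[ok]) - 1e-9]
      idx <- best[1]:n                      # earliest start = longest window
    } else {                                # fall back to the trailing half
      idx <- (n - max(3L, ceiling(n / 2)) + 1L):n
    }
  }

  f <- .windowFit(t[idx], y[idx])
  flagged <- !is.finite(f$slope) || f$slope <= 0
  lag <- if (flagged) 0 else max(0, -f$intercept / f$slope)
  list(slope = if (flagged) 0 else f$slope, intercept = f$intercept,
       lagTime = lag, window = as.integer(idx), r2 = f$r2, flagged = flagged)
}

#' Permeability coefficient
#'
#' `Kp = J / (C * A)` with the permeation rate J in ug/h, the donor
#' concentration C in ug/mL and the contact area A in cm^2, giving Kp in
#' cm/h.
#'
#' @param J permeation rate, ug/h, >= 0.
#' @param C donor-compartment concentration, ug/mL, > 0.
#' @param A contact surface area, cm^2, > 0.
#' @return The permeability coefficient in cm/h.
#' @examples
#' permeabilityCoefficient(J = 100, C = 4000, A = 4.909)
#' @export
permeabilityCoefficient <- function(J, C, A) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    .invalidArg("donor concentration C must be a single positive value")
  if (!is.numeric(A) || length(A) != 1 || A <= 0)
    .invalidArg("contact area A must be a single positive value")
  if (!is.numeric(J) || length(J) != 1 || J < 0)
    .invalidArg("permeation rate J must be a single non-negative value")
  J / (C * A)
}

#' Full permeation analysis of one series
#'
#' Estimates the per-area steady-state flux Jss (ug/cm^2/h) from the series,
#' converts it to the permeation rate `J = Jss * A` (ug/h) and applies
#' `Kp = J / (C * A)` — equivalently `Kp = Jss / C`. Both Jss and J are kept
#' in the result.
#'
#' @inheritParams steadyStateFlux
#' @return A [PermeationResult-class].
#' @export
analyzePermeation <- function(series, window = NULL, rsqMin = 0.99) {
  ss <- steadyStateFlux(series, window = window, rsqMin = rsqMin)
  if (ss$flagged) {
    return(new("PermeationResult", fluxJ = 0, jss = 0, lagTime = 0,
               kp = NA_real_, window = as.integer(ss$window), flagged = TRUE))
  }
  J <- ss$slope * series@contactArea
  kp <- permeabilityCoefficient(J, series@donorConcentration,
                                series@contactArea)
  new("PermeationResult", fluxJ = J, jss = ss$slope, lagTime = ss$lagTime,
      kp = kp, window = as.integer(ss$window), flagged = FALSE)
}
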