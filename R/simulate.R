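## Synthetic-data module: seeded generators for every input the pipeline
## consumes — dissolution curves, permeation series, H-DAB images of known
## zone composition, and group measurement sets.

## Evaluate expr under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a dissolution profile from a kinetic model
#'
#' Evaluates the chosen release law at the given times (constants on the
#' percent/hour convention, see [predictRelease()]), optionally adds
#' seeded Gaussian noise on the fraction scale, and clamps to `[0, 1]`.
#' With `noiseSd = 0` the profile is the exact model curve.
#'
#' @param model a kinetic model identifier.
#' @param constants named constants for the model (percent/hour convention).
#' @param times sampling times in hours, strictly increasing.
#' @param noiseSd additive Gaussian noise standard deviation on the
#'   released-fraction scale (>= 0).
#' @param seed optional integer seed; identical seeds give identical
#'   profiles.
#' @param label profile label.
#' @return A [DissolutionProfile-class].
#' @examples
#' simulateDissolution("korsmeyer_peppas", c(KP = 1.192, n = 0.650),
#'                     times = 1:12)
#' @export
simulateDissolution <- function(model, constants, times, noiseSd = 0,
                                seed = NULL, label = model) {
  if (noiseSd < 0) .invalidArg("'noiseSd' must be >= 0")
  pct <- predictRelease(model, constants, times)
  frac <- pct / 100
  if (noiseSd > 0)
    frac <- frac + .withSeed(seed, stats::rnorm(length(times), 0, noiseSd))
  DissolutionProfile(times, pmin(pmax(frac, 0), 1), label = label)
}

#' Simulate a cumulative permeation series
#'
#' `cumulative(t) = max(0, slope * (t - lag))` plus optional seeded Gaussian
#' noise, floored at zero so cumulative amounts stay non-negative.
#'
#' @param slope steady-state per-area flux, ug/cm^2/h, >= 0.
#' @param lag lag time in hours, >= 0.
#' @param times sampling times in hours.
#' @param noiseSd Gaussian noise SD in ug/cm^2.
#' @param seed optional integer seed.
#' @param donorConcentration donor concentration, ug/mL.
#' @param contactArea contact area, cm^2.
#' @param membrane membrane tag.
#' @return A [PermeationSeries-class].
#' @export
simulatePermeation <- function(slope, lag = 0, times, noiseSd = 0,
                               seed = NULL, donorConcentration,
                               contactArea = 4.909, membrane = "other") {
  if (slope < 0 || lag < 0) .invalidArg("'slope' and 'lag' must be >= 0")
  y <- pmax(0, slope * (times - lag))
  if (noiseSd > 0)
    y <- pmax(0, y + .withSeed(seed, stats::rnorm(length(times), 0, noiseSd)))
  PermeationSeries(times, y, donorConcentration = donorConcentration,
                   contactArea = contactArea, membrane = membrane)
}

## Largest-remainder allocation of n items to fractions (exactly conserves n).
.largestRemainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

## Mid-zone representative DAB intensities used by the image simulator.
.defaultZoneIntensity <- c(high_positive = 30, positive = 90,
                           low_positive = 150, negative = 208,
                           excluded = 245)

#' Simulate an H-DAB image of known zone composition
#'
#' Allocates pixels to the scoring zones by largest-remainder rounding of
#' the requested fractions (any remainder becomes excluded-range pixels),
#' shuffles pixel positions with the seed, assigns each pixel its zone's
#' representative DAB intensity plus a uniform hematoxylin counterstain, and
#' renders the RGB image through the same H-DAB stain matrix that
#' [deconvolveHDAB()] inverts — so the round trip differs only by 8-bit
#' quantization. The analytically expected score is computed from the
#' realized integer counts.
#'
#' @param width,height image size in pixels.
#' @param zoneFractions named fractions over the four scoring zones, summing
#'   to <= 1; the remainder becomes excluded-range pixels.
#' @param dabIntensity representative DAB intensity per zone (must lie
#'   inside each zone's range); defaults to mid-zone values.
#' @param hematoxylinOd uniform counterstain optical density.
#' @param seed optional integer seed for the position shuffle.
#' @return A list: `image` ([RgbImage-class]), `mask` ([PixelMask-class],
#'   full image), `expected` ([IhcScore-class] from realized counts, or NULL
#'   when all pixels are excluded), `counts` (realized per-zone counts).
#' @examples
#' sim <- simulateIhcImage(32, 32, c(positive = 0.5, negative = 0.5),
#'                         seed = 7)
#' sim$expected
#' @export
simulateIhcImage <- function(width, height, zoneFractions,
                             dabIntensity = .defaultZoneIntensity,
                             hematoxylinOd = 0.3, seed = NULL) {
  if (width < 1 || height < 1) .invalidArg("image dimensions must be >= 1")
  scoring <- names(.zoneWeights)
  bad <- setdiff(names(zoneFractions), scoring)
  if (length(bad))
    .invalidArg(paste("unknown zone(s):", paste(bad, collapse = ", ")))
  f <- stats::setNames(numeric(4), scoring)
  f[names(zoneFractions)] <- zoneFractions
  if (any(f < 0) || sum(f) > 1 + 1e-12)
    .invalidArg("zone fractions must be >= 0 and sum to <= 1")
  for (z in names(dabIntensity))
    if (dabIntensity[[z]] < .zoneLower[[z]] ||
        dabIntensity[[z]] > .zoneUpper[[z]])
      .invalidArg(sprintf("representative intensity for '%s' outside its zone range", z))

  npix <- as.integer(width) * as.integer(height)
  counts <- .largestRemainder(c(f, excluded = max(0, 1 - sum(f))), npix)
  names(counts) <- c(scoring, "excluded")

  repInt <- .defaultZoneIntensity
  repInt[names(dabIntensity)] <- dabIntensity
  intensities <- rep(repInt[.zoneNames], counts[.zoneNames])
  pos <- .withSeed(seed, sample.int(npix))
  dabI <- numeric(npix)
  dabI[pos] <- intensities

  dabAmount <- -log10(dabI / 255)
  m <- hdabStainMatrix()
  od <- outer(dabAmount, m["dab", ]) +
    matrix(hematoxylinOd * m["hematoxylin", ], npix, 3, byrow = TRUE)
  img <- array(pmin(pmax(round(255 * 10^(-od)), 0), 255),
               dim = c(height, width, 3))

  included <- npix - counts[["excluded"]]
  expected <- NULL
  if (included > 0) {
    partial <- counts[scoring] * .zoneWeights / included
    expected <- new("IhcScore", partialScores = partial,
                    globalScore = sum(partial), zoneWeights = .zoneWeights,
                    includedTotal = as.integer(included))
  }
  list(image = new("RgbImage", img),
       mask = PixelMask(matrix(TRUE, height, width)),
       expected = expected, counts = counts)
}

#' Simulate one measurement group
#'
#' `mode = "exact_moments"` draws seeded normal values then affinely
#' rescales them so the sample mean and n-1 SD match the targets to
#' numerical precision; `mode = "gaussian"` returns the raw seeded draws.
#' A zero target SD gives n copies of the mean.
#'
#' @param label group label.
#' @param mean,sd target mean and sample SD (`sd >= 0`).
#' @param n group size, >= 2.
#' @param mode `"exact_moments"` (default) or `"gaussian"`.
#' @param seed optional integer seed.
#' @return A [GroupMeasurements-class].
#' @examples
#' g <- simulateGroup("C_BCNU@HCLI", 75.63, 23.59, n = 7, seed = 1)
#' summarizeGroup(g)
#' @export
simulateGroup <- function(label, mean, sd, n,
                          mode = c("exact_moments", "gaussian"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (n < 2) .invalidArg("group size n must be >= 2")
  if (sd < 0) .invalidArg("target SD must be >= 0")
  if (sd == 0)
    return(GroupMeasurements(label, rep(mean, n)))
  x <- .withSeed(seed, stats::rnorm(n, mean, sd))
  if (mode == "exact_moments") {
    while (stats::sd(x) == 0)   # degenerate draw; cannot be rescaled
      x <- x + seq_along(x) * .Machine$double.eps * max(1, abs(mean))
    x <- mean + (x - base::mean(x)) * sd / stats::sd(x)
  }
  GroupMeasurements(label, x)
}

#' Simulate several measurement groups
#'
#' @param specs a data.frame with columns `label`, `mean`, `sd`, `n` and
#'   optionally `mode`; one group per row.
#' @param seed optional integer base seed; row i uses `seed + i - 1`.
#' @return A list of [GroupMeasurements-class] objects.
#' @export
simulateGroups <- function(specs, seed = NULL) {
  need <- c("label", "mean", "sd", "n")
  if (!all(need %in% names(specs)))
    .invalidArg("'specs' must have columns label, mean, sd, n")
  lapply(seq_len(nrow(specs)), function(i) {
    simulateGroup(specs$label[i], specs$mean[i], specs$sd[i], specs$n[i],
                  mode = if ("mode" %in% names(specs)) specs$mode[i]
                         else "exact_moments",
                  seed = if (is.null(seed)) NULL else seed + i - 1)
  })
}
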