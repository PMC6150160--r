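#' @import methods
NULL

## ---- internal condition helpers ------------------------------------------

.tqStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "topiQuant_error")))
}

.invalidArg <- function(msg) .tqStop(msg, "invalidArgumentError")
.fitFailure <- function(msg) .tqStop(msg, "fitFailureError")
.schemaError <- function(msg) .tqStop(msg, "schemaError")
.noScore <- function(msg) .tqStop(msg, "noScoreError")

## The four supported release laws, in the fixed order used for tie-breaking.
.kineticModels <- c("zero_order", "first_order", "higuchi", "korsmeyer_peppas")

## Number of free parameters per model (ties in model selection go to fewer).
.modelNParams <- c(zero_order = 1L, first_order = 1L,
                   higuchi = 1L, korsmeyer_peppas = 2L)

## Parameter names expected per model, on the percent/hour convention.
.modelParams <- list(zero_order = "K0", first_order = "K1",
                     higuchi = "KH", korsmeyer_peppas = c("KP", "n"))

## ---- release kinetics -----------------------------------------------------

#' DissolutionProfile: a cumulative drug-release time series
#'
#' Stores elapsed time in hours and the cumulative released amount as a
#' fraction of the drug load in `[0, 1]`. File I/O and reporting use percent;
#' the object itself always holds fractions.
#'
#' @slot times numeric, strictly increasing, first value >= 0 (hours).
#' @slot released numeric, cumulative released fraction in `[0, 1]`. Observed
#'   profiles may be locally non-monotone (measurement noise); noiseless
#'   simulated profiles are non-decreasing.
#' @slot label character(1), free-text system identifier.
#'
#' @seealso [DissolutionProfile()], [fitKineticModel()], [simulateDissolution()]
#' @export
setClass("DissolutionProfile",
  representation(times = "numeric", released = "numeric", label = "character"),
  prototype(label = ""))

setValidity("DissolutionProfile", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@released))
    msgs <- c(msgs, "'times' and 'released' must have equal length")
  if (length(object@times) > 0) {
    if (any(!is.finite(object@times)) || object@times[1] < 0)
      msgs <- c(msgs, "'times' must be finite and start at >= 0")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msgs <- c(msgs, "'times' must be strictly increasing")
    if (any(!is.finite(object@released)) ||
        any(object@released < 0 | object@released > 1))
      msgs <- c(msgs, "'released' must be fractions in [0, 1]")
  }
  if (length(object@label) != 1)
    msgs <- c(msgs, "'label' must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DissolutionProfile
#'
#' @param times elapsed time in hours, strictly increasing.
#' @param released cumulative released fraction of the load in `[0, 1]`.
#' @param label system identifier, e.g. `"BCNU@HCLI"`.
#' @return A [DissolutionProfile-class] object.
#' @examples
#' DissolutionProfile(times = 1:4, released = c(0.05, 0.09, 0.12, 0.15))
#' @export
DissolutionProfile <- function(times, released, label = "") {
  new("DissolutionProfile", times = as.numeric(times),
      released = as.numeric(released), label = as.character(label))
}

#' KineticFit: one release model fitted to a dissolution profile
#'
#' Constants follow the hour/percent convention: release is expressed as
#' percent of load, time in hours, so e.g. a zero-order `K0` has units
#' percent/hour. The first-order `K1` sits in an exponent and is per hour
#' regardless of the release scale.
#'
#' @slot model one of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`.
#' @slot constants named numeric: exactly the parameters of the model
#'   (`K0`, `K1`, `KH`, or `KP` and `n`).
#' @slot rSquared determination coefficient on the untransformed release
#'   scale; at most 1, may be negative for a bad model.
#' @slot residuals observed minus predicted, percent scale.
#' @slot fitted predicted release, percent scale.
#' @export
setClass("KineticFit",
  representation(model = "character", constants = "numeric",
                 rSquared = "numeric", residuals = "numeric",
                 fitted = "numeric"))

setValidity("KineticFit", function(object) {
  msgs <- character()
  if (!(length(object@model) == 1 && object@model %in% .kineticModels))
    msgs <- c(msgs, "unknown model identifier")
  else {
    want <- .modelParams[[object@model]]
    if (!setequal(names(object@constants), want) ||
        length(object@constants) != length(want))
      msgs <- c(msgs, sprintf("constants must be exactly {%s}",
                              paste(want, collapse = ", ")))
    else {
      rates <- object@constants[setdiff(want, "n")]
      if (any(rates <= 0))
        msgs <- c(msgs, "rate constants must be > 0")
      if ("n" %in% want) {
        n <- object@constants[["n"]]
        if (!(n > 0 && n <= 2))
          msgs <- c(msgs, "release exponent n must lie in (0, 2]")
      }
    }
  }
  if (length(object@rSquared) != 1 || object@rSquared > 1 + 1e-12)
    msgs <- c(msgs, "rSquared must be a single value <= 1")
  if (length(msgs)) msgs else TRUE
})

#' ModelSelection: candidate fits and the winning model
#'
#' @slot fits list of [KineticFit-class], one per candidate model.
#' @slot best model identifier with the maximal R-squared (ties broken by
#'   fewer parameters).
#' @slot criterion fixed tag `"max R²"`.
#' @export
setClass("ModelSelection",
  representation(fits = "list", best = "character", criterion = "character"),
  prototype(criterion = "max R²"))

setValidity("ModelSelection", function(object) {
  msgs <- character()
  if (!all(vapply(object@fits, is, logical(1), class2 = "KineticFit")))
    msgs <- c(msgs, "'fits' must be a list of KineticFit objects")
  if (length(object@best) != 1 || !object@best %in% .kineticModels)
    msgs <- c(msgs, "'best' must be a single known model id")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationLine: a linear assay calibration
#'
#' @slot slope response per unit concentration; > 0 for a valid assay.
#' @slot intercept response at zero concentration.
#' @slot rSquared determination coefficient of the calibration fit.
#' @slot sigma residual (or blank) standard deviation used for detection
#'   limits.
#' @seealso [lodLoq()]
#' @export
setClass("CalibrationLine",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", sigma = "numeric"))

setValidity("CalibrationLine", function(object) {
  if (length(object@slope) != 1 || object@slope <= 0)
    return("'slope' must be a single positive value")
  if (length(object@sigma) != 1 || object@sigma < 0)
    return("'sigma' must be a single non-negative value")
  TRUE
})

## ---- permeation -----------------------------------------------------------

#' PermeationSeries: cumulative permeated amount per area versus time
#'
#' @slot times hours, strictly increasing.
#' @slot cumulative cumulative permeated amount per unit area, ug/cm^2,
#'   non-negative.
#' @slot membrane membrane tag: `"nylon"`, `"collagen"` or `"other"`.
#' @slot donorConcentration donor-compartment concentration C, ug/mL, > 0.
#' @slot contactArea contact area A, cm^2, > 0.
#' @slot label free-text identifier.
#' @export
setClass("PermeationSeries",
  representation(times = "numeric", cumulative = "numeric",
                 membrane = "character", donorConcentration = "numeric",
                 contactArea = "numeric", label = "character"),
  prototype(membrane = "other", label = ""))

setValidity("PermeationSeries", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@cumulative))
    msgs <- c(msgs, "'times' and 'cumulative' must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "'times' must be strictly increasing")
  if (any(object@cumulative < 0))
    msgs <- c(msgs, "'cumulative' must be non-negative")
  if (length(object@membrane) != 1 ||
      !object@membrane %in% c("nylon", "collagen", "other"))
    msgs <- c(msgs, "'membrane' must be one of nylon, collagen, other")
  if (length(object@donorConcentration) != 1 || object@donorConcentration <= 0)
    msgs <- c(msgs, "'donorConcentration' must be a single positive value")
  if (length(object@contactArea) != 1 || object@contactArea <= 0)
    msgs <- c(msgs, "'contactArea' must be a single positive value")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PermeationSeries
#'
#' @param times hours, strictly increasing.
#' @param cumulative cumulative permeated amount per area, ug/cm^2.
#' @param donorConcentration donor concentration, ug/mL.
#' @param contactArea contact area, cm^2; defaults to a 2.5 cm diameter
#'   diffusion-cell disc (4.909 cm^2).
#' @param membrane `"nylon"`, `"collagen"` or `"other"`.
#' @param label free-text identifier.
#' @return A [PermeationSeries-class] object.
#' @export
PermeationSeries <- function(times, cumulative, donorConcentration,
                             contactArea = 4.909, membrane = "other",
                             label = "") {
  new("PermeationSeries", times = as.numeric(times),
      cumulative = as.numeric(cumulative), membrane = membrane,
      donorConcentration = as.numeric(donorConcentration),
      contactArea = as.numeric(contactArea), label = as.character(label))
}

#' PermeationResult: steady-state flux and permeability coefficient
#'
#' @slot fluxJ steady-state permeation rate J, ug/h (per-area slope times
#'   contact area).
#' @slot jss per-area steady-state flux, ug/cm^2/h (slope of the linear late
#'   phase).
#' @slot lagTime hours; x-intercept of the steady-state line, clamped at 0.
#' @slot kp permeability coefficient J / (C * A), cm/h; `NA` when flagged.
#' @slot window integer indices of the points used for the regression.
#' @slot flagged TRUE when the steady-state slope is zero or negative, in
#'   which case `kp` is not computed.
#' @export
setClass("PermeationResult",
  representation(fluxJ = "numeric", jss = "numeric", lagTime = "numeric",
                 kp = "numeric", window = "integer", flagged = "logical"))

setValidity("PermeationResult", function(object) {
  msgs <- character()
  if (!object@flagged && length(object@window) < 3)
    msgs <- c(msgs, "steady-state window must contain >= 3 points")
  if (!object@flagged && object@fluxJ > 0 &&
      !(is.finite(object@kp) && object@kp > 0))
    msgs <- c(msgs, "'kp' must be positive when flux is positive")
  if (length(msgs)) msgs else TRUE
})

## ---- quantitative IHC -----------------------------------------------------

#' RgbImage: an 8-bit RGB brightfield image
#'
#' A `height x width x 3` array with integer channel values in `[0, 255]`.
#'
#' @seealso [RgbImage()], [readRgbImage()], [deconvolveHDAB()]
#' @export
setClass("RgbImage", contains = "array")

setValidity("RgbImage", function(object) {
  d <- dim(object)
  if (length(d) != 3 || d[3] != 3)
    return("an RgbImage must be a height x width x 3 array")
  if (d[1] < 1 || d[2] < 1)
    return("image dimensions must be >= 1")
  if (any(!is.finite(object)) || any(object < 0 | object > 255))
    return("channel values must lie in [0, 255]")
  TRUE
})

#' Construct an RgbImage from an array
#'
#' @param x numeric array `height x width x 3` with values in `[0, 255]`
#'   (integers; values are rounded).
#' @return An [RgbImage-class] object.
#' @export
RgbImage <- function(x) {
  new("RgbImage", round(array(as.numeric(x), dim = dim(x))))
}

#' PixelMask: region-of-interest mask for an image
#'
#' Logical matrix with TRUE marking pixels inside the analysed stained
#' region.
#'
#' @seealso [PixelMask()], [zoneHistogram()], [chromogenEnergy()]
#' @export
setClass("PixelMask", contains = "matrix")

setValidity("PixelMask", function(object) {
  if (!is.logical(object@.Data))
    return("a PixelMask must be a logical matrix")
  TRUE
})

#' Construct a PixelMask
#'
#' @param x logical matrix (or coercible), TRUE = inside the region.
#' @return A [PixelMask-class] object.
#' @export
PixelMask <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "logical"
  new("PixelMask", m)
}

#' StainChannels: per-stain intensity images from colour deconvolution
#'
#' Each channel is a `height x width` matrix of 8-bit-style intensities in
#' `[0, 255]`, where 0 is the darkest shade (most chromogen) and 255 the
#' lightest (none), matching the brightfield convention.
#'
#' @slot dab DAB (brown chromogen) intensity.
#' @slot hematoxylin nuclear counterstain intensity.
#' @slot complementary residual third channel.
#' @export
setClass("StainChannels",
  representation(dab = "matrix", hematoxylin = "matrix",
                 complementary = "matrix"))

setValidity("StainChannels", function(object) {
  chans <- list(object@dab, object@hematoxylin, object@complementary)
  d <- dim(object@dab)
  for (ch in chans) {
    if (!identical(dim(ch), d))
      return("all stain channels must share the image dimensions")
    if (any(!is.finite(ch)) || any(ch < 0 | ch > 255))
      return("stain intensities must lie in [0, 255]")
  }
  TRUE
})

.zoneNames <- c("high_positive", "positive", "low_positive",
                "negative", "excluded")

## DAB-intensity zone boundaries (inclusive): darkest pixels carry the most
## chromogen. 236-255 is predominantly fat/background and is excluded from
## scoring.
.zoneLower <- c(high_positive = 0L, positive = 61L, low_positive = 121L,
                negative = 181L, excluded = 236L)
.zoneUpper <- c(high_positive = 60L, positive = 120L, low_positive = 180L,
                negative = 235L, excluded = 255L)

## Pathological weight of each scoring zone.
.zoneWeights <- c(high_positive = 4, positive = 3, low_positive = 2,
                  negative = 1)

#' ZoneHistogram: masked-pixel counts per DAB intensity zone
#'
#' Zones on the 0-255 DAB intensity scale: high positive `[0, 60]`, positive
#' `[61, 120]`, low positive `[121, 180]`, negative `[181, 235]`; `[236, 255]`
#' is excluded (fat/background).
#'
#' @slot counts named integer vector over the five zones.
#' @slot total total masked pixel count; equals the sum of the five counts.
#' @export
setClass("ZoneHistogram",
  representation(counts = "integer", total = "integer"))

setValidity("ZoneHistogram", function(object) {
  if (!identical(names(object@counts), .zoneNames))
    return("counts must be named by the five zones")
  if (any(object@counts < 0))
    return("zone counts must be non-negative")
  if (sum(object@counts) != object@total)
    return("zone counts must sum to the masked-pixel total")
  TRUE
})

#' IhcScore: the zone-weighted IHC expression score
#'
#' Partial score of a zone = (pixels in zone) x (zone weight) / (included
#' pixels); the global score is the sum over the four scoring zones and lies
#' in `[1, 4]`. Weights: high positive 4, positive 3, low positive 2,
#' negative 1.
#'
#' @slot partialScores named numeric over the four scoring zones.
#' @slot globalScore sum of the partial scores.
#' @slot zoneWeights the fixed weight map.
#' @slot includedTotal masked pixels minus excluded pixels.
#' @export
setClass("IhcScore",
  representation(partialScores = "numeric", globalScore = "numeric",
                 zoneWeights = "numeric", includedTotal = "integer"))

setValidity("IhcScore", function(object) {
  if (object@includedTotal > 0 &&
      (object@globalScore < 1 - 1e-9 || object@globalScore > 4 + 1e-9))
    return("global score must lie in [1, 4]")
  if (abs(object@globalScore - sum(object@partialScores)) > 1e-9)
    return("global score must equal the sum of partial scores")
  TRUE
})

#' EnergyMeasure: control-corrected chromogen energy per pixel
#'
#' @slot euPerPixel sample energy units per pixel on the 0-255 amplitude
#'   scale.
#' @slot controlEuPerPixel same measure from the no-primary-antibody control.
#' @slot corrected `max(0, sample - control)`.
#' @slot clamped TRUE when the raw difference was negative and floored at 0.
#' @slot mode `"rms"` or `"mean_square"`, the energy definition used.
#' @export
setClass("EnergyMeasure",
  representation(euPerPixel = "numeric", controlEuPerPixel = "numeric",
                 corrected = "numeric", clamped = "logical",
                 mode = "character"))

setValidity("EnergyMeasure", function(object) {
  if (object@corrected < 0)
    return("corrected energy must be non-negative")
  TRUE
})

## ---- group statistics -----------------------------------------------------

#' GroupMeasurements: per-sample measurements for one treatment group
#'
#' @slot label treatment name.
#' @slot values finite per-sample measurements (EU/pixel or scores); at least
#'   2 values for any inferential operation.
#' @export
setClass("GroupMeasurements",
  representation(label = "character", values = "numeric"))

setValidity("GroupMeasurements", function(object) {
  if (length(object@label) != 1 || !nzchar(object@label))
    return("'label' must be a single non-empty string")
  if (any(!is.finite(object@values)))
    return("'values' must be finite")
  TRUE
})

#' Construct a GroupMeasurements object
#'
#' @param label treatment name.
#' @param values numeric measurements.
#' @return A [GroupMeasurements-class] object.
#' @export
GroupMeasurements <- function(label, values) {
  new("GroupMeasurements", label = as.character(label),
      values = as.numeric(values))
}

#' GroupSummary: mean, SD and SE of one group
#'
#' @slot mean sample mean.
#' @slot sd sample standard deviation (n - 1 denominator).
#' @slot se standard error, exactly `sd / sqrt(n)`.
#' @slot n sample count.
#' @export
setClass("GroupSummary",
  representation(mean = "numeric", sd = "numeric", se = "numeric",
                 n = "integer"))

setValidity("GroupSummary", function(object) {
  if (abs(object@se - object@sd / sqrt(object@n)) > 1e-12 * max(1, object@sd))
    return("'se' must equal sd / sqrt(n)")
  TRUE
})

.pCategories <- c("NS", "p<0.05", "p<0.01", "p<0.001")

#' PairwiseComparison: one Welch t-test between two groups
#'
#' @slot tStatistic Welch t statistic.
#' @slot df Welch-Satterthwaite degrees of freedom (non-integer allowed).
#' @slot pValue two-tailed p-value.
#' @slot category `"NS"`, `"p<0.05"`, `"p<0.01"` or `"p<0.001"` by strict
#'   thresholds.
#' @slot degenerate TRUE for the both-variances-zero, unequal-means case
#'   where p is reported as 0.
#' @export
setClass("PairwiseComparison",
  representation(tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 category = "character", degenerate = "logical"),
  prototype(degenerate = FALSE))

setValidity("PairwiseComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("p-value must lie in [0, 1]")
  if (!object@category %in% .pCategories)
    return("unknown significance category")
  TRUE
})

#' ComparisonMatrix: pairwise Welch significance categories
#'
#' Symmetric matrix of significance categories with `"NS"` on the diagonal;
#' the matching two-tailed p-values are kept alongside.
#'
#' @slot labels group labels (unique).
#' @slot categories character matrix of categories.
#' @slot pValues numeric matrix of two-tailed p-values (1 on the diagonal).
#' @export
setClass("ComparisonMatrix",
  representation(labels = "character", categories = "matrix",
                 pValues = "matrix"))

setValidity("ComparisonMatrix", function(object) {
  k <- length(object@labels)
  if (anyDuplicated(object@labels))
    return("group labels must be unique")
  if (!identical(dim(object@categories), c(k, k)) ||
      !identical(dim(object@pValues), c(k, k)))
    return("matrices must be square over the group labels")
  if (!identical(object@categories, t(object@categories)))
    return("category matrix must be symmetric")
  if (!all(diag(object@categories) == "NS"))
    return("diagonal must be NS")
  TRUE
})
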