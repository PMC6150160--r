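## Quantitative IHC module: H-DAB colour deconvolution, zoned DAB-intensity
## histogram scoring, and the chromogen energy-per-pixel measure with
## no-primary-antibody control subtraction.

#' The H-DAB stain matrix
#'
#' Rows are the unit optical-density vectors of hematoxylin
#' (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.767) and a complementary
#' third vector (normalized cross product), the standard values of
#' Ruifrok-Johnston colour deconvolution.
#'
#' @return A 3 x 3 numeric matrix; rows hematoxylin, dab, complementary.
#' @export
hdabStainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.767)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  x <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  x <- x / sqrt(sum(x^2))
  m <- rbind(hematoxylin = h, dab = d, complementary = x)
  colnames(m) <- c("r", "g", "b")
  m
}

## intensity (0-255, white = none) <-> optical density
.toOD <- function(v) -log10(pmax(v, 1) / 255)
.toIntensity <- function(amount) {
  pmin(pmax(round(255 * 10^(-amount)), 0), 255)
}

#' Unmix an RGB brightfield image into H-DAB stain channels
#'
#' Converts each 8-bit channel value to optical density
#' `OD = -log10(max(v, 1) / 255)` (white background assumed), inverts the
#' 3 x 3 H-DAB stain matrix to obtain per-pixel stain amounts, and maps each
#' amount back to an 8-bit-style intensity `255 * 10^(-amount)` clipped to
#' `[0, 255]`, so 0 is the darkest shade (most chromogen) and 255 the
#' lightest.
#'
#' @param image an [RgbImage-class] (or a `height x width x 3` array of
#'   values in `[0, 255]`).
#' @return A [StainChannels-class] with `dab`, `hematoxylin` and
#'   `complementary` intensity matrices.
#' @examples
#' img <- simulateIhcImage(20, 20, c(high_positive = 1), seed = 1)$image
#' deconvolveHDAB(img)
#' @export
deconvolveHDAB <- function(image) {
  if (!is(image, "RgbImage")) image <- RgbImage(image)
  d <- dim(image)
  od <- cbind(.toOD(as.vector(image[, , 1])),
              .toOD(as.vector(image[, , 2])),
              .toOD(as.vector(image[, , 3])))
  amounts <- od %*% solve(hdabStainMatrix())   # pixel OD = amounts %*% M
  shape <- function(a) matrix(.toIntensity(a), nrow = d[1], ncol = d[2])
  new("StainChannels",
      hematoxylin = shape(amounts[, 1]),
      dab = shape(amounts[, 2]),
      complementary = shape(amounts[, 3]))
}

## Stain amounts per pixel (OD units), without the intensity re-mapping.
## Used by tests and the forward simulator.
.stainAmounts <- function(image) {
  if (!is(image, "RgbImage")) image <- RgbImage(image)
  od <- cbind(.toOD(as.vector(image[, , 1])),
              .toOD(as.vector(image[, , 2])),
              .toOD(as.vector(image[, , 3])))
  a <- od %*% solve(hdabStainMatrix())
  colnames(a) <- c("hematoxylin", "dab", "complementary")
  a
}

.resolveMask <- function(mask, dims) {
  if (is.null(mask))
    mask <- PixelMask(matrix(TRUE, dims[1], dims[2]))
  if (!is(mask, "PixelMask")) mask <- PixelMask(mask)
  if (!identical(dim(mask@.Data), dims))
    .invalidArg("mask dimensions must match the image")
  if (!any(mask@.Data))
    .invalidArg("mask must contain at least one pixel")
  mask
}

#' Zone histogram of DAB intensities
#'
#' Bins the masked DAB intensities into the standard scoring zones:
#' high positive `[0, 60]`, positive `[61, 120]`, low positive `[121, 180]`,
#' negative `[181, 235]`; intensities in `[236, 255]` (predominantly fatty
#' tissue / background) are counted as excluded. The five counts always sum
#' to the number of masked pixels.
#'
#' @param stain a [StainChannels-class] (its `dab` channel is binned), or a
#'   plain intensity matrix.
#' @param mask optional [PixelMask-class] (defaults to the full image).
#' @return A [ZoneHistogram-class].
#' @export
zoneHistogram <- function(stain, mask = NULL) {
  dab <- if (is(stain, "StainChannels")) stain@dab else as.matrix(stain)
  mask <- .resolveMask(mask, dim(dab))
  v <- round(dab[mask@.Data])
  counts <- vapply(.zoneNames, function(z) {
    sum(v >= .zoneLower[[z]] & v <= .zoneUpper[[z]])
  }, integer(1))
  new("ZoneHistogram", counts = counts, total = length(v))
}

#' Zone-weighted IHC expression score
#'
#' Partial score of each scoring zone = (pixels in the zone) x (zone weight)
#' / (included pixels), with weights 4 (high positive), 3 (positive),
#' 2 (low positive) and 1 (negative); the global score is the sum of the
#' four partial scores and lies in `[1, 4]`. Excluded pixels do not
#' contribute. If every masked pixel is excluded no score exists and an
#' error of class `noScoreError` is signalled.
#'
#' @param hist a [ZoneHistogram-class].
#' @return An [IhcScore-class].
#' @examples
#' res <- simulateIhcImage(40, 40, c(positive = 0.5, negative = 0.5),
#'                         seed = 1)
#' ihcScore(zoneHistogram(deconvolveHDAB(res$image), res$mask))
#' @export
ihcScore <- function(hist) {
  if (!is(hist, "ZoneHistogram"))
    .invalidArg("'hist' must be a ZoneHistogram")
  included <- hist@total - hist@counts[["excluded"]]
  if (included == 0)
    .noScore("all masked pixels fall in the excluded intensity range")
  scoring <- names(.zoneWeights)
  partial <- hist@counts[scoring] * .zoneWeights / included
  new("IhcScore", partialScores = partial, globalScore = sum(partial),
      zoneWeights = .zoneWeights, includedTotal = as.integer(included))
}

#' Chromogen energy per pixel
#'
#' Treats each masked pixel's DAB amplitude `s = 255 - intensity` as signal
#' and reports its root-mean-square, `sqrt(mean(s^2))` — a per-pixel norm of
#' the cumulative signal strength, bounded in `[0, 255]`. Setting
#' `mode = "mean_square"` reports `mean(s^2)` instead.
#'
#' @param stain a [StainChannels-class] or DAB intensity matrix.
#' @param mask optional [PixelMask-class].
#' @param mode `"rms"` (default) or `"mean_square"`.
#' @return Energy units per pixel (numeric scalar).
#' @export
chromogenEnergy <- function(stain, mask = NULL,
                            mode = c("rms", "mean_square")) {
  mode <- match.arg(mode)
  dab <- if (is(stain, "StainChannels")) stain@dab else as.matrix(stain)
  mask <- .resolveMask(mask, dim(dab))
  s <- 255 - dab[mask@.Data]
  ms <- mean(s^2)
  if (mode == "rms") sqrt(ms) else ms
}

#' Control-corrected chromogen energy
#'
#' Subtracts the no-primary-antibody control's energy from the sample's,
#' flooring at zero (a negative difference is clamped and flagged).
#'
#' @param sampleEU sample energy units per pixel, >= 0.
#' @param controlEU control energy units per pixel, >= 0.
#' @param mode the energy definition both values were computed under.
#' @return An [EnergyMeasure-class].
#' @examples
#' correctedEnergy(100, 30)
#' @export
correctedEnergy <- function(sampleEU, controlEU, mode = "rms") {
  if (sampleEU < 0 || controlEU < 0)
    .invalidArg("energies must be non-negative")
  raw <- sampleEU - controlEU
  clamped <- raw < 0
  if (clamped)
    warning("control energy exceeds sample energy; corrected value clamped at 0",
            call. = FALSE)
  new("EnergyMeasure", euPerPixel = sampleEU, controlEuPerPixel = controlEU,
      corrected = max(0, raw), clamped = clamped, mode = mode)
}
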