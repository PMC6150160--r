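## I/O and orchestration: delimited-table readers with schema validation,
## 8-bit image read/write (PNG and TIFF), report writing, and the
## config-driven pipeline runner.

.numericColumn <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (any(is.na(df[[col]])) || length(bad))
    .schemaError(sprintf("%s: non-numeric or missing value in column '%s' (row %d)",
                         path, col,
                         if (length(bad)) bad[1] else which(is.na(df[[col]]))[1]))
  v
}

.checkHeader <- function(df, want, path) {
  missing <- setdiff(want, names(df))
  if (length(missing))
    .schemaError(sprintf("%s: missing column(s) %s (expected header '%s')",
                         path, paste(missing, collapse = ", "),
                         paste(want, collapse = ",")))
}

.checkTimes <- function(t, path) {
  if (length(t) > 1 && any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1] + 1
    .schemaError(sprintf("%s: 'time_h' not strictly increasing at row %d",
                         path, i))
  }
  if (t[1] < 0) .schemaError(sprintf("%s: negative time at row 1", path))
}

#' Read a delimited profile table
#'
#' Reads one of the package's three delimited-text schemas (comma-separated,
#' UTF-8, one header row):
#' \describe{
#'   \item{dissolution}{columns `time_h,release_pct`; percent in
#'     `[0, 100]`, converted to fractions. Returns a
#'     [DissolutionProfile-class].}
#'   \item{permeation}{columns `time_h,cumulative_ug_per_cm2`. Returns a
#'     [PermeationSeries-class]; pass `donorConcentration`, `contactArea`
#'     and `membrane` through `...`.}
#'   \item{groups}{columns `group,value`. Returns a list of
#'     [GroupMeasurements-class], one per distinct group, in order of first
#'     appearance.}
#' }
#' Schema violations (missing columns, non-numeric cells, non-increasing
#' times, out-of-range percentages) raise an error of class `schemaError`
#' naming the row and column.
#'
#' @param path file path.
#' @param kind `"dissolution"`, `"permeation"` or `"groups"`.
#' @param sep field separator (default comma).
#' @param label label for the returned profile/series.
#' @param ... extra arguments for the permeation constructor.
#' @return See Description.
#' @export
readProfileTable <- function(path, kind = c("dissolution", "permeation",
                                            "groups"),
                             sep = ",", label = basename(path), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .schemaError(paste("file not found:", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (kind == "dissolution") {
    .checkHeader(df, c("time_h", "release_pct"), path)
    t <- .numericColumn(df, "time_h", path)
    pct <- .numericColumn(df, "release_pct", path)
    .checkTimes(t, path)
    out <- which(pct < 0 | pct > 100)
    if (length(out))
      .schemaError(sprintf("%s: 'release_pct' out of [0, 100] at row %d",
                           path, out[1]))
    DissolutionProfile(t, pct / 100, label = label)
  } else if (kind == "permeation") {
    .checkHeader(df, c("time_h", "cumulative_ug_per_cm2"), path)
    t <- .numericColumn(df, "time_h", path)
    y <- .numericColumn(df, "cumulative_ug_per_cm2", path)
    .checkTimes(t, path)
    if (any(y < 0))
      .schemaError(sprintf("%s: negative cumulative amount at row %d",
                           path, which(y < 0)[1]))
    PermeationSeries(t, y, label = label, ...)
  } else {
    .checkHeader(df, c("group", "value"), path)
    v <- .numericColumn(df, "value", path)
    g <- as.character(df$group)
    lapply(unique(g), function(lab) GroupMeasurements(lab, v[g == lab]))
  }
}

## ---- images ---------------------------------------------------------------

.imageReader <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::readPNG,
         tif = , tiff = tiff::readTIFF,
         .schemaError(paste("unsupported image format:", ext)))
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' An alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return An [RgbImage-class].
#' @export
readRgbImage <- function(path) {
  if (!file.exists(path)) .schemaError(paste("file not found:", path))
  a <- .imageReader(path)(path)
  if (length(dim(a)) != 3 || dim(a)[3] < 3)
    .schemaError(paste(path, "is not an RGB image"))
  RgbImage(a[, , 1:3, drop = FALSE] * 255)
}

#' Write an RgbImage as PNG or TIFF (by extension)
#'
#' @param image an [RgbImage-class].
#' @param path output path ending in .png, .tif or .tiff.
#' @return The path, invisibly.
#' @export
writeRgbImage <- function(image, path) {
  if (!is(image, "RgbImage")) image <- RgbImage(image)
  a <- image@.Data / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(a, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(a, path,
                                                      bits.per.sample = 8L)
  else .schemaError(paste("unsupported image format:", ext))
  invisible(path)
}

#' Read a single-channel mask image (0 = outside, >0 = inside)
#'
#' @param path mask file path (PNG or TIFF).
#' @return A [PixelMask-class].
#' @export
readMask <- function(path) {
  if (!file.exists(path)) .schemaError(paste("file not found:", path))
  a <- .imageReader(path)(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  PixelMask(a > 0)
}

#' Write a PixelMask as a single-channel image
#'
#' @param mask a [PixelMask-class].
#' @param path output path (.png, .tif or .tiff).
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  a <- matrix(as.numeric(mask@.Data), nrow(mask@.Data), ncol(mask@.Data))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(a, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(a, path,
                                                      bits.per.sample = 8L)
  else .schemaError(paste("unsupported image format:", ext))
  invisible(path)
}

## ---- reports --------------------------------------------------------------

.fitsTable <- function(fits, best = NULL) {
  rows <- lapply(fits, function(f) {
    k <- constants(f)
    data.frame(model = modelId(f),
               parameter = names(k), value = unname(k),
               r_squared = rSquaredValue(f),
               best = if (is.null(best)) NA else modelId(f) == best,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Serialize analysis results to a report directory
#'
#' Writes `<name>.json` (all results plus a provenance block) and a CSV
#' mirror of each tabular element. File names are deterministic and the
#' JSON payload contains no timestamps, so identical inputs reproduce
#' byte-identical reports.
#'
#' @param results named list of JSON-serialisable results; elements that are
#'   data.frames are additionally written as `<name>_<element>.csv`.
#' @param outDir output directory (created if needed).
#' @param name report base name.
#' @param provenance named list recorded under `$provenance` (inputs, seed,
#'   config); the package version is always added.
#' @return Character vector of the files written, invisibly.
#' @export
writeReport <- function(results, outDir, name = "report",
                        provenance = list()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  provenance$package <- "topiQuant"
  provenance$version <- as.character(utils::packageVersion("topiQuant"))
  payload <- list(results = results, provenance = provenance)
  jsonPath <- file.path(outDir, paste0(name, ".json"))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  written <- jsonPath
  for (el in names(results)) {
    if (is.data.frame(results[[el]])) {
      csvPath <- file.path(outDir, paste0(name, "_", el, ".csv"))
      utils::write.csv(results[[el]], csvPath, row.names = FALSE)
      written <- c(written, csvPath)
    }
  }
  invisible(written)
}

## ---- pipeline -------------------------------------------------------------

.knownStageKeys <- list(
  release = c("input", "models"),
  permeation = c("input", "donor_concentration_ug_per_ml",
                 "contact_area_cm2", "membrane", "window"),
  qihc = c("image", "mask", "control_image", "control_mask", "energy_mode"),
  groups = c("input", "adjust"))

.validateConfig <- function(config) {
  known <- c("seed", "out", "stages")
  extra <- setdiff(names(config), known)
  if (length(extra))
    .schemaError(paste("unknown config key(s):", paste(extra, collapse = ", ")))
  if (is.null(config$stages) || !length(config$stages))
    .schemaError("config must define at least one stage under 'stages'")
  badStage <- setdiff(names(config$stages), names(.knownStageKeys))
  if (length(badStage))
    .schemaError(paste("unknown stage(s):", paste(badStage, collapse = ", ")))
  for (st in names(config$stages)) {
    extra <- setdiff(names(config$stages[[st]]), .knownStageKeys[[st]])
    if (length(extra))
      .schemaError(sprintf("unknown key(s) in stage '%s': %s", st,
                           paste(extra, collapse = ", ")))
  }
  config
}

.stageRelease <- function(opts) {
  profile <- readProfileTable(opts$input, "dissolution")
  models <- opts$models
  if (is.null(models) || identical(models, "all")) models <- .kineticModels
  fits <- fitAllModels(profile, models)
  if (!length(fits)) .fitFailure("no model could be fitted")
  sel <- if (length(fits) >= 2) selectModel(fits) else NULL
  list(fits = .fitsTable(fits, if (is.null(sel)) NULL else bestModel(sel)),
       best = if (is.null(sel)) modelId(fits[[1]]) else bestModel(sel))
}

.stagePermeation <- function(opts) {
  C <- opts$donor_concentration_ug_per_ml
  if (is.null(C)) .schemaError("permeation stage needs donor_concentration_ug_per_ml")
  A <- if (is.null(opts$contact_area_cm2)) 4.909 else opts$contact_area_cm2
  series <- readProfileTable(opts$input, "permeation",
                             donorConcentration = C, contactArea = A,
                             membrane = if (is.null(opts$membrane)) "other"
                                        else opts$membrane)
  res <- analyzePermeation(series, window = opts$window)
  list(jss_ug_per_cm2_per_h = steadyStateSlope(res),
       flux_J_ug_per_h = fluxJ(res), lag_time_h = lagTime(res),
       kp_cm_per_h = permeability(res), flagged = res@flagged,
       window = res@window)
}

.stageQihc <- function(opts) {
  img <- readRgbImage(opts$image)
  mask <- if (is.null(opts$mask)) NULL else readMask(opts$mask)
  mode <- if (is.null(opts$energy_mode)) "rms" else opts$energy_mode
  stains <- deconvolveHDAB(img)
  hist <- zoneHistogram(stains, mask)
  score <- ihcScore(hist)
  eu <- chromogenEnergy(stains, mask, mode = mode)
  out <- list(
    zone_counts = as.list(zoneCounts(hist)),
    zone_percent = as.list(100 * zoneCounts(hist) / hist@total),
    partial_scores = as.list(partialScores(score)),
    global_score = globalScore(score),
    eu_per_pixel = eu)
  if (!is.null(opts$control_image)) {
    cimg <- readRgbImage(opts$control_image)
    cmask <- if (is.null(opts$control_mask)) NULL
             else readMask(opts$control_mask)
    ceu <- chromogenEnergy(deconvolveHDAB(cimg), cmask, mode = mode)
    corr <- correctedEnergy(eu, ceu, mode = mode)
    out$control_eu_per_pixel <- ceu
    out$corrected_eu_per_pixel <- correctedEU(corr)
  }
  out
}

.stageGroups <- function(opts) {
  groups <- readProfileTable(opts$input, "groups")
  summaries <- do.call(rbind, lapply(groups, function(g) {
    s <- summarizeGroup(g)
    data.frame(group = groupLabel(g), n = s@n, mean = s@mean, sd = s@sd,
               se = s@se)
  }))
  out <- list(summaries = summaries)
  if (length(groups) >= 2) {
    cm <- comparisonMatrix(groups,
                           adjust = if (is.null(opts$adjust)) "none"
                                    else opts$adjust)
    out$categories <- as.data.frame(cbind(group = cm@labels, cm@categories))
    out$p_values <- as.data.frame(cm@pValues)
  }
  out
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in the fixed order release -> permeation ->
#' qihc -> groups. The config is a named list (or a YAML file path) with
#' optional `seed` and `out`, and a `stages` block whose entries configure
#' each stage; unknown keys anywhere are rejected. A failing stage is
#' recorded as an error entry naming the stage and does not disturb the
#' other stages' results. When `out` is set the report bundle is also
#' written there via [writeReport()].
#'
#' @param config named list or path to a YAML config file.
#' @return A list with `results` (one entry per requested stage) and
#'   `provenance` (config, seed, package version).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- .validateConfig(config)
  runners <- list(release = .stageRelease, permeation = .stagePermeation,
                  qihc = .stageQihc, groups = .stageGroups)
  results <- list()
  for (st in intersect(names(runners), names(config$stages))) {
    results[[st]] <- tryCatch(
      runners[[st]](config$stages[[st]]),
      error = function(e) list(error = sprintf("stage '%s': %s", st,
                                               conditionMessage(e))))
  }
  bundle <- list(results = results,
                 provenance = list(config = config$stages,
                                   seed = config$seed))
  if (!is.null(config$out)) {
    flat <- list()
    for (st in names(results)) {
      r <- results[[st]]
      if (is.data.frame(r)) flat[[st]] <- r
      else for (el in names(r)) flat[[paste(st, el, sep = "_")]] <- r[[el]]
    }
    writeReport(flat, config$out, name = "pipeline",
                provenance = bundle$provenance)
  }
  bundle
}
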