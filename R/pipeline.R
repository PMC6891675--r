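# End-to-end orchestration: trim -> split -> recipe -> CV -> PLS ->
# validation statistics, for each requested property.

#' Run the full calibration/validation pipeline
#'
#' For every requested property: the spectra are trimmed to the working
#' window, split 90/10 into calibration and validation by Kennard-Stone
#' (group-aware by default, so the replicate spectra of one sample never
#' straddle the split), the latent-variable count is chosen by
#' leave-five-out cross-validation within the calibration set, the
#' preprocessing recipe is fitted on calibration rows and applied to both
#' sets, a final NIPALS PLS1 model is fitted, and SEC / R2cal on the
#' calibration set plus SEP / R2val / bias / paired-t on the external
#' validation set are computed. Fully deterministic given the seed.
#'
#' The Kennard-Stone split depends only on the spectra, so one split is
#' shared by all properties (as when a single instrument database is
#' partitioned once).
#'
#' @param spectra a [SpectralMatrix-class]
#' @param properties property data.frame (`sample_id` + property columns);
#'   every spectral sample must be present
#' @param propertyNames properties to model (default: all ten)
#' @param recipe an unfitted [PreprocessRecipe-class]
#' @param lvMax largest candidate LV count for cross-validation
#' @param fraction calibration share of the split
#' @param groupAware keep replicate rows of a sample on one side of the
#'   split (`FALSE` reproduces a row-wise split of the replicate-expanded
#'   matrix)
#' @param window trimming window in cm-1 (closed interval)
#' @param seed root seed; per-property fold seeds are derived from it
#' @param foldSize CV fold size (default 5, i.e. leave-five-out)
#' @param cvScheme CV fold scheme, see [makeFoldsLeaveFiveOut()]
#' @param tLevel,tTail paired-t band settings (see [pairedT()])
#' @param split optional precomputed split (a [kennardStoneSplit()] result
#'   on the trimmed spectra) overriding the internal one
#' @return a [PipelineRun-class]
#' @export
runPipeline <- function(spectra, properties,
                        propertyNames = honeyProperties()$name,
                        recipe = defaultRecipe(),
                        lvMax = 10L, fraction = 0.9, groupAware = TRUE,
                        window = c(201, 2000), seed = 1L, foldSize = 5L,
                        cvScheme = "random",
                        tLevel = 0.95, tTail = "one", split = NULL) {
  stopifnot(is(spectra, "SpectralMatrix"))
  properties <- .validatePropertyTable(properties)
  unknown <- setdiff(propertyNames, honeyProperties()$name)
  if (length(unknown))
    .stopf("runPipeline: unknown propert%s: %s",
           if (length(unknown) > 1) "ies" else "y",
           paste(unknown, collapse = ", "))
  absent <- setdiff(propertyNames, names(properties))
  if (length(absent))
    .stopf("runPipeline: property table lacks column(s): %s",
           paste(absent, collapse = ", "))
  missing <- setdiff(unique(spectra@sampleIds), properties$sample_id)
  if (length(missing))
    .stopf("runPipeline: sample id(s) in spectra but not in properties: %s",
           paste(utils::head(missing, 10L), collapse = ", "))

  x <- trimToWindow(spectra, window[1], window[2])
  if (is.null(split)) {
    split <- kennardStoneSplit(
      x, fraction = fraction,
      groupIds = if (groupAware) x@sampleIds else NULL)
  }
  cal <- x[split$calibration]
  val <- x[split$validation]
  yAll <- properties[match(x@sampleIds, properties$sample_id), , drop = FALSE]

  # The recipe head (alignment + row-local treatments) does not depend on
  # the modeled property, so it is fitted on the calibration set once and
  # shared; only the trailing centering/autoscaling is property-specific
  # work (refit per CV fold inside crossValidateLV).
  stages <- .splitRecipeForCV(recipe)
  headFitted <- fitRecipe(stages$head, cal)
  calH <- applyRecipe(headFitted, cal)
  valH <- applyRecipe(headFitted, val)
  scalerRecipe <- new("PreprocessRecipe", steps = stages$scalerSteps,
                      state = list(), fitted = FALSE)
  scalerFitted <- fitRecipe(scalerRecipe, calH)
  calT <- applyRecipe(scalerFitted, calH)
  valT <- applyRecipe(scalerFitted, valH)

  units <- setNames(honeyProperties()$unit, honeyProperties()$name)
  rows <- vector("list", length(propertyNames))
  models <- list()
  cvs <- list()

  for (k in seq_along(propertyNames)) {
    prop <- propertyNames[k]
    yCal <- yAll[[prop]][split$calibration]
    yVal <- yAll[[prop]][split$validation]

    cv <- crossValidateLV(calH, yCal, recipe = scalerRecipe, lvMax = lvMax,
                          seed = .subSeed(seed, paste0("folds:", prop)),
                          foldSize = foldSize, scheme = cvScheme)
    model <- fitPLS(calT, yCal, cv$chosenLV)
    predCal <- predict(model, calT)
    predVal <- predict(model, valT)

    tt <- pairedT(yVal, predVal, level = tLevel, tail = tTail)
    rows[[k]] <- data.frame(
      property = prop,
      units = unname(units[prop]),
      lv = model@nLV,
      sec = sec(yCal, predCal, model@nLV),
      r2_cal = rSquared(yCal, predCal),
      sep = sep(yVal, predVal),
      r2_val = rSquared(yVal, predVal),
      t_c = tt$t,
      t_critical = tt$tCritical,
      bias = predictionBias(yVal, predVal),
      stringsAsFactors = FALSE
    )
    models[[prop]] <- model
    cvs[[prop]] <- cv
  }

  new("PipelineRun",
      results = do.call(rbind, rows),
      models = models,
      split = split,
      cv = cvs,
      recipeSteps = recipe@steps,
      wavenumbers = x@wavenumbers,
      seed = as.integer(seed))
}

#' Write the per-property validation report as CSV
#'
#' One row per property with columns property, units, lv, sec, r2_cal,
#' sep, r2_val, t_c, t_critical, bias; numeric values printed with 4
#' decimal places. Re-running an identical pipeline reproduces the file
#' byte-identically.
#'
#' @param run a [PipelineRun-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
reportTable <- function(run, path) {
  stopifnot(is(run, "PipelineRun"))
  df <- run@results
  if (!nrow(df)) .stopf("reportTable: empty report")
  numCols <- setdiff(names(df), c("property", "units", "lv"))
  out <- df
  for (nc in numCols) out[[nc]] <- formatC(df[[nc]], format = "f",
                                           digits = 4)
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Export first-component loading spectra with region rankings
#'
#' One CSV row per property: the property name, the top-ranked loading
#' region (see [topLoadingRegions()]), and the full component-1 loading
#' spectrum (one column per wavenumber).
#'
#' @param run a [PipelineRun-class]
#' @param path output CSV path
#' @param regions region table (default [honeyLoadingRegions()])
#' @return invisibly, a data.frame with the region ranking per property
#' @export
exportLoadings <- function(run, path, regions = honeyLoadingRegions()) {
  stopifnot(is(run, "PipelineRun"))
  props <- run@results$property
  if (!length(props)) .stopf("exportLoadings: run has no fitted models")
  w <- run@wavenumbers
  header <- paste(c("property", "top_region_lo", "top_region_hi",
                    .fmtNum(w)), collapse = ",")
  rankings <- list()
  lines <- character(length(props))
  for (k in seq_along(props)) {
    prop <- props[k]
    model <- run@models[[prop]]
    if (is.null(model))
      .stopf("exportLoadings: no fitted model for %s", prop)
    if (model@nLV < 1L)
      .stopf("exportLoadings: model for %s has no components", prop)
    ld <- model@xLoadings[, 1L]
    rk <- topLoadingRegions(ld, w, regions)
    rankings[[prop]] <- rk
    lines[k] <- paste(c(prop, .fmtNum(rk$lo[1]), .fmtNum(rk$hi[1]),
                        .fmtNum(ld)), collapse = ",")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(rankings)
}
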