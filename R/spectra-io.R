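# Domain constructors, canonical property catalog, CSV I/O, window trimming.

#' Construct a SpectralMatrix
#'
#' @param intensities numeric matrix, one row per spectrum, one column per
#'   grid point (arbitrary units).
#' @param wavenumbers strictly increasing Raman-shift grid (cm-1).
#' @param sampleIds per-row physical-sample labels (recycled from row
#'   numbers when missing).
#' @param replicateIds per-row replicate indices (default all 1).
#' @return a validated [SpectralMatrix-class]
#' @examples
#' sm <- SpectralMatrix(matrix(rnorm(6), 2), c(400, 500, 600))
#' dim(sm)
#' @export
SpectralMatrix <- function(intensities, wavenumbers,
                           sampleIds = NULL, replicateIds = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (is.null(sampleIds)) sampleIds <- as.character(seq_len(n))
  if (is.null(replicateIds)) replicateIds <- rep(1L, n)
  new("SpectralMatrix",
      wavenumbers = as.numeric(wavenumbers),
      intensities = intensities,
      sampleIds = as.character(sampleIds),
      replicateIds = as.integer(replicateIds))
}

#' Canonical honey properties and their units
#'
#' The ten physicochemical parameters the package models, in report order,
#' with the units used throughout (acidity in milliequivalents per kg,
#' conductivity in mS/cm, Redox potential in mV, HMF in mg/kg, ash in
#' g/100 g; moisture and total soluble solids in percent).
#'
#' @return data.frame with columns `name` and `unit`
#' @export
honeyProperties <- function() {
  data.frame(
    name = c("pH", "moisture", "TSS", "free_acidity", "lactonic_acidity",
             "total_acidity", "electrical_conductivity", "redox_potential",
             "HMF", "ash"),
    unit = c("-", "%", "%", "meq kg-1", "meq kg-1", "meq kg-1",
             "mS cm-1", "mV", "mg kg-1", "g/100 g"),
    stringsAsFactors = FALSE
  )
}

# Validate a property table: one row per sample, finite positive values,
# only canonical columns.
.validatePropertyTable <- function(tab, context = "property table") {
  if (!is.data.frame(tab)) .stopf("%s must be a data.frame", context)
  if (!"sample_id" %in% names(tab))
    .stopf("%s must contain a sample_id column", context)
  extra <- setdiff(names(tab), c("sample_id", honeyProperties()$name))
  if (length(extra))
    .stopf("%s has unknown column(s): %s (allowed: sample_id, %s)",
           context, paste(extra, collapse = ", "),
           paste(honeyProperties()$name, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    .stopf("%s has duplicate sample_id value(s): %s", context,
           paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                 collapse = ", "))
  propCols <- setdiff(names(tab), "sample_id")
  for (pc in propCols) {
    v <- tab[[pc]]
    if (!is.numeric(v) || !all(is.finite(v)))
      .stopf("%s: column %s must be finite numeric", context, pc)
    if (any(v < 0))
      .stopf("%s: column %s has negative value(s)", context, pc)
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

# ---- spectra CSV ----------------------------------------------------------

#' Read a wide-format spectra CSV
#'
#' Expected layout: header `sample_id,replicate_id,<w1>,<w2>,...` where the
#' remaining column names parse as decimal wavenumbers (cm-1), strictly
#' increasing left to right; one spectrum per row.
#'
#' @param path file path
#' @return a [SpectralMatrix-class]
#' @seealso [writeSpectraCSV()] for the complementary writer (the two
#'   round-trip exactly at the printed precision)
#' @export
readSpectraCSV <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE,
                          colClasses = list(character = "sample_id"))
  nm <- names(dt)
  if (length(nm) < 3L || nm[1] != "sample_id" || nm[2] != "replicate_id")
    .stopf("spectra CSV %s: header must start with sample_id,replicate_id",
           path)
  w <- suppressWarnings(as.numeric(nm[-(1:2)]))
  if (any(is.na(w)))
    .stopf("spectra CSV %s: non-numeric wavenumber header(s): %s", path,
           paste(nm[-(1:2)][is.na(w)], collapse = ", "))
  if (any(diff(w) <= 0))
    .stopf("spectra CSV %s: wavenumber headers must be strictly increasing",
           path)
  m <- as.matrix(dt[, -(1:2)])
  suppressWarnings(storage.mode(m) <- "double")  # NAs flagged below
  if (nrow(m) > 0) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      .stopf("spectra CSV %s: non-numeric/non-finite cell at row %d, column %s",
             path, bad[1, 1], nm[-(1:2)][bad[1, 2]])
  }
  SpectralMatrix(m, w, dt$sample_id, dt$replicate_id)
}

# Format numbers at 12 significant digits for serialization; round-trips
# through the readers bit-identically at that precision.
.fmtNum <- function(x) formatC(x, digits = 12, format = "g", width = 1)

#' Write a SpectralMatrix to wide-format CSV
#'
#' Numbers are serialized with 12 significant digits; reading the file back
#' with [readSpectraCSV()] reproduces the matrix at that precision.
#'
#' @param x a [SpectralMatrix-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectralMatrix"))
  header <- paste(c("sample_id", "replicate_id", .fmtNum(x@wavenumbers)),
                  collapse = ",")
  n <- nrow(x@intensities)
  rows <- character(n)
  if (n > 0) {
    vals <- matrix(.fmtNum(x@intensities), nrow = n)
    rows <- paste(x@sampleIds, x@replicateIds,
                  apply(vals, 1L, paste, collapse = ","), sep = ",")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

# ---- property CSV ---------------------------------------------------------

#' Read a property table CSV
#'
#' The header must contain `sample_id` plus a subset of the ten canonical
#' property names (see [honeyProperties()]); unknown columns and duplicate
#' sample ids are rejected.
#'
#' @param path file path
#' @return data.frame with `sample_id` plus one numeric column per property
#' @export
readPropertyCSV <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = "sample_id"))
  .validatePropertyTable(dt, context = sprintf("property CSV %s", path))
}

#' Write a property table CSV
#'
#' @param tab validated property data.frame (`sample_id` + canonical
#'   property columns)
#' @param path output file path
#' @return `path`, invisibly
#' @export
writePropertyCSV <- function(tab, path) {
  tab <- .validatePropertyTable(tab)
  propCols <- setdiff(names(tab), "sample_id")
  header <- paste(c("sample_id", propCols), collapse = ",")
  rows <- character(nrow(tab))
  if (nrow(tab)) {
    vals <- vapply(propCols, function(pc) .fmtNum(tab[[pc]]),
                   character(nrow(tab)))
    vals <- matrix(vals, nrow = nrow(tab))
    rows <- paste(tab$sample_id,
                  apply(vals, 1L, paste, collapse = ","), sep = ",")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

# ---- trimming -------------------------------------------------------------

#' Trim a spectral matrix to a wavenumber window
#'
#' Retains exactly the grid points with `lo <= w <= hi` (closed interval on
#' both ends — the conservative reading of a stated working range such as
#' 201-2000 cm-1). Row order and labels are preserved.
#'
#' @param x a [SpectralMatrix-class]
#' @param lo,hi window bounds in cm-1, `lo < hi`
#' @return the trimmed [SpectralMatrix-class]
#' @export
trimToWindow <- function(x, lo = 201, hi = 2000) {
  stopifnot(is(x, "SpectralMatrix"))
  if (!(lo < hi)) .stopf("trimToWindow: lo (%g) must be < hi (%g)", lo, hi)
  keep <- x@wavenumbers >= lo & x@wavenumbers <= hi
  if (sum(keep) < 2L)
    .stopf("trimToWindow: window [%g, %g] retains %d grid point(s); need >= 2",
           lo, hi, sum(keep))
  SpectralMatrix(x@intensities[, keep, drop = FALSE], x@wavenumbers[keep],
                 x@sampleIds, x@replicateIds)
}
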