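# Synthetic honey Raman dataset generator.
#
# The generator emulates the statistical structure the calibration pipeline
# assumes: a shared set of Gaussian Raman bands whose amplitudes respond
# linearly to standardized property values, a gentle per-sample polynomial
# baseline (fluorescence-like background), additive detector noise, a
# per-replicate intensity offset, and a small random integer grid
# misalignment per replicate. Band-property couplings are chosen so that
# moisture, the acidities, Redox potential and TSS are strongly encoded
# while HMF and especially ash are nearly buried in noise, mirroring the
# predictability ordering reported for real multifloral honey.

#' Default per-municipality sample counts
#'
#' The documented default composition of a 189-sample honey survey across
#' the eight producing municipalities of Campeche. Used as the default
#' `nSamples` total and available for labeling; the pooled property
#' distributions (see [honeyPropertyDefaults()]) do not differ by
#' municipality.
#'
#' @return named integer vector summing to 189
#' @export
honeyMunicipalityCounts <- function() {
  c(Calakmul = 40L, Calkini = 14L, Campeche = 26L, Champoton = 34L,
    Escarcega = 20L, Hecelchakan = 4L, Hopelchen = 22L, Sabancuy = 29L)
}

#' Default pooled property distributions
#'
#' Truncated-normal parameters per property: the mean is the average of the
#' municipal means of the source survey, the sd the average municipal sd,
#' and min/max the envelope over municipalities. `total_acidity` and `TSS`
#' rows are kept for reference, but the generator derives those two
#' properties (total = free + lactonic; TSS = 100 - moisture + jitter)
#' rather than sampling them.
#'
#' @return data.frame with columns property, mean, sd, min, max
#' @export
honeyPropertyDefaults <- function() {
  data.frame(
    property = c("pH", "moisture", "TSS", "free_acidity", "lactonic_acidity",
                 "total_acidity", "electrical_conductivity",
                 "redox_potential", "HMF", "ash"),
    mean = c(4.009, 15.166, 84.561, 19.894, 3.376, 23.273, 0.570,
             176.521, 2.754, 0.137),
    sd   = c(0.195, 2.093, 1.940, 4.394, 1.049, 4.850, 0.081,
             12.300, 0.993, 0.050),
    min  = c(3.49, 11.81, 74.20, 6.50, 1.23, 10.41, 0.28, 105.6, 1.27, 0.018),
    max  = c(5.20, 25.81, 88.19, 35.10, 9.45, 38.28, 0.755, 207.4,
             6.39, 0.88),
    stringsAsFactors = FALSE
  )
}

#' Default Raman band catalog with band-property couplings
#'
#' Gaussian bands centered at the midpoints of the vibrational assignments
#' of honey Raman spectra (sugar skeleton C-O/C-C-O/C-C-C modes below
#' 600 cm-1, unsaturated-ring modes of HMF and phenolics near 640 cm-1,
#' glucose C-C/C-H near 800 cm-1, the dominant C-H/C-O-H sugar envelope
#' around 920 cm-1, protein/carbohydrate C-O-C and C-N modes near
#' 1140 cm-1, CH/OH bending near 1380-1490 cm-1 and carbonyl/water modes
#' near 1815 cm-1). Each band may carry a coupling coefficient (a.u. per
#' standardized property unit) toward one or more properties; amplitudes
#' respond linearly, and band assignments are disjoint across properties so
#' every property has its own spectral signature.
#'
#' Coupling magnitudes were set by a matched-filter signal-to-noise
#' argument (see the package vignette): with the default noise of
#' 0.02 a.u. per point, the strongly coupled properties (moisture, the
#' acidities, Redox potential, TSS) have per-spectrum SNR well above 20,
#' pH and electrical conductivity sit near SNR 2 (acceptable but imperfect
#' models), HMF near 1.4, and ash near 0.6 — the weakest signal of the ten.
#'
#' @return data.frame: center, width (Gaussian sigma, cm-1), baseAmplitude
#'   (a.u.) and one `coupling_<property>` column per property
#' @export
honeyBandCatalog <- function() {
  bd <- data.frame(
    center = c(367, 422, 475, 552.5, 643, 721.5, 795, 922, 1059,
               1142.5, 1226.5, 1281, 1380, 1485, 1815),
    width = c(18.5, 9, 17.5, 21, 24, 15, 12.5, 35, 17.5,
              24, 17.75, 9.5, 40, 42, 32),
    baseAmplitude = c(1.1, 0.6, 0.7, 1.1, 0.45, 0.8, 0.9, 2.0, 1.3,
                      1.0, 0.9, 0.6, 0.9, 1.2, 0.8),
    stringsAsFactors = FALSE
  )
  for (p in honeyProperties()$name) bd[[paste0("coupling_", p)]] <- 0
  cpl <- function(center, prop, value)
    bd[[paste0("coupling_", prop)]][match(center, bd$center)] <<- value
  cpl(367,    "free_acidity", 0.30); cpl(721.5, "free_acidity", 0.20)
  cpl(1226.5, "lactonic_acidity", 0.25)
  cpl(475,    "total_acidity", 0.10)
  cpl(552.5,  "redox_potential", 0.30); cpl(1281, "redox_potential", 0.15)
  cpl(1485,   "moisture", 0.30); cpl(1815, "moisture", 0.20)
  cpl(922,    "TSS", 0.30); cpl(795, "TSS", 0.15)
  cpl(422,    "pH", 0.010); cpl(1059, "pH", 0.007)
  cpl(1142.5, "electrical_conductivity", 0.010)
  cpl(643,    "HMF", 0.006)
  cpl(1380,   "ash", 0.002)
  bd
}

#' Build a synthetic dataset configuration
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 189 samples measured in triplicate on a 900-point grid spanning
#' 201-2000 cm-1, pooled property distributions from
#' [honeyPropertyDefaults()], the band catalog of [honeyBandCatalog()],
#' additive noise of 0.02 a.u., a 0.02 a.u. replicate offset, and up to 2
#' grid points of replicate misalignment. `scenario = "noiseless"` zeroes
#' every stochastic nuisance term (noise, replicate jitter, shifts,
#' baseline) so spectra are an exactly linear function of the standardized
#' properties — the regime in which the pipeline must recover every
#' property perfectly.
#'
#' @param nSamples number of physical samples
#' @param nReplicates spectra per sample
#' @param gridPoints,gridRange wavenumber grid specification (uniform)
#' @param propertyDistributions data.frame as [honeyPropertyDefaults()]
#' @param bands data.frame as [honeyBandCatalog()]
#' @param baselineRanges 2 x k matrix of lower/upper bounds for the k
#'   baseline polynomial coefficients (constant term first; the polynomial
#'   argument is the grid rescaled to 0..1)
#' @param noiseSd additive per-point noise sd (a.u.)
#' @param replicateSd per-replicate intensity offset sd (a.u.)
#' @param shiftMax maximum absolute replicate grid shift (grid points)
#' @param tssJitterSd sd of the jitter on TSS = 100 - moisture (%)
#' @param seed root seed; all draws flow from it via named substreams
#' @param scenario `"default"` or `"noiseless"`
#' @return a [SyntheticConfig-class]
#' @export
syntheticConfig <- function(nSamples = 189L,
                            nReplicates = 3L,
                            gridPoints = 900L,
                            gridRange = c(201, 2000),
                            propertyDistributions = honeyPropertyDefaults(),
                            bands = honeyBandCatalog(),
                            baselineRanges = rbind(lower = c(0, -0.3, -0.2, -0.2),
                                                   upper = c(0.5, 0.3, 0.2, 0.2)),
                            noiseSd = 0.02,
                            replicateSd = 0.02,
                            shiftMax = 2L,
                            tssJitterSd = 0.3,
                            seed = 20191113L,
                            scenario = c("default", "noiseless")) {
  scenario <- match.arg(scenario)
  if (scenario == "noiseless") {
    noiseSd <- 0
    replicateSd <- 0
    shiftMax <- 0L
    baselineRanges <- rbind(lower = 0, upper = 0)
    tssJitterSd <- 0
  }
  cfg <- new("SyntheticConfig",
      nSamples = as.integer(nSamples),
      nReplicates = as.integer(nReplicates),
      wavenumbers = seq(gridRange[1], gridRange[2],
                        length.out = as.integer(gridPoints)),
      propertyDistributions = propertyDistributions,
      bands = bands,
      baselineRanges = baselineRanges,
      noiseSd = noiseSd, replicateSd = replicateSd,
      shiftMax = as.integer(shiftMax), seed = as.integer(seed))
  attr(cfg@propertyDistributions, "tssJitterSd") <- tssJitterSd
  cfg
}

# truncated-normal draw by clipping (documented choice: clipping rather
# than resampling keeps every draw a deterministic function of its
# substream position)
.rtruncClip <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic property table
#'
#' Independent truncated-normal draws per property, except for the two
#' structural constraints of honey composition: `total_acidity` is the sum
#' of free and lactonic acidity, and `TSS` is `100 - moisture` plus a small
#' jitter (sugars and water are near-complementary). Deterministic under a
#' fixed config seed.
#'
#' @param config a [SyntheticConfig-class]
#' @return data.frame: `sample_id` plus the ten property columns
#' @export
generatePropertyTable <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  n <- config@nSamples
  pd <- config@propertyDistributions
  tab <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  drawn <- setdiff(pd$property, c("total_acidity", "TSS"))
  for (p in drawn) {
    row <- pd[pd$property == p, ]
    tab[[p]] <- .withSeed(.subSeed(config@seed, paste0("property:", p)),
                          function()
                            .rtruncClip(n, row$mean, row$sd, row$min, row$max))
  }
  jsd <- attr(pd, "tssJitterSd") %||% 0.3
  tab$TSS <- 100 - tab$moisture +
    .withSeed(.subSeed(config@seed, "property:TSS_jitter"),
              function() rnorm(n, 0, jsd))
  tab$total_acidity <- tab$free_acidity + tab$lactonic_acidity
  tab[, c("sample_id", honeyProperties()$name)]
}

#' Generate synthetic Raman spectra for a property table
#'
#' For each sample the noise-free spectrum is
#' `sum_b A_b * exp(-(w - center_b)^2 / (2 width_b^2)) + baseline(w)` with
#' `A_b = baseAmplitude_b + sum_props coupling_bp * z_p`, where `z_p` is
#' the property standardized over the table (so coupling magnitudes are
#' comparable across properties). Each replicate re-draws additive noise,
#' a constant intensity offset, and an integer grid shift of at most
#' `shiftMax` points (edge values extended). Rows are ordered sample-major
#' (all replicates of sample 1, then sample 2, ...).
#'
#' @param properties property data.frame (from [generatePropertyTable()] or
#'   [readPropertyCSV()]); must contain every property named by a nonzero
#'   band coupling
#' @param config a [SyntheticConfig-class]
#' @return a [SpectralMatrix-class] with
#'   `nrow(properties) * config@nReplicates` rows
#' @export
generateSpectra <- function(properties, config) {
  stopifnot(is(config, "SyntheticConfig"))
  if (!is.data.frame(properties) || nrow(properties) == 0L)
    .stopf("generateSpectra: properties must be a non-empty data.frame")
  bd <- config@bands
  w <- config@wavenumbers
  npt <- length(w)
  n <- nrow(properties)
  nrep <- config@nReplicates
  cplCols <- grep("^coupling_", names(bd), value = TRUE)
  cplProps <- sub("^coupling_", "", cplCols)
  active <- cplCols[vapply(cplCols, function(cc) any(bd[[cc]] != 0), TRUE)]
  missing <- setdiff(sub("^coupling_", "", active), names(properties))
  if (length(missing))
    .stopf("generateSpectra: coupled propert%s absent from table: %s",
           if (length(missing) > 1) "ies" else "y",
           paste(missing, collapse = ", "))

  # standardized property values (z-scores over the supplied table)
  z <- matrix(0, n, length(cplProps), dimnames = list(NULL, cplProps))
  for (p in intersect(cplProps, names(properties))) {
    v <- properties[[p]]
    s <- stats::sd(v)
    z[, p] <- if (n > 1L && s > 0) (v - mean(v)) / s else 0
  }

  # band amplitudes per sample: n x nBands
  C <- as.matrix(bd[, cplCols, drop = FALSE])      # nBands x nProps
  A <- matrix(rep(bd$baseAmplitude, each = n), n) +
    z[, cplProps, drop = FALSE] %*% t(C)
  # band profiles: nBands x npt
  G <- t(vapply(seq_len(nrow(bd)), function(b)
    exp(-(w - bd$center[b])^2 / (2 * bd$width[b]^2)), numeric(npt)))
  clean <- A %*% G                                  # n x npt

  # per-sample polynomial baseline on u = (w - min) / range in [0, 1]
  k <- ncol(config@baselineRanges)
  u <- (w - w[1]) / (w[npt] - w[1])
  U <- t(vapply(seq_len(k), function(j) u^(j - 1), numeric(npt)))  # k x npt
  coefs <- .withSeed(.subSeed(config@seed, "baseline"), function()
    matrix(runif(n * k, rep(config@baselineRanges[1, ], each = n),
                 rep(config@baselineRanges[2, ], each = n)), n, k))
  clean <- clean + coefs %*% U

  nrow_total <- n * nrep
  out <- clean[rep(seq_len(n), each = nrep), , drop = FALSE]

  shifts <- .withSeed(.subSeed(config@seed, "shifts"), function()
    if (config@shiftMax > 0L)
      sample(seq(-config@shiftMax, config@shiftMax), nrow_total,
             replace = TRUE)
    else rep(0L, nrow_total))
  if (any(shifts != 0L)) {
    idx <- seq_len(npt)
    for (r in which(shifts != 0L)) {
      src <- pmin(pmax(idx - shifts[r], 1L), npt)  # edge-extended shift
      out[r, ] <- out[r, src]
    }
  }

  offs <- .withSeed(.subSeed(config@seed, "replicate_offsets"), function()
    rnorm(nrow_total, 0, config@replicateSd))
  out <- out + offs
  if (config@noiseSd > 0) {
    out <- out + .withSeed(.subSeed(config@seed, "noise"), function()
      matrix(rnorm(nrow_total * npt, 0, config@noiseSd), nrow_total, npt))
  }

  SpectralMatrix(out, w,
                 sampleIds = rep(properties$sample_id, each = nrep),
                 replicateIds = rep(seq_len(nrep), times = n))
}

#' Generate a matched property table and spectra in one call
#'
#' @param config a [SyntheticConfig-class]
#' @return list with elements `properties` (data.frame) and `spectra`
#'   ([SpectralMatrix-class])
#' @export
simulateHoneyDataset <- function(config = syntheticConfig()) {
  props <- generatePropertyTable(config)
  list(properties = props, spectra = generateSpectra(props, config))
}
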