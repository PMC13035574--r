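# Physiological index maps. The four indices (StO2, NIR-PI, TWI, OHI) are
# band-mean absorbance ratios on the RAW reflectance cube (SNV destroys the
# absolute scale the ratios need), min-max clamped through a per-index
# scaling interval to [0, 1]. The scaling floors equal each index's
# absorber-free scatter-baseline ratio on the default wavelength grid, so a
# tissue with no chromophores maps to 0; the ceilings are set beyond the
# physiological extremes so ordering information is never saturated away.

#' Band-ratio index configuration
#'
#' @param name Index name, one of `"StO2"`, `"NIR-PI"`, `"TWI"`, `"OHI"`.
#' @param numerator_band,denominator_band Wavelength windows `c(lo, hi)`
#'   in nm.
#' @param scaling Interval `c(lo, hi)` the raw absorbance ratio is min-max
#'   clamped through.
#' @return An object of class `index_band_config`.
#' @export
index_band_config <- function(name, numerator_band, denominator_band,
                              scaling) {
  stopifnot(is.character(name), length(numerator_band) == 2,
            length(denominator_band) == 2, length(scaling) == 2,
            numerator_band[1] < numerator_band[2],
            denominator_band[1] < denominator_band[2],
            scaling[1] < scaling[2])
  structure(list(name = name, numerator_band = numerator_band,
                 denominator_band = denominator_band, scaling = scaling),
            class = "index_band_config")
}

#' Default index definitions
#'
#' Window defaults follow the established camera-side convention for the
#' four tissue indices: oxygenation contrasts the 570-590 nm oxyhemoglobin
#' band against the 740-780 nm deoxyhemoglobin band; the NIR perfusion
#' index contrasts deep-penetrating 825-925 nm absorbance against
#' 655-735 nm; the hemoglobin index contrasts the 530-590 nm hemoglobin
#' bands against a 785-825 nm reference; the water index contrasts the
#' 955-980 nm water band against an 880-900 nm reference.
#'
#' @return Named list of [index_band_config()] objects.
#' @export
default_index_configs <- function() {
  list(
    `StO2`   = index_band_config("StO2",  c(570, 590), c(740, 780),
                                 c(0.3473, 4.0)),
    `NIR-PI` = index_band_config("NIR-PI", c(825, 925), c(655, 735),
                                 c(1.7092, 4.0)),
    `TWI`    = index_band_config("TWI",   c(955, 980), c(880, 900),
                                 c(1.1456, 3.5)),
    `OHI`    = index_band_config("OHI",   c(530, 590), c(785, 825),
                                 c(0.2295, 4.5))
  )
}

#' Reflectance to absorbance
#'
#' `A = -log10(max(R, floor))`; the floor guard keeps the transform finite
#' at zero reflectance.
#'
#' @param cube A [hypercube()].
#' @param floor Positive reflectance floor (default `1e-4`).
#' @return List with `absorbance` (H x W x B array) and `wavelengths`.
#' @export
reflectance_to_absorbance <- function(cube, floor = 1e-4) {
  stopifnot(inherits(cube, "hypercube"), floor > 0)
  list(absorbance = -log10(pmax(cube$reflectance, floor)),
       wavelengths = cube$wavelengths)
}

#' Compute one band-ratio index map
#'
#' Per pixel: mean absorbance over the numerator window divided by mean
#' absorbance over the denominator window, min-max clamped through the
#' scaling interval into `[0, 1]`. Pixels whose denominator mean falls
#' below `denom_tol` are flagged invalid (NA in the map).
#'
#' @param absorbance Output of [reflectance_to_absorbance()].
#' @param config An [index_band_config()].
#' @param denom_tol Invalid-pixel threshold on the denominator mean.
#' @return List with `map` (H x W, values in `[0, 1]` or NA) and `valid`
#'   (logical H x W).
#' @export
band_ratio_index <- function(absorbance, config, denom_tol = 1e-6) {
  stopifnot(inherits(config, "index_band_config"))
  wl <- absorbance$wavelengths
  num_sel <- wl >= config$numerator_band[1] & wl <= config$numerator_band[2]
  den_sel <- wl >= config$denominator_band[1] &
    wl <= config$denominator_band[2]
  if (!any(num_sel) || !any(den_sel))
    stop("range error: index '", config$name,
         "' has an empty band selection on this wavelength grid")
  d <- dim(absorbance$absorbance)
  m <- matrix(absorbance$absorbance, d[1] * d[2], d[3])
  num <- rowMeans(m[, num_sel, drop = FALSE])
  den <- rowMeans(m[, den_sel, drop = FALSE])
  valid <- den >= denom_tol
  ratio <- ifelse(valid, num / pmax(den, denom_tol), NA_real_)
  sc <- config$scaling
  scaled <- pmin(1, pmax(0, (ratio - sc[1]) / (sc[2] - sc[1])))
  list(map = matrix(scaled, d[1], d[2]),
       valid = matrix(valid, d[1], d[2]))
}

#' Compute the four physiological index maps
#'
#' Applies the four default band-ratio indices to a raw (non-SNV)
#' reflectance cube. Index maps branch off before SNV normalization and
#' are therefore invariant to the preprocessing configuration.
#'
#' @param cube A raw reflectance [hypercube()] covering the index windows.
#' @param configs Index definitions (default [default_index_configs()]).
#' @param floor Reflectance floor for the absorbance transform.
#' @param denom_tol Invalid-pixel threshold on denominator absorbance.
#' @return An object of class `physio_maps`: list with `maps` (named list
#'   of H x W matrices in `[0, 1]`), `valid` (logical H x W, conjunction of
#'   all per-index validity), `patient_id`.
#' @export
compute_physio_maps <- function(cube, configs = default_index_configs(),
                                floor = 1e-4, denom_tol = 1e-6) {
  stopifnot(inherits(cube, "hypercube"))
  absorb <- reflectance_to_absorbance(cube, floor)
  res <- lapply(configs, band_ratio_index, absorbance = absorb,
                denom_tol = denom_tol)
  valid <- Reduce(`&`, lapply(res, `[[`, "valid"))
  structure(list(maps = lapply(res, `[[`, "map"), valid = valid,
                 patient_id = cube$patient_id),
            class = "physio_maps")
}

#' Summarize index maps over annotated regions
#'
#' One row per (patient, tissue class, index): the mean index value over
#' the region's valid pixels. Empty or all-invalid regions are skipped
#' with a warning.
#'
#' @param maps A `physio_maps` object from [compute_physio_maps()].
#' @param mask Annotation mask aligned with the maps.
#' @param patient_id Patient identifier for the output rows.
#' @param tumor_stage Stage label (`"T1"`..`"T4"` or NA).
#' @return Data frame with columns `patient_id`, `tissue_class`,
#'   `tumor_stage`, `index`, `mean_value`, `n_pixels`.
#' @export
summarize_regions <- function(maps, mask, patient_id = maps$patient_id,
                              tumor_stage = NA_character_) {
  stopifnot(inherits(maps, "physio_maps"))
  mask <- validate_mask(mask)
  if (!identical(dim(mask), dim(maps$valid)))
    stop("shape error: mask does not align with the index maps")
  rows <- list()
  for (k in seq_along(tissue_classes())) {
    sel <- mask == k & maps$valid
    if (!any(mask == k)) next
    if (!any(sel)) {
      warning("region '", tissue_classes()[k], "' of patient ", patient_id,
              " has no valid pixels; skipped")
      next
    }
    for (idx in names(maps$maps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, tissue_class = tissue_classes()[k],
        tumor_stage = tumor_stage, index = idx,
        mean_value = mean(maps$maps[[idx]][sel]),
        n_pixels = sum(sel), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), tissue_class = character(),
                      tumor_stage = character(), index = character(),
                      mean_value = numeric(), n_pixels = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Region summaries for a whole cohort
#'
#' @param cohort A `phantom_cohort`.
#' @param ... Passed to [compute_physio_maps()].
#' @return Row-bound [summarize_regions()] output for every patient.
#' @export
summarize_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  do.call(rbind, lapply(cohort, function(p) {
    maps <- compute_physio_maps(p$cube, ...)
    summarize_regions(maps, p$mask, p$patient_id, p$stage)
  }))
}

#' Export index maps as grayscale PNGs
#'
#' @param maps A `physio_maps` object.
#' @param dir Output directory.
#' @return Vector of file paths, invisibly.
#' @export
write_physio_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "physio_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps$maps), function(nm) {
    m <- maps$maps[[nm]]
    m[is.na(m)] <- 0
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "", nm), ".png"))
    png::writePNG(m, target = path)
    path
  }, "")
  invisible(paths)
}
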