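# Spectral preprocessing: median smoothing along the spectral axis,
# standard normal variate (SNV) normalization per pixel spectrum, and
# wavelength cropping. The pipeline order is fixed: median filter, then
# SNV, then crop.

#' Preprocessing configuration
#'
#' @param median_kernel Odd spectral-axis window of the median filter
#'   (default 5, the smallest kernel that removes single- and double-band
#'   spikes).
#' @param snv_epsilon Spectra with sample SD below this map to the all-zero
#'   spectrum instead of dividing by ~0 (keeps fully shadowed pixels from
#'   aborting a run).
#' @param crop_lo,crop_hi Closed wavelength interval retained after
#'   normalization, in nm. The default drops the noisy bands below 520 nm.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(median_kernel = 5, snv_epsilon = 1e-8,
                              crop_lo = 520, crop_hi = 1000) {
  if (median_kernel < 1 || median_kernel %% 2 != 1)
    stop("parameter error: median_kernel must be an odd integer >= 1")
  stopifnot(snv_epsilon > 0, crop_lo < crop_hi)
  structure(list(median_kernel = as.integer(median_kernel),
                 snv_epsilon = snv_epsilon,
                 crop_lo = crop_lo, crop_hi = crop_hi),
            class = "preprocess_config")
}

# Row-wise sorting network over a list of equal-length vectors; returns the
# element-wise median. Exact for small odd k and fully vectorized.
.row_median_k <- function(cols) {
  k <- length(cols)
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1]])
      hi <- pmax(cols[[j]], cols[[j + 1]])
      cols[[j]] <- lo
      cols[[j + 1]] <- hi
    }
  }
  cols[[(k + 1) / 2]]
}

# Median-filter every row of a spectra matrix (rows = pixels, cols = bands)
# with symmetric (edge-inclusive) reflection padding.
.median_filter_rows <- function(m, kernel) {
  if (kernel == 1) return(m)
  b <- ncol(m)
  if (kernel > b)
    stop("parameter error: kernel exceeds spectrum length")
  h <- (kernel - 1) / 2
  padded <- cbind(m[, h:1, drop = FALSE], m, m[, b:(b - h + 1), drop = FALSE])
  out <- m
  for (j in seq_len(b)) {
    cols <- lapply(seq_len(kernel), function(d) padded[, j + d - 1])
    out[, j] <- .row_median_k(cols)
  }
  out
}

#' Median-filter a single spectrum
#'
#' Each band is replaced by the median of its `kernel`-wide spectral
#' window; the spectrum is reflect-padded (edge value included in the
#' mirror) so the length is preserved.
#'
#' @param spectrum Numeric vector.
#' @param kernel Odd window width, at most the spectrum length.
#' @return Filtered spectrum of the same length.
#' @examples
#' median_filter_spectrum(c(1, 9, 1, 1, 1), 3)  # spike removed
#' @export
median_filter_spectrum <- function(spectrum, kernel) {
  if (kernel %% 2 != 1 || kernel < 1)
    stop("parameter error: kernel must be odd and >= 1")
  drop(.median_filter_rows(matrix(spectrum, nrow = 1), kernel))
}

# SNV over matrix rows; sample SD (n - 1); degenerate rows -> 0.
.snv_rows <- function(m, epsilon = 1e-8) {
  b <- ncol(m)
  mu <- rowMeans(m)
  centered <- m - mu
  sdev <- sqrt(rowSums(centered^2) / (b - 1))
  degenerate <- sdev < epsilon
  sdev[degenerate] <- 1
  out <- centered / sdev
  out[degenerate, ] <- 0
  out
}

#' Standard normal variate normalization of a spectrum
#'
#' `(x - mean(x)) / sd(x)` with the sample SD (`n - 1`). Spectra whose SD
#' falls below `epsilon` return the all-zero spectrum.
#'
#' @param spectrum Numeric vector of length >= 2, finite.
#' @param epsilon Degeneracy guard.
#' @return Normalized spectrum with mean 0 and sample SD 1 (unless
#'   degenerate).
#' @examples
#' snv_normalize(c(1, 2, 3))
#' @export
snv_normalize <- function(spectrum, epsilon = 1e-8) {
  if (length(spectrum) < 2)
    stop("parameter error: SNV needs a spectrum of length >= 2")
  if (!all(is.finite(spectrum)))
    stop("parameter error: spectrum must be finite")
  drop(.snv_rows(matrix(spectrum, nrow = 1), epsilon))
}

#' Crop a cube to a closed wavelength interval
#'
#' Keeps exactly the bands with `lo <= lambda <= hi`.
#'
#' @param cube A [hypercube()].
#' @param lo,hi Interval bounds in nm.
#' @return The cropped [hypercube()].
#' @export
crop_wavelengths <- function(cube, lo = 520, hi = 1000) {
  stopifnot(inherits(cube, "hypercube"))
  keep <- cube$wavelengths >= lo & cube$wavelengths <= hi
  if (!any(keep))
    stop("range error: no bands inside [", lo, ", ", hi, "] nm")
  hypercube(cube$reflectance[, , keep, drop = FALSE],
            cube$wavelengths[keep], cube$patient_id)
}

#' Preprocess a cube for classification
#'
#' Applies, in fixed order: the spectral median filter per pixel spectrum,
#' SNV per pixel spectrum, and the wavelength crop. SNV precedes the crop,
#' so the normalization moments are taken over the full recorded range.
#' SNV output is no longer non-negative, so the result is returned as a
#' plain cube-shaped structure (class `hypercube` invariants on
#' non-negativity do not apply); downstream classification consumes it
#' directly.
#'
#' @param cube A raw reflectance [hypercube()].
#' @param config A [preprocess_config()].
#' @return A list with the same layout as a [hypercube()] (fields
#'   `reflectance`, `wavelengths`, `patient_id`), class
#'   `preprocessed_cube`.
#' @export
preprocess_cube <- function(cube, config = preprocess_config()) {
  stopifnot(inherits(cube, "hypercube"),
            inherits(config, "preprocess_config"))
  d <- dim(cube$reflectance)
  m <- matrix(cube$reflectance, d[1] * d[2], d[3])
  m <- .median_filter_rows(m, config$median_kernel)
  m <- .snv_rows(m, config$snv_epsilon)
  keep <- cube$wavelengths >= config$crop_lo &
    cube$wavelengths <= config$crop_hi
  if (!any(keep))
    stop("range error: crop interval retains no bands")
  m <- m[, keep, drop = FALSE]
  structure(list(reflectance = array(m, c(d[1], d[2], sum(keep))),
                 wavelengths = cube$wavelengths[keep],
                 patient_id = cube$patient_id),
            class = "preprocessed_cube")
}
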