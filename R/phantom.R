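#' @keywords internal
"_PACKAGE"

# ---- seeded evaluation -------------------------------------------------

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# ---- chromophore parameters --------------------------------------------

#' Chromophore parameters of a simulated tissue class
#'
#' Bundles the absorber and scatterer quantities that determine a tissue's
#' reflectance spectrum under the package's Beer-Lambert forward model:
#' hemoglobin oxygen saturation, total hemoglobin, water fraction, and a
#' power-law scattering background.
#'
#' @param oxy_hb_fraction Fraction of hemoglobin that is oxygenated, in
#'   `[0, 1]`.
#' @param total_hb Total hemoglobin concentration (arbitrary units, >= 0).
#' @param water_fraction Tissue water fraction, in `[0, 1]`.
#' @param scatter_amplitude Scattering amplitude at 500 nm (>= 0).
#' @param scatter_slope Power-law exponent of the scattering background.
#' @return An object of class `chromophore_params`.
#' @examples
#' chromophore_params(oxy_hb_fraction = 0.7, total_hb = 1.2,
#'                    water_fraction = 0.5)
#' @export
chromophore_params <- function(oxy_hb_fraction = 0.6, total_hb = 1,
                               water_fraction = 0.4, scatter_amplitude = 1,
                               scatter_slope = 1) {
  vals <- c(oxy_hb_fraction, total_hb, water_fraction,
            scatter_amplitude, scatter_slope)
  if (!all(is.finite(vals)))
    stop("invalid-parameter: chromophore parameters must be finite")
  if (oxy_hb_fraction < 0 || oxy_hb_fraction > 1)
    stop("invalid-parameter: oxy_hb_fraction must be in [0, 1]")
  if (water_fraction < 0 || water_fraction > 1)
    stop("invalid-parameter: water_fraction must be in [0, 1]")
  if (total_hb < 0 || scatter_amplitude < 0)
    stop("invalid-parameter: total_hb and scatter_amplitude must be >= 0")
  structure(list(oxy_hb_fraction = oxy_hb_fraction, total_hb = total_hb,
                 water_fraction = water_fraction,
                 scatter_amplitude = scatter_amplitude,
                 scatter_slope = scatter_slope),
            class = "chromophore_params")
}

#' Default chromophore parameters per tissue class
#'
#' Cancer is parameterized with higher hemoglobin, water, and oxygen
#' saturation than the two healthy mucosa classes, mirroring the
#' angiogenesis/edema physiology that distinguishes tumors on index maps.
#'
#' @return Named list of [chromophore_params()] for `esophagus`, `stomach`
#'   and `cancer`.
#' @export
default_class_params <- function() {
  list(
    esophagus = chromophore_params(0.55, 0.8, 0.35, 1.00, 0.9),
    stomach   = chromophore_params(0.65, 1.1, 0.45, 0.97, 1.1),
    cancer    = chromophore_params(0.75, 1.4, 0.60, 0.99, 1.0)
  )
}

# Gaussian absorption bump
.gauss <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

# Synthetic extinction templates (unitless). Oxyhemoglobin: alpha/beta
# bands at 542/577 nm plus a broad NIR shoulder; deoxyhemoglobin: 555 nm
# band and the 760 nm NIR peak; water: dominant 970 nm band plus a minor
# 740 nm overtone.
.eps_oxy <- function(wl) {
  1.0 * .gauss(wl, 542, 12) + 1.1 * .gauss(wl, 577, 12) +
    0.45 * .gauss(wl, 850, 25)
}
.eps_deoxy <- function(wl) {
  0.9 * .gauss(wl, 555, 14) + 0.45 * .gauss(wl, 760, 28)
}
.eps_water <- function(wl) {
  1.0 * .gauss(wl, 970, 38) + 0.2 * .gauss(wl, 740, 30)
}

#' Reflectance spectrum of a chromophore parameter set
#'
#' Forward model `R(lambda) = S(lambda) * 10^(-A(lambda))` with total
#' absorbance
#' `A = total_hb * (f * eps_oxy + (1 - f) * eps_deoxy) + water * eps_water`
#' and scattering background
#' `S = scatter_amplitude * (lambda / 500)^(-scatter_slope)`.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, within
#'   `[400, 1100]`.
#' @param params A [chromophore_params()] object.
#' @return Reflectance vector of the same length as `wavelengths`.
#' @examples
#' wl <- seq(500, 1000, length.out = 100)
#' r <- reflectance_template(wl, chromophore_params())
#' @export
reflectance_template <- function(wavelengths, params) {
  stopifnot(inherits(params, "chromophore_params"))
  if (!all(is.finite(wavelengths)))
    stop("invalid-parameter: wavelengths must be finite")
  if (any(wavelengths < 400 | wavelengths > 1100))
    stop("invalid-parameter: wavelengths must lie within [400, 1100] nm")
  a <- params$total_hb *
    (params$oxy_hb_fraction * .eps_oxy(wavelengths) +
       (1 - params$oxy_hb_fraction) * .eps_deoxy(wavelengths)) +
    params$water_fraction * .eps_water(wavelengths)
  s <- params$scatter_amplitude *
    (wavelengths / 500)^(-params$scatter_slope)
  s * 10^(-a)
}

# ---- phantom layout and spec -------------------------------------------

#' Three-region phantom layout
#'
#' Default annotation geometry: esophageal mucosa on the left, gastric
#' mucosa on the right of a vertical split, and a cancer ellipse straddling
#' the boundary. With the default split and radii the cancer region covers
#' about 7.5% of the image, reproducing the order-of-magnitude class
#' imbalance of a gastric-dominated clinical cohort.
#'
#' @param split_frac Column fraction of the esophagus/stomach boundary.
#' @param ellipse_center Ellipse center as `(row, col)` fractions.
#' @param ellipse_radii Ellipse semi-axes as `(row, col)` fractions.
#' @return A layout description list, class `phantom_layout`.
#' @export
phantom_layout <- function(split_frac = 0.4,
                           ellipse_center = c(0.5, 0.4),
                           ellipse_radii = c(0.155, 0.155)) {
  stopifnot(split_frac > 0, split_frac < 1,
            all(ellipse_radii > 0), length(ellipse_center) == 2,
            length(ellipse_radii) == 2)
  structure(list(split_frac = split_frac, ellipse_center = ellipse_center,
                 ellipse_radii = ellipse_radii),
            class = "phantom_layout")
}

# Rasterize a layout into an annotation mask (1 esophagus, 2 stomach,
# 3 cancer). Pixel centers are at integer coordinates.
layout_mask <- function(layout, height, width) {
  stopifnot(inherits(layout, "phantom_layout"))
  cc <- matrix(rep(seq_len(width), each = height), nrow = height)
  rr <- matrix(rep(seq_len(height), times = width), nrow = height)
  mask <- matrix(2L, height, width)
  mask[cc <= layout$split_frac * width] <- 1L
  cy <- layout$ellipse_center[1] * height
  cx <- layout$ellipse_center[2] * width
  ry <- layout$ellipse_radii[1] * height
  rx <- layout$ellipse_radii[2] * width
  inside <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
  mask[inside] <- 3L
  if (any(mask < 0L | mask > 3L))
    stop("layout error: layout does not cover the image with valid classes")
  mask
}

#' Phantom specification
#'
#' All knobs needed to generate one annotated synthetic patient: image size,
#' wavelength grid, per-class chromophore parameters, region layout,
#' per-pixel biological variability and sensor noise.
#'
#' @param height,width Image size in pixels.
#' @param wavelengths Wavelength grid in nm (strictly increasing). Default:
#'   100 evenly spaced bands on `[500, 1000]`, the resolution of the target
#'   camera system.
#' @param class_params Named list of [chromophore_params()] for
#'   `esophagus`, `stomach`, `cancer`.
#' @param layout A [phantom_layout()].
#' @param pixel_jitter_sd Log-scale SD of the per-pixel multiplicative
#'   jitter applied to `total_hb` and `water_fraction` (models the large
#'   within-class spectral variance of real mucosa).
#' @param noise_sd SD of additive Gaussian reflectance noise.
#' @param seed Integer seed; `(spec, seed)` fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64,
                         wavelengths = seq(500, 1000, length.out = 100),
                         class_params = default_class_params(),
                         layout = phantom_layout(),
                         pixel_jitter_sd = 0.15, noise_sd = 0.01,
                         seed = 1L) {
  if (any(diff(wavelengths) <= 0))
    stop("invalid-parameter: wavelengths must be strictly increasing")
  if (pixel_jitter_sd < 0 || noise_sd < 0)
    stop("invalid-parameter: SDs must be >= 0")
  stopifnot(height >= 1, width >= 1,
            all(c("esophagus", "stomach", "cancer") %in%
                  names(class_params)))
  for (p in class_params) stopifnot(inherits(p, "chromophore_params"))
  structure(list(height = as.integer(height), width = as.integer(width),
                 wavelengths = wavelengths, class_params = class_params,
                 layout = layout, pixel_jitter_sd = pixel_jitter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# ---- hypercube container ------------------------------------------------

#' Hyperspectral cube
#'
#' @param reflectance Numeric `H x W x B` array of non-negative reflectance.
#' @param wavelengths Strictly increasing wavelength vector of length `B`.
#' @param patient_id Optional patient identifier string.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(reflectance, wavelengths, patient_id = "") {
  if (length(dim(reflectance)) != 3L)
    stop("format error: reflectance must be an H x W x B array")
  if (!all(is.finite(reflectance)) || any(reflectance < 0))
    stop("format error: reflectance must be finite and >= 0")
  if (dim(reflectance)[3] != length(wavelengths))
    stop("format error: band count must equal length(wavelengths)")
  if (any(diff(wavelengths) <= 0))
    stop("format error: wavelengths must be strictly increasing")
  structure(list(reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths),
                 patient_id = as.character(patient_id)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (nzchar(x$patient_id))
                paste0(", patient ", x$patient_id) else ""))
  invisible(x)
}

#' Validate an annotation mask against a cube
#'
#' Annotation masks are integer matrices with values 0 (unlabeled),
#' 1 (esophagus), 2 (stomach), 3 (cancer).
#'
#' @param mask Integer matrix.
#' @param cube Optional [hypercube()] the mask must align with.
#' @return The mask, invisibly, as an integer matrix.
#' @export
validate_mask <- function(mask, cube = NULL) {
  if (!is.matrix(mask)) stop("format error: mask must be a matrix")
  if (!all(mask %in% 0:3))
    stop("enum error: mask values must be in {0, 1, 2, 3}")
  if (!is.null(cube) &&
      !identical(dim(mask), dim(cube$reflectance)[1:2]))
    stop("shape error: mask dimensions do not match the cube")
  invisible(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

#' Tissue class labels
#'
#' @return Character vector mapping label codes 1:3 to class names.
#' @export
tissue_classes <- function() c("esophagus", "stomach", "cancer")

# ---- phantom generation -------------------------------------------------

#' Generate one annotated phantom cube
#'
#' Every pixel receives the reflectance template of its class with
#' `total_hb` and `water_fraction` perturbed by multiplicative log-normal
#' jitter (water clipped to `[0, 1]`), plus additive Gaussian noise, clipped
#' to non-negative reflectance. The same spec and seed yield bit-identical
#' output.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Identifier stored in the cube.
#' @return List with elements `cube` ([hypercube()]) and `mask`
#'   (integer matrix).
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 16, width = 16, seed = 7))
#' table(ph$mask)
#' @export
generate_phantom <- function(spec, patient_id = "P01") {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  wl <- spec$wavelengths
  mask <- layout_mask(spec$layout, h, w)
  refl <- matrix(0, h * w, length(wl))
  with_seed(spec$seed, {
    for (k in seq_along(tissue_classes())) {
      idx <- which(mask == k)  # column-major order, fixed
      if (!length(idx)) next
      p <- spec$class_params[[tissue_classes()[k]]]
      n <- length(idx)
      if (spec$pixel_jitter_sd > 0) {
        hb <- p$total_hb * exp(stats::rnorm(n, 0, spec$pixel_jitter_sd))
        wf <- pmin(1, pmax(0, p$water_fraction *
                             exp(stats::rnorm(n, 0, spec$pixel_jitter_sd))))
      } else {
        hb <- rep(p$total_hb, n)
        wf <- rep(p$water_fraction, n)
      }
      hb_eps <- p$oxy_hb_fraction * .eps_oxy(wl) +
        (1 - p$oxy_hb_fraction) * .eps_deoxy(wl)
      a <- outer(hb, hb_eps) + outer(wf, .eps_water(wl))
      s <- p$scatter_amplitude * (wl / 500)^(-p$scatter_slope)
      refl[idx, ] <- 10^(-a) * rep(s, each = n)
    }
    if (spec$noise_sd > 0)
      refl <- refl + stats::rnorm(length(refl), 0, spec$noise_sd)
  })
  refl <- pmax(refl, 0)
  cube <- hypercube(array(refl, c(h, w, length(wl))), wl, patient_id)
  list(cube = cube, mask = mask)
}

#' Generate a phantom cohort with tumor-stage labels
#'
#' Draws per-patient variants of a base phantom spec (log-normal jitter of
#' each class's `total_hb` and `water_fraction`) and assigns tumor stages.
#' Patients staged T3/T4 receive an additive `water_fraction` increment in
#' all tissue classes, encoding the stage-dependent water content the
#' analysis is meant to recover.
#'
#' @param n_patients Number of patients (>= 5: leave-one-patient-out needs
#'   one test, three validation, and at least one training patient).
#' @param base_spec A [phantom_spec()] all patients are drawn around.
#' @param stage_assignment Optional character vector of stages in
#'   `{"T1","T2","T3","T4"}` (length `n_patients`); default cycles
#'   `T1, T3, T2, T4` so early and advanced stages are balanced.
#' @param seed Integer seed for the cohort draws.
#' @param patient_sd Log-scale SD of the per-patient parameter jitter.
#' @param stage_water_increment Water-fraction increment applied to T3/T4
#'   patients (all classes, clipped to 1).
#' @return An object of class `phantom_cohort`: a list of patients, each
#'   with `patient_id`, `cube`, `mask`, `params`, `stage`.
#' @export
generate_cohort <- function(n_patients = 8, base_spec = phantom_spec(),
                            stage_assignment = NULL, seed = 1L,
                            patient_sd = 0.1,
                            stage_water_increment = 0.15) {
  if (n_patients < 5)
    stop("cohort-size error: need at least 5 patients for LOPO")
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (is.null(stage_assignment))
    stage_assignment <- rep(c("T1", "T3", "T2", "T4"),
                            length.out = n_patients)
  stopifnot(length(stage_assignment) == n_patients,
            all(stage_assignment %in% c("T1", "T2", "T3", "T4")))
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    stage <- stage_assignment[i]
    params <- with_seed(seed + 7919L * i, {
      lapply(base_spec$class_params, function(p) {
        hb <- p$total_hb * exp(stats::rnorm(1, 0, patient_sd))
        wf <- p$water_fraction * exp(stats::rnorm(1, 0, patient_sd))
        if (stage %in% c("T3", "T4")) wf <- wf + stage_water_increment
        chromophore_params(p$oxy_hb_fraction, hb, min(1, max(0, wf)),
                           p$scatter_amplitude, p$scatter_slope)
      })
    })
    spec_i <- base_spec
    spec_i$class_params <- params
    spec_i$seed <- as.integer(seed + 104729L + i)
    pid <- sprintf("P%02d", i)
    ph <- generate_phantom(spec_i, patient_id = pid)
    patients[[i]] <- list(patient_id = pid, cube = ph$cube, mask = ph$mask,
                          params = params, stage = stage)
  }
  ids <- vapply(patients, `[[`, "", "patient_id")
  stopifnot(!anyDuplicated(ids))
  structure(patients, class = "phantom_cohort",
            seed = as.integer(seed))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, stages: %s\n", length(x),
              paste(vapply(x, `[[`, "", "stage"), collapse = " ")))
  invisible(x)
}
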