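# Shared fixtures: everything is generated in code at test time.

# Small wavelength grid that still covers all four index windows.
small_wavelengths <- function(n = 20) seq(500, 1000, length.out = n)

# A single-class "pixel" phantom: one chromophore parameter set evaluated
# on a grid, as a 1 x 1 x B cube.
param_cube <- function(params, wavelengths = seq(500, 1000,
                                                 length.out = 100)) {
  r <- reflectance_template(wavelengths, params)
  hypercube(array(r, c(1, 1, length(r))), wavelengths)
}

# Fast desk-scale cohort for pipeline tests.
tiny_cohort <- function(n_patients = 8, seed = 1, height = 12, width = 12,
                        n_bands = 20, stage_water_increment = 0.15,
                        noise_sd = 0.01) {
  generate_cohort(
    n_patients,
    phantom_spec(height = height, width = width,
                 wavelengths = small_wavelengths(n_bands),
                 noise_sd = noise_sd),
    seed = seed, stage_water_increment = stage_water_increment)
}

# Low-cost model configuration for training tests (small filters and
# short spectral kernels so 20-band fixtures fit the conv stack).
tiny_model_config <- function(...) {
  defaults <- list(patch_size = 1, conv3d_filters = c(4, 8),
                   conv3d_kernel = c(3, 3, 5), conv1d_filters = c(8, 16),
                   conv1d_kernel = 3, batch_size = 64, max_epochs = 10,
                   early_stop_patience = 3, seed = 1)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}
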