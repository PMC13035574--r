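test_that("reflectance template obeys the Beer-Lambert structure", {
  wl <- seq(500, 1000, length.out = 100)

  # no absorbers, flat unit scatter -> perfect reflector
  flat <- chromophore_params(oxy_hb_fraction = 0.5, total_hb = 0,
                             water_fraction = 0, scatter_amplitude = 1,
                             scatter_slope = 0)
  expect_equal(reflectance_template(wl, flat), rep(1, length(wl)))

  # wetter tissue absorbs more at the 970 nm water band
  dry <- chromophore_params(water_fraction = 0.2)
  wet <- chromophore_params(water_fraction = 0.8)
  expect_lt(reflectance_template(970, wet), reflectance_template(970, dry))

  # deoxygenated blood absorbs more at its 760 nm band: evaluate the
  # templates numerically at 760 nm
  oxy <- chromophore_params(oxy_hb_fraction = 1, total_hb = 1,
                            water_fraction = 0, scatter_amplitude = 1,
                            scatter_slope = 0)
  deoxy <- chromophore_params(oxy_hb_fraction = 0, total_hb = 1,
                              water_fraction = 0, scatter_amplitude = 1,
                              scatter_slope = 0)
  a760 <- function(p) -log10(reflectance_template(760, p))
  expect_gt(a760(deoxy), a760(oxy))

  expect_error(chromophore_params(total_hb = NaN), "invalid-parameter")
  expect_error(chromophore_params(oxy_hb_fraction = 1.2),
               "invalid-parameter")
  expect_error(reflectance_template(c(300, 600), chromophore_params()),
               "invalid-parameter")
})

test_that("phantom generation is deterministic and degenerates correctly", {
  spec0 <- phantom_spec(height = 12, width = 12,
                        wavelengths = small_wavelengths(),
                        pixel_jitter_sd = 0, noise_sd = 0, seed = 5)
  ph <- generate_phantom(spec0)
  # degenerate noise: every pixel of a class equals its template exactly
  for (k in 1:3) {
    tmpl <- reflectance_template(
      spec0$wavelengths, spec0$class_params[[tissue_classes()[k]]])
    idx <- which(ph$mask == k, arr.ind = TRUE)
    for (i in seq_len(min(4, nrow(idx))))
      expect_equal(ph$cube$reflectance[idx[i, 1], idx[i, 2], ], tmpl)
  }

  spec1 <- phantom_spec(height = 12, width = 12,
                        wavelengths = small_wavelengths(), seed = 5)
  a <- generate_phantom(spec1)
  b <- generate_phantom(spec1)
  expect_identical(a$cube$reflectance, b$cube$reflectance)
  expect_identical(a$mask, b$mask)

  spec2 <- phantom_spec(height = 12, width = 12,
                        wavelengths = small_wavelengths(), seed = 6)
  c2 <- generate_phantom(spec2)
  expect_false(identical(a$cube$reflectance, c2$cube$reflectance))
  expect_identical(dim(a$cube$reflectance), dim(c2$cube$reflectance))
  expect_identical(sort(unique(as.vector(c2$mask))), 1:3)
})

test_that("layout rasterization matches the analytic region areas", {
  lay <- phantom_layout()
  mask <- esohsi:::layout_mask(lay, 64, 64)
  counts <- tabulate(mask, 3)
  expect_identical(sum(counts), 64L * 64L)
  # cancer ellipse: area pi * ry * rx, rasterization error bounded by the
  # perimeter in pixels
  ry <- lay$ellipse_radii[1] * 64; rx <- lay$ellipse_radii[2] * 64
  analytic <- pi * ry * rx
  perimeter <- 2 * pi * sqrt((ry^2 + rx^2) / 2)
  expect_lt(abs(counts[3] - analytic), perimeter)
  # esophagus occupies the left split minus its ellipse share
  expect_lt(abs(sum(counts[1:2]) + counts[3] - 64^2), 0.5)
})

test_that("default layout reproduces the clinical class imbalance scale", {
  mask <- esohsi:::layout_mask(phantom_layout(), 64, 64)
  frac <- tabulate(mask, 3) / length(mask)
  # cancer is a small minority (~7.5%), stomach the majority class
  expect_lt(abs(frac[3] - 0.075), 0.02)
  expect_gt(frac[2], frac[1])
  expect_gt(frac[1], frac[3])
})

test_that("absorbance at 970 nm increases strictly with water fraction", {
  wl <- seq(500, 1000, length.out = 100)
  grid <- seq(0, 1, by = 0.05)
  a970 <- vapply(grid, function(w) {
    p <- chromophore_params(water_fraction = w)
    -log10(reflectance_template(970, p))
  }, 0)
  expect_equal(stats::cor(grid, a970, method = "spearman"), 1)
  expect_true(all(diff(a970) > 0))
})

test_that("cohort generation encodes the programmed stage effect", {
  expect_error(generate_cohort(4), "cohort-size")

  water_of <- function(coh, stages) {
    vapply(Filter(function(p) p$stage %in% stages, coh),
           function(p) p$params$cancer$water_fraction, 0)
  }

  # null increment: both stage groups are draws from the same law
  null <- tiny_cohort(8, seed = 2, stage_water_increment = 0)
  base_w <- phantom_spec()$class_params$cancer$water_fraction
  expect_lt(abs(mean(water_of(null, c("T1", "T2"))) -
                  mean(water_of(null, c("T3", "T4")))), 0.15)
  expect_lt(abs(mean(water_of(null, c("T1", "T2", "T3", "T4"))) - base_w),
            0.1)

  # forced increment raises the advanced-stage group
  eff <- tiny_cohort(8, seed = 2, stage_water_increment = 0.2)
  expect_gt(mean(water_of(eff, c("T3", "T4"))),
            mean(water_of(eff, c("T1", "T2"))) + 0.1)

  # different seeds: different cubes, identical shapes and class sets
  c1 <- tiny_cohort(6, seed = 10)
  c2 <- tiny_cohort(6, seed = 11)
  expect_false(identical(c1[[1]]$cube$reflectance,
                         c2[[1]]$cube$reflectance))
  expect_identical(dim(c1[[1]]$cube$reflectance),
                   dim(c2[[1]]$cube$reflectance))
  expect_identical(sort(unique(as.vector(c1[[3]]$mask))),
                   sort(unique(as.vector(c2[[3]]$mask))))
  # determinism
  expect_identical(tiny_cohort(6, seed = 10)[[2]]$cube$reflectance,
                   c1[[2]]$cube$reflectance)
})
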