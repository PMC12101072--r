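test_that("power-law generator: determinism, mean control, clipping", {
  a <- gen_powerlaw_image(-1, 128, seed = 7)
  b <- gen_powerlaw_image(-1, 128, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, gen_powerlaw_image(-1, 128, seed = 8)))

  for (ml in c(0.3, 0.5, 0.7)) {
    img <- gen_powerlaw_image(-1.2, 128, mean_level = ml, seed = 1)
    expect_lt(abs(mean(img) - ml), 1e-6)
    expect_lt(attr(img, "clip_frac"), 0.01)
    expect_true(all(img >= 0 & img <= 1))
  }

  expect_error(gen_powerlaw_image(-1, 32), "size_px")
  expect_error(gen_powerlaw_image(-1, 128, mean_level = 1.2), "mean_level")
  expect_error(gen_powerlaw_image(-1, 128, mean_level = 0.02,
                                  contrast = 0.6, seed = 1), "clip")
})

test_that("power-law generator: beta = 0 gives a flat spectrum", {
  img <- gen_powerlaw_image(0, 256, seed = 3)
  rs <- rotational_average(amplitude_spectrum(img - mean(img)))
  sel <- rs[rs$freq_cpi >= 5 & rs$freq_cpi <= 25, ]
  # sampling noise only: ring means stay within a few percent of each other
  expect_lt(diff(range(sel$amplitude)) / mean(sel$amplitude), 0.1)
})

test_that("power-law generator round-trips through the slope pipeline", {
  est <- vapply(1:6, function(s)
    measure_spectral_slope(gen_powerlaw_image(-1, 512, seed = s))$slope, 0)
  expect_lt(abs(mean(est) - (-1)), 0.05)
  expect_true(all(abs(est - (-1)) < 0.1))
})

test_that("abdomen mask: connectivity, coverage, determinism, geometry", {
  for (sh in c("ellipse", "fan")) {
    for (s in 1:5) {
      m <- gen_abdomen_mask(128, shape = sh, seed = s)
      lab <- specslope:::label_components(m)
      expect_equal(max(lab), 1L)
      expect_gte(mean(m), 0.2)
      expect_lte(mean(m), 0.8)
    }
  }
  expect_identical(gen_abdomen_mask(96, seed = 4),
                   gen_abdomen_mask(96, seed = 4))

  # circular mask: inscribed square side = floor(a*sqrt(2)) +/- 1
  a <- 50
  m <- gen_abdomen_mask(128, "ellipse", semi_axes = c(a, a),
                        center = c(64.5, 64.5))
  side <- largest_inscribed_square(m)$side_px
  expect_lte(abs(side - floor(a * sqrt(2))), 1)
  expect_equal(side, oracle_inscribed_side(m))
})

test_that("multispectral stack simulation matches its forward model", {
  basis <- make_basis()
  refl <- sensitivity_curve(seq(300, 700, 2),
                            rep(0.5, 201))
  scene <- gen_powerlaw_image(-1, 64, seed = 2)

  st <- gen_multispectral_stack(scene, basis, refl, dark_offset = 250,
                                saturate_fraction = 0, seed = 1,
                                read_noise_sd = 5)
  expect_s3_class(st, "mspec_stack")
  expect_equal(sum(vapply(st$saturated, sum, 0)), 0)
  # dark-column mean: SE = 5 / sqrt(n_dark_px)
  expect_lt(abs(estimate_dark_noise(st$dark_columns) - 250),
            4 * 5 / sqrt(length(st$dark_columns)))

  # noise-free: each channel is exactly gain * scene * <refl, filter> + dark
  st0 <- gen_multispectral_stack(scene, basis, refl, dark_offset = 100,
                                 saturate_fraction = 0, seed = 1,
                                 read_noise_sd = 0)
  g <- st0$meta$gain
  ip <- st0$meta$inner_products
  for (k in seq_along(basis))
    expect_equal(st0$channels[[k]], g * scene * ip[k] + 100,
                 tolerance = 1e-9, ignore_attr = TRUE)

  # receptor image after filter fitting is proportional to the scene
  w <- fit_computational_filter(basis, basis[[3]])
  rec <- apply_filter_weights(
    mspec_stack(lapply(st0$channels, function(ch) ch - 100)), w)
  ratio <- rec / scene
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)

  # saturation forcing and flagging
  sts <- gen_multispectral_stack(scene, basis, refl, saturate_fraction = 0.01,
                                 seed = 3)
  n_sat <- vapply(sts$saturated, sum, 0)
  expect_true(all(n_sat >= round(0.01 * 64 * 64)))
  expect_error(gen_multispectral_stack(
    scene, basis, sensitivity_curve(c(900, 950), c(1, 1))),
    "common wavelength")
})

test_that("cohort generator obeys its hierarchy", {
  # all variance off: slopes are exactly the group means
  co <- gen_cohort(n_species = 4, n_per_sex = 3, mu_female = -1.2,
                   delta_sex = -0.31, sd_species = 0, sd_species_sex = 0,
                   sd_resid = 0, n_scenes = 0, seed = 1)
  expect_true(all(co$slope[co$sex == "female"] == -1.2))
  expect_true(all(abs(co$slope[co$sex == "male"] - (-1.51)) < 1e-12))

  # scene CLT check at stated defaults
  co2 <- gen_cohort(n_scenes = 41, mu_scene = -1.09, sd_scene = 0.14,
                    seed = 5)
  sc <- co2$slope[co2$group == "scene"]
  expect_equal(length(sc), 41L)
  expect_lt(abs(mean(sc) - (-1.09)), 3 * 0.14 / sqrt(41))

  expect_identical(gen_cohort(seed = 9), gen_cohort(seed = 9))
  expect_error(gen_cohort(sd_species = -1), "sd")
  tr <- attr(co2, "truth")
  expect_equal(tr$delta_sex, -0.31)
})
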