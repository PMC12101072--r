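test_that("dark-noise estimation", {
  expect_equal(estimate_dark_noise(matrix(100, 10, 10)), 100)
  expect_equal(estimate_dark_noise(matrix(0, 5, 5)), 0)
  expect_error(estimate_dark_noise(numeric()), "empty")
  # SE check: 2048 dark pixels at SD 5 pin the mean within ~0.5
  st <- gen_multispectral_stack(gen_powerlaw_image(-1, 128, seed = 1),
                                make_basis(),
                                sensitivity_curve(seq(300, 700, 2),
                                                  rep(0.5, 201)),
                                dark_offset = 250, read_noise_sd = 5,
                                seed = 6)
  expect_lt(abs(estimate_dark_noise(st$dark_columns) - 250), 0.5)
})

test_that("exposure-stability QC uses 3-frame sliding windows", {
  expect_true(check_exposure_stability(c(100, 100, 100))$pass)
  expect_equal(check_exposure_stability(c(100, 100, 100))$max_variation, 0)

  r <- check_exposure_stability(c(100, 100.6, 100))
  expect_false(r$pass)
  expect_equal(r$max_variation, 0.6 / 100.2)  # 0.598% > 0.5%

  r2 <- check_exposure_stability(c(100, 100.5, 100))
  expect_true(r2$pass)                        # 0.499%: strictly greater rule
  expect_equal(r2$max_variation, 0.5 / (300.5 / 3))

  # a drifting tail is caught by the sliding window
  r3 <- check_exposure_stability(c(100, 100, 100, 100, 103))
  expect_false(r3$pass)
  expect_length(r3$window_variation, 3)
  expect_error(check_exposure_stability(c(1, 2)), "3 frames")
})

test_that("saturated-pixel repair fills from valid neighbours", {
  img <- matrix(10, 5, 5)
  bad <- matrix(FALSE, 5, 5)
  bad[3, 3] <- TRUE
  img[3, 3] <- 999
  out <- repair_saturated_pixels(img, bad)
  expect_equal(out[3, 3], 10)
  expect_equal(attr(out, "repaired_pixels"), 1L)
  # unflagged pixels bit-identical
  expect_identical(out[!bad], img[!bad])

  # corner pixel: mean of its 3 valid neighbours
  img2 <- matrix(0, 3, 3)
  img2[1, 2] <- 8; img2[2, 1] <- 10; img2[2, 2] <- 12
  bad2 <- matrix(FALSE, 3, 3); bad2[1, 1] <- TRUE
  expect_equal(repair_saturated_pixels(img2, bad2)[1, 1], 10)

  expect_error(repair_saturated_pixels(matrix(1, 2, 2),
                                       matrix(TRUE, 2, 2)),
               "no valid neighbours")
  expect_error(repair_saturated_pixels(matrix(1, 2, 2),
                                       matrix(FALSE, 3, 3)), "dimensions")
})

test_that("cluster repair equals the brute-force iterative-fill oracle", {
  set.seed(42)
  for (rep in 1:5) {
    img <- matrix(seq_len(100) + rnorm(100), 10, 10)  # noisy ramp
    bad <- matrix(FALSE, 10, 10)
    # one 2x1 cluster and one 2x2 block at random positions
    i <- sample(2:8, 1); j <- sample(2:8, 1)
    bad[i, j] <- bad[i + 1, j] <- TRUE
    i2 <- sample(2:7, 1); j2 <- sample(2:7, 1)
    bad[i2:(i2 + 1), j2:(j2 + 1)] <- TRUE
    expect_equal(unclass(repair_saturated_pixels(img, bad)),
                 oracle_iterative_fill(img, bad), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("normalisation and Naka-Rushton transform", {
  img <- matrix(runif(64, 0, 2), 8, 8)
  expect_equal(mean(normalize_image(img, mean(img))), 1)
  expect_equal(normalize_image(matrix(1), 2)[1], 0.5)
  expect_error(normalize_image(img, 0), "positive")
  expect_error(normalize_image(img, -3), "positive")

  expect_equal(naka_rushton(matrix(1))[1], 0.5)
  expect_equal(naka_rushton(matrix(0))[1], 0)
  expect_equal(naka_rushton(matrix(3))[1], 0.75)
  expect_error(naka_rushton(matrix(-0.1)), "non-negative")

  # strictly increasing, bounded in [0, 1) on a wide grid
  p <- seq(0, 1000, length.out = 1000)
  e <- naka_rushton(matrix(p, 1))
  expect_true(all(diff(as.vector(e)) > 0))
  expect_true(all(e >= 0 & e < 1))
})

test_that("re-running normalise + excitation is not idempotent", {
  img <- matrix(runif(100, 0.2, 1.8), 10, 10)
  e1 <- naka_rushton(normalize_image(img, mean(img)))
  e2 <- naka_rushton(normalize_image(e1, mean(e1)))
  expect_gt(max(abs(e1 - e2)), 1e-3)  # guards against double application
})

test_that("full preprocessing chain honours the grey standard", {
  basis <- make_basis()
  refl <- sensitivity_curve(seq(300, 700, 2), rep(0.5, 201))
  scene <- gen_powerlaw_image(-1, 64, seed = 9)
  gp <- list(rows = 1:8, cols = 1:8, reflectance = 0.2)
  st <- gen_multispectral_stack(scene, basis, refl, dark_offset = 200,
                                read_noise_sd = 0, seed = 1,
                                grey_patch = gp)
  w <- fit_computational_filter(basis, basis[[3]])
  rec <- preprocess_stack(st, w, "grey_standard")
  expect_s3_class(rec, "receptor_image")
  expect_true(all(rec$values >= 0 & rec$values < 1))

  # outside the patch E = P/(P+1) with P = scene * 0.5 / 0.2; invert and
  # compare with the known reflectance ratio
  p_rec <- rec$values / (1 - rec$values)
  outside <- matrix(TRUE, 64, 64); outside[gp$rows, gp$cols] <- FALSE
  expect_equal(p_rec[outside], (scene * 0.5 / 0.2)[outside],
               tolerance = 1e-6)
  expect_error(preprocess_stack(
    gen_multispectral_stack(scene, basis, refl, seed = 1), w,
    "grey_standard"), "grey patch")
})
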