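test_that("cosine taper: boundary behaviour and errors", {
  const <- matrix(3.7, 64, 64)
  expect_equal(cosine_taper(const), const, ignore_attr = TRUE)

  img <- gen_powerlaw_image(-1, 128, seed = 2)
  mu <- mean(img)
  tp <- cosine_taper(img)
  corners <- tp[c(1, 128), c(1, 128)]
  expect_lt(max(abs(corners - mu)), 1e-9)
  # interior untouched (window is 1 well inside the roll-off)
  expect_equal(tp[60:68, 60:68], img[60:68, 60:68], ignore_attr = TRUE)

  expect_error(cosine_taper(matrix(0, 10, 20)), "square")
  expect_error(cosine_taper(img, taper_frequency = 0), "positive")
  expect_error(cosine_taper(matrix(0, 6, 6), taper_frequency = 4), "2 px")
})

test_that("taper changes steep-slope estimates by less than 0.05", {
  d <- vapply(1:8, function(s) {
    img <- gen_powerlaw_image(-1, 512, seed = s)
    measure_spectral_slope(img)$slope -
      measure_spectral_slope(img, taper = FALSE)$slope
  }, 0)
  expect_lt(abs(mean(d)), 0.05)
})

test_that("amplitude spectrum: DC centring, sinusoid closed form, Parseval", {
  n <- 64
  const <- matrix(5, n, n)
  a <- amplitude_spectrum(const)
  ctr <- n / 2 + 1
  expect_equal(a[ctr, ctr], 5 * n^2)
  a[ctr, ctr] <- 0
  expect_lt(max(a) / (5 * n^2), 1e-9)

  # horizontal sinusoid at 8 cycles/image, amplitude 2: two coefficients of
  # modulus a*N^2/2 at radius 8 on the axis through DC
  x <- outer(rep(1, n), 0:(n - 1))
  sin8 <- 2 * cos(2 * pi * 8 * x / n)
  as8 <- amplitude_spectrum(sin8)
  expect_equal(as8[ctr, ctr + 8], 2 * n^2 / 2, tolerance = 1e-9)
  expect_equal(as8[ctr, ctr - 8], 2 * n^2 / 2, tolerance = 1e-9)
  expect_lt(sort(as8, decreasing = TRUE)[3] / (n^2), 1e-9)

  img <- gen_powerlaw_image(-1, 128, seed = 5)
  expect_equal(sum(amplitude_spectrum(img)^2), 128^2 * sum(img^2),
               tolerance = 1e-6)
  expect_error(amplitude_spectrum(matrix(0, 4, 6)), "square")
})

test_that("rotational average equals explicit enumeration", {
  # constant grid: profile constant at that value
  cg <- matrix(2.5, 32, 32)
  rs <- rotational_average(cg)
  expect_true(all(rs$amplitude == 2.5))
  expect_equal(max(rs$freq_cpi), 16)

  # ring-3 example: four axis coefficients of value v
  n <- 16; ctr <- 9
  g <- matrix(0, n, n)
  v <- 7
  g[ctr + 3, ctr] <- g[ctr - 3, ctr] <- g[ctr, ctr + 3] <- g[ctr, ctr - 3] <- v
  rs3 <- rotational_average(g)
  ring3 <- oracle_rotational_average(g)
  expect_equal(rs3$amplitude, ring3$amplitude, tolerance = 1e-12)
  n_ring3 <- sum(floor(sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+")) + 0.5) == 3)
  expect_equal(rs3$amplitude[rs3$freq_cpi == 3], v * 4 / n_ring3)
  expect_true(all(rs3$amplitude[rs3$freq_cpi != 3] == 0))

  # random grids, even and odd sizes
  for (n in c(16, 17, 33, 64)) {
    set.seed(n)
    g <- matrix(runif(n * n), n, n)
    rs <- rotational_average(g)
    or <- oracle_rotational_average(g)
    expect_equal(rs$freq_cpi, or$freq_cpi)
    expect_equal(rs$amplitude, or$amplitude, tolerance = 1e-12)
  }

  # physical-unit consistency
  rsmm <- rotational_average(matrix(1, 32, 32), crop_mm = 2.5)
  expect_equal(rsmm$freq_cpmm, rsmm$freq_cpi / 2.5, tolerance = 1e-9)
})

test_that("frequency-range rule", {
  expect_equal(unname(select_frequency_range(1036)), c(5, 103))
  expect_equal(unname(select_frequency_range(391)), c(5, 39))
  expect_error(select_frequency_range(50), "2 analysable")
})

test_that("species range harmonisation", {
  two <- data.frame(side_px = c(200, 250), crop_mm = c(2.0, 2.5))
  hz <- harmonize_species_range(two)
  expect_equal(hz$f_lo_cpmm, 2.5)        # max(5/2.0, 5/2.5)
  expect_equal(hz$f_hi_cpmm, 10)         # min(20/2.0, 25/2.5)
  # literal mode takes the lowest minimum instead (excludes nothing)
  hz_lit <- harmonize_species_range(two, mode = "literal")
  expect_equal(hz_lit$f_lo_cpmm, 2.0)
  # per-member analysed integer frequencies respect the common cpmm range
  expect_equal(hz$member_freqs_cpi[[1]], 5:20)
  expect_equal(hz$member_freqs_cpi[[2]], ceiling(2.5 * 2.5):25)

  one <- data.frame(side_px = 391, crop_mm = 1.6)
  h1 <- harmonize_species_range(one)
  expect_equal(h1$f_lo_cpmm, 5 / 1.6)
  expect_equal(h1$f_hi_cpmm, 39 / 1.6)
  expect_equal(h1$member_freqs_cpi[[1]], 5:39)

  # high-magnification member capped at the shortest-extension limit
  hi <- data.frame(side_px = 1000, crop_mm = 2.5)   # f_hi 40 cycles/mm
  hc <- harmonize_species_range(hi, cap_cpmm = 24.4)
  expect_equal(hc$f_hi_cpmm, 24.4)
  expect_equal(max(hc$member_freqs_cpi[[1]]), floor(24.4 * 2.5))

  bad <- data.frame(side_px = c(60, 60), crop_mm = c(0.5, 10))
  expect_error(harmonize_species_range(bad), "empty")
})

test_that("log-binning conventions", {
  # exactly 9 frequencies, one per bin: identity on (log f, log A)
  f9 <- 10^seq(1, 2, length.out = 9)
  A9 <- runif(9, 1, 2)
  b9 <- bin_log_spectrum(f9, A9)
  expect_equal(b9$log10_freq, log10(f9))
  expect_equal(b9$log10_amplitude, log10(A9))

  # mean-then-log within a bin
  b2 <- bin_log_spectrum(c(10, 10.1, 100), c(2, 4, 1), n_bins = 2)
  expect_equal(b2$log10_amplitude[1], log10(3))

  # a pure power law is near-invariant under binning; the mean-then-log
  # convention leaves a curvature residue of order 1e-5
  f <- 5:103
  fit <- fit_spectral_slope(bin_log_spectrum(f, f^(-1)))
  expect_equal(fit$slope, -1, tolerance = 1e-4)
  expect_gte(fit$r2, 0.999)

  expect_warning(bin_log_spectrum(c(1, 1.01, 100), c(1, 1, 1)), "empty")
  suppressWarnings(
    expect_error(bin_log_spectrum(c(10, 10), c(1, 2)), "2 non-empty"))
})

test_that("slope fitting: exact line, errors, reported diagnostics", {
  x <- seq(0.7, 2, length.out = 9)
  pts <- data.frame(log10_freq = x, log10_amplitude = -1.2 * x + 3)
  fit <- fit_spectral_slope(pts, f_range_cpi = c(5, 100))
  expect_equal(fit$slope, -1.2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n_bins, 9)
  expect_equal(fit$f_lo_cpi, 5)

  expect_error(fit_spectral_slope(pts[1, ]), "2 points")
  same <- data.frame(log10_freq = rep(1, 3), log10_amplitude = 1:3)
  expect_error(fit_spectral_slope(same), "variance")
})

test_that("slope is invariant to log base and image rescaling", {
  img <- gen_powerlaw_image(-1.3, 256, seed = 6)
  fit <- measure_spectral_slope(img)

  # rescaling the image shifts only the intercept
  fit2 <- measure_spectral_slope(img * 4.2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
  expect_equal(fit2$intercept - fit$intercept, log10(4.2), tolerance = 1e-9)

  # refitting the same binned points in natural log gives the same slope
  ln_slope <- stats::coef(stats::lm(I(fit$bin_means * log(10)) ~
                                      I(fit$bin_centers * log(10))))[2]
  expect_equal(unname(ln_slope), fit$slope, tolerance = 1e-9)
})

test_that("white noise measures flat; known beta round-trips at 256", {
  est0 <- vapply(1:6, function(s)
    measure_spectral_slope(gen_powerlaw_image(0, 256, seed = s))$slope, 0)
  expect_lt(abs(mean(est0)), 0.05)
  est15 <- vapply(1:6, function(s)
    measure_spectral_slope(gen_powerlaw_image(-1.5, 256, seed = s))$slope, 0)
  expect_lt(abs(mean(est15) + 1.5), 0.06)
})
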