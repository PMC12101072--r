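#' Synthesise a power-law (1/f-family) test image
#'
#' Builds a real-valued square raster whose 2D Fourier amplitude spectrum is
#' proportional to `f^beta` (radial frequency in cycles/image) with uniformly
#' random, Hermitian-symmetric phases. This is the ground-truth generator for
#' the spectral-slope pipeline: natural scenes sit near `beta = -1`, white
#' noise at `beta = 0`.
#'
#' The DC coefficient is set so the raster mean equals `mean_level` exactly;
#' the zero-mean fluctuation is scaled to RMS `contrast` before adding the
#' mean. Values are clipped to `[0, 1]` afterwards and the clipped fraction
#' is recorded (attribute `clip_frac`), because clipping distorts spectra and
#' must be observable. More than 5% clipping is rejected.
#'
#' @param beta spectral exponent (amplitude vs frequency), typically in
#'   `[-2, 0]`.
#' @param size_px side length in pixels, `>= 64`.
#' @param mean_level target mean pixel value in (0, 1).
#' @param contrast RMS amplitude of the fluctuation around the mean.
#' @param seed integer seed; identical seeds give bit-identical rasters.
#' @return `size_px` x `size_px` matrix in `[0, 1]` with attributes `beta`,
#'   `clip_frac`, `seed`.
#' @export
gen_powerlaw_image <- function(beta, size_px, mean_level = 0.5,
                               contrast = 0.1, seed = 1L) {
  if (size_px < 64) stop("size_px must be >= 64")
  if (mean_level <= 0 || mean_level >= 1) stop("mean_level must be in (0,1)")
  if (contrast <= 0) stop("contrast must be positive")
  n <- as.integer(size_px)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  # unshifted DFT frequency coordinates in cycles/image
  f1 <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  r <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- r^beta
  amp[1, 1] <- 0  # DC handled via mean_level

  # FFT of white Gaussian noise: Hermitian by construction, uniform phases
  w <- stats::fft(matrix(stats::rnorm(n * n), n, n))
  mod <- Mod(w)
  mod[mod == 0] <- 1
  x <- Re(stats::fft(amp * w / mod, inverse = TRUE)) / n^2

  s <- sqrt(mean(x^2))          # x has exactly zero mean (DC = 0)
  x <- x * (contrast / s) + mean_level
  clip <- mean(x < 0 | x > 1)
  if (clip > 0.05)
    stop(sprintf(paste("contrast too large: %.1f%% of pixels clip;",
                       "reduce contrast or move mean_level"), 100 * clip))
  # clipping shifts the mean; re-centre and re-clip to a fixed point so the
  # requested mean holds exactly even when a few pixels saturate
  for (k in 1:100) {
    x[x < 0] <- 0
    x[x > 1] <- 1
    err <- mean(x) - mean_level
    if (abs(err) < 1e-9) break
    x <- x - err
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  structure(x, beta = beta, clip_frac = clip, seed = as.integer(seed))
}

#' Generate an abdomen-like binary mask
#'
#' Stand-in for abdomen segmentation: a single 4-connected foreground region
#' (filled ellipse, or an ellipse with a flattened base resembling a spider's
#' display fan) covering 20-80% of the raster.
#'
#' @param size_px side length, `>= 64`.
#' @param shape `"ellipse"` or `"fan"`.
#' @param seed integer seed.
#' @param semi_axes optional `c(a, b)` semi-axes in pixels (rows, cols);
#'   random within safe coverage bounds when `NULL`.
#' @param center optional `c(row, col)` centre; defaults near the middle.
#' @return logical matrix (TRUE = foreground) with attribute `coverage`.
#' @export
gen_abdomen_mask <- function(size_px, shape = c("ellipse", "fan"),
                             seed = 1L, semi_axes = NULL, center = NULL) {
  if (size_px < 64) stop("size_px must be >= 64")
  shape <- match.arg(shape)
  n <- as.integer(size_px)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (is.null(semi_axes))
    semi_axes <- stats::runif(2, 0.30, 0.44) * n
  if (is.null(center))
    center <- (n + 1) / 2 + stats::runif(2, -0.02, 0.02) * n
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  m <- ((rr - center[1]) / semi_axes[1])^2 +
       ((cc - center[2]) / semi_axes[2])^2 <= 1
  if (shape == "fan") {
    # flatten the base: cut below 0.6 of the lower semi-axis, like a fan's
    # straight attachment edge; region stays 4-connected
    m[rr > center[1] + 0.6 * semi_axes[1]] <- FALSE
  }
  cov <- mean(m)
  if (cov < 0.2 || cov > 0.8)
    stop(sprintf("mask coverage %.2f outside [0.2, 0.8]; adjust semi_axes",
                 cov))
  structure(m, coverage = cov)
}

#' Multispectral camera stack
#'
#' Container for one co-registered 16-bit raster per optical filter, with
#' per-channel saturation flags, a dark-column region (sensor columns that
#' receive no light, used to estimate dark noise), the sensor maximum, and an
#' optional grey-standard patch location.
#'
#' @param channels named list of equal-size numeric matrices (DN values).
#' @param saturated list of logical matrices, same shapes.
#' @param dark_columns numeric matrix of dark-column samples.
#' @param sensor_max sensor saturation value (65535 for 16 bit).
#' @param grey_patch optional `list(rows =, cols =, reflectance =)`.
#' @param meta optional list of extra metadata (gain, wavelengths, ...).
#' @return object of class `mspec_stack`.
#' @export
mspec_stack <- function(channels, saturated = NULL, dark_columns = NULL,
                        sensor_max = 65535, grey_patch = NULL, meta = list()) {
  stopifnot(length(channels) >= 1)
  d <- dim(channels[[1]])
  for (ch in channels) if (!identical(dim(ch), d))
    stop("channels must be co-registered (equal dimensions)")
  if (is.null(saturated))
    saturated <- lapply(channels, function(ch) ch >= sensor_max)
  structure(list(channels = channels, saturated = saturated,
                 dark_columns = dark_columns, sensor_max = sensor_max,
                 grey_patch = grey_patch, meta = meta),
            class = "mspec_stack")
}

#' @export
print.mspec_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mspec_stack> %d channels (%s), %d x %d px, sensor max %g\n",
              length(x$channels),
              paste(names(x$channels), collapse = ", "), d[1], d[2],
              x$sensor_max))
  cat(sprintf("  saturated px: %d; dark columns: %s; grey patch: %s\n",
              sum(vapply(x$saturated, sum, 0)),
              if (is.null(x$dark_columns)) "none" else
                paste(dim(x$dark_columns), collapse = " x "),
              if (is.null(x$grey_patch)) "none" else "yes"))
  invisible(x)
}

#' Simulate a multispectral stack from a scene and filter curves
#'
#' Forward model for the preprocessing chain: each channel is the scene
#' raster modulated by the inner product of the per-pixel spectral
#' reflectance with that filter's sensitivity curve, scaled by a gain, plus a
#' dark offset and Gaussian read noise. A stated fraction of pixel sites is
#' forced to the sensor maximum (and flagged), and dark sensor columns are
#' recorded alongside the stack. An optional grey-standard patch of known
#' flat reflectance is painted into a corner for normalisation tests.
#'
#' Per-pixel reflectance is `scene[px] * reflectance(lambda)`, i.e. the scene
#' raster scales a single spectral reflectance shape; inside the grey patch
#' the reflectance is flat at `grey_patch$reflectance`.
#'
#' @param scene matrix in `[0, 1]`.
#' @param filter_curves named list of [sensitivity_curve] (camera filters).
#' @param reflectance [sensitivity_curve]-like spectral reflectance shape.
#' @param dark_offset dark level in DN added to every pixel.
#' @param saturate_fraction fraction of pixel sites forced to sensor max.
#' @param seed integer seed.
#' @param read_noise_sd Gaussian read noise SD in DN (0 disables noise).
#' @param gain DN per unit (scene x inner product); `NULL` auto-scales so the
#'   brightest ideal pixel sits at 60% of sensor max.
#' @param sensor_max sensor saturation value.
#' @param grey_patch `list(rows =, cols =, reflectance =)` or `NULL`.
#' @param n_dark_cols number of dark sensor columns to simulate.
#' @return [mspec_stack].
#' @export
gen_multispectral_stack <- function(scene, filter_curves, reflectance,
                                    dark_offset = 250,
                                    saturate_fraction = 0, seed = 1L,
                                    read_noise_sd = 5, gain = NULL,
                                    sensor_max = 65535,
                                    grey_patch = NULL, n_dark_cols = 16L) {
  stopifnot(is.matrix(scene))
  if (!inherits(reflectance, "sensitivity_curve"))
    reflectance <- sensitivity_curve(reflectance$wavelength_nm,
                                     reflectance$sensitivity)
  grid <- common_grid(c(filter_curves, list(reflectance)))
  refl <- curve_on_grid(reflectance, grid)
  inner <- vapply(filter_curves, function(cu)
    sum(refl * curve_on_grid(cu, grid)), 0)
  flat_inner <- vapply(filter_curves, function(cu)
    sum(curve_on_grid(cu, grid)), 0)
  if (is.null(gain))
    gain <- 0.6 * sensor_max / (max(scene) * max(inner))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  h <- nrow(scene); w <- ncol(scene)
  sat_sites <- if (saturate_fraction > 0)
    sample(h * w, size = round(saturate_fraction * h * w)) else integer()

  channels <- saturated <- vector("list", length(filter_curves))
  names(channels) <- names(saturated) <- names(filter_curves)
  for (k in seq_along(filter_curves)) {
    ideal <- gain * scene * inner[k]
    if (!is.null(grey_patch))
      ideal[grey_patch$rows, grey_patch$cols] <-
        gain * grey_patch$reflectance * flat_inner[k]
    ch <- ideal + dark_offset
    if (read_noise_sd > 0)
      ch <- ch + matrix(stats::rnorm(h * w, sd = read_noise_sd), h, w)
    ch[ch < 0] <- 0
    ch[ch > sensor_max] <- sensor_max
    ch[sat_sites] <- sensor_max
    channels[[k]] <- ch
    saturated[[k]] <- ch >= sensor_max
  }
  dark <- matrix(dark_offset, h, n_dark_cols)
  if (read_noise_sd > 0)
    dark <- dark + matrix(stats::rnorm(h * n_dark_cols, sd = read_noise_sd),
                          h, n_dark_cols)
  mspec_stack(channels, saturated, dark_columns = dark,
              sensor_max = sensor_max, grey_patch = grey_patch,
              meta = list(gain = gain, dark_offset = dark_offset,
                          inner_products = inner,
                          flat_inner_products = flat_inner,
                          wavelengths_nm = grid, seed = as.integer(seed)))
}

#' Simulate a hierarchically structured slope cohort
#'
#' Draws per-specimen spectral slopes from the Gaussian hierarchy the group
#' comparison assumes: species-level random intercepts (SD `sd_species`) and
#' species-level sex-effect deviations (SD `sd_species_sex`), a fixed sex
#' effect `delta_sex` (male minus female), residual SD `sd_resid`, plus
#' independent natural-scene slopes `Normal(mu_scene, sd_scene)` split over
#' two regions. Defaults mirror published summary statistics for peacock
#' spiders and ground scenes, so demo runs look like real cohorts; that is an
#' interpretability choice, not a validation.
#'
#' @param n_species number of species (each with both sexes).
#' @param n_per_sex specimens per sex per species.
#' @param mu_female population mean female slope.
#' @param delta_sex male minus female slope difference.
#' @param sd_species SD of species random intercepts.
#' @param sd_species_sex SD of species-level sex-effect deviations.
#' @param sd_resid residual SD.
#' @param mu_scene mean natural-scene slope.
#' @param sd_scene scene SD.
#' @param n_scenes number of scene images.
#' @param region_delta difference between the two region means (region 2
#'   minus region 1); scenes alternate regions.
#' @param seed integer seed.
#' @return cohort data.frame (`unit_id`, `group`, `species`, `sex`, `region`,
#'   `slope`) with attribute `truth` holding every generating parameter and
#'   the realised species effects.
#' @export
gen_cohort <- function(n_species = 18L, n_per_sex = 5L,
                       mu_female = -1.15, delta_sex = -0.31,
                       sd_species = 0.08, sd_species_sex = 0.22,
                       sd_resid = 0.10,
                       mu_scene = -1.09, sd_scene = 0.14, n_scenes = 41L,
                       region_delta = 0, seed = 1L) {
  stopifnot(n_species >= 1, n_per_sex >= 1, n_scenes >= 0,
            sd_species >= 0, sd_species_sex >= 0, sd_resid >= 0,
            sd_scene >= 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  a <- stats::rnorm(n_species, 0, sd_species)
  b <- stats::rnorm(n_species, 0, sd_species_sex)
  sp_names <- sprintf("sp%02d", seq_len(n_species))
  rows <- list()
  for (j in seq_len(n_species)) {
    for (sx in c("female", "male")) {
      mu <- mu_female + a[j] + if (sx == "male") delta_sex + b[j] else 0
      sl <- stats::rnorm(n_per_sex, mu, sd_resid)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = sprintf("%s_%s_%02d", sp_names[j], sx, seq_len(n_per_sex)),
        group = "spider", species = sp_names[j], sex = sx,
        region = NA_character_, slope = sl)
    }
  }
  if (n_scenes > 0) {
    regions <- rep(c("Skane", "Queensland"), length.out = n_scenes)
    mu_r <- ifelse(regions == "Skane", mu_scene - region_delta / 2,
                   mu_scene + region_delta / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = sprintf("scene_%02d", seq_len(n_scenes)),
      group = "scene", species = NA_character_, sex = NA_character_,
      region = regions, slope = stats::rnorm(n_scenes, mu_r, sd_scene))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    mu_female = mu_female, delta_sex = delta_sex, sd_species = sd_species,
    sd_species_sex = sd_species_sex, sd_resid = sd_resid,
    mu_scene = mu_scene, sd_scene = sd_scene, region_delta = region_delta,
    species_intercepts = a, species_sex_dev = b, seed = as.integer(seed))
  validate_cohort(out)
}
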