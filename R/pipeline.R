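#' Write / read a multispectral stack as plain-text rasters
#'
#' Channels and dark columns are stored as ASCII PGM files plus a
#' `stack.json` with the sensor maximum, grey-patch location and metadata —
#' a directory layout that round-trips the [mspec_stack] exactly (to integer
#' DN).
#'
#' @param stack [mspec_stack].
#' @param dir directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_mspec_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$channels))
    write_pgm(stack$channels[[nm]], file.path(dir, paste0("channel_", nm, ".pgm")),
              maxval = stack$sensor_max)
  if (!is.null(stack$dark_columns))
    write_pgm(stack$dark_columns, file.path(dir, "dark.pgm"),
              maxval = stack$sensor_max)
  meta <- list(filters = names(stack$channels), sensor_max = stack$sensor_max,
               grey_patch = if (is.null(stack$grey_patch)) NULL else
                 list(rows = range(stack$grey_patch$rows),
                      cols = range(stack$grey_patch$cols),
                      reflectance = stack$grey_patch$reflectance))
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_mspec_stack
#' @export
read_mspec_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$filters, function(nm)
    read_pgm(file.path(dir, paste0("channel_", nm, ".pgm"))))
  names(channels) <- meta$filters
  darkp <- file.path(dir, "dark.pgm")
  gp <- if (!is.null(meta$grey_patch$rows))
    list(rows = meta$grey_patch$rows[1]:meta$grey_patch$rows[2],
         cols = meta$grey_patch$cols[1]:meta$grey_patch$cols[2],
         reflectance = meta$grey_patch$reflectance)
  mspec_stack(channels,
              dark_columns = if (file.exists(darkp)) read_pgm(darkp),
              sensor_max = meta$sensor_max, grey_patch = gp)
}

#' Built-in camera filter basis and receptor target (synthetic)
#'
#' A synthetic stand-in for a five-filter camera: Gaussian-shaped
#' sensitivities peaking at 360-700 nm, plus a Gaussian target emulating a
#' salticid green receptor peaking at 530 nm. Real curve sets should be
#' loaded from CSV with [read_sensitivity_curves()]; these exist so the
#' pipeline is runnable end-to-end without measured hardware curves.
#'
#' @param wl_nm wavelength grid (default 300-700 nm in 1 nm steps).
#' @return named list of [sensitivity_curve] (`default_filter_curves`), or a
#'   single curve (`salticid_green_target`).
#' @export
default_filter_curves <- function(wl_nm = 300:700) {
  peaks <- c(UV = 360, B = 450, G = 530, Y = 580, R = 650)
  sds <- c(25, 35, 40, 40, 45)
  out <- Map(function(p, s)
    sensitivity_curve(wl_nm, exp(-(wl_nm - p)^2 / (2 * s^2))),
    peaks, sds)
  names(out) <- names(peaks)
  out
}

#' @rdname default_filter_curves
#' @export
salticid_green_target <- function(wl_nm = 300:700) {
  sensitivity_curve(wl_nm, exp(-(wl_nm - 530)^2 / (2 * 45^2)))
}

flat_reflectance <- function(level = 0.5, wl_nm = 300:700) {
  sensitivity_curve(wl_nm, rep(level, length(wl_nm)))
}

#' Simulate a specimen image set on disk
#'
#' Writes a complete synthetic study to `dir`: per-specimen multispectral
#' stacks built from power-law scenes whose exponents follow the cohort
#' hierarchy (species random effects, sex effect), abdomen masks for
#' spiders, rectangular ground-scene stacks, and a `manifest.csv` naming
#' them all. Ground truth (each unit's generating exponent) is stored in
#' the manifest column `beta_true`.
#'
#' @param dir output directory.
#' @param cohort cohort data.frame from [gen_cohort()] (its `slope` column
#'   is used as the generating exponent per unit).
#' @param size_px specimen raster side (default 512).
#' @param scene_dim scene raster `c(height, width)` (default
#'   `c(518, 696)`, the classic 4:3 sensor halved).
#' @param fov_mm horizontal field of view of the specimen frames.
#' @param contrast RMS contrast of the generated scenes.
#' @param dark_offset,read_noise_sd,saturate_fraction sensor model, passed
#'   to [gen_multispectral_stack()].
#' @param seed integer seed.
#' @return the manifest data.frame (also written to `manifest.csv`).
#' @export
simulate_specimen_set <- function(dir, cohort, size_px = 512L,
                                  scene_dim = c(518L, 696L), fov_mm = 5.7,
                                  contrast = 0.08, dark_offset = 250,
                                  read_noise_sd = 2,
                                  saturate_fraction = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  filters <- default_filter_curves()
  refl <- flat_reflectance(0.5)
  gp <- list(rows = 1:24, cols = 1:24, reflectance = 0.2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort) * 2L)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    u <- cohort[i, ]
    udir <- file.path(dir, u$unit_id)
    if (u$group == "spider") {
      # paste the power-law texture exactly into the square the pipeline
      # will crop, so each unit's ground-truth exponent refers to the
      # analysed region (a sub-window of a larger power-law field would
      # carry extra windowing bias that is not part of the stated truth)
      mask <- gen_abdomen_mask(size_px, shape = "fan",
                               seed = sub_seeds[2 * i])
      reg <- largest_inscribed_square(mask)
      tex <- gen_powerlaw_image(u$slope, reg$side_px, mean_level = 0.5,
                                contrast = contrast,
                                seed = sub_seeds[2 * i - 1])
      scene <- matrix(0.5, size_px, size_px)
      scene[reg$row0 + seq_len(reg$side_px),
            reg$col0 + seq_len(reg$side_px)] <- tex
      stack <- gen_multispectral_stack(
        scene, filters, refl, dark_offset = dark_offset,
        saturate_fraction = saturate_fraction, seed = sub_seeds[2 * i],
        read_noise_sd = read_noise_sd, grey_patch = gp)
      write_mspec_stack(stack, udir)
      maskp <- file.path(udir, "mask.pgm")
      write_pgm(mask * 255, maskp, maxval = 255)
    } else {
      side <- min(scene_dim)
      tex <- gen_powerlaw_image(u$slope, side, mean_level = 0.5,
                                contrast = contrast,
                                seed = sub_seeds[2 * i - 1])
      scene <- matrix(0.5, scene_dim[1], scene_dim[2])
      reg <- center_square_crop(scene)
      scene[reg$row0 + seq_len(side), reg$col0 + seq_len(side)] <- tex
      stack <- gen_multispectral_stack(
        scene, filters, refl, dark_offset = dark_offset,
        saturate_fraction = saturate_fraction, seed = sub_seeds[2 * i],
        read_noise_sd = read_noise_sd, grey_patch = NULL)
      write_mspec_stack(stack, udir)
      maskp <- ""
    }
    rows[[i]] <- data.frame(
      unit_id = u$unit_id, group = u$group, species = u$species,
      sex = u$sex, region = u$region, path = udir, mask = maskp,
      fov_mm = fov_mm, width_px = if (u$group == "spider") size_px else
        scene_dim[2], beta_true = u$slope)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Process a batch of specimens and scenes into spectral slopes
#'
#' Runs the measurement chain in acquisition order for every manifest row:
#' dark subtraction, computational-filter conversion, saturated-pixel repair
#' (after conversion), grey-standard normalisation (spiders) or scene-mean
#' normalisation (scenes), Naka-Rushton transform, inscribed-square crop
#' (spiders) or centre crop (scenes), cosine taper, FFT, rotational
#' averaging — then harmonises frequency ranges within each species (in
#' cycles/mm, capped at the camera's `cap_cpmm`), log-bins and fits the
#' slope. Row failures are collected and reported; remaining rows complete.
#'
#' @param manifest data.frame with columns `unit_id`, `group`, `species`,
#'   `sex`, `region`, `path` (stack directory), `mask` (PGM path, spiders),
#'   `fov_mm`, `width_px`.
#' @param weights `filter_weights` (or numeric vector) for the receptor
#'   conversion.
#' @param taper_frequency,n_bins measurement settings.
#' @param harmonize_mode `"intent"` or `"literal"`, see
#'   [harmonize_species_range()].
#' @param cap_cpmm cycles/mm cap; default from [max_analyzed_frequency()]
#'   using each row's `width_px` and `fov_mm`.
#' @return data.frame of per-image slope fits, with attribute `failures`
#'   (named list of error messages).
#' @export
run_specimen_batch <- function(manifest, weights, taper_frequency = 4,
                               n_bins = 9,
                               harmonize_mode = c("intent", "literal"),
                               cap_cpmm = NULL) {
  harmonize_mode <- match.arg(harmonize_mode)
  if (nrow(manifest) == 0) {
    warning("empty manifest")
    return(data.frame())
  }
  failures <- list()
  pre <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    # single-bracket list assignment so an error row stays as NULL instead
    # of shrinking the list
    pre[i] <- list(tryCatch({
      stack <- read_mspec_stack(row$path)
      is_spider <- row$group == "spider"
      rec <- preprocess_stack(stack, weights,
                              normalization = if (is_spider)
                                "grey_standard" else "scene_mean")
      reg <- if (is_spider) {
        largest_inscribed_square(read_pgm(row$mask) > 127)
      } else {
        center_square_crop(rec$values)
      }
      reg <- calibrate_crop(reg, row$fov_mm, row$width_px)
      img <- apply_crop(rec$values, reg)
      rs <- rotational_average(
        amplitude_spectrum(cosine_taper(img, taper_frequency)),
        crop_mm = reg$physical_size_mm)
      list(row = row, rs = rs, side_px = reg$side_px,
           crop_mm = reg$physical_size_mm,
           repaired = rec$repaired_pixels)
    }, error = function(e) {
      failures[[row$unit_id]] <<- conditionMessage(e)
      NULL
    }))
  }
  ok <- !vapply(pre, is.null, TRUE)
  out <- vector("list", nrow(manifest))
  # harmonised ranges within species (spiders); scenes use their own range
  spider_idx <- which(ok & manifest$group == "spider")
  for (spp in unique(manifest$species[spider_idx])) {
    idx <- spider_idx[manifest$species[spider_idx] == spp]
    members <- data.frame(
      side_px = vapply(pre[idx], `[[`, 0L, "side_px"),
      crop_mm = vapply(pre[idx], `[[`, 0, "crop_mm"))
    cap <- if (is.null(cap_cpmm))
      min(mapply(max_analyzed_frequency,
                 manifest$width_px[idx], manifest$fov_mm[idx]))
    else cap_cpmm
    hz <- tryCatch(harmonize_species_range(members, cap_cpmm = cap,
                                           mode = harmonize_mode),
                   error = function(e) {
                     for (j in idx)
                       failures[[manifest$unit_id[j]]] <<-
                         conditionMessage(e)
                     NULL
                   })
    if (is.null(hz)) { ok[idx] <- FALSE; next }
    for (k in seq_along(idx))
      pre[[idx[k]]]$freqs <- hz$member_freqs_cpi[[k]]
  }
  for (i in which(ok & manifest$group == "scene")) {
    fr <- select_frequency_range(pre[[i]]$side_px)
    pre[[i]]$freqs <- fr[1]:fr[2]
  }
  for (i in which(ok)) {
    p <- pre[[i]]
    out[i] <- list(tryCatch({
      sel <- p$rs[p$rs$freq_cpi %in% p$freqs, ]
      binned <- bin_log_spectrum(sel$freq_cpi, sel$amplitude,
                                 n_bins = n_bins)
      fit <- fit_spectral_slope(binned,
                                f_range_cpi = range(sel$freq_cpi),
                                f_range_cpmm = range(sel$freq_cpi) /
                                  p$crop_mm)
      data.frame(unit_id = p$row$unit_id, group = p$row$group,
                 species = p$row$species, sex = p$row$sex,
                 region = p$row$region, side_px = p$side_px,
                 crop_mm = p$crop_mm,
                 f_lo_cpi = fit$f_lo_cpi, f_hi_cpi = fit$f_hi_cpi,
                 f_lo_cpmm = fit$f_lo_cpmm, f_hi_cpmm = fit$f_hi_cpmm,
                 slope = fit$slope, intercept = fit$intercept,
                 r2 = fit$r2, n_bins_used = fit$n_bins,
                 repaired_pixels = p$repaired)
    }, error = function(e) {
      failures[[p$row$unit_id]] <<- conditionMessage(e)
      NULL
    }))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (length(failures))
    warning(length(failures), " manifest row(s) failed: ",
            paste(names(failures), collapse = ", "))
  structure(res, failures = failures)
}

# tiny FNV-1a hash so reports can embed a config fingerprint without
# external digest dependencies
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run a complete synthetic study end to end
#'
#' Simulates a cohort of spider specimens and ground scenes as image stacks
#' on disk, fits the computational receptor filter, measures every spectral
#' slope through the full preprocessing and spectrum chain, fits the
#' hierarchical group model, and reports the three contrasts
#' (male - female, male - scene, female - scene) plus the acuity bounds.
#'
#' @param out_dir working directory for simulated stacks and reports.
#' @param cohort cohort data.frame; default [gen_cohort()] scaled by
#'   `...`-style arguments is up to the caller.
#' @param size_px specimen raster side.
#' @param fov_mm field of view for specimen frames.
#' @param distance_mm viewing distance for the acuity bound.
#' @param acuity_sensor_width_px,acuity_fov_mm physical-camera constants for
#'   the reported acuity cap (defaults: the standard 1392 px sensor across a
#'   5.7 mm field), independent of the synthetic raster size.
#' @param chains,iterations,warmup MCMC settings.
#' @param seed integer master seed.
#' @param write_report write `report.json` and `slopes.csv` under
#'   `out_dir`.
#' @return report list: `slopes` (per-image table), `model` (fit), `contrasts`,
#'   `acuity`, `config_hash`, `seed`.
#' @export
run_full_study <- function(out_dir, cohort = gen_cohort(seed = 1L),
                           size_px = 256L, fov_mm = 5.7,
                           distance_mm = 27,
                           acuity_sensor_width_px = 1392,
                           acuity_fov_mm = 5.7,
                           chains = 4L, iterations = 2000L, warmup = 1000L,
                           seed = 1L, write_report = TRUE) {
  config <- list(size_px = size_px, fov_mm = fov_mm,
                 distance_mm = distance_mm, chains = chains,
                 iterations = iterations, warmup = warmup, seed = seed)
  manifest <- simulate_specimen_set(file.path(out_dir, "stacks"), cohort,
                                    size_px = size_px, fov_mm = fov_mm,
                                    seed = seed)
  w <- fit_computational_filter(default_filter_curves(),
                                salticid_green_target())
  slopes <- run_specimen_batch(manifest, w)
  cohort_meas <- data.frame(unit_id = slopes$unit_id, group = slopes$group,
                            species = slopes$species, sex = slopes$sex,
                            region = slopes$region, slope = slopes$slope)
  fit <- fit_hierarchical_model(cohort_meas, chains = chains,
                                iterations = iterations, warmup = warmup,
                                seed = seed)
  contrasts <- list(
    male_vs_female = contrast(fit, "male_mean", "female_mean"),
    male_vs_scene = contrast(fit, "male_mean", "scene_mean"),
    female_vs_scene = contrast(fit, "female_mean", "scene_mean"))
  acuity <- list(
    f_max_cpmm = max_analyzed_frequency(
      sensor_width_px = acuity_sensor_width_px, fov_mm = acuity_fov_mm),
    f_s_cpmm = spatial_resolution_limit(distance_mm))
  report <- list(slopes = slopes, model = fit, contrasts = contrasts,
                 acuity = acuity, config = config,
                 config_hash = config_hash(config), seed = seed)
  if (write_report) {
    utils::write.csv(slopes, file.path(out_dir, "slopes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      config = config, config_hash = report$config_hash,
      acuity = acuity,
      posterior_summary = fit$summary,
      contrasts = lapply(contrasts, function(x)
        x[c("delta_mean", "delta_sd", "cri_lo", "cri_hi", "crosses_zero")]),
      converged = fit$converged,
      failures = attr(slopes, "failures")),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
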