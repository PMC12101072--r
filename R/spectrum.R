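#' Raised-cosine edge taper
#'
#' Blends a square image toward its own mean at the borders so the FFT's
#' periodic-boundary assumption does not inject spurious high-frequency
#' energy. The window is separable, 1 in the interior, with a raised-cosine
#' roll-off of width `side / taper_frequency` at each edge (a Tukey window
#' with taper fraction `2 / taper_frequency` per axis); corners and edge
#' pixels end up exactly at the image mean. `taper_frequency` names the
#' approximate upper edge, in cycles/image, of the window's own spectral
#' content: with the default 4 the taper's energy stays below the
#' 5 cycles/image analysis floor, which a narrower roll-off would violate
#' (a half-side-over-eight roll-off measurably contaminates the 5-8
#' cycles/image rings and biases steep-slope estimates).
#'
#' @param image square numeric matrix.
#' @param taper_frequency taper spatial frequency in cycles/image
#'   (default 4).
#' @return tapered matrix, same size; attribute `taper_window` holds the 2D
#'   window.
#' @export
cosine_taper <- function(image, taper_frequency = 4) {
  if (nrow(image) != ncol(image)) stop("taper requires a square image")
  if (taper_frequency <= 0) stop("taper_frequency must be positive")
  n <- nrow(image)
  w <- n / taper_frequency
  if (w < 2) stop("taper roll-off narrower than 2 px; image too small")
  d <- pmin(seq_len(n) - 1, n - seq_len(n))   # distance from nearest edge
  win1 <- ifelse(d >= w, 1, 0.5 * (1 - cos(pi * d / w)))
  W <- outer(win1, win1)
  mu <- mean(image)
  out <- mu + W * (image - mu)
  attr(out, "taper_window") <- W
  out
}

# reorder so DC sits at index floor(n/2)+1 (the grid centre)
fftshift_idx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))

#' Centred 2D Fourier amplitude spectrum
#'
#' Modulus of the 2D DFT with the DC component shifted to the grid centre
#' (index `floor(n/2) + 1` on each axis).
#'
#' @param image square numeric matrix.
#' @return matrix of amplitudes, DC centred.
#' @export
amplitude_spectrum <- function(image) {
  if (nrow(image) != ncol(image)) stop("FFT analysis requires a square image")
  n <- nrow(image)
  a <- Mod(stats::fft(image))
  a[fftshift_idx(n), fftshift_idx(n)]
}

#' Rotationally averaged amplitude profile
#'
#' Collapses a centred 2D amplitude grid to amplitude vs radial spatial
#' frequency: each coefficient is assigned to the integer ring nearest its
#' Euclidean distance from DC (half-up rounding), rings are averaged, DC is
#' excluded, and rings beyond the Nyquist radius `floor(n/2)` are dropped.
#'
#' @param amp2d square amplitude grid with DC at the centre
#'   (from [amplitude_spectrum()]).
#' @param crop_mm physical side of the analysed crop in mm (optional; enables
#'   cycles/mm frequencies).
#' @return `radial_spectrum`: data.frame with `freq_cpi` (cycles/image),
#'   `amplitude`, and `freq_cpmm` when `crop_mm` is given; attributes
#'   `side_px`, `crop_mm`.
#' @export
rotational_average <- function(amp2d, crop_mm = NA_real_) {
  if (nrow(amp2d) != ncol(amp2d)) stop("amplitude grid must be square")
  n <- nrow(amp2d)
  ctr <- floor(n / 2) + 1
  dx <- seq_len(n) - ctr
  r <- sqrt(outer(dx^2, dx^2, "+"))
  ring <- floor(r + 0.5)
  rmax <- floor(n / 2)
  keep <- ring >= 1 & ring <= rmax
  sums <- tabulate(ring[keep], nbins = rmax)
  asum <- rep(0, rmax)
  tt <- tapply(amp2d[keep], ring[keep], sum)
  asum[as.integer(names(tt))] <- tt
  freqs <- which(sums > 0)
  out <- data.frame(freq_cpi = freqs, amplitude = asum[freqs] / sums[freqs])
  if (!is.na(crop_mm)) out$freq_cpmm <- out$freq_cpi / crop_mm
  structure(out, side_px = n, crop_mm = crop_mm,
            class = c("radial_spectrum", "data.frame"))
}

#' Standard analysed frequency range for a crop
#'
#' Frequencies from 5 cycles/image up to the crop side in pixels divided
#' by 10 (floor). The lower bound excludes the taper's own content; the
#' upper bound guards against aliasing.
#'
#' @param side_px crop side length in pixels (`>= 60`).
#' @return `c(f_lo = 5, f_hi = floor(side_px / 10))` in cycles/image.
#' @export
select_frequency_range <- function(side_px) {
  if (side_px < 60)
    stop("crop side ", side_px,
         " px leaves fewer than 2 analysable frequencies")
  f_hi <- floor(side_px / 10)
  c(f_lo = 5, f_hi = f_hi)
}

#' Harmonise analysed frequency ranges across one species
#'
#' Males and females of a species must be compared over the same physical
#' spatial scales, so per-image frequency bounds (cycles/image) are mapped
#' to cycles/mm and a common range is imposed. The common lower bound is, in
#' `"intent"` mode (default), the maximum of the per-member minimum
#' frequencies in cycles/mm — the smallest range containing every member's
#' floor, so every image is restricted identically; `"literal"` mode takes
#' the minimum instead (which excludes nothing). The common upper bound is
#' the minimum of the per-member maxima in cycles/mm, optionally capped at
#' the shortest-extension camera limit `cap_cpmm`.
#'
#' @param members data.frame with columns `side_px` and `crop_mm`, one row
#'   per image of the species.
#' @param cap_cpmm optional cycles/mm cap from [max_analyzed_frequency()].
#' @param mode `"intent"` or `"literal"` (see Details).
#' @return list: `f_lo_cpmm`, `f_hi_cpmm`, and `member_freqs_cpi` — for each
#'   member the integer cycles/image whose cycles/mm fall inside the common
#'   range.
#' @export
harmonize_species_range <- function(members, cap_cpmm = NULL,
                                    mode = c("intent", "literal")) {
  mode <- match.arg(mode)
  stopifnot(nrow(members) >= 1,
            all(c("side_px", "crop_mm") %in% names(members)))
  lo_i <- 5 / members$crop_mm
  hi_i <- floor(members$side_px / 10) / members$crop_mm
  f_lo <- if (mode == "intent") max(lo_i) else min(lo_i)
  f_hi <- min(hi_i)
  if (!is.null(cap_cpmm)) f_hi <- min(f_hi, cap_cpmm)
  if (f_lo >= f_hi)
    stop("harmonised frequency range is empty for this species")
  eps <- 1e-9
  member_freqs <- lapply(seq_len(nrow(members)), function(i) {
    mm <- members$crop_mm[i]
    lo_cpi <- max(5, ceiling(f_lo * mm - eps))
    hi_cpi <- min(floor(members$side_px[i] / 10), floor(f_hi * mm + eps))
    if (lo_cpi > hi_cpi)
      stop("harmonised range empty for member ", i)
    lo_cpi:hi_cpi
  })
  list(f_lo_cpmm = f_lo, f_hi_cpmm = f_hi, member_freqs_cpi = member_freqs)
}

#' Log-bin a radial spectrum
#'
#' On log-log axes, high frequencies are much more densely sampled than low
#' ones and would dominate an unweighted fit; the analysed frequencies are
#' therefore averaged into bins evenly spaced in log10 frequency (default
#' 9). Per bin, x is the mean log10 frequency of the members and y is the
#' log10 of the mean amplitude (mean first, then log). Empty bins are
#' dropped with a warning.
#'
#' @param freq analysed frequencies (cycles/image or cycles/mm).
#' @param amplitude matching amplitudes.
#' @param n_bins bin count (default 9).
#' @param x_convention `"mean_log"` (default) or `"geometric_center"` for
#'   the bin x coordinate.
#' @return data.frame `log10_freq`, `log10_amplitude`, `n_members`;
#'   attribute `n_bins_used`.
#' @export
bin_log_spectrum <- function(freq, amplitude, n_bins = 9,
                             x_convention = c("mean_log",
                                              "geometric_center")) {
  x_convention <- match.arg(x_convention)
  stopifnot(length(freq) == length(amplitude), all(freq > 0), n_bins >= 2)
  lf <- log10(freq)
  edges <- seq(min(lf), max(lf), length.out = n_bins + 1)
  bin <- findInterval(lf, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  present <- sort(unique(bin))
  if (length(present) < n_bins)
    warning(n_bins - length(present), " empty log-frequency bin(s) dropped")
  if (length(present) < 2) stop("fewer than 2 non-empty bins")
  xs <- vapply(present, function(b)
    if (x_convention == "mean_log") mean(lf[bin == b])
    else (edges[b] + edges[b + 1]) / 2, 0)
  ys <- vapply(present, function(b) log10(mean(amplitude[bin == b])), 0)
  ns <- vapply(present, function(b) sum(bin == b), 0L)
  structure(data.frame(log10_freq = xs, log10_amplitude = ys,
                       n_members = ns),
            n_bins_used = length(present))
}

#' Fit the spectral slope
#'
#' Ordinary least squares of log10 amplitude on log10 frequency over the
#' binned points. The slope is the image's second-order statistic of
#' interest (around -1 for natural scenes); the intercept tracks overall
#' contrast and the R^2 is reported for the binned regression actually
#' fitted.
#'
#' @param binned data.frame from [bin_log_spectrum()] (columns `log10_freq`,
#'   `log10_amplitude`).
#' @param f_range_cpi,f_range_cpmm optional analysed bounds to store.
#' @return `slope_fit`: `slope`, `intercept`, `r2`, bounds, `n_bins`,
#'   `bin_centers`, `bin_means`.
#' @export
fit_spectral_slope <- function(binned, f_range_cpi = c(NA, NA),
                               f_range_cpmm = c(NA, NA)) {
  x <- binned$log10_freq
  y <- binned$log10_amplitude
  if (length(x) < 2) stop("need at least 2 points to fit a slope")
  if (stats::var(x) == 0) stop("zero variance in log frequency")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 f_lo_cpi = f_range_cpi[1], f_hi_cpi = f_range_cpi[2],
                 f_lo_cpmm = f_range_cpmm[1], f_hi_cpmm = f_range_cpmm[2],
                 n_bins = length(x), bin_centers = x, bin_means = y),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> slope %.4f, intercept %.4f, R^2 %.4f (%d bins, f %g-%g cpi)\n",
    x$slope, x$intercept, x$r2, x$n_bins, x$f_lo_cpi, x$f_hi_cpi))
  invisible(x)
}

#' Measure the spectral slope of one image
#'
#' Convenience wrapper over the measurement chain: cosine taper, 2D FFT
#' amplitude spectrum, rotational averaging, standard frequency-range
#' selection, log-binning, least-squares fit.
#'
#' @param image square matrix (already cropped and preprocessed).
#' @param crop_mm physical crop side in mm (optional).
#' @param taper_frequency taper frequency, cycles/image.
#' @param n_bins log-frequency bin count.
#' @param freqs_cpi optional explicit set of integer cycles/image to analyse
#'   (e.g. a harmonised set); defaults to [select_frequency_range()].
#' @param taper apply the cosine taper (default TRUE).
#' @return [fit_spectral_slope()] result.
#' @export
measure_spectral_slope <- function(image, crop_mm = NA_real_,
                                   taper_frequency = 4, n_bins = 9,
                                   freqs_cpi = NULL, taper = TRUE) {
  img <- if (taper) cosine_taper(image, taper_frequency) else image
  rs <- rotational_average(amplitude_spectrum(img), crop_mm = crop_mm)
  if (is.null(freqs_cpi)) {
    fr <- select_frequency_range(nrow(image))
    freqs_cpi <- fr[1]:fr[2]
  }
  sel <- rs[rs$freq_cpi %in% freqs_cpi, ]
  if (nrow(sel) < 2) stop("fewer than 2 analysed frequencies")
  binned <- bin_log_spectrum(sel$freq_cpi, sel$amplitude, n_bins = n_bins)
  fit_spectral_slope(binned,
                     f_range_cpi = range(sel$freq_cpi),
                     f_range_cpmm = if (is.na(crop_mm)) c(NA, NA) else
                       range(sel$freq_cpi) / crop_mm)
}
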