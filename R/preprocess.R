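#' Estimate sensor dark noise from dark columns
#'
#' Cameras expose a few sensor columns that receive no light; their mean
#' gives the dark level subtracted from every pixel before any further
#' processing.
#'
#' @param dark_columns numeric matrix or vector of dark-column samples.
#' @return scalar mean dark level.
#' @export
estimate_dark_noise <- function(dark_columns) {
  if (length(dark_columns) == 0) stop("dark-column region is empty")
  mean(dark_columns)
}

#' Exposure-stability quality control
#'
#' Lighting must be stable while the filter wheel cycles. For every window
#' of three consecutive frames taken through the same filter, the relative
#' variation is `(max - min) / mean` of the three frame means; the set fails
#' if any window's variation is strictly greater than the threshold
#' (default 0.5%).
#'
#' @param frame_means per-frame mean pixel values for one filter, in
#'   acquisition order (`>= 3` frames).
#' @param threshold relative-variation threshold (default `0.005`).
#' @return list: `pass`, `max_variation`, `window_variation` (one value per
#'   3-frame window), `threshold`.
#' @export
check_exposure_stability <- function(frame_means, threshold = 0.005) {
  n <- length(frame_means)
  if (n < 3) stop("need at least 3 frames for stability QC")
  wv <- vapply(seq_len(n - 2L), function(i) {
    w <- frame_means[i:(i + 2L)]
    (max(w) - min(w)) / mean(w)
  }, 0)
  list(pass = all(wv <= threshold), max_variation = max(wv),
       window_variation = wv, threshold = threshold)
}

# sum and count of valid 8-neighbours, vectorised with padded shifts
neighbour_stats <- function(values, valid) {
  nr <- nrow(values); nc <- ncol(values)
  v <- matrix(0, nr + 2L, nc + 2L)
  ok <- matrix(FALSE, nr + 2L, nc + 2L)
  v[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(valid, values, 0)
  ok[2:(nr + 1L), 2:(nc + 1L)] <- valid
  s <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- (2:(nr + 1L)) + dr
    cs <- (2:(nc + 1L)) + dc
    s <- s + v[rs, cs]
    cnt <- cnt + ok[rs, cs]
  }
  list(sum = s, count = cnt)
}

#' Repair over- and underexposed pixels
#'
#' Each flagged pixel is replaced by the mean of its valid 8-neighbours,
#' excluding neighbours that are themselves flagged. Clusters are handled
#' iteratively: pixels repaired in one pass become valid donors in the next,
#' so fill proceeds inward from the cluster boundary. Run after conversion
#' to the computational receptor image.
#'
#' @param image numeric matrix.
#' @param bad logical matrix of flagged pixels, same shape.
#' @param max_iter iteration cap for pathological masks.
#' @return repaired matrix with attribute `repaired_pixels` (count).
#' @export
repair_saturated_pixels <- function(image, bad, max_iter = 1000L) {
  if (!identical(dim(image), dim(bad)))
    stop("bad-pixel mask must match image dimensions")
  bad <- bad & TRUE
  n_bad <- sum(bad)
  out <- image
  remaining <- bad
  it <- 0L
  while (any(remaining)) {
    it <- it + 1L
    if (it > max_iter)
      stop("flagged region has no valid neighbours; cannot repair")
    ns <- neighbour_stats(out, !remaining)
    fixable <- remaining & ns$count > 0L
    if (!any(fixable))
      stop("flagged region has no valid neighbours; cannot repair")
    out[fixable] <- ns$sum[fixable] / ns$count[fixable]
    remaining <- remaining & !fixable
  }
  attr(out, "repaired_pixels") <- n_bad
  out
}

#' Normalise an image by a reference mean
#'
#' Emulates light adaptation: every pixel is divided by the mean value of
#' the grey standard (specimen images) or by the image's own mean (scene
#' images).
#'
#' @param image numeric matrix.
#' @param reference_mean positive scalar.
#' @return normalised matrix.
#' @export
normalize_image <- function(image, reference_mean) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1 ||
      !is.finite(reference_mean) || reference_mean <= 0)
    stop("reference_mean must be a positive scalar")
  image / reference_mean
}

#' Naka-Rushton receptor excitation transform
#'
#' Converts normalised pixel values P to receptor excitation
#' `E = P / (P + 1)`: a saturating nonlinearity that is strictly increasing
#' and maps `[0, Inf)` into `[0, 1)`, with half-maximal excitation at the
#' adaptation level P = 1.
#'
#' @param image numeric matrix of normalised pixel values, all `>= 0`.
#' @return matrix of excitation values in `[0, 1)`.
#' @export
naka_rushton <- function(image) {
  if (any(image < 0)) stop("Naka-Rushton input must be non-negative")
  image / (image + 1)
}

#' Bundle a preprocessed receptor image with its provenance
#'
#' @param values excitation raster in `[0, 1)`.
#' @param normalization `"grey_standard"` or `"scene_mean"`.
#' @param repaired_pixels count of repaired pixels.
#' @return object of class `receptor_image`.
#' @export
receptor_image <- function(values,
                           normalization = c("grey_standard", "scene_mean"),
                           repaired_pixels = 0L) {
  normalization <- match.arg(normalization)
  if (any(values < 0) || any(values >= 1))
    stop("receptor excitation values must lie in [0, 1)")
  structure(list(values = values, normalization = normalization,
                 repaired_pixels = as.integer(repaired_pixels)),
            class = "receptor_image")
}

#' @export
print.receptor_image <- function(x, ...) {
  cat(sprintf(
    "<receptor_image> %d x %d, normalisation: %s, repaired px: %d\n",
    nrow(x$values), ncol(x$values), x$normalization, x$repaired_pixels))
  invisible(x)
}

#' Preprocess one multispectral stack into a receptor image
#'
#' The full chain in acquisition order: dark-noise subtraction, conversion
#' with computational-filter weights, repair of flagged pixels (after the
#' conversion), normalisation by the grey-standard patch mean (specimens) or
#' the image mean (scenes), then the Naka-Rushton transform.
#'
#' @param stack [mspec_stack].
#' @param weights `filter_weights` or numeric weight vector.
#' @param normalization `"grey_standard"` (requires `stack$grey_patch`) or
#'   `"scene_mean"`.
#' @return [receptor_image].
#' @export
preprocess_stack <- function(stack, weights,
                             normalization = c("grey_standard",
                                               "scene_mean")) {
  normalization <- match.arg(normalization)
  dark <- if (is.null(stack$dark_columns)) 0 else
    estimate_dark_noise(stack$dark_columns)
  sub <- lapply(stack$channels, function(ch) pmax(ch - dark, 0))
  stack2 <- stack
  stack2$channels <- sub
  recep <- apply_filter_weights(stack2, weights)
  sat <- attr(recep, "saturated")
  repaired <- if (any(sat)) repair_saturated_pixels(recep, sat) else recep
  n_rep <- sum(sat)
  ref <- if (normalization == "grey_standard") {
    gp <- stack$grey_patch
    if (is.null(gp))
      stop("grey_standard normalisation requires a grey patch in the stack")
    mean(repaired[gp$rows, gp$cols])
  } else {
    mean(repaired)
  }
  e <- naka_rushton(pmax(normalize_image(unclass(repaired), ref), 0))
  receptor_image(e, normalization, n_rep)
}
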