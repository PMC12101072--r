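#' Spectral sensitivity curve
#'
#' A wavelength grid (nm, strictly increasing) with non-negative,
#' dimensionless sensitivities. Used both for the camera's physical filters
#' (the basis) and for the target photoreceptor (e.g. a jumping spider's
#' green receptor peaking near 530 nm).
#'
#' @param wavelength_nm numeric, strictly increasing.
#' @param sensitivity numeric, finite, `>= 0`, same length.
#' @return object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(wavelength_nm, sensitivity) {
  wavelength_nm <- as.numeric(wavelength_nm)
  sensitivity <- as.numeric(sensitivity)
  if (length(wavelength_nm) != length(sensitivity))
    stop("wavelength and sensitivity lengths differ")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0))
    stop("sensitivities must be finite and non-negative")
  structure(list(wavelength_nm = wavelength_nm, sensitivity = sensitivity),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> %d points, %g-%g nm, peak %g at %g nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), max(x$sensitivity),
              x$wavelength_nm[which.max(x$sensitivity)]))
  invisible(x)
}

# Finest common wavelength grid over the intersection of all curve ranges.
common_grid <- function(curves) {
  lo <- max(vapply(curves, function(cu) min(cu$wavelength_nm), 0))
  hi <- min(vapply(curves, function(cu) max(cu$wavelength_nm), 0))
  if (hi <= lo) stop("curves have no common wavelength range")
  step <- min(vapply(curves, function(cu) min(diff(cu$wavelength_nm)), 0))
  seq(lo, hi, by = step)
}

curve_on_grid <- function(curve, grid) {
  stats::approx(curve$wavelength_nm, curve$sensitivity, xout = grid,
                rule = 1)$y
}

# Lawson-Hanson style non-negative least squares, x >= 0 minimising |Ax-b|.
nnls_fit <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  it <- 0L
  while (any(!passive & w > tol) && it < max_iter) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Fit a computational receptor filter
#'
#' Finds the weights that best combine the camera's filter sensitivities into
#' the target receptor sensitivity, by least squares over a common wavelength
#' grid. The same weights applied to a co-registered multispectral stack
#' yield the receptor's view of the scene.
#'
#' @param basis named list of [sensitivity_curve] (the camera filters).
#' @param target [sensitivity_curve] for the receptor to emulate.
#' @param nonneg constrain weights to be non-negative (default `FALSE`:
#'   unconstrained least squares).
#' @return `filter_weights` object: `weights` (one per basis filter),
#'   `fit_rmse`, `fit_r2`, the fitting grid and the fitted curve.
#' @export
fit_computational_filter <- function(basis, target, nonneg = FALSE) {
  stopifnot(length(basis) >= 1)
  basis <- lapply(basis, function(cu)
    if (inherits(cu, "sensitivity_curve")) cu else
      sensitivity_curve(cu$wavelength_nm, cu$sensitivity))
  grid <- common_grid(c(basis, list(target)))
  t_span <- diff(range(target$wavelength_nm))
  if (diff(range(grid)) < 0.5 * t_span)
    stop("wavelength grid overlap covers < 50% of the target support")
  A <- vapply(basis, curve_on_grid, numeric(length(grid)), grid = grid)
  y <- curve_on_grid(target, grid)
  if (nonneg) {
    w <- nnls_fit(A, y)
  } else {
    qa <- qr(A)
    if (qa$rank < ncol(A)) {
      warning("rank-deficient filter basis; returning minimum-norm solution")
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      w <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      w <- drop(w)
    } else {
      w <- drop(qr.coef(qa, y))
    }
  }
  names(w) <- names(basis)
  fitted <- drop(A %*% w)
  res <- y - fitted
  r2 <- if (stats::var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_
  structure(list(weights = w,
                 fit_rmse = sqrt(mean(res^2)),
                 fit_r2 = r2,
                 grid_nm = grid, fitted = fitted, target = y,
                 nonneg = nonneg),
            class = "filter_weights")
}

#' @export
print.filter_weights <- function(x, ...) {
  cat("<filter_weights>\n")
  print(round(x$weights, 6))
  cat(sprintf("fit RMSE %.3g, R^2 %.5f\n", x$fit_rmse, x$fit_r2))
  invisible(x)
}

#' Apply computational-filter weights to a multispectral stack
#'
#' Per-pixel weighted sum of the stack's channels. A pixel in the output is
#' flagged as saturated if any channel with a nonzero weight flags it.
#'
#' @param stack a [mspec_stack] (or plain named list of equal-size matrices).
#' @param w `filter_weights` from [fit_computational_filter()], or a bare
#'   numeric vector with one weight per channel.
#' @return numeric matrix with attribute `saturated` (logical matrix).
#' @export
apply_filter_weights <- function(stack, w) {
  if (inherits(w, "filter_weights")) w <- w$weights
  chans <- if (inherits(stack, "mspec_stack")) stack$channels else stack
  if (length(chans) != length(w))
    stop("channel count (", length(chans), ") != weight count (",
         length(w), ")")
  out <- 0
  for (k in seq_along(chans)) out <- out + w[k] * chans[[k]]
  out <- matrix(out, nrow = nrow(chans[[1]]))
  sat <- matrix(FALSE, nrow(out), ncol(out))
  if (inherits(stack, "mspec_stack")) {
    for (k in seq_along(chans))
      if (w[k] != 0) sat <- sat | stack$saturated[[k]]
  }
  attr(out, "saturated") <- sat
  out
}
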