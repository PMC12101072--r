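# Generic MCMC utilities: univariate slice sampler and the rank-normalised
# split-Rhat / bulk-ESS convergence diagnostics.

# Stepping-out univariate slice sampler (Neal 2003). logf must be a
# log-density up to a constant; bounds are respected by shrinkage.
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- max(x0 - u * w, lower)
  R <- max(L, min(x0 + (1 - u) * w, upper))
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(L - w, lower); k <- k - 1L }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(R + w, upper); k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# biased (1/n) autocovariance via FFT
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(Conj(f) * f, inverse = TRUE))[1:n] / (m * n)
}

rank_normalize <- function(draws) {
  z <- stats::qnorm((rank(draws) - 3 / 8) / (length(draws) + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}

split_chains <- function(draws) {
  n <- nrow(draws)
  h <- n %/% 2L
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1):n, , drop = FALSE])
}

rhat_basic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(colMeans(draws))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-Rhat convergence diagnostic
#'
#' Rank-normalised split-Rhat: chains are split in half, draws are replaced
#' by normal scores of their pooled ranks, and the classic potential
#' scale-reduction factor is computed on the result. Values at or below
#' 1.01 indicate convergence.
#'
#' @param draws iterations x chains matrix for one parameter (`>= 2`
#'   chains).
#' @return scalar Rhat (NA with a warning for zero-variance draws).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("Rhat requires at least 2 chains")
  if (stats::var(as.vector(draws)) == 0) {
    warning("zero-variance draws: Rhat undefined")
    return(NA_real_)
  }
  rhat_basic(rank_normalize(split_chains(draws)))
}

#' Bulk effective sample size
#'
#' Rank-normalised bulk ESS with Geyer's initial monotone positive sequence
#' estimator of the autocorrelation time, computed on split chains.
#'
#' @param draws iterations x chains matrix for one parameter.
#' @return scalar ESS (NA with a warning for zero-variance draws).
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("ESS requires at least 2 chains")
  if (stats::var(as.vector(draws)) == 0) {
    warning("zero-variance draws: ESS undefined")
    return(NA_real_)
  }
  z <- rank_normalize(split_chains(draws))
  n <- nrow(z); m <- ncol(z)
  acov <- apply(z, 2, autocov_fft)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + n * stats::var(colMeans(z)) / n
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer paired sums, truncated at first negative pair, forced monotone
  maxpair <- floor((n - 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in 0:maxpair) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  ess <- m * n / max(2 * tau - 1, 1e-12)
  min(ess, m * n * log10(m * n))
}

#' Convergence diagnostics for a set of chains
#'
#' @param draws 3-d array `[iteration, chain, parameter]` (or a matrix for a
#'   single parameter).
#' @return data.frame with one row per parameter: `parameter`, `rhat`,
#'   `ess_bulk`.
#' @export
convergence_diagnostics <- function(draws) {
  if (is.matrix(draws)) {
    draws <- array(draws, c(nrow(draws), ncol(draws), 1),
                   dimnames = list(NULL, NULL, "parameter"))
  }
  if (dim(draws)[2] < 2)
    stop("convergence diagnostics require at least 2 chains")
  pars <- dimnames(draws)[[3]]
  if (is.null(pars)) pars <- sprintf("par%d", seq_len(dim(draws)[3]))
  data.frame(
    parameter = pars,
    rhat = vapply(seq_len(dim(draws)[3]),
                  function(k) suppressWarnings(rhat(draws[, , k])), 0),
    ess_bulk = vapply(seq_len(dim(draws)[3]),
                      function(k) suppressWarnings(ess_bulk(draws[, , k])),
                      0))
}
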