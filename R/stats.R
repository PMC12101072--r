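#' Hierarchical Bayesian comparison of slope distributions
#'
#' Fits the joint Gaussian model behind the group comparison: spider slopes
#' get a fixed sex effect with species-level random intercepts and random
#' sex effects,
#' \deqn{y_{ij} = \alpha + \beta\,male_{ij} + a_j + b_j\,male_{ij} +
#'   \epsilon_{ij},}
#' with \eqn{(a_j, b_j)} bivariate zero-mean normal (SDs `tau_species`,
#' `tau_species_sex`, correlation `cor_species`), and natural-scene slopes
#' get a region mean each, \eqn{y_k = \mu_{region(k)} + \eta_k}. Priors are
#' weakly informative: improper flat on the fixed effects and region means,
#' half-Normal(0, 5) on all SDs, uniform on the random-effect correlation.
#'
#' Sampling is Gibbs for the conditionally conjugate blocks (fixed effects,
#' random effects, region means) with univariate slice updates for the SD
#' and correlation parameters — a correct MCMC for this conjugate normal
#' hierarchy that needs no tuning. Species without both sexes are dropped
#' (with a message), matching the paired design the sex contrast requires.
#'
#' @param cohort cohort data.frame (see [validate_cohort()]); scene rows are
#'   optional.
#' @param chains number of chains (default 4).
#' @param iterations total iterations per chain (default 5000).
#' @param warmup discarded warmup iterations per chain (default 2500).
#' @param seed integer seed.
#' @param prior_sd_scale scale of the half-Normal SD priors (default 5).
#' @return `slope_model_fit`: `draws` (iterations x chains x parameters
#'   array, warmup removed), `summary` (posterior mean, SD, 95% CrI, Rhat,
#'   bulk ESS per parameter), `regions`, `converged`.
#' @export
fit_hierarchical_model <- function(cohort, chains = 4L, iterations = 5000L,
                                   warmup = 2500L, seed = 1L,
                                   prior_sd_scale = 5) {
  cohort <- validate_cohort(cohort)
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  sp <- cohort[cohort$group == "spider", ]
  sc <- cohort[cohort$group == "scene", ]
  if (nrow(sp) == 0) stop("cohort has no spider rows")

  both <- tapply(sp$sex, sp$species, function(s) all(c("male", "female") %in% s))
  keep <- names(both)[both]
  if (length(keep) < length(both))
    message("dropping ", length(both) - length(keep),
            " species without both sexes")
  sp <- sp[sp$species %in% keep, ]
  J <- length(keep)
  if (J < 2)
    stop("random-slope model needs >= 2 species with both sexes; ",
         "use a fixed-effects model for a single species")

  y <- sp$slope
  male <- as.numeric(sp$sex == "male")
  spid <- match(sp$species, keep)
  nS <- length(y)
  n_j <- as.vector(rowsum(rep(1, nS), spid))
  nm_j <- as.vector(rowsum(male, spid))

  regions <- if (nrow(sc)) sort(unique(sc$region)) else character()
  yR <- lapply(regions, function(r) sc$slope[sc$region == r])
  nR <- vapply(yR, length, 0L)

  pars <- c("alpha", "beta_sex", "tau_species", "tau_species_sex",
            "cor_species", "sigma",
            if (length(regions)) paste0("mu_", regions),
            if (length(regions)) "sigma_scene",
            "female_mean", "male_mean",
            if (length(regions)) "scene_mean")
  kept <- iterations - warmup
  draws <- array(NA_real_, c(kept, chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  lsd_lo <- log(1e-6); lsd_hi <- log(1e3)
  log_halfnorm <- function(s) -s^2 / (2 * prior_sd_scale^2)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    # moment-based inits, jittered per chain
    fem <- mean(y[male == 0]); mal <- mean(y[male == 1])
    alpha <- fem + stats::rnorm(1, 0, 0.05)
    beta <- mal - fem + stats::rnorm(1, 0, 0.05)
    a <- stats::rnorm(J, 0, 0.05)
    b <- stats::rnorm(J, 0, 0.05)
    sigma <- max(stats::sd(y), 0.05) * stats::runif(1, 0.5, 1.5)
    tau_a <- 0.1 * stats::runif(1, 0.5, 2)
    tau_b <- 0.1 * stats::runif(1, 0.5, 2)
    rho <- 0
    mu_r <- vapply(yR, mean, 0)
    sigma_sc <- if (length(regions))
      max(stats::sd(sc$slope), 0.05) * stats::runif(1, 0.5, 1.5) else NA

    for (it in seq_len(iterations)) {
      ## fixed effects | Sigma, sigma — random effects integrated out
      ## (blocked update; avoids the ridge between alpha and the a_j when
      ## the residual SD is tiny). Per species, V_j = sigma^2 I + Z S Z',
      ## and Z_j = X_j here, so Woodbury gives 2x2 arithmetic throughout.
      s2 <- sigma^2
      det_S <- tau_a^2 * tau_b^2 * (1 - rho^2)
      Sm <- matrix(c(tau_a^2, rho * tau_a * tau_b,
                     rho * tau_a * tau_b, tau_b^2), 2)
      A <- matrix(0, 2, 2); m0 <- c(0, 0)
      sy <- as.vector(rowsum(y, spid))
      sym <- as.vector(rowsum(y * male, spid))
      for (j in seq_len(J)) {
        G <- matrix(c(n_j[j], nm_j[j], nm_j[j], nm_j[j]), 2)
        tj <- c(sy[j], sym[j])
        M <- solve(s2 * solve(Sm) + G)
        A <- A + (G - G %*% M %*% G) / s2
        m0 <- m0 + (tj - G %*% M %*% tj) / s2
      }
      Ainv <- solve(A)
      fx <- drop(Ainv %*% m0) + drop(t(chol(Ainv)) %*% stats::rnorm(2))
      alpha <- fx[1]; beta <- fx[2]

      ## random effects | fixed, Sigma, sigma  (vectorised 2x2 solves)
      r2 <- y - alpha - beta * male
      S1 <- as.vector(rowsum(r2, spid))
      S2 <- as.vector(rowsum(r2 * male, spid))
      s2 <- sigma^2
      det_S <- tau_a^2 * tau_b^2 * (1 - rho^2)
      Si11 <- tau_b^2 / det_S
      Si22 <- tau_a^2 / det_S
      Si12 <- -rho * tau_a * tau_b / det_S
      P11 <- Si11 + n_j / s2
      P12 <- Si12 + nm_j / s2
      P22 <- Si22 + nm_j / s2
      dP <- P11 * P22 - P12^2
      q1 <- S1 / s2; q2 <- S2 / s2
      ma <- (P22 * q1 - P12 * q2) / dP
      mb <- (P11 * q2 - P12 * q1) / dP
      C11 <- P22 / dP; C12 <- -P12 / dP; C22 <- P11 / dP
      L11 <- sqrt(C11)
      L21 <- C12 / L11
      L22 <- sqrt(pmax(C22 - L21^2, 1e-300))
      z1 <- stats::rnorm(J); z2 <- stats::rnorm(J)
      a <- ma + L11 * z1
      b <- mb + L21 * z1 + L22 * z2

      ## residual SD | rest (slice on log sigma, half-normal prior)
      SSR <- sum((r2 - a[spid] - b[spid] * male)^2)
      ls <- slice_sample1(log(sigma), function(l)
        -nS * l - SSR / 2 * exp(-2 * l) + log_halfnorm(exp(l)) + l,
        w = 0.5, lower = lsd_lo, upper = lsd_hi)
      sigma <- exp(ls)

      ## random-effect SDs and correlation | a, b
      biv_ll <- function(ta, tb, rh) {
        om <- 1 - rh^2
        -J * (log(ta) + log(tb) + 0.5 * log(om)) -
          sum(a^2 / ta^2 - 2 * rh * a * b / (ta * tb) + b^2 / tb^2) / (2 * om)
      }
      tau_a <- exp(slice_sample1(log(tau_a), function(l)
        biv_ll(exp(l), tau_b, rho) + log_halfnorm(exp(l)) + l,
        w = 0.5, lower = lsd_lo, upper = lsd_hi))
      tau_b <- exp(slice_sample1(log(tau_b), function(l)
        biv_ll(tau_a, exp(l), rho) + log_halfnorm(exp(l)) + l,
        w = 0.5, lower = lsd_lo, upper = lsd_hi))
      rho <- tanh(slice_sample1(atanh(rho), function(z)
        biv_ll(tau_a, tau_b, tanh(z)) + log(1 - tanh(z)^2),
        w = 0.5, lower = -5, upper = 5))

      ## scene submodel
      if (length(regions)) {
        for (g in seq_along(regions))
          mu_r[g] <- stats::rnorm(1, mean(yR[[g]]), sigma_sc / sqrt(nR[g]))
        SSRs <- sum(unlist(Map(function(yy, mu) (yy - mu)^2, yR, mu_r)))
        sigma_sc <- exp(slice_sample1(log(sigma_sc), function(l)
          -sum(nR) * l - SSRs / 2 * exp(-2 * l) + log_halfnorm(exp(l)) + l,
          w = 0.5, lower = lsd_lo, upper = lsd_hi))
      }

      if (it > warmup) {
        k <- it - warmup
        vals <- c(alpha, beta, tau_a, tau_b, rho, sigma,
                  if (length(regions)) mu_r,
                  if (length(regions)) sigma_sc,
                  alpha, alpha + beta,
                  if (length(regions)) mean(mu_r))
        draws[k, ch, ] <- vals
      }
    }
  }

  summ <- summarize_draws(draws)
  converged <- chains < 2 || all(is.na(summ$rhat) | summ$rhat <= 1.01)
  if (!converged)
    warning("possible non-convergence: max Rhat = ",
            round(max(summ$rhat, na.rm = TRUE), 3),
            "; summaries emitted anyway")
  structure(list(draws = draws, summary = summ, regions = regions,
                 species = keep, converged = converged,
                 settings = list(chains = chains, iterations = iterations,
                                 warmup = warmup, seed = seed,
                                 prior_sd_scale = prior_sd_scale)),
            class = "slope_model_fit")
}

#' Summarise posterior draws
#'
#' @param draws iterations x chains x parameters array.
#' @return data.frame: `parameter`, `mean`, `sd`, `cri_lo`, `cri_hi` (95%
#'   equal-tailed), `rhat`, `ess_bulk`.
#' @export
summarize_draws <- function(draws) {
  pars <- dimnames(draws)[[3]]
  multi <- dim(draws)[2] >= 2
  out <- lapply(seq_along(pars), function(k) {
    d <- draws[, , k]
    v <- as.vector(d)
    data.frame(parameter = pars[k], mean = mean(v), sd = stats::sd(v),
               cri_lo = unname(stats::quantile(v, 0.025)),
               cri_hi = unname(stats::quantile(v, 0.975)),
               rhat = if (multi) suppressWarnings(rhat(d)) else NA_real_,
               ess_bulk = if (multi) suppressWarnings(ess_bulk(d))
                          else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.slope_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<slope_model_fit> %d species, %d chains x %d draws%s\n",
              length(x$species), dim(x$draws)[2], dim(x$draws)[1],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  df <- x$summary
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

group_mean_draws <- function(fit, name) {
  pars <- dimnames(fit$draws)[[3]]
  if (!name %in% pars)
    stop("unknown group/parameter '", name, "'; available: ",
         paste(pars, collapse = ", "))
  as.vector(fit$draws[, , name])
}

#' Posterior contrast between two group means
#'
#' Per-draw difference `a - b` between two fitted group means (or any two
#' sampled parameters), summarised by its posterior mean (the effect size
#' Delta), SD, and 95% equal-tailed credible interval, plus a
#' `crosses_zero` verdict: an interval excluding zero is read as credible
#' evidence of a difference.
#'
#' @param fit `slope_model_fit`, or a numeric vector of draws for `a`.
#' @param a,b parameter names (e.g. `"male_mean"`, `"female_mean"`,
#'   `"scene_mean"`) when `fit` is a model fit; when `fit` is numeric, `a`
#'   must be the numeric draws for the second group and `b` is ignored.
#' @return `slope_contrast` list: `delta_mean`, `delta_sd`, `cri_lo`,
#'   `cri_hi`, `crosses_zero`, `label`.
#' @export
contrast <- function(fit, a, b = NULL) {
  if (inherits(fit, "slope_model_fit")) {
    da <- group_mean_draws(fit, a)
    db <- group_mean_draws(fit, b)
    label <- paste(a, "-", b)
  } else {
    da <- as.numeric(fit)
    db <- as.numeric(a)
    label <- "a - b"
  }
  if (length(da) != length(db)) stop("mismatched draw counts")
  d <- da - db
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  structure(list(delta_mean = mean(d), delta_sd = stats::sd(d),
                 cri_lo = ci[1], cri_hi = ci[2],
                 crosses_zero = ci[1] <= 0 && ci[2] >= 0,
                 label = label),
            class = "slope_contrast")
}

#' @export
print.slope_contrast <- function(x, ...) {
  cat(sprintf(
    "<contrast %s> Delta = %.3f (SD %.3f; 95%% CrI %.3f to %.3f) %s\n",
    x$label, x$delta_mean, x$delta_sd, x$cri_lo, x$cri_hi,
    if (x$crosses_zero) "[CrI crosses zero]" else "[credible difference]"))
  invisible(x)
}
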