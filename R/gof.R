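# Goodness-of-fit engine: per-feature marginal fits of five count models
# (NB, ZINB, zero-inflated Gaussian, hurdle Gaussian, Dirichlet-multinomial),
# each summarized by its estimated mean count (EY) and zero probability (P0),
# and scored against the observed per-feature means and zero fractions.
#
# All fits are intercept-only (no covariates): the question is whether the
# marginal distribution of counts is captured, not a regression fit.
# Dispersion is parametrized throughout as variance = mu + phi * mu^2.

GOF_PHI_MIN <- 1e-10
GOF_PHI_MAX <- 1e4
GOF_MAX_ITER <- 500L
GOF_TOL <- 1e-8

new_fit_stats <- function(model, feature_ids, EY, P0, converged, params) {
  structure(list(model = model, feature_ids = feature_ids,
                 EY = as.numeric(EY), P0 = as.numeric(P0),
                 converged = as.logical(converged), params = params),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("<fit_stats> %s: %d features, %.0f%% converged\n",
              x$model, length(x$EY), 100 * mean(x$converged)))
  invisible(x)
}

# Zero mass of NB(mu, phi) with the Poisson limit for tiny dispersion.
nb_zero_prob <- function(mu, phi) {
  if (mu == 0) return(1)
  if (phi < 1e-8) exp(-mu) else exp(-log1p(phi * mu) / phi)
}

# Intercept-only NB maximum likelihood for one feature: the ML mean is the
# sample mean for any dispersion, so only phi is profiled (on the log scale).
nb_fit_one <- function(x) {
  mu <- mean(x)
  if (mu == 0) return(list(mu = 0, phi = 0, EY = 0, P0 = 1, converged = TRUE))
  ll <- function(lphi) sum(stats::dnbinom(x, mu = mu, size = exp(-lphi), log = TRUE))
  opt <- tryCatch(
    stats::optimize(ll, c(log(GOF_PHI_MIN), log(GOF_PHI_MAX)),
                    maximum = TRUE, tol = GOF_TOL),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective))
    return(list(mu = mu, phi = NA_real_, EY = mu, P0 = NA_real_, converged = FALSE))
  phi <- exp(opt$maximum)
  # the boundary (Poisson) can beat the interior optimum for underdispersed data
  if (sum(stats::dpois(x, mu, log = TRUE)) >= opt$objective) phi <- GOF_PHI_MIN
  list(mu = mu, phi = phi, EY = mu, P0 = nb_zero_prob(mu, phi), converged = TRUE)
}

#' Fit a negative binomial model per feature
#'
#' Per-feature intercept-only ML fit of NB with variance `mu + phi * mu^2`.
#' `EY = mu`; `P0 = (1 + phi mu)^(-1/phi)`, with the Poisson limit
#' `exp(-mu)` when `phi < 1e-8`. All-zero features get `EY = 0`, `P0 = 1`.
#'
#' @param table A [count_table()] with at least 2 samples.
#' @return A `fit_stats` object with per-feature `EY`, `P0`, `converged`
#'   and `params` (`mu`, `dispersion`).
#' @export
fit_nb <- function(table) {
  x <- unclass(table)
  fits <- apply(x, 1L, nb_fit_one)
  new_fit_stats("NB", rownames(x),
                vapply(fits, `[[`, numeric(1), "EY"),
                vapply(fits, `[[`, numeric(1), "P0"),
                vapply(fits, `[[`, logical(1), "converged"),
                data.frame(mu = vapply(fits, `[[`, numeric(1), "mu"),
                           dispersion = vapply(fits, `[[`, numeric(1), "phi")))
}

zinb_loglik <- function(x, pi0, mu, phi) {
  p0nb <- nb_zero_prob(mu, phi)
  lz <- log(pi0 + (1 - pi0) * p0nb)
  lnz <- log1p(-pi0) + stats::dnbinom(x, mu = mu, size = 1 / max(phi, GOF_PHI_MIN),
                                      log = TRUE)
  sum(ifelse(x == 0, lz, lnz))
}

# EM for one feature under pi0 * delta_0 + (1 - pi0) * NB(mu, phi).
# Both M-sub-steps (weighted mean for mu; 1-d profile for phi) are exact
# conditional maximizations, so the observed-data likelihood is monotone.
zinb_fit_one <- function(x, max_iter = GOF_MAX_ITER, tol = GOF_TOL,
                         trace = FALSE) {
  if (all(x == 0))
    return(list(mu = 0, phi = 0, pi0 = 1, EY = 0, P0 = 1, converged = TRUE))
  if (!any(x == 0)) {
    f <- nb_fit_one(x)
    return(list(mu = f$mu, phi = f$phi, pi0 = 0, EY = f$EY, P0 = f$P0,
                converged = f$converged))
  }
  mu <- mean(x[x > 0]); phi <- 0.5
  pi0 <- max(0.01, min(0.99, mean(x == 0) - nb_zero_prob(mu, phi)))
  ll_old <- -Inf; converged <- FALSE
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    p0nb <- nb_zero_prob(mu, phi)
    z <- ifelse(x == 0, pi0 / (pi0 + (1 - pi0) * p0nb), 0)
    pi0 <- mean(z)
    w <- 1 - z
    mu <- sum(w * x) / sum(w)
    obj <- function(lphi) sum(w * stats::dnbinom(x, mu = mu, size = exp(-lphi),
                                                 log = TRUE))
    opt <- stats::optimize(obj, c(log(GOF_PHI_MIN), log(GOF_PHI_MAX)),
                           maximum = TRUE, tol = GOF_TOL)
    phi <- exp(opt$maximum)
    ll <- zinb_loglik(x, pi0, mu, phi)
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  out <- list(mu = mu, phi = phi, pi0 = pi0, EY = (1 - pi0) * mu,
              P0 = pi0 + (1 - pi0) * nb_zero_prob(mu, phi),
              converged = converged)
  if (trace) out$ll_trace <- ll_trace
  out
}

#' Fit a zero-inflated negative binomial model per feature
#'
#' EM fit of the mixture `pi0 * delta_0 + (1 - pi0) * NB(mu, phi)` per
#' feature. `EY = (1 - pi0) mu`; `P0 = pi0 + (1 - pi0)(1 + phi mu)^(-1/phi)`.
#' Features with no observed zeros collapse to the plain NB fit with
#' `pi0 = 0`.
#'
#' @inheritParams fit_nb
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A `fit_stats` object with `params` (`mu`, `dispersion`, `pi0`).
#' @export
fit_zinb <- function(table, max_iter = GOF_MAX_ITER, tol = GOF_TOL) {
  x <- unclass(table)
  fits <- apply(x, 1L, zinb_fit_one, max_iter = max_iter, tol = tol)
  new_fit_stats("ZINB", rownames(x),
                vapply(fits, `[[`, numeric(1), "EY"),
                vapply(fits, `[[`, numeric(1), "P0"),
                vapply(fits, `[[`, logical(1), "converged"),
                data.frame(mu = vapply(fits, `[[`, numeric(1), "mu"),
                           dispersion = vapply(fits, `[[`, numeric(1), "phi"),
                           pi0 = vapply(fits, `[[`, numeric(1), "pi0")))
}

# Boundary below which a back-transformed log2 value counts as "zero":
# 2^z - 1 < 0.5, i.e. z < log2(1.5). A continuous model needs an explicit
# zero event to have a zero probability at all.
ZIG_ZERO_BOUNDARY <- log2(1.5)

zig_summaries <- function(pi0, mu, sigma) {
  P0 <- if (sigma > 0) {
    pi0 + (1 - pi0) * stats::pnorm((ZIG_ZERO_BOUNDARY - mu) / sigma)
  } else {
    pi0 + (1 - pi0) * as.numeric(mu < ZIG_ZERO_BOUNDARY)
  }
  EY <- (1 - pi0) * max(0, 2^(mu + sigma^2 * log(2) / 2) - 1)
  list(P0 = min(1, max(0, P0)), EY = EY)
}

zig_fit_one <- function(x, max_iter = GOF_MAX_ITER, tol = GOF_TOL) {
  z <- log2(x + 1)
  zero <- z == 0
  if (all(zero))
    return(list(pi0 = 1, mu_log = 0, sigma_log = 0, EY = 0, P0 = 1,
                converged = TRUE))
  point_mass <- function() {
    pi0 <- mean(zero)
    zp <- z[!zero]
    mu <- mean(zp)
    sigma <- if (length(zp) >= 2L) sqrt(mean((zp - mu)^2)) else 0
    s <- zig_summaries(pi0, mu, sigma)
    list(pi0 = pi0, mu_log = mu, sigma_log = sigma, EY = s$EY, P0 = s$P0,
         converged = TRUE)
  }
  if (!any(zero)) {
    mu <- mean(z); sigma <- sqrt(mean((z - mu)^2))
    s <- zig_summaries(0, mu, sigma)
    return(list(pi0 = 0, mu_log = mu, sigma_log = sigma, EY = s$EY, P0 = s$P0,
                converged = TRUE))
  }
  # (near-)constant positive part: the Gaussian component degenerates to a
  # point mass and the unbounded-likelihood ML is the hurdle-like solution
  if (sum(!zero) < 2L || stats::sd(z[!zero]) < 1e-8) return(point_mass())
  mu <- mean(z[!zero])
  sigma <- max(stats::sd(z), 1e-3)
  pi0 <- 0.9 * mean(zero)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d0 <- stats::dnorm(0, mu, sigma)
    r <- ifelse(zero, pi0 / (pi0 + (1 - pi0) * d0), 0)
    pi0 <- mean(r)
    w <- 1 - r
    mu <- sum(w * z) / sum(w)
    sigma <- sqrt(sum(w * (z - mu)^2) / sum(w))
    if (!is.finite(sigma) || sigma < 1e-6) return(point_mass())
    ll <- sum(ifelse(zero,
                     log(pi0 + (1 - pi0) * stats::dnorm(0, mu, sigma)),
                     log1p(-pi0) + stats::dnorm(z, mu, sigma, log = TRUE)))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  s <- zig_summaries(pi0, mu, sigma)
  list(pi0 = pi0, mu_log = mu, sigma_log = sigma, EY = s$EY, P0 = s$P0,
       converged = converged)
}

#' Fit a zero-inflated Gaussian model per feature
#'
#' EM fit, on `z = log2(count + 1)`, of a point mass at zero mixed with a
#' Gaussian. `P0` adds to `pi0` the Gaussian mass below the back-transformed
#' zero boundary `z < log2(1.5)`; `EY` is the lognormal back-transform of
#' the Gaussian component, floored at 0.
#'
#' @inheritParams fit_zinb
#' @return A `fit_stats` object with `params` (`mu_log`, `sigma_log`, `pi0`).
#' @export
fit_zig <- function(table, max_iter = GOF_MAX_ITER, tol = GOF_TOL) {
  x <- unclass(table)
  fits <- apply(x, 1L, zig_fit_one, max_iter = max_iter, tol = tol)
  new_fit_stats("ZIG", rownames(x),
                vapply(fits, `[[`, numeric(1), "EY"),
                vapply(fits, `[[`, numeric(1), "P0"),
                vapply(fits, `[[`, logical(1), "converged"),
                data.frame(mu_log = vapply(fits, `[[`, numeric(1), "mu_log"),
                           sigma_log = vapply(fits, `[[`, numeric(1), "sigma_log"),
                           pi0 = vapply(fits, `[[`, numeric(1), "pi0")))
}

#' Fit a hurdle (truncated Gaussian) model per feature
#'
#' The zero mass is the observed zero fraction, exactly; the positive part
#' is a Gaussian ML fit on `log2(count + 1)` restricted to positive counts.
#' By construction `P0` equals the observed zero fraction, so the
#' zero-probability error of this model is identically 0.
#'
#' @inheritParams fit_nb
#' @return A `fit_stats` object with `params` (`mu_pos`, `sigma_pos`, `pi0`).
#' @export
fit_hurdle <- function(table) {
  x <- unclass(table)
  fits <- apply(x, 1L, function(xi) {
    pi0 <- mean(xi == 0)
    zp <- log2(xi[xi > 0] + 1)
    mu <- if (length(zp)) mean(zp) else 0
    sigma <- if (length(zp) >= 2L) sqrt(mean((zp - mu)^2)) else 0
    EY <- (1 - pi0) * max(0, 2^(mu + sigma^2 * log(2) / 2) - 1)
    list(pi0 = pi0, mu_pos = mu, sigma_pos = sigma, EY = EY, P0 = pi0)
  })
  new_fit_stats("HURDLE", rownames(x),
                vapply(fits, `[[`, numeric(1), "EY"),
                vapply(fits, `[[`, numeric(1), "P0"),
                rep(TRUE, nrow(x)),
                data.frame(mu_pos = vapply(fits, `[[`, numeric(1), "mu_pos"),
                           sigma_pos = vapply(fits, `[[`, numeric(1), "sigma_pos"),
                           pi0 = vapply(fits, `[[`, numeric(1), "pi0")))
}

dm_loglik <- function(x, alpha) {
  alpha0 <- sum(alpha)
  N <- colSums(x)
  sum(lgamma(alpha0) - lgamma(N + alpha0) +
        colSums(lgamma(x + alpha) - lgamma(alpha)))
}

#' Fit a Dirichlet-multinomial model jointly over features
#'
#' Joint ML estimate of the concentration vector `alpha` by the standard
#' fixed-point iteration on the digamma score equations. Per feature,
#' `EY_i` is the mean over samples of `N_j * alpha_i / alpha0` and `P0_i`
#' the mean beta-binomial zero mass
#' `B(alpha_i, alpha0 - alpha_i + N_j) / B(alpha_i, alpha0 - alpha_i)`.
#'
#' @param table A [count_table()] with at least 2 features and 2 samples.
#' @param max_iter,tol Fixed-point iteration cap and relative
#'   log-likelihood tolerance.
#' @return A `fit_stats` object with `params` (`alpha`, scalar `alpha0`).
#' @export
fit_dm <- function(table, max_iter = GOF_MAX_ITER, tol = GOF_TOL) {
  x <- unclass(table)
  if (nrow(x) < 2L) stopf("Dirichlet-multinomial needs >= 2 features")
  if (ncol(x) < 2L) stopf("Dirichlet-multinomial needs >= 2 samples to estimate overdispersion")
  n <- ncol(x)
  N <- colSums(x)
  pbar <- rowMeans(sweep(x, 2L, pmax(N, 1), "/"))
  alpha <- pmax(pbar, 1e-10) * 10
  ll_old <- dm_loglik(x, alpha)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    alpha0 <- sum(alpha)
    den <- sum(digamma(N + alpha0)) - n * digamma(alpha0)
    num <- rowSums(digamma(x + alpha)) - n * digamma(alpha)
    alpha <- pmax(alpha * num / den, 1e-10)
    ll <- dm_loglik(x, alpha)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  if (!converged)
    warning(sprintf("Dirichlet-multinomial fixed point did not converge in %d iterations",
                    max_iter))
  alpha0 <- sum(alpha)
  EY <- alpha / alpha0 * mean(N)
  beta <- alpha0 - alpha
  P0 <- vapply(seq_len(nrow(x)), function(i) {
    mean(exp(lbeta(alpha[i], beta[i] + N) - lbeta(alpha[i], beta[i])))
  }, numeric(1))
  new_fit_stats("DM", rownames(x), EY, pmin(1, pmax(0, P0)),
                rep(converged, nrow(x)),
                list(alpha = stats::setNames(alpha, rownames(x)), alpha0 = alpha0))
}

#' Score a fit against the observed table
#'
#' Per feature: mean difference `MD = log(EY + 1) - log(mean count + 1)`
#' and zero-probability difference `ZPD = P0 - observed zero fraction`.
#' RMSEs are taken over converged features only; the convergence fraction
#' is reported alongside.
#'
#' @param fit A `fit_stats` object computed on `table`.
#' @param table The [count_table()] the fit was computed on.
#' @return A list of class `gof_metrics` with `MD`, `ZPD`, `RMSE_MD`,
#'   `RMSE_ZPD` and `frac_converged`.
#' @export
evaluate_fit <- function(fit, table) {
  stopifnot(inherits(fit, "fit_stats"))
  x <- unclass(table)
  if (length(fit$EY) != nrow(x) || !identical(fit$feature_ids, rownames(x)))
    stopf("fit and table cover different features")
  MD <- log(fit$EY + 1) - log(rowMeans(x) + 1)
  ZPD <- fit$P0 - rowMeans(x == 0)
  conv <- fit$converged & is.finite(MD) & is.finite(ZPD)
  structure(list(model = fit$model, feature_ids = fit$feature_ids,
                 MD = MD, ZPD = ZPD,
                 RMSE_MD = sqrt(mean(MD[conv]^2)),
                 RMSE_ZPD = sqrt(mean(ZPD[conv]^2)),
                 frac_converged = mean(fit$converged)),
            class = "gof_metrics")
}

#' Rank fitted models by goodness of fit
#'
#' @param fits List of `fit_stats` objects (typically the five models).
#' @param table The [count_table()] they were fitted on.
#' @return Data frame with one row per model (`model`, `RMSE_MD`,
#'   `RMSE_ZPD`, `frac_converged`), sorted by `RMSE_ZPD` then `RMSE_MD`.
#' @export
compare_fits <- function(fits, table) {
  if (inherits(fits, "fit_stats")) fits <- list(fits)
  if (length(fits) < 1L) stopf("need at least one fit")
  rows <- lapply(fits, function(f) {
    m <- evaluate_fit(f, table)
    data.frame(model = m$model, RMSE_MD = m$RMSE_MD, RMSE_ZPD = m$RMSE_ZPD,
               frac_converged = m$frac_converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$RMSE_ZPD, out$RMSE_MD), , drop = FALSE]
}

# All five fitters keyed by model name; used by the workflow runner.
#' @noRd
gof_fitters <- function() {
  list(NB = fit_nb, ZINB = fit_zinb, ZIG = fit_zig, HURDLE = fit_hurdle,
       DM = fit_dm)
}
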