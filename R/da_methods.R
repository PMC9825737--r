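# Pluggable DA-method layer: a registry of method specs (test + paired
# normalization + params) and three native two-group methods. Every method
# returns a `da_result` (p_raw, p_adj, statistic, direction) — the contract
# all downstream engines consume. Custom methods plug in as functions with
# signature function(exp, norm, params, seed).

#' Create an empty method registry
#' @return A `method_registry` object.
#' @export
method_registry <- function() {
  structure(list(methods = list()), class = "method_registry")
}

#' Describe a DA method to be run by the framework
#'
#' @param method_id Unique identifier within a registry.
#' @param test Either one of the native test names `"wilcoxon"`,
#'   `"ttest_clr"`, `"negbin_wald"`, or a plugin function with signature
#'   `function(exp, norm, params, seed)` returning a [da_result()].
#' @param normalization One of `"TSS"`, `"CLR"`, `"TMM"`, `"RLE"`, `"CSS"`,
#'   `"none"`.
#' @param params Named list of test parameters.
#' @param seed Optional method-level seed (used by stochastic tests).
#' @return A `method_spec` object.
#' @export
method_spec <- function(method_id, test, normalization = "TSS",
                        params = list(), seed = NULL) {
  if (!is.character(method_id) || length(method_id) != 1L || !nzchar(method_id))
    stopf("method_id must be a non-empty string")
  if (is.character(test)) {
    if (!test %in% c("wilcoxon", "ttest_clr", "negbin_wald"))
      stopf("unknown native test '%s'", test)
  } else if (!is.function(test)) {
    stopf("test must be a native test name or a function")
  }
  normalization <- match.arg(normalization,
                             c("TSS", "CLR", "TMM", "RLE", "CSS", "none"))
  structure(list(method_id = method_id, test = test,
                 normalization = normalization, params = params, seed = seed),
            class = "method_spec")
}

#' Register a method spec
#'
#' @param spec A [method_spec()].
#' @param registry A [method_registry()].
#' @return The updated registry; listing order is insertion order.
#' @export
register_method <- function(spec, registry) {
  stopifnot(inherits(spec, "method_spec"), inherits(registry, "method_registry"))
  if (spec$method_id %in% names(registry$methods))
    stopf("method id '%s' already registered", spec$method_id)
  registry$methods[[spec$method_id]] <- spec
  registry
}

#' @export
print.method_registry <- function(x, ...) {
  cat(sprintf("<method_registry> %d method(s): %s\n", length(x$methods),
              paste(names(x$methods), collapse = ", ")))
  invisible(x)
}

# ---- native tests -----------------------------------------------------------

two_group_index <- function(exp) {
  g <- exp$group
  if (nlevels(g) != 2L)
    stopf("native DA methods need exactly 2 groups (found %d)", nlevels(g))
  idx1 <- which(g == levels(g)[1L])
  idx2 <- which(g == levels(g)[2L])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stopf("each group needs >= 2 samples")
  list(idx1 = idx1, idx2 = idx2)
}

# Two-sided Wilcoxon rank-sum on one feature, exact when the sample is
# tie-free and small (pwilcox), normal approximation with tie correction and
# continuity correction otherwise — mirroring the classical test so that the
# generic stats implementation can serve as an oracle in the tests.
wilcox_one <- function(v, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  if (all(v == v[1L])) return(list(p = NA_real_, stat = NA_real_, dir = 0L))
  r <- rank(v)
  U <- sum(r[idx1]) - n1 * (n1 + 1) / 2
  stat <- U - n1 * n2 / 2  # centred Mann-Whitney statistic
  has_ties <- anyDuplicated(r) > 0L
  if (!has_ties && n1 < 50 && n2 < 50) {
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(p = 1, stat = stat, dir = 0L))
    z <- (stat - sign(stat) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  dir <- sign(stats::median(v[idx2]) - stats::median(v[idx1]))
  list(p = p, stat = stat, dir = as.integer(dir))
}

#' Wilcoxon rank-sum DA test
#'
#' Per-feature two-sided Wilcoxon rank-sum on normalized abundances
#' (CLR-transformed values when `norm` is CLR, counts divided by the
#' per-sample scale otherwise). The statistic is the centred Mann-Whitney
#' statistic; direction is the sign of the group-2 minus group-1 median.
#' Features constant across all samples get a missing p-value.
#'
#' @param exp A [validate_experiment()] object with exactly 2 groups.
#' @param norm A `norm_factors` object for `exp$table`.
#' @return A [da_result()].
#' @export
da_wilcoxon <- function(exp, norm = norm_tss(exp$table)) {
  gi <- two_group_index(exp)
  mat <- normalized_matrix(exp$table, norm)
  fits <- apply(mat, 1L, wilcox_one, idx1 = gi$idx1, idx2 = gi$idx2)
  da_result("wilcoxon", rownames(exp$table),
            vapply(fits, `[[`, numeric(1), "p"),
            vapply(fits, `[[`, numeric(1), "stat"),
            vapply(fits, `[[`, integer(1), "dir"),
            params = list(test = "wilcoxon", normalization = norm$method))
}

# Vectorized Welch t-test over the rows of `mat`.
welch_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- apply(mat[, idx1, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, idx2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  diff <- m2 - m1
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  t[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
  list(p = p, t = t, diff = diff)
}

#' CLR t-test DA method (optionally Dirichlet Monte-Carlo averaged)
#'
#' With `mc_samples = 0`: Welch t-test per feature on CLR-transformed
#' counts (`log(count + pseudocount)` centred per sample). With
#' `mc_samples = W > 0`: W Dirichlet instances are drawn per sample with
#' concentration `counts + 0.5`, each instance is CLR-transformed and
#' Welch-tested, and the per-feature p-value is the mean over instances —
#' an ALDEx2-style compositional test.
#'
#' @param exp A [validate_experiment()] object with exactly 2 groups.
#' @param pseudocount Offset for the `mc_samples = 0` CLR transform.
#' @param mc_samples Number of Monte-Carlo Dirichlet instances (>= 0).
#' @param seed Seed for the Dirichlet draws (default 1).
#' @return A [da_result()].
#' @export
da_ttest_clr <- function(exp, pseudocount = 1, mc_samples = 0, seed = 1) {
  if (!is.numeric(mc_samples) || length(mc_samples) != 1L || mc_samples < 0)
    stopf("mc_samples must be a non-negative integer")
  mc_samples <- as.integer(mc_samples)
  gi <- two_group_index(exp)
  x <- unclass(exp$table)
  params <- list(test = "ttest_clr", pseudocount = pseudocount,
                 mc_samples = mc_samples)
  if (mc_samples == 0L) {
    clr <- norm_clr(exp$table, pseudocount)$clr
    w <- welch_rows(clr, gi$idx1, gi$idx2)
    return(da_result("ttest_clr", rownames(x), w$p, w$t,
                     as.integer(sign(w$diff)), params = params))
  }
  m <- nrow(x); n <- ncol(x)
  p_sum <- numeric(m); diff_sum <- numeric(m)
  with_seed(seed %||% 1, {
    for (w_i in seq_len(mc_samples)) {
      gam <- matrix(stats::rgamma(m * n, shape = x + 0.5), m, n)
      lg <- log(gam)
      clr <- sweep(lg, 2L, colMeans(lg), "-")
      wt <- welch_rows(clr, gi$idx1, gi$idx2)
      p_sum <- p_sum + wt$p
      diff_sum <- diff_sum + wt$diff
    }
  })
  p <- p_sum / mc_samples
  diff <- diff_sum / mc_samples
  da_result("ttest_clr", rownames(x), p, diff, as.integer(sign(diff)),
            params = params)
}

# NB regression NLL and analytic gradient for (b0, b1, log phi) with fixed
# per-sample offsets. size = 1/phi.
nb_reg_nll <- function(par, x, d, off) {
  s <- exp(-par[3L])
  mu <- exp(par[1L] + par[2L] * d + off)
  -sum(stats::dnbinom(x, mu = mu, size = s, log = TRUE))
}

nb_reg_grad <- function(par, x, d, off) {
  s <- exp(-par[3L])
  mu <- exp(par[1L] + par[2L] * d + off)
  w <- x - mu * (x + s) / (mu + s)
  dls <- digamma(x + s) - digamma(s) + log(s) + 1 - log(s + mu) - (x + s) / (s + mu)
  c(-sum(w), -sum(w * d), sum(dls) * s)
}

nb_wald_one <- function(x, d, off) {
  fail <- list(p = NA_real_, stat = NA_real_, dir = 0L)
  if (all(x == 0)) return(fail)
  sc <- exp(off)
  m1 <- mean(x[d == 0] / sc[d == 0]); m2 <- mean(x[d == 1] / sc[d == 1])
  init <- c(log(m1 + 1e-4), log(m2 + 1e-4) - log(m1 + 1e-4), log(0.5))
  opt <- tryCatch(
    stats::optim(init, nb_reg_nll, gr = nb_reg_grad, x = x, d = d, off = off,
                 method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0L || !all(is.finite(opt$hessian)))
    return(fail)
  cov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(cov) || !is.finite(cov[2L, 2L]) || cov[2L, 2L] <= 0) return(fail)
  beta <- opt$par[2L]
  se <- sqrt(cov[2L, 2L])
  z <- beta / se
  list(p = 2 * stats::pnorm(-abs(z)), stat = z, dir = as.integer(sign(beta)))
}

#' Negative binomial Wald DA test
#'
#' Per-feature NB regression with log link, intercept plus group
#' coefficient, and offset `log(scale_j)` from the supplied normalization.
#' Dispersion is estimated per feature by ML jointly with the coefficients;
#' the reported p-value is the two-sided normal Wald p for the group
#' coefficient. Non-convergent features get a missing p-value.
#'
#' @inheritParams da_wilcoxon
#' @return A [da_result()].
#' @export
da_negbin_wald <- function(exp, norm = norm_tss(exp$table)) {
  gi <- two_group_index(exp)
  x <- unclass(exp$table)
  sc <- effective_scale(norm)
  d <- as.numeric(exp$group == levels(exp$group)[2L])
  off <- log(sc)
  fits <- apply(x, 1L, nb_wald_one, d = d, off = off)
  da_result("negbin_wald", rownames(x),
            vapply(fits, `[[`, numeric(1), "p"),
            vapply(fits, `[[`, numeric(1), "stat"),
            vapply(fits, `[[`, integer(1), "dir"),
            params = list(test = "negbin_wald", normalization = norm$method))
}

# Resolve a spec to a callable and run it.
#' @noRd
run_one_method <- function(exp, spec, norm = NULL, seed = NULL) {
  if (is.null(norm)) norm <- compute_norm(exp$table, spec$normalization)
  seed <- spec$seed %||% seed
  res <- if (is.function(spec$test)) {
    spec$test(exp, norm, spec$params, seed)
  } else {
    switch(spec$test,
           wilcoxon = da_wilcoxon(exp, norm),
           ttest_clr = da_ttest_clr(exp,
                                    pseudocount = spec$params$pseudocount %||% 1,
                                    mc_samples = spec$params$mc_samples %||% 0,
                                    seed = seed),
           negbin_wald = da_negbin_wald(exp, norm))
  }
  if (!inherits(res, "da_result")) stopf("method '%s' did not return a da_result",
                                         spec$method_id)
  res$method_id <- spec$method_id
  res$params_fingerprint <- params_fingerprint(spec$params)
  res
}

#' Run registered methods on an experiment
#'
#' Normalization factors are computed once per distinct normalization; runs
#' happen in the requested order and per-method wall time and failure
#' counts are attached as the `"run_log"` attribute.
#'
#' @param exp A [validate_experiment()] object.
#' @param registry A [method_registry()].
#' @param method_ids Methods to run; default all registered, in insertion
#'   order.
#' @param seed Optional master seed for stochastic methods without their
#'   own seed.
#' @return Named list of [da_result()] objects, in request order.
#' @export
run_methods <- function(exp, registry, method_ids = names(registry$methods),
                        seed = NULL) {
  unknown <- setdiff(method_ids, names(registry$methods))
  if (length(unknown))
    stopf("unknown method id(s): %s", paste(unknown, collapse = ", "))
  norms <- list()
  results <- list()
  log <- data.frame(method_id = character(0), seconds = numeric(0),
                    n_failed = integer(0), stringsAsFactors = FALSE)
  for (k in seq_along(method_ids)) {
    id <- method_ids[[k]]
    spec <- registry$methods[[id]]
    if (is.null(norms[[spec$normalization]]))
      norms[[spec$normalization]] <- compute_norm(exp$table, spec$normalization)
    t0 <- proc.time()[["elapsed"]]
    res <- run_one_method(exp, spec, norm = norms[[spec$normalization]],
                          seed = if (is.null(seed)) NULL else child_seed(seed, k))
    log <- rbind(log, data.frame(method_id = id,
                                 seconds = proc.time()[["elapsed"]] - t0,
                                 n_failed = res$n_failed,
                                 stringsAsFactors = FALSE))
    results[[id]] <- res
  }
  attr(results, "run_log") <- log
  results
}
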