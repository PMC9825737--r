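# Independent brute-force oracles. These deliberately take the slow, literal
# route (sorting, enumeration, direct formula evaluation) so they stay
# independent of the implementation paths they check.

# Benjamini-Hochberg step-up by direct enumeration: sort, scale by m/rank,
# cumulative minimum from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# CSS factor for one sample: sort the positive counts, take the empirical
# quantile, sum everything at or below it.
oracle_css_factors <- function(mat, q) {
  raw <- vapply(seq_len(ncol(mat)), function(j) {
    pos <- sort(mat[mat[, j] > 0, j])
    cutoff <- stats::quantile(pos, probs = q, names = FALSE)
    sum(mat[, j][mat[, j] <= cutoff])
  }, numeric(1))
  raw / stats::median(raw)
}

# RLE factors by the literal recipe: geometric-mean reference over features
# positive in every sample, explicit sorted median of the count/reference
# ratios (mean of the two central values when even), geometric mean 1.
# Note DESeq2 medians log-ratios instead, which differs at even counts.
oracle_rle_factors <- function(mat) {
  keep <- apply(mat, 1, function(r) all(r > 0))
  ref <- apply(mat[keep, , drop = FALSE], 1,
               function(r) prod(r)^(1 / length(r)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    ratios <- sort(mat[keep, j] / ref)
    n <- length(ratios)
    if (n %% 2 == 1) ratios[(n + 1) / 2] else mean(ratios[n / 2 + 0:1])
  }, numeric(1))
  f / prod(f)^(1 / length(f))
}

# Fisher exact p by full enumeration over the hypergeometric support using
# log-binomial coefficients (no dhyper).
oracle_fisher <- function(a, b, c, d, alternative = "two_sided") {
  n <- a + b + c + d
  if (n == 0) return(1)
  m1 <- a + b; k <- a + c
  support <- max(0, k - (n - m1)):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(n - m1, k - support) - lchoose(n, k)
  mass <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(n - m1, k - a) - lchoose(n, k))
  p <- if (alternative == "two_sided") sum(mass[mass <= p_obs * (1 + 1e-7)])
       else sum(mass[support >= a])
  min(1, p)
}

# sup |ECDF(x) - x| evaluated directly at all jump points from both sides.
oracle_ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  ec <- stats::ecdf(p)
  pts <- sort(unique(c(p, 0, 1)))
  below <- vapply(pts, function(x) abs(ec(x - 1e-12) - x), numeric(1))
  at <- vapply(pts, function(x) abs(ec(x) - x), numeric(1))
  max(below, at)
}

# Random NB count table for property tests.
random_table <- function(m, n, mu = 50, phi = 0.5, seed = 1) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rnbinom(m * n, mu = mu, size = 1 / phi), m, n)
    count_table(counts, sprintf("f%03d", seq_len(m)), sprintf("s%02d", seq_len(n)))
  })
}

# Minimal two-group experiment from a matrix of values.
toy_experiment <- function(counts, n1, n2) {
  tab <- count_table(counts)
  meta <- sample_metadata(data.frame(
    sample_id = colnames(tab),
    group = rep(c("A", "B"), c(n1, n2)),
    stringsAsFactors = FALSE))
  validate_experiment(tab, meta, "group")
}

# Plugin DA method emitting a fixed p-value vector regardless of labels.
fixed_p_method <- function(p) {
  function(exp, norm, params, seed) {
    da_result("fixed", rownames(exp$table), p, statistic = rep(0, length(p)),
              direction = rep(1L, length(p)))
  }
}

# Anti-conservative fixture: p = U^2 with U ~ Uniform(0,1), seeded per run.
psq_method <- function(exp, norm, params, seed) {
  m <- nrow(exp$table)
  p <- withr::with_seed(seed %||% 1, stats::runif(m)^2)
  da_result("psq", rownames(exp$table), p, statistic = rep(0, m),
            direction = rep(1L, m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
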