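# Type-I-error-control engine: the input samples are re-labelled at random
# into two balanced mock groups, so no feature is truly differentially
# abundant; any discovery is a false positive. Repeating the re-labelling N
# times yields calibration summaries per method: false positive rates at
# nominal levels, "false discovery" rates on adjusted p-values, and the
# Kolmogorov-Smirnov departure of the raw p-value distribution from
# Uniform(0,1).

#' Generate balanced mock labelings
#'
#' Every labeling assigns all samples to two groups whose sizes differ by at
#' most one; mock i draws from a child seed of `seed`, so results are
#' reproducible under partial reruns.
#'
#' @param sample_ids Character vector of at least 4 sample ids.
#' @param N Number of mock comparisons (the more the better; >= 1000 for
#'   production use, smaller for quick checks).
#' @param seed Master seed.
#' @return A `mock_set` object with a list of N factor labelings.
#' @export
create_mocks <- function(sample_ids, N, seed = 1) {
  n <- length(sample_ids)
  if (n < 4L) stopf("mock comparisons need >= 4 samples (got %d)", n)
  if (N < 1L) stopf("N must be >= 1")
  n1 <- n %/% 2L
  labelings <- lapply(seq_len(N), function(i) {
    with_seed(child_seed(seed, i), {
      perm <- sample(sample_ids)
      g <- factor(ifelse(sample_ids %in% perm[seq_len(n1)], "mockA", "mockB"),
                  levels = c("mockA", "mockB"))
      names(g) <- sample_ids
      g
    })
  })
  structure(list(N = N, sample_ids = sample_ids, labelings = labelings,
                 seed = seed),
            class = "mock_set")
}

#' Run registered methods over a set of mock labelings
#'
#' Per-mock failures are recorded, not fatal; a method failing (all-missing
#' p-values) on more than half of the mocks triggers a warning.
#'
#' @param table A [count_table()] covering the mock sample ids.
#' @param mocks A [create_mocks()] object.
#' @param registry A [method_registry()].
#' @param method_ids Methods to run (default: all registered).
#' @param seed Optional master seed forwarded to stochastic methods.
#' @return A `mock_results` object: list with one element per mock, each a
#'   named list of [da_result()] objects.
#' @export
run_mocks <- function(table, mocks, registry,
                      method_ids = names(registry$methods), seed = NULL) {
  stopifnot(inherits(mocks, "mock_set"))
  per_mock <- vector("list", mocks$N)
  for (i in seq_len(mocks$N)) {
    g <- mocks$labelings[[i]]
    meta <- sample_metadata(data.frame(sample_id = names(g),
                                       mock_group = as.character(g),
                                       stringsAsFactors = FALSE))
    exp <- validate_experiment(table, meta, "mock_group")
    per_mock[[i]] <- run_methods(exp, registry, method_ids,
                                 seed = if (is.null(seed)) NULL
                                        else child_seed(seed, i))
  }
  for (id in method_ids) {
    all_missing <- vapply(per_mock, function(mk) all(is.na(mk[[id]]$table$p_raw)),
                          logical(1))
    if (mean(all_missing) > 0.5)
      warning(sprintf("method '%s' failed on %.0f%% of mocks", id,
                      100 * mean(all_missing)))
  }
  structure(list(results = per_mock, method_ids = method_ids, N = mocks$N),
            class = "mock_results")
}

# sup_x |ECDF(x) - x| for p in [0,1] against Uniform(0,1).
ks_uniform <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  if (n == 0L) return(NA_real_)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Summarize type-I-error control over mock comparisons
#'
#' Per method: mean false positive rate (fraction of non-missing raw
#' p-values below each `alpha`), mean per-mock KS distance of raw p-values
#' from Uniform(0,1), the mean fraction of features passing adjusted-p
#' thresholds `gamma` together with the fraction of mocks with at least one
#' such discovery (two readings of a "false discovery rate" when nothing is
#' truly DA), and a per-mock detail table.
#'
#' @param mock_results A [run_mocks()] object.
#' @param alphas Nominal raw-p levels.
#' @param gammas Adjusted-p thresholds.
#' @return A `type1_summary` object with elements `fpr`, `ks`, `fdr`,
#'   `detail`.
#' @export
eval_type1 <- function(mock_results, alphas = c(0.01, 0.05, 0.1),
                       gammas = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(mock_results, "mock_results"))
  methods <- mock_results$method_ids
  detail <- list()
  fpr <- matrix(NA_real_, length(methods), length(alphas),
                dimnames = list(methods, paste0("alpha_", alphas)))
  fdr_mean <- matrix(NA_real_, length(methods), length(gammas),
                     dimnames = list(methods, paste0("gamma_", gammas)))
  fdr_any <- fdr_mean
  ks_mean <- stats::setNames(rep(NA_real_, length(methods)), methods)
  for (id in methods) {
    per_mock_fpr <- matrix(NA_real_, mock_results$N, length(alphas))
    per_mock_disc <- matrix(NA_real_, mock_results$N, length(gammas))
    per_mock_ks <- rep(NA_real_, mock_results$N)
    for (i in seq_len(mock_results$N)) {
      tb <- mock_results$results[[i]][[id]]$table
      p <- tb$p_raw[!is.na(tb$p_raw)]
      if (length(p) == 0L) next
      per_mock_fpr[i, ] <- vapply(alphas, function(a) mean(p < a), numeric(1))
      per_mock_ks[i] <- ks_uniform(p)
      padj <- tb$p_adj[!is.na(tb$p_adj)]
      per_mock_disc[i, ] <- vapply(gammas, function(g) mean(padj < g), numeric(1))
    }
    if (all(is.na(per_mock_ks))) {
      warning(sprintf("method '%s' produced no usable p-values; excluded", id))
      next
    }
    fpr[id, ] <- colMeans(per_mock_fpr, na.rm = TRUE)
    ks_mean[id] <- mean(per_mock_ks, na.rm = TRUE)
    fdr_mean[id, ] <- colMeans(per_mock_disc, na.rm = TRUE)
    fdr_any[id, ] <- colMeans(per_mock_disc > 0, na.rm = TRUE)
    detail[[id]] <- data.frame(mock_id = seq_len(mock_results$N),
                               method_id = id,
                               ks = per_mock_ks,
                               fpr = per_mock_fpr,
                               stringsAsFactors = FALSE)
  }
  structure(list(alphas = alphas, gammas = gammas, fpr = fpr, ks = ks_mean,
                 fdr = list(mean_fraction = fdr_mean,
                            any_discovery = fdr_any),
                 detail = if (length(detail)) do.call(rbind, detail) else NULL),
            class = "type1_summary")
}

#' @export
print.type1_summary <- function(x, ...) {
  cat("<type1_summary>\nFPR:\n")
  print(round(x$fpr, 4))
  cat("mean KS vs Uniform(0,1):\n")
  print(round(x$ks, 4))
  invisible(x)
}
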