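# Enrichment engine: direction-aware evaluation of DA calls against prior
# knowledge (an annotation level per feature plus the group in which
# features of that level are expected over-abundant), Fisher exact tests on
# the resulting 2x2 tables, mutual findings across methods, TP - FP ranking
# curves, and power analysis against simulated truth.

#' Construct an enrichment prior
#'
#' @param feature_ids Feature identifiers.
#' @param annotation Per-feature annotation level (NA = unannotated).
#' @param expected_direction Named character vector mapping annotation
#'   levels to `"UP"` or `"DOWN"` — the direction in which features of that
#'   level are expected differentially abundant (UP = over-abundant in the
#'   second group level).
#' @return An `enrichment_prior` object.
#' @export
enrichment_prior <- function(feature_ids, annotation, expected_direction) {
  stopifnot(length(feature_ids) == length(annotation))
  annotation <- as.character(annotation)
  lev <- unique(annotation[!is.na(annotation)])
  if (!all(names(expected_direction) %in% lev))
    stopf("expected_direction names must be annotation levels; unknown: %s",
          paste(setdiff(names(expected_direction), lev), collapse = ", "))
  if (!all(expected_direction %in% c("UP", "DOWN")))
    stopf("expected directions must be 'UP' or 'DOWN'")
  structure(list(feature_ids = as.character(feature_ids),
                 annotation = annotation,
                 expected_direction = expected_direction),
            class = "enrichment_prior")
}

#' Construct a truth set for simulated data
#'
#' @param feature_ids Feature identifiers.
#' @param is_da Logical per-feature DA flag.
#' @param direction `"UP"`/`"DOWN"` where `is_da`, NA elsewhere.
#' @param fold_change Positive per-feature fold change (1 where not DA).
#' @return A `truth_set` object.
#' @export
truth_set <- function(feature_ids, is_da, direction, fold_change) {
  stopifnot(length(is_da) == length(feature_ids),
            length(direction) == length(feature_ids))
  if (any(is_da & is.na(direction)) || any(!is_da & !is.na(direction)))
    stopf("direction must be defined exactly for DA features")
  structure(list(feature_ids = as.character(feature_ids),
                 is_da = as.logical(is_da),
                 direction = as.character(direction),
                 fold_change = as.numeric(fold_change)),
            class = "truth_set")
}

#' Classify features from a DA result
#'
#' `UP` if `p_adj < threshold` and direction > 0, `DOWN` if significant with
#' direction < 0, `NONDA` otherwise (including missing p-values and
#' significant features with direction 0, which are anomalous).
#'
#' @param result A [da_result()].
#' @param threshold Adjusted-p cutoff in (0, 1\].
#' @return Named character vector in `{"UP", "DOWN", "NONDA"}`.
#' @export
classify_features <- function(result, threshold = 0.1) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0,1]")
  tb <- result$table
  sig <- !is.na(tb$p_adj) & tb$p_adj < threshold
  out <- rep("NONDA", nrow(tb))
  out[sig & tb$direction > 0] <- "UP"
  out[sig & tb$direction < 0] <- "DOWN"
  stats::setNames(out, tb$feature_id)
}

#' Build a direction-aware 2x2 enrichment table
#'
#' Rows: feature in the annotation `level` (yes/no); columns: called DA in
#' `direction` (yes/no). Unannotated features are excluded.
#'
#' @param classes Output of [classify_features()].
#' @param prior An [enrichment_prior()].
#' @param level Annotation level of interest.
#' @param direction `"UP"` or `"DOWN"`; defaults to the level's expected
#'   direction.
#' @return A 2x2 integer matrix of class `contingency_table`.
#' @export
build_contingency <- function(classes, prior, level,
                              direction = prior$expected_direction[[level]]) {
  stopifnot(inherits(prior, "enrichment_prior"))
  if (!level %in% prior$annotation)
    stopf("annotation level '%s' is empty", level)
  ann <- prior$annotation[match(names(classes), prior$feature_ids)]
  keep <- !is.na(ann)
  in_level <- ann[keep] == level
  called <- classes[keep] == direction
  tab <- matrix(c(sum(in_level & called), sum(in_level & !called),
                  sum(!in_level & called), sum(!in_level & !called)),
                2L, 2L, byrow = TRUE,
                dimnames = list(level = c("in_level", "out_level"),
                                call = c("called", "not_called")))
  class(tab) <- c("contingency_table", class(tab))
  tab
}

#' Fisher exact test on a 2x2 table
#'
#' Exact p by hypergeometric enumeration: `two_sided` sums the point masses
#' of all tables (with the observed margins) no more probable than the
#' observed one; `greater` sums the upper tail. The odds ratio is the
#' sample odds ratio `ad/bc` (infinite when `bc = 0` and `ad > 0`, missing
#' for a degenerate table).
#'
#' @param table 2x2 matrix of non-negative integers.
#' @param alternative `"two_sided"` or `"greater"`.
#' @return List with `p_value` and `odds_ratio`.
#' @export
fisher_test <- function(table, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(unclass(table))
  if (!all(dim(tab) == 2L) || !is_count_vector(as.numeric(tab)))
    stopf("need a 2x2 table of non-negative integers")
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c <- tab[2L, 1L]; d <- tab[2L, 2L]
  or <- if (b * c == 0 && a * d == 0) NA_real_
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  n <- a + b + c + d
  if (n == 0) return(list(p_value = 1, odds_ratio = NA_real_))
  m1 <- a + b   # in level
  k <- a + c    # called
  support <- max(0, k - (n - m1)):min(k, m1)
  mass <- stats::dhyper(support, m1, n - m1, k)
  p_obs <- stats::dhyper(a, m1, n - m1, k)
  p <- switch(alternative,
              two_sided = sum(mass[mass <= p_obs * (1 + 1e-7)]),
              greater = sum(mass[support >= a]))
  list(p_value = min(1, p), odds_ratio = or)
}

#' Features called DA by more than one method
#'
#' @param results List of at least two [da_result()] objects.
#' @param threshold Adjusted-p cutoff for a call (any direction).
#' @return List with `counts` (per-feature number of calling methods) and
#'   `highlighted` (feature ids called by >= 2 methods).
#' @export
mutual_findings <- function(results, threshold = 0.1) {
  if (length(results) < 2L) stopf("mutual findings need >= 2 methods")
  fids <- results[[1L]]$table$feature_id
  counts <- stats::setNames(integer(length(fids)), fids)
  for (res in results) {
    cls <- classify_features(res, threshold)
    counts <- counts + as.integer(cls[fids] != "NONDA")
  }
  list(counts = counts, highlighted = fids[counts >= 2L])
}

expected_direction_by_feature <- function(prior_or_truth) {
  if (inherits(prior_or_truth, "enrichment_prior")) {
    pr <- prior_or_truth
    dir <- rep(NA_character_, length(pr$feature_ids))
    known <- !is.na(pr$annotation) & pr$annotation %in% names(pr$expected_direction)
    dir[known] <- unname(pr$expected_direction[pr$annotation[known]])
    stats::setNames(dir, pr$feature_ids)
  } else if (inherits(prior_or_truth, "truth_set")) {
    # non-DA features carry no expected direction: neutral in TP-FP counting
    stats::setNames(ifelse(prior_or_truth$is_da, prior_or_truth$direction,
                           NA_character_),
                    prior_or_truth$feature_ids)
  } else {
    stopf("need an enrichment_prior or truth_set")
  }
}

#' TP - FP ranking curve
#'
#' Features are ranked by the chosen statistic (ascending p-values, or
#' descending absolute statistic). At each rank depth, TP counts top-ranked
#' features whose call direction matches the expected (prior) or true
#' direction, FP counts those whose direction contradicts it; features
#' without an expected direction count toward neither.
#'
#' @param result A [da_result()].
#' @param prior_or_truth An [enrichment_prior()] or [truth_set()].
#' @param thresholds Ascending rank depths (default `1..m`).
#' @param statistic Ranking key: `"p_raw"`, `"p_adj"` or `"statistic"`.
#' @return A data.frame (`threshold`, `TP`, `FP`, `TPminusFP`) of class
#'   `tpfp_curve`.
#' @export
tp_fp_ranking <- function(result, prior_or_truth,
                          thresholds = seq_len(nrow(result$table)),
                          statistic = c("p_raw", "p_adj", "statistic")) {
  statistic <- match.arg(statistic)
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly ascending rank depths")
  tb <- result$table
  ord <- if (statistic == "statistic") {
    s <- abs(tb$statistic); s[is.na(s)] <- -Inf
    order(-s, tb$feature_id, method = "radix")
  } else {
    p <- tb[[statistic]]; p[is.na(p)] <- Inf
    s <- abs(tb$statistic); s[is.na(s)] <- -Inf
    order(p, -s, tb$feature_id, method = "radix")
  }
  expected <- expected_direction_by_feature(prior_or_truth)
  exp_ord <- expected[tb$feature_id[ord]]
  dir_ord <- tb$direction[ord]
  called_dir <- ifelse(dir_ord > 0, "UP", ifelse(dir_ord < 0, "DOWN", NA))
  tp_cum <- cumsum(!is.na(exp_ord) & !is.na(called_dir) & called_dir == exp_ord)
  fp_cum <- cumsum(!is.na(exp_ord) & (is.na(called_dir) | called_dir != exp_ord))
  out <- data.frame(threshold = thresholds,
                    TP = tp_cum[thresholds], FP = fp_cum[thresholds])
  out$TPminusFP <- out$TP - out$FP
  class(out) <- c("tpfp_curve", "data.frame")
  out
}

#' Run the full enrichment analysis for a set of methods
#'
#' For every method and every annotation level, builds the contingency
#' table in the level's expected direction plus the opposite direction as a
#' negative control, Fisher-tests both, and reports mutual findings.
#'
#' @param results Named list of [da_result()] objects.
#' @param prior An [enrichment_prior()].
#' @param threshold Adjusted-p cutoff for calls.
#' @param alternative Fisher alternative (default `"greater"`: enrichment).
#' @return Data frame with one row per (method, level, direction) plus a
#'   `mutual` attribute.
#' @export
run_enrichment <- function(results, prior, threshold = 0.1,
                           alternative = "greater") {
  rows <- list()
  for (id in names(results)) {
    cls <- classify_features(results[[id]], threshold)
    for (level in names(prior$expected_direction)) {
      expected <- prior$expected_direction[[level]]
      for (dir in c(expected, setdiff(c("UP", "DOWN"), expected))) {
        tab <- build_contingency(cls, prior, level, dir)
        ft <- fisher_test(tab, alternative)
        rows[[length(rows) + 1L]] <- data.frame(
          method_id = id, level = level, direction = dir,
          is_expected_direction = dir == expected,
          a = tab[1L, 1L], b = tab[1L, 2L], c = tab[2L, 1L], d = tab[2L, 2L],
          p_value = ft$p_value, odds_ratio = ft$odds_ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (length(results) >= 2L)
    attr(out, "mutual") <- mutual_findings(results, threshold)
  out
}

#' Power analysis on simulated scenarios
#'
#' Each scenario is a simulated experiment with known truth. Per scenario
#' and method, power is the fraction of true DA features discovered in the
#' correct direction at the adjusted-p threshold, and the observed FDR is
#' the fraction of discoveries that are not true DA in the called direction.
#'
#' @param scenarios List of `list(exp = , truth = , label = )` entries, as
#'   produced from [sim_counts()] output.
#' @param registry A [method_registry()].
#' @param method_ids Methods to run.
#' @param threshold Adjusted-p discovery threshold.
#' @param seed Optional master seed for stochastic methods.
#' @return Data frame (`scenario`, `method_id`, `n_true_da`, `discoveries`,
#'   `TP`, `FP`, `power`, `fdr`).
#' @export
power_analysis <- function(scenarios, registry,
                           method_ids = names(registry$methods),
                           threshold = 0.05, seed = NULL) {
  rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    if (is.null(sc$truth) || !inherits(sc$truth, "truth_set"))
      stopf("scenario %d carries no truth set", s)
    results <- run_methods(sc$exp, registry, method_ids,
                           seed = if (is.null(seed)) NULL else child_seed(seed, s))
    truth_dir <- expected_direction_by_feature(sc$truth)
    n_true <- sum(sc$truth$is_da)
    for (id in method_ids) {
      cls <- classify_features(results[[id]], threshold)
      called <- cls[cls != "NONDA"]
      tp <- sum(!is.na(truth_dir[names(called)]) &
                  truth_dir[names(called)] == called)
      fp <- length(called) - tp
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$label %||% as.character(s), method_id = id,
        n_true_da = n_true, discoveries = length(called), TP = tp, FP = fp,
        power = if (n_true > 0) tp / n_true else NA_real_,
        fdr = fp / max(1L, length(called)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
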