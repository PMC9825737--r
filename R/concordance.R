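# Concordance engine: the samples are split in half N times (stratified by
# group), DA analysis runs on each half, and agreement between feature
# rankings is measured by concordance-at-top (CAT) curves. Within-method
# concordance (WMC) compares a method to itself across the two halves;
# between-method concordance (BMC) compares two methods on the same half.
# Curves are summarized by an area rescaled so that identical rankings score
# 1 and independent rankings score about 0.

#' Generate stratified half-splits
#'
#' Each split partitions all samples into two disjoint subsets, halving
#' every group level separately (sizes within a level differ by at most 1).
#' Every group level therefore needs at least 4 samples so each subset
#' retains >= 2 per level.
#'
#' @param metadata A [sample_metadata()] data frame.
#' @param group_column Grouping column name.
#' @param N Number of splits (>= 100 for production use).
#' @param seed Master seed; split i uses a derived child seed.
#' @return A `split_set` object with `pairs`, a list of
#'   `list(subset1, subset2)` sample-id vectors.
#' @export
create_splits <- function(metadata, group_column, N, seed = 1) {
  metadata <- sample_metadata(metadata)
  if (!group_column %in% names(metadata))
    stopf("group column '%s' not found", group_column)
  g <- factor(as.character(metadata[[group_column]]))
  sizes <- table(g)
  small <- names(sizes)[sizes < 4L]
  if (length(small))
    stopf("group level(s) with < 4 samples cannot be half-split: %s",
          paste(small, collapse = ", "))
  ids_by_group <- split(metadata$sample_id, g)
  pairs <- lapply(seq_len(N), function(i) {
    with_seed(child_seed(seed, i), {
      s1 <- unlist(lapply(ids_by_group, function(ids) {
        sample(ids, length(ids) %/% 2L)
      }), use.names = FALSE)
      list(subset1 = metadata$sample_id[metadata$sample_id %in% s1],
           subset2 = setdiff(metadata$sample_id, s1))
    })
  })
  structure(list(N = N, pairs = pairs, seed = seed,
                 group_column = group_column),
            class = "split_set")
}

#' Rank features of a DA result
#'
#' Ascending raw p-value; ties broken by descending absolute statistic,
#' then lexicographic feature id. Features with missing p rank last (among
#' themselves by the same tie-breaks).
#'
#' @param result A [da_result()].
#' @return Character vector of feature ids, best-ranked first.
#' @export
rank_features <- function(result) {
  tb <- result$table
  p <- tb$p_raw
  p[is.na(p)] <- Inf
  s <- abs(tb$statistic)
  s[is.na(s)] <- -Inf
  tb$feature_id[order(p, -s, tb$feature_id, method = "radix")]
}

#' Concordance-at-top curve between two rankings
#'
#' `CAT(k) = |top_k(A) intersect top_k(B)| / k` for `k = 1..K`.
#'
#' @param rankA,rankB Character rankings over the same feature universe.
#' @param K Maximum rank depth (`<= m`).
#' @return A `cat_curve` object with `values` of length K.
#' @export
cat_curve <- function(rankA, rankB, K = min(length(rankA), 100L)) {
  if (!setequal(rankA, rankB) || length(rankA) != length(rankB))
    stopf("rankings cover different feature universes")
  m <- length(rankA)
  if (K < 1L || K > m) stopf("K must lie in [1, %d]", m)
  posB <- match(rankA, rankB)
  # feature at position i of A enters the shared top-k at k = max(i, posB[i])
  entry <- pmax(seq_len(m), posB)
  shared <- cumsum(tabulate(entry, nbins = m))[seq_len(K)]
  structure(list(K = K, m = m, values = shared / seq_len(K)),
            class = "cat_curve")
}

#' Rescaled area under a CAT curve
#'
#' Raw area `(1/K) sum CAT(k)` centred at the expectation for independent
#' rankings, `(1/K) sum k/m`, and rescaled so that identical rankings score
#' exactly 1 and independent rankings score about 0 in expectation.
#'
#' @param curve A [cat_curve()].
#' @param m Feature-universe size (defaults to the curve's).
#' @return Scalar rescaled area.
#' @export
rescaled_area <- function(curve, m = curve$m) {
  stopifnot(inherits(curve, "cat_curve"), curve$K >= 1L)
  ra_raw <- mean(curve$values)
  r_rand <- mean(seq_len(curve$K) / m)
  if (r_rand >= 1) return(1)  # degenerate K = m = 1
  (ra_raw - r_rand) / (1 - r_rand)
}

run_on_subset <- function(table, metadata, group_column, subset_ids,
                          registry, method_ids, seed = NULL) {
  meta_sub <- metadata[metadata$sample_id %in% subset_ids, , drop = FALSE]
  exp <- validate_experiment(
    count_table(unclass(table)[, meta_sub$sample_id, drop = FALSE]),
    meta_sub, group_column)
  run_methods(exp, registry, method_ids, seed = seed)
}

#' Run registered methods on both halves of every split
#'
#' @param table A [count_table()].
#' @param metadata A [sample_metadata()] data frame.
#' @param group_column Grouping column name.
#' @param splits A [create_splits()] object.
#' @param registry A [method_registry()].
#' @param method_ids Methods to run (default: all registered).
#' @param seed Optional master seed for stochastic methods.
#' @return A `split_results` object: per split, `subset1` and `subset2`
#'   named lists of [da_result()] objects.
#' @export
run_splits <- function(table, metadata, group_column, splits, registry,
                       method_ids = names(registry$methods), seed = NULL) {
  stopifnot(inherits(splits, "split_set"))
  res <- lapply(seq_len(splits$N), function(i) {
    pair <- splits$pairs[[i]]
    list(subset1 = run_on_subset(table, metadata, group_column, pair$subset1,
                                 registry, method_ids,
                                 seed = if (is.null(seed)) NULL
                                        else child_seed(seed, 2L * i - 1L)),
         subset2 = run_on_subset(table, metadata, group_column, pair$subset2,
                                 registry, method_ids,
                                 seed = if (is.null(seed)) NULL
                                        else child_seed(seed, 2L * i)))
  })
  structure(list(results = res, method_ids = method_ids, N = splits$N),
            class = "split_results")
}

#' Within- and between-method concordance
#'
#' `WMC(method)`: mean over splits of the rescaled CAT area between the
#' method's rankings on Subset1 and Subset2. `BMC(i, j)`: mean over splits
#' and over both subsets of the rescaled CAT area between the rankings of
#' methods i and j on the same subset; the matrix is symmetric with unit
#' diagonal.
#'
#' @param split_results A [run_splits()] object.
#' @param K Maximum rank depth (default `min(m, 100)`).
#' @return A `concordance_summary` object with `WMC`, `BMC` and a long
#'   `detail` table of per-split areas.
#' @export
eval_concordance <- function(split_results, K = NULL) {
  stopifnot(inherits(split_results, "split_results"))
  methods <- split_results$method_ids
  first <- split_results$results[[1L]]$subset1[[methods[1L]]]
  m <- nrow(first$table)
  if (is.null(K)) K <- min(m, 100L)
  wmc_acc <- stats::setNames(lapply(methods, function(.) numeric(0)), methods)
  bmc_acc <- array(list(), c(length(methods), length(methods)))
  detail <- list()
  for (i in seq_len(split_results$N)) {
    spl <- split_results$results[[i]]
    ranks1 <- lapply(spl$subset1, rank_features)
    ranks2 <- lapply(spl$subset2, rank_features)
    for (a in seq_along(methods)) {
      ida <- methods[[a]]
      wa <- rescaled_area(cat_curve(ranks1[[ida]], ranks2[[ida]], K))
      wmc_acc[[ida]] <- c(wmc_acc[[ida]], wa)
      detail[[length(detail) + 1L]] <- data.frame(
        split = i, kind = "WMC", method1 = ida, method2 = ida, area = wa,
        stringsAsFactors = FALSE)
      for (b in seq_len(a)) {
        idb <- methods[[b]]
        ab <- mean(c(rescaled_area(cat_curve(ranks1[[ida]], ranks1[[idb]], K)),
                     rescaled_area(cat_curve(ranks2[[ida]], ranks2[[idb]], K))))
        bmc_acc[[a, b]] <- c(bmc_acc[[a, b]], ab)
        detail[[length(detail) + 1L]] <- data.frame(
          split = i, kind = "BMC", method1 = ida, method2 = idb, area = ab,
          stringsAsFactors = FALSE)
      }
    }
  }
  WMC <- vapply(wmc_acc, mean, numeric(1))
  BMC <- matrix(NA_real_, length(methods), length(methods),
                dimnames = list(methods, methods))
  for (a in seq_along(methods)) {
    for (b in seq_len(a)) {
      v <- mean(bmc_acc[[a, b]])
      BMC[a, b] <- v
      BMC[b, a] <- v
    }
  }
  structure(list(WMC = WMC, BMC = BMC, K = K, m = m,
                 detail = do.call(rbind, detail)),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> K = %d over %d features\nWMC:\n", x$K, x$m))
  print(round(x$WMC, 3))
  cat("BMC:\n")
  print(round(x$BMC, 3))
  invisible(x)
}
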