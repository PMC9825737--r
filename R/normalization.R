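# Normalization layer: per-sample scaling factors (TSS/TMM/RLE/CSS) and the
# per-cell CLR transform. DA methods consume these through `norm_factors`
# objects so any method can be paired with any normalization.

new_norm_factors <- function(method, factors = NULL, clr = NULL, lib_size = NULL) {
  if (!is.null(factors)) {
    if (any(!is.finite(factors)) || any(factors <= 0))
      stopf("%s produced non-positive or non-finite factors", method)
  }
  structure(list(method = method, factors = factors, clr = clr,
                 lib_size = lib_size),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  if (is.null(x$factors)) {
    cat(sprintf("<norm_factors> %s transform, %d x %d matrix\n",
                x$method, nrow(x$clr), ncol(x$clr)))
  } else {
    cat(sprintf("<norm_factors> %s: %s\n", x$method,
                paste(format(x$factors, digits = 4), collapse = " ")))
  }
  invisible(x)
}

#' Total-sum scaling
#'
#' Per-sample factor equal to the library size, so that counts divided by
#' their factor are proportions summing to 1.
#'
#' @param table A [count_table()].
#' @return A `norm_factors` object with `method = "TSS"`.
#' @export
norm_tss <- function(table) {
  libs <- colSums(unclass(table))
  if (any(libs == 0))
    stopf("sample(s) with zero library size: %s",
          paste(colnames(table)[libs == 0], collapse = ", "))
  new_norm_factors("TSS", factors = libs, lib_size = libs)
}

#' Centred log-ratio transform
#'
#' Per sample, `log(count + pseudocount)` centred by its per-sample mean over
#' features; each sample (column) of the returned matrix sums to 0.
#'
#' @param table A [count_table()].
#' @param pseudocount Positive offset added before taking logs; default 1.
#' @return A `norm_factors` object whose `clr` element is the transformed
#'   feature-by-sample matrix.
#' @export
norm_clr <- function(table, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stopf("pseudocount must be a positive scalar")
  lg <- log(unclass(table) + pseudocount)
  clr <- sweep(lg, 2L, colMeans(lg), "-")
  new_norm_factors("CLR", clr = clr, lib_size = colSums(unclass(table)))
}

# Single-sample TMM factor vs a reference, the standard doubly trimmed
# weighted mean of M-values with delta-method precision weights.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L) {
    warning("all features excluded in TMM pair; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * abundance_trim) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values normalization
#'
#' Relative scaling factors from a doubly trimmed, precision-weighted mean of
#' per-feature log2 ratios against a reference sample, after excluding
#' features that are zero in either sample. Factors are rescaled to
#' geometric mean 1. The reference defaults to the sample whose
#' upper-quartile count (relative to library size) is closest to the mean.
#'
#' @param table A [count_table()].
#' @param ref_sample Optional reference sample id.
#' @param logratio_trim Fraction of extreme M-values trimmed on each side.
#' @param abundance_trim Fraction of extreme A-values trimmed on each side.
#' @return A `norm_factors` object with `method = "TMM"`.
#' @export
norm_tmm <- function(table, ref_sample = NULL,
                     logratio_trim = 0.30, abundance_trim = 0.05) {
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abundance_trim < 0 || abundance_trim >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  x <- unclass(table)
  libs <- colSums(x)
  if (any(libs == 0))
    stopf("sample(s) with zero library size: %s",
          paste(colnames(x)[libs == 0], collapse = ", "))
  keep_rows <- rowSums(x > 0) > 0L
  xk <- x[keep_rows, , drop = FALSE]
  if (is.null(ref_sample)) {
    f75 <- vapply(seq_len(ncol(xk)),
                  function(j) stats::quantile(xk[, j], probs = 0.75, names = FALSE),
                  numeric(1)) / libs
    ref_j <- if (stats::median(f75) < 1e-20) which.max(colSums(sqrt(xk)))
             else which.min(abs(f75 - mean(f75)))
  } else {
    ref_j <- match(ref_sample, colnames(x))
    if (is.na(ref_j)) stopf("unknown reference sample '%s'", ref_sample)
  }
  f <- vapply(seq_len(ncol(xk)), function(j)
    tmm_pair_factor(xk[, j], xk[, ref_j], libs[j], libs[ref_j],
                    logratio_trim, abundance_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  new_norm_factors("TMM", factors = f, lib_size = libs)
}

#' Relative log expression (median-of-ratios) normalization
#'
#' Reference pseudo-sample: per-feature geometric mean over samples,
#' restricted to features positive in every sample. The per-sample factor is
#' the median ratio of counts to the reference, rescaled to geometric mean 1.
#'
#' @param table A [count_table()].
#' @return A `norm_factors` object with `method = "RLE"`.
#' @export
norm_rle <- function(table) {
  x <- unclass(table)
  allpos <- rowSums(x == 0) == 0L
  if (!any(allpos))
    stopf("RLE needs at least one feature positive in all samples; consider a pseudocount")
  xr <- x[allpos, , drop = FALSE]
  log_ref <- rowMeans(log(xr))
  f <- apply(xr, 2L, function(col) stats::median(col / exp(log_ref)))
  f <- f / exp(mean(log(f)))
  new_norm_factors("RLE", factors = f, lib_size = colSums(x))
}

#' Cumulative-sum scaling
#'
#' Per-sample factor: the sum of counts no greater than the sample's
#' empirical `quantile` of its positive counts, rescaled by the median
#' factor across samples. The quantile is fixed (default median of the
#' positive counts) rather than adaptively chosen.
#'
#' @param table A [count_table()].
#' @param quantile Quantile of the positive-count distribution, in (0,1).
#' @return A `norm_factors` object with `method = "CSS"`.
#' @export
norm_css <- function(table, quantile = 0.5) {
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stopf("quantile must lie strictly inside (0,1)")
  x <- unclass(table)
  raw <- vapply(seq_len(ncol(x)), function(j) {
    pos <- x[x[, j] > 0, j]
    if (length(pos) == 0L)
      stopf("sample '%s' has no positive counts", colnames(x)[j])
    q <- stats::quantile(pos, probs = quantile, names = FALSE)
    sum(x[x[, j] <= q, j])
  }, numeric(1))
  f <- raw / stats::median(raw)
  names(f) <- colnames(x)
  new_norm_factors("CSS", factors = f, lib_size = colSums(x))
}

#' Identity normalization (no scaling)
#' @param table A [count_table()].
#' @export
norm_none <- function(table) {
  f <- rep(1, ncol(table))
  names(f) <- colnames(table)
  new_norm_factors("none", factors = f, lib_size = colSums(unclass(table)))
}

# Dispatch a normalization by name; used by the method registry.
#' @noRd
compute_norm <- function(table, method, ...) {
  switch(method,
         TSS = norm_tss(table),
         CLR = norm_clr(table, ...),
         TMM = norm_tmm(table, ...),
         RLE = norm_rle(table, ...),
         CSS = norm_css(table, ...),
         none = norm_none(table),
         stopf("unknown normalization '%s'", method))
}

# Per-sample absolute scale used for offsets / abundance scaling.
# TMM and RLE factors are relative (geometric mean 1), so the effective
# scale multiplies them by the library size; TSS/CSS/none factors are used
# directly. Only relative differences between samples matter downstream.
#' @noRd
effective_scale <- function(norm) {
  if (is.null(norm$factors))
    stopf("normalization '%s' has no per-sample factors", norm$method)
  if (norm$method %in% c("TMM", "RLE")) norm$factors * norm$lib_size
  else norm$factors
}

# Normalized abundance matrix handed to rank-based methods: CLR matrix for
# CLR, counts divided by the effective scale otherwise.
#' @noRd
normalized_matrix <- function(table, norm) {
  if (identical(norm$method, "CLR")) return(norm$clr)
  sweep(unclass(table), 2L, effective_scale(norm), "/")
}

#' Write per-sample normalization factors to a two-column TSV
#' @param norm A `norm_factors` object with per-sample factors.
#' @param path Output path.
#' @export
write_norm_factors <- function(norm, path) {
  if (is.null(norm$factors))
    stopf("'%s' normalization has no per-sample factors to export", norm$method)
  utils::write.table(data.frame(sample_id = names(norm$factors),
                                factor = unname(norm$factors)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
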