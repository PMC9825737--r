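# Seeded synthetic-data generators: count tables with known distributional
# structure and known DA truth. These are first-class citizens — the
# calibration, concordance, enrichment and power engines are all validated
# against them — and every generator is a pure function of its scenario,
# seed included.

#' Describe a simulation scenario
#'
#' Defaults describe a modest two-group 16S-like experiment: 100 features,
#' 20 samples per group, NB counts with dispersion 0.5, per-feature log
#' means uniform on `log(2)..log(100)`, 10% DA features at fold change 3
#' (half up, half down in group 2), and up to 4-fold library-size variation.
#'
#' @param m Number of features.
#' @param n_per_group Samples per group (two groups).
#' @param model Count model: `"NB"`, `"ZINB"` or `"DM"`.
#' @param mean_log_range Range for per-feature baseline log means
#'   (natural log scale).
#' @param dispersion NB/ZINB dispersion (`variance = mu + phi mu^2`).
#' @param pi0 ZINB zero-inflation probability in \[0, 1).
#' @param alpha0 DM total concentration (smaller = more overdispersed).
#' @param frac_da Fraction of DA features in \[0, 1\].
#' @param fold_change Fold change applied to group-2 means of DA features.
#' @param direction_balance Fraction of DA features that are UP in group 2.
#' @param library_size_range Range of multiplicative per-sample library
#'   factors.
#' @param compositional If TRUE, per-sample expected totals are renormalized
#'   after the DA spike-in so fold changes perturb the composition instead
#'   of the total.
#' @param seed Scenario seed.
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(m = 100L, n_per_group = 20L, model = c("NB", "ZINB", "DM"),
                         mean_log_range = log(c(2, 100)), dispersion = 0.5,
                         pi0 = 0.3, alpha0 = 100, frac_da = 0.1,
                         fold_change = 3, direction_balance = 0.5,
                         library_size_range = c(0.5, 2),
                         compositional = FALSE, seed = 1L) {
  model <- match.arg(model)
  bad <- character(0)
  chk <- function(cond, name) if (!cond) bad <<- c(bad, name)
  chk(m >= 1, "m"); chk(n_per_group >= 2, "n_per_group")
  chk(length(mean_log_range) == 2L && diff(mean_log_range) >= 0, "mean_log_range")
  chk(all(dispersion >= 0), "dispersion")
  chk(pi0 >= 0 && pi0 < 1, "pi0")
  chk(alpha0 > 0, "alpha0")
  chk(frac_da >= 0 && frac_da <= 1, "frac_da")
  chk(fold_change > 0, "fold_change")
  chk(direction_balance >= 0 && direction_balance <= 1, "direction_balance")
  chk(length(library_size_range) == 2L && library_size_range[1L] > 0 &&
        diff(library_size_range) >= 0, "library_size_range")
  if (length(bad)) stopf("invalid scenario field(s): %s", paste(bad, collapse = ", "))
  structure(list(m = as.integer(m), n_per_group = as.integer(n_per_group),
                 model = model, mean_log_range = mean_log_range,
                 dispersion = dispersion, pi0 = pi0, alpha0 = alpha0,
                 frac_da = frac_da, fold_change = fold_change,
                 direction_balance = direction_balance,
                 library_size_range = library_size_range,
                 compositional = compositional, seed = as.integer(seed)),
            class = "sim_scenario")
}

draw_model_counts <- function(mu, scenario) {
  m <- nrow(mu); n <- ncol(mu)
  if (scenario$model == "DM") {
    N <- round(1e4 * attr(mu, "lib_factor"))
    counts <- vapply(seq_len(n), function(j) {
      alpha <- mu[, j] / sum(mu[, j]) * scenario$alpha0
      p <- stats::rgamma(m, shape = alpha)
      p <- p / sum(p)
      stats::rmultinom(1L, N[j], p)[, 1L]
    }, numeric(m))
    return(counts)
  }
  counts <- if (all(scenario$dispersion == 0)) {
    matrix(stats::rpois(m * n, lambda = mu), m, n)
  } else {
    matrix(stats::rnbinom(m * n, mu = mu, size = 1 / scenario$dispersion), m, n)
  }
  if (scenario$model == "ZINB" && scenario$pi0 > 0) {
    drop <- matrix(stats::rbinom(m * n, 1L, scenario$pi0), m, n) == 1L
    counts[drop] <- 0
  }
  counts
}

#' Simulate a two-group count table with known DA truth
#'
#' Per-feature baseline means are drawn from `mean_log_range`;
#' `round(frac_da * m)` features (round-half-to-even) become DA, their
#' group-2 means multiplied (UP) or divided (DOWN) by `fold_change`; counts
#' are drawn under the scenario's model and per-sample library factors
#' applied multiplicatively.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `table` ([count_table()]), `metadata`
#'   ([sample_metadata()] with a `group` column), `truth` ([truth_set()])
#'   and the echoed `scenario`.
#' @export
sim_counts <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- scenario$m; npg <- scenario$n_per_group; n <- 2L * npg
  with_seed(scenario$seed, {
    base <- exp(stats::runif(m, scenario$mean_log_range[1L],
                             scenario$mean_log_range[2L]))
    n_da <- round(scenario$frac_da * m)
    da_idx <- if (n_da > 0) sample.int(m, n_da) else integer(0)
    n_up <- round(scenario$direction_balance * n_da)
    up_idx <- if (n_up > 0) da_idx[seq_len(n_up)] else integer(0)
    down_idx <- setdiff(da_idx, up_idx)
    mean2 <- base
    mean2[up_idx] <- mean2[up_idx] * scenario$fold_change
    mean2[down_idx] <- mean2[down_idx] / scenario$fold_change
    lib <- stats::runif(n, scenario$library_size_range[1L],
                        scenario$library_size_range[2L])
    group <- rep(c("grp1", "grp2"), each = npg)
    mu <- cbind(matrix(base, m, npg), matrix(mean2, m, npg))
    if (scenario$compositional) {
      # keep per-sample expected totals equal to the baseline total
      mu <- sweep(mu, 2L, colSums(mu) / sum(base), "/")
    }
    mu <- sweep(mu, 2L, lib, "*")
    attr(mu, "lib_factor") <- lib
    counts <- draw_model_counts(mu, scenario)
    sample_ids <- sprintf("S%02d", seq_len(n))
    table <- count_table(counts, feature_ids = sprintf("F%04d", seq_len(m)),
                         sample_ids = sample_ids)
    metadata <- sample_metadata(data.frame(sample_id = sample_ids,
                                           group = group,
                                           stringsAsFactors = FALSE))
    direction <- rep(NA_character_, m)
    direction[up_idx] <- "UP"
    direction[down_idx] <- "DOWN"
    fold <- rep(1, m)
    fold[da_idx] <- scenario$fold_change
    truth <- truth_set(rownames(table), seq_len(m) %in% da_idx, direction, fold)
    list(table = table, metadata = metadata, truth = truth, scenario = scenario)
  })
}

#' Simulate a null table with exchangeable samples
#'
#' All samples are i.i.d. draws from the same per-feature distribution
#' (`frac_da` forced to 0), so any balanced relabeling of the columns is a
#' true null — the input the mock-comparison engine expects.
#'
#' @param scenario A [sim_scenario()]; `frac_da` is ignored.
#' @return A [count_table()].
#' @export
sim_null <- function(scenario = sim_scenario()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  scenario$frac_da <- 0
  sim_counts(scenario)$table
}

#' Simulate a validated experiment plus truth
#'
#' Convenience wrapper bundling [sim_counts()] output into the
#' `list(exp, truth)` shape [power_analysis()] consumes.
#'
#' @param scenario A [sim_scenario()].
#' @param label Optional scenario label.
#' @export
sim_experiment <- function(scenario = sim_scenario(), label = NULL) {
  out <- sim_counts(scenario)
  list(exp = validate_experiment(out$table, out$metadata, "group"),
       truth = out$truth, label = label, scenario = scenario)
}

#' Synthetic annotation aligned with simulated truth
#'
#' True-UP features get level `"expectedUP"`, true-DOWN features
#' `"expectedDOWN"`, non-DA features stay unannotated. A fraction `noise`
#' of the annotated labels (exactly `round(noise * n_annotated)`) is
#' flipped to the opposite level.
#'
#' @param truth A [truth_set()].
#' @param noise Label noise fraction in \[0, 0.5).
#' @param seed Seed for the noise flips.
#' @return An [enrichment_prior()].
#' @export
sim_annotation <- function(truth, noise = 0, seed = 1) {
  stopifnot(inherits(truth, "truth_set"))
  if (noise < 0 || noise >= 0.5) stopf("noise must lie in [0, 0.5)")
  ann <- rep(NA_character_, length(truth$feature_ids))
  ann[truth$is_da & truth$direction == "UP"] <- "expectedUP"
  ann[truth$is_da & truth$direction == "DOWN"] <- "expectedDOWN"
  n_flip <- round(noise * sum(!is.na(ann)))
  if (n_flip > 0) {
    with_seed(seed, {
      flip <- sample(which(!is.na(ann)), n_flip)
      ann[flip] <- ifelse(ann[flip] == "expectedUP", "expectedDOWN", "expectedUP")
    })
  }
  map <- c(expectedUP = "UP", expectedDOWN = "DOWN")
  map <- map[names(map) %in% ann]
  enrichment_prior(truth$feature_ids, ann, map)
}
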