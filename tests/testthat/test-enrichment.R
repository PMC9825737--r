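mk_result <- function(ids, p_adj, dir, p_raw = p_adj) {
  da_result("m", ids, p_raw, statistic = -seq_along(ids), direction = dir,
            p_adj = p_adj)
}

test_that("classify_features applies the threshold and direction rules", {
  r <- mk_result(c("f1", "f2", "f3", "f4"),
                 p_adj = c(0.01, NA, 0.2, 0.01),
                 dir = c(1L, 1L, -1L, 0L))
  cls <- classify_features(r, threshold = 0.05)
  expect_equal(unname(cls), c("UP", "NONDA", "NONDA", "NONDA"))
  cls2 <- classify_features(r, threshold = 0.5)
  expect_equal(unname(cls2["f3"]), "DOWN")
  expect_error(classify_features(r, threshold = 0), "threshold")
})

test_that("build_contingency counts toy configurations correctly", {
  ids <- paste0("f", 1:8)
  prior <- enrichment_prior(ids, rep(c("aerobic", NA), each = 4),
                            c(aerobic = "UP"))
  # all 4 in-level called UP, nothing else called
  cls <- setNames(rep(c("UP", "NONDA"), each = 4), ids)
  prior8 <- enrichment_prior(ids, rep(c("aerobic", "other"), each = 4),
                             c(aerobic = "UP"))
  tab <- build_contingency(cls, prior8, "aerobic")
  expect_equal(unname(unclass(tab)), matrix(c(4, 0, 0, 4), 2, byrow = TRUE))

  # mixed: 3 in-level + 1 out-of-level called
  cls2 <- setNames(c("UP", "UP", "UP", "NONDA", "UP", "NONDA", "NONDA", "NONDA"),
                   ids)
  tab2 <- build_contingency(cls2, prior8, "aerobic")
  expect_equal(unname(unclass(tab2)), matrix(c(3, 1, 1, 3), 2, byrow = TRUE))

  # unannotated features are excluded from the margins
  tab3 <- build_contingency(cls2, prior, "aerobic")
  expect_equal(sum(tab3), 4)

  # nobody called: 'called' column all zero
  none <- setNames(rep("NONDA", 8), ids)
  expect_equal(unname(unclass(build_contingency(none, prior8, "aerobic"))[, 1]),
               c(0, 0))
  expect_error(build_contingency(cls, prior8, "anaerobic"), "empty|level")
})

test_that("fisher_test reproduces enumerated hypergeometric tails", {
  ft <- fisher_test(matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE))
  expect_equal(ft$p_value, 34 / 70, tolerance = 1e-12)
  ft2 <- fisher_test(matrix(c(4, 0, 0, 4), 2, 2, byrow = TRUE), "greater")
  expect_equal(ft2$p_value, 1 / 70, tolerance = 1e-12)
  expect_equal(ft2$odds_ratio, Inf)
  ft0 <- fisher_test(matrix(0, 2, 2))
  expect_equal(ft0$p_value, 1)
  expect_true(is.na(ft0$odds_ratio))
  expect_error(fisher_test(matrix(c(1.5, 1, 1, 1), 2, 2)), "non-negative integers")
})

# the exhaustive sweep up to total 30 runs in the acceptance suite; this
# keeps the module-level check quick
test_that("fisher_test equals the enumeration oracle on all tables, total <= 15", {
  worst_two <- 0; worst_gr <- 0
  for (n in 0:15) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
      worst_two <- max(worst_two,
                       abs(fisher_test(tab)$p_value - oracle_fisher(a, b, c, d)))
      worst_gr <- max(worst_gr,
                      abs(fisher_test(tab, "greater")$p_value -
                            oracle_fisher(a, b, c, d, "greater")))
    }
  }
  expect_lt(worst_two, 1e-12)
  expect_lt(worst_gr, 1e-12)
})

test_that("mutual_findings counts calling methods order-independently", {
  ids <- paste0("f", 1:6)
  r1 <- mk_result(ids, p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.5),
                  dir = rep(1L, 6))
  r2 <- mk_result(ids, p_adj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.5),
                  dir = rep(-1L, 6))
  r3 <- mk_result(ids, p_adj = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.01),
                  dir = rep(1L, 6))
  mf <- mutual_findings(list(r1, r2), threshold = 0.05)
  expect_equal(unname(mf$counts), c(2, 2, 2, 2, 2, 0))
  expect_length(mf$highlighted, 5L)
  # disjoint call sets
  mf2 <- mutual_findings(list(r1, r3), threshold = 0.05)
  expect_length(mf2$highlighted, 0L)
  expect_identical(mutual_findings(list(r3, r1), threshold = 0.05)$counts,
                   mf2$counts)
  expect_error(mutual_findings(list(r1)), ">= 2")
})

test_that("tp_fp_ranking matches direct counting on the annotated toy", {
  ids <- paste0("f", 1:6)
  truth <- truth_set(ids, is_da = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     direction = c("UP", "UP", "UP", NA, NA, NA),
                     fold_change = c(3, 3, 3, 1, 1, 1))
  # ranking f1, f4, f2, f5, f3, f6 via increasing p; all directions UP
  res <- da_result("m", ids, p_raw = c(0.01, 0.03, 0.05, 0.02, 0.04, 0.06),
                   statistic = rep(1, 6), direction = rep(1L, 6))
  curve <- tp_fp_ranking(res, truth)
  expect_equal(curve$TPminusFP, c(1, 1, 2, 2, 3, 3))

  # perfect method: true DA ranked first with correct directions
  ids10 <- paste0("g", sprintf("%02d", 1:20))
  truth10 <- truth_set(ids10, is_da = rep(c(TRUE, FALSE), each = 10),
                       direction = c(rep("UP", 10), rep(NA, 10)),
                       fold_change = rep(c(3, 1), each = 10))
  perfect <- da_result("m", ids10, p_raw = seq(0.001, 0.9, length.out = 20),
                       statistic = rep(1, 20), direction = rep(1L, 20))
  expect_equal(tp_fp_ranking(perfect, truth10, thresholds = 1:10)$TPminusFP,
               1:10)
  inverted <- da_result("m", ids10, p_raw = seq(0.001, 0.9, length.out = 20),
                        statistic = rep(1, 20), direction = rep(-1L, 20))
  expect_equal(tp_fp_ranking(inverted, truth10, thresholds = 1:10)$TPminusFP,
               -(1:10))
})

test_that("TP - FP at full depth is order-free", {
  withr::with_seed(47, {
    ids <- paste0("f", 1:30)
    truth <- truth_set(ids, is_da = rep(c(TRUE, FALSE), 15),
                       direction = ifelse(rep(c(TRUE, FALSE), 15),
                                          sample(c("UP", "DOWN"), 30, TRUE), NA),
                       fold_change = rep(1, 30))
    dirs <- sample(c(-1L, 1L), 30, TRUE)
    expected <- ifelse(truth$is_da, truth$direction, NA)
    called <- ifelse(dirs > 0, "UP", "DOWN")
    tp_direct <- sum(!is.na(expected) & called == expected)
    fp_direct <- sum(!is.na(expected) & called != expected)
    for (i in 1:5) {
      res <- da_result("m", ids, p_raw = runif(30), statistic = rnorm(30),
                       direction = dirs)
      curve <- tp_fp_ranking(res, truth)
      expect_equal(curve$TPminusFP[30], tp_direct - fp_direct)
    }
  })
})

test_that("run_enrichment emits expected and control tables per level", {
  sim <- sim_counts(sim_scenario(m = 60, n_per_group = 15, frac_da = 0.2,
                                 fold_change = 8, seed = 51))
  exp <- validate_experiment(sim$table, sim$metadata, "group")
  prior <- sim_annotation(sim$truth, noise = 0)
  reg <- register_method(method_spec("w", "wilcoxon"), method_registry())
  res <- run_methods(exp, reg)
  enr <- run_enrichment(res, prior, threshold = 0.1)
  expect_setequal(unique(enr$level), c("expectedUP", "expectedDOWN"))
  expect_equal(nrow(enr), 4L)  # 2 levels x {expected, control} x 1 method
  key <- enr[enr$is_expected_direction, ]
  ctrl <- enr[!enr$is_expected_direction, ]
  # strong signal: enrichment p in the expected direction beats the control
  expect_lt(min(key$p_value), min(0.05, min(ctrl$p_value)))
})

test_that("power_analysis reports NA power on null scenarios and high power at huge fc", {
  reg <- register_method(method_spec("w", "wilcoxon"), method_registry())
  null_sc <- sim_experiment(sim_scenario(m = 30, n_per_group = 10, frac_da = 0,
                                         seed = 53), label = "null")
  strong <- sim_experiment(sim_scenario(m = 50, n_per_group = 50,
                                        fold_change = 100, frac_da = 0.2,
                                        seed = 54), label = "strong")
  pow <- power_analysis(list(null_sc, strong), reg, threshold = 0.05)
  expect_true(is.na(pow$power[pow$scenario == "null"]))
  expect_gt(pow$power[pow$scenario == "strong"], 0.9)
  expect_true(all(pow$fdr >= 0 & pow$fdr <= 1))
  expect_error(power_analysis(list(list(exp = strong$exp)), reg), "truth")
})
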