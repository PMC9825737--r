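# Feature rows live in small constructed tables; a count_table always needs
# >= 2 samples, so degenerate single-feature cases ride along with a dummy row.
feature_table <- function(...) {
  rows <- list(...)
  count_table(do.call(rbind, rows),
              feature_ids = paste0("f", seq_along(rows)),
              sample_ids = paste0("s", seq_along(rows[[1]])))
}

test_that("fit_nb handles degenerate features and recovers NB parameters", {
  tab <- feature_table(rep(5, 20), rep(0, 20))
  fit <- fit_nb(tab)
  expect_equal(fit$EY, c(5, 0))
  expect_lt(abs(fit$P0[1] - exp(-5)), 1e-6)
  expect_equal(fit$P0[2], 1)
  expect_true(all(fit$converged))

  # 1000 NB(mu = 10, phi = 0.5) draws: P0 = (1 + 5)^(-2) = 1/36 at truth
  x <- withr::with_seed(11, rnbinom(1000, mu = 10, size = 2))
  fit2 <- fit_nb(feature_table(x, x))
  expect_gt(fit2$EY[1], 9); expect_lt(fit2$EY[1], 11)
  expect_lt(abs(fit2$P0[1] - 1 / 36), 0.02)
})

test_that("fit_nb's zero probability hits the Poisson closed form at tiny dispersion", {
  # equal counts force the dispersion to its 1e-10 floor
  fit <- fit_nb(feature_table(rep(7, 30), rep(2, 30)))
  expect_lt(max(abs(fit$P0 - exp(-fit$params$mu))), 1e-8)
  expect_lte(max(fit$params$dispersion), 1e-8)
})

test_that("fit_zinb collapses without zeros, recovers pi0, flags all-zero rows", {
  x <- withr::with_seed(3, rnbinom(500, mu = 30, size = 2) + 1)
  tab <- feature_table(x, x)
  zi <- fit_zinb(tab); nb <- fit_nb(tab)
  expect_lt(abs(zi$params$pi0[1]), 1e-8)
  expect_lt(abs(zi$EY[1] - nb$EY[1]), 1e-3)
  expect_lt(abs(zi$P0[1] - nb$P0[1]), 1e-3)

  z <- withr::with_seed(5, {
    x <- rnbinom(1000, mu = 10, size = 2)
    x[rbinom(1000, 1, 0.3) == 1] <- 0
    x
  })
  fit <- fit_zinb(feature_table(z, z))
  expect_lt(abs(fit$params$pi0[1] - 0.3), 0.05)

  allz <- fit_zinb(feature_table(rep(0, 10), rep(1, 10)))
  expect_equal(allz$params$pi0[1], 1)
  expect_equal(allz$P0[1], 1)
})

test_that("each ZINB EM iteration is non-decreasing in observed log-likelihood", {
  withr::with_seed(17, {
    for (i in 1:10) {
      x <- rnbinom(60, mu = runif(1, 2, 30), size = 1 / runif(1, 0.2, 2))
      x[rbinom(60, 1, runif(1, 0.1, 0.5)) == 1] <- 0
      if (all(x == 0) || all(x > 0)) next
      fit <- dabench:::zinb_fit_one(x, trace = TRUE)
      if (length(fit$ll_trace) > 1)
        expect_gte(min(diff(fit$ll_trace)), -1e-6)
    }
  })
})

test_that("fit_zig matches point-mass limits and Gaussian data", {
  allz <- fit_zig(feature_table(rep(0, 6), c(0, 0, 0, 3, 3, 3)))
  expect_equal(allz$params$pi0[1], 1)
  expect_equal(allz$P0[1], 1)
  expect_equal(allz$EY[1], 0)
  # half zeros, half 3s: point-mass continuous part
  expect_equal(allz$params$pi0[2], 0.5)
  expect_equal(allz$EY[2], 1.5)

  # zero-free log-scale Gaussian data reduces to Gaussian ML
  z <- withr::with_seed(9, round(2^rnorm(200, mean = 4, sd = 0.5)))
  z[z == 0] <- 1
  fit <- fit_zig(feature_table(z, z))
  expect_equal(fit$params$pi0[1], 0)
  expect_lt(abs(fit$params$mu_log[1] - mean(log2(z + 1))), 0.1)
})

test_that("fit_hurdle has zero ZPD by construction and exact back-transforms", {
  tab <- feature_table(c(0, 0, 7, 7), c(1, 2, 3, 4), c(0, 5, 5, 5))
  fit <- fit_hurdle(tab)
  met <- evaluate_fit(fit, tab)
  expect_equal(unname(met$ZPD), c(0, 0, 0))
  expect_equal(met$RMSE_ZPD, 0)
  expect_equal(fit$params$pi0, c(0.5, 0, 0.25))
  expect_equal(fit$EY[1], 3.5)  # sigma_pos = 0, 0.5 * (2^3 - 1) = 3.5
})

test_that("fit_dm recovers symmetric proportions and the multinomial limit", {
  # two dominant equal-concentration features, large depth
  tab <- withr::with_seed(21, {
    counts <- vapply(1:40, function(j) {
      p <- rgamma(2, shape = c(50, 50)); p <- p / sum(p)
      rmultinom(1, 5000, p)[, 1]
    }, numeric(2))
    count_table(counts)
  })
  # the fixed point crawls near the multinomial boundary; give it headroom
  fit <- fit_dm(tab, max_iter = 5000)
  prop <- fit$params$alpha / fit$params$alpha0
  expect_lt(max(abs(prop - 0.5)), 0.05)

  expect_error(fit_dm(count_table(matrix(1:2, 2, 1))), "2 samples")

  # multinomial data (alpha0 -> infinity): P0 -> mean_j (1 - p_i)^(N_j)
  tabm <- withr::with_seed(22, {
    p <- c(0.5, 0.3, 0.15, 0.05)
    counts <- vapply(1:60, function(j) rmultinom(1, 80, p)[, 1], numeric(4))
    count_table(counts)
  })
  fitm <- fit_dm(tabm, max_iter = 20000)
  N <- colSums(unclass(tabm))
  p_hat <- rowSums(unclass(tabm)) / sum(N)
  p0_lim <- vapply(p_hat, function(pi) mean((1 - pi)^N), numeric(1))
  expect_lt(max(abs(fitm$P0 - p0_lim)), 0.02)
})

test_that("evaluate_fit is exact on perfect fits and compare_fits ranks models", {
  tab <- random_table(30, 15, mu = 20, phi = 0.5, seed = 31)
  x <- unclass(tab)
  perfect <- dabench:::new_fit_stats("NB", rownames(x), rowMeans(x),
                                     rowMeans(x == 0), rep(TRUE, nrow(x)),
                                     list())
  met <- evaluate_fit(perfect, tab)
  expect_equal(unname(met$MD), rep(0, 30))
  expect_equal(met$RMSE_MD, 0)
  expect_equal(met$RMSE_ZPD, 0)
  expect_error(evaluate_fit(perfect, random_table(10, 5)), "different features")

  single <- compare_fits(fit_nb(tab), tab)
  expect_equal(nrow(single), 1L)

  # ZINB-simulated data: NB under-predicts zeros; ZINB wins on RMSE_ZPD
  zt <- sim_counts(sim_scenario(m = 60, n_per_group = 25, model = "ZINB",
                                pi0 = 0.5, frac_da = 0, seed = 33))$table
  nb <- fit_nb(zt); zi <- fit_zinb(zt)
  expect_lt(mean(evaluate_fit(nb, zt)$ZPD), 0)
  cmp <- compare_fits(list(nb, zi), zt)
  expect_equal(cmp$model[1], "ZINB")
  expect_lt(cmp$RMSE_ZPD[cmp$model == "ZINB"], cmp$RMSE_ZPD[cmp$model == "NB"])
})

test_that("all five models keep P0 in [0,1] and EY >= 0 on random tables", {
  fitters <- list(fit_nb, fit_zinb, fit_zig, fit_hurdle, fit_dm)
  for (s in 1:5) {
    tab <- sim_counts(sim_scenario(m = 25, n_per_group = 8, model = "ZINB",
                                   pi0 = 0.4, frac_da = 0, seed = 40 + s))$table
    for (fit_fn in fitters) {
      fit <- suppressWarnings(fit_fn(tab))
      expect_true(all(fit$P0 >= 0 & fit$P0 <= 1))
      expect_true(all(fit$EY >= 0))
      expect_true(all(is.finite(fit$EY[fit$converged])))
    }
  }
})
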