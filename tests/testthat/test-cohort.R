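test_that("Mann-Whitney exact branch matches brute-force enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(mw$method, "exact")
  set.seed(42)
  x <- rnorm(5); y <- rnorm(7) + 1
  expect_equal(mann_whitney(x, y)$p, mw_enumeration_p(x, y), tolerance = 1e-12)
})

test_that("exact and normal-approximation branches agree closely at n = 8 + 8", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, -1, 1)
    pe <- mann_whitney(x, y, exact_max = 8)$p
    pn <- mann_whitney(x, y, exact_max = 0)$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("ties route to the tie-corrected normal approximation", {
  mw <- mann_whitney(c(1, 2, 2, 3), c(2, 3, 4))
  expect_equal(mw$method, "normal")
  same <- mann_whitney(c(1, 2, 3, 1, 2, 3, 1, 2, 3), c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  expect_gt(same$p, 0.9)
})

test_that("Mann-Whitney has power against a 1-sd shift", {
  rej <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    mann_whitney(rnorm(50), rnorm(50) + 1)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("Welch t matches the hand Satterthwaite computation", {
  x <- c(1.1, 2.3, 3.1, 4.8)
  y <- c(2.0, 2.2, 2.1, 7.5, 6.1)
  wt <- welch_t(x, y)
  se2x <- var(x) / 4; se2y <- var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_hand <- (se2x + se2y)^2 / (se2x^2 / 3 + se2y^2 / 4)
  expect_equal(wt$t, t_hand, tolerance = 1e-12)
  expect_equal(wt$df, df_hand, tolerance = 1e-12)
  expect_equal(wt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  deg <- welch_t(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)
})

test_that("compare_groups detects a programmed birth-size shift and only that", {
  tab <- sim_strain_table(n_ll = 100, n_nll = 100, birth_size_shift = -0.05,
                          fitness_shift = 0, within_sd = 0.01, seed = 13)
  res <- compare_groups(tab)
  bs <- res[res$variable == "birth_size_fl", ]
  expect_lt(bs$mw_p, 0.01)
  expect_lt(bs$t_p, 0.01)
  expect_lt(bs$mean_LL, bs$mean_NLL)
  fit <- res[res$variable == "fitness", ]
  expect_gt(fit$mw_p, 0.001)  # no programmed shift
  skipped <- dplyr::mutate(tab, fitness = ifelse(rls_class == "LL", NA, fitness))
  expect_warning(res2 <- compare_groups(skipped), "skipped")
  expect_false("fitness" %in% res2$variable)
})

test_that("both compare_groups tests hold their size under the null", {
  ps <- purrr::map_dfr(1:1000, function(s) {
    tab <- sim_strain_table(n_ll = 30, n_nll = 30, birth_size_shift = 0,
                            fitness_shift = 0, seed = 3000 + s)
    compare_groups(tab, variables = "birth_size_fl")
  })
  expect_gt(mean(ps$mw_p < 0.05), 0.03)
  expect_lt(mean(ps$mw_p < 0.05), 0.07)
  expect_gt(mean(ps$t_p < 0.05), 0.03)
  expect_lt(mean(ps$t_p < 0.05), 0.07)
  # p-values roughly uniform: median near 0.5
  expect_gt(median(ps$mw_p), 0.35)
  expect_lt(median(ps$mw_p), 0.65)
})

test_that("logistic coefficient for a binary predictor equals the table log odds ratio", {
  tab <- tibble::tibble(
    x = rep(c(1, 0, 1, 0), c(30, 10, 20, 40)),
    rls_class = rep(c("LL", "NLL"), c(40, 60))
  )
  fit <- logistic_rank(tab, predictors = "x", standardize = FALSE)
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_equal(est, log((30 * 40) / (10 * 20)), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a null predictor gets a near-zero standardized coefficient", {
  tab <- sim_strain_table(n_ll = 500, n_nll = 500, birth_size_shift = 0,
                          fitness_shift = 0, seed = 17)
  fit <- logistic_rank(tab)
  co <- fit$coefficients
  expect_lt(max(abs(co$estimate[co$term != "(Intercept)"])), 0.15)
  expect_true(all(co$wald_p[co$term != "(Intercept)"] > 0.001))
})

test_that("complete separation is flagged, not silently reported", {
  tab <- tibble::tibble(x = c(rnorm(20, 10), rnorm(20, -10)),
                        rls_class = rep(c("LL", "NLL"), each = 20))
  fit <- logistic_rank(tab, predictors = "x")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("predictors are returned in increasing Wald-p order", {
  tab <- sim_strain_table(n_ll = 137, n_nll = 1000, birth_size_shift = -0.05,
                          fitness_shift = 0, seed = 19)
  fit <- logistic_rank(tab)
  co <- fit$coefficients
  preds <- co[co$term != "(Intercept)", ]
  expect_equal(preds$term[1], "birth_size_fl")
  expect_true(!is.unsorted(preds$wald_p))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
})
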