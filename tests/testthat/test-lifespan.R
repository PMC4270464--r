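test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  km <- survival_curve(tibble::tibble(group = "a", lifespan = c(1, 2, 3),
                                      event = 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  cens <- survival_curve(tibble::tibble(group = "a", lifespan = rep(5, 4),
                                        event = 0))
  expect_equal(cens$survival, 1)
  # hand product-limit on 5 records with interleaved censoring:
  # deaths at 1, 3, 4; censored at 2 and 5
  mixed <- survival_curve(tibble::tibble(
    group = "a", lifespan = 1:5, event = c(1, 0, 1, 1, 0)))
  expect_equal(mixed$survival[mixed$time %in% c(1, 3, 4)],
               c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
})

test_that("lifespan summaries report mean, median, max and the age of 90% mortality", {
  s <- lifespan_summary(tibble::tibble(group = "a", lifespan = c(10, 20, 30),
                                       event = 1))
  expect_equal(s$mean, 20)
  expect_equal(s$median, 20)
  expect_equal(s$max, 30)
  s2 <- lifespan_summary(tibble::tibble(group = "a", lifespan = 1:10,
                                        event = 1))
  expect_equal(s2$age_90pct_mortality, 9)
  # censored cohorts fall back to the restricted mean and are flagged
  cens <- tibble::tibble(group = "a", lifespan = c(2, 4, 6, 8),
                         event = c(1, 1, 0, 1))
  sc <- lifespan_summary(cens)
  expect_true(sc$censored)
  expect_lt(sc$mean, mean(c(2, 4, 6, 8) + 2))
})

test_that("cohort means match a larger Monte-Carlo draw of the same hazard", {
  big <- sim_lifespan_cohort(1e5, seed = 21)
  small <- sim_lifespan_cohort(2e4, seed = 22)
  expect_equal(lifespan_summary(small)$mean, mean(big$lifespan),
               tolerance = 0.01)
})

test_that("percent extension is the relative change in mean lifespan", {
  expect_equal(percent_extension(cohort_tbl(rep(20, 5), rep(23, 5))), 15)
  d <- sim_lifespan_cohort(50, seed = 9)
  both <- dplyr::bind_rows(d, dplyr::mutate(d, group = "b"))
  expect_equal(percent_extension(both), 0)
  expect_equal(percent_extension(cohort_tbl(c(24, 26), c(29, 29.5))), 17)
})

test_that("the log-rank statistic matches a hand-computed Mantel-Cox table", {
  # a = {1,2,3}, b = {4,5,6}: O_a = 3, E_a = 0.5+0.4+0.25, V = 0.25+0.24+0.1875
  lr <- logrank_test(cohort_tbl(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(lr$chi_square, (3 - 1.15)^2 / 0.6775, tolerance = 1e-9)
  expect_equal(lr$p, pchisq((3 - 1.15)^2 / 0.6775, 1, lower.tail = FALSE))
  ident <- cohort_tbl(c(3, 5, 8), c(3, 5, 8))
  lr0 <- logrank_test(ident)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(cohort_tbl(1:3, 4:6, ea = 0, eb = 0)),
               class = "g1span_not_estimable")
})

test_that("the Wang-Allison table and chi-square match the hand construction", {
  wa <- wang_allison_test(cohort_tbl(1:10, 11:20))
  expect_equal(wa$threshold, 18)  # order statistic at ceiling(0.9 * 20)
  expect_equal(as.vector(wa$table), c(10, 8, 0, 2))
  expect_equal(wa$chi_square, 2 + 2 / 9, tolerance = 1e-9)
  expect_equal(wa$p, pchisq(2 + 2 / 9, 1, lower.tail = FALSE))
  # mirrored cohorts: observed equals expected, chi-square 0
  mir <- wang_allison_test(cohort_tbl(1:10, 1:10))
  expect_equal(mir$chi_square, 0, tolerance = 1e-12)
  # degenerate: nobody above the pooled maximum quantile
  deg <- wang_allison_test(cohort_tbl(rep(5, 6), rep(5, 6)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("both tests are invariant to group relabeling and unit changes", {
  d <- dplyr::bind_rows(sim_lifespan_cohort(30, group = "a", seed = 31),
                        sim_lifespan_cohort(30, scale = 1.4, group = "b",
                                            seed = 32))
  relab <- dplyr::mutate(d, group = ifelse(group == "a", "zzz", "aaa"))
  days <- dplyr::mutate(d, lifespan = lifespan * 3.7)
  for (f in list(logrank_test, function(x) suppressWarnings(wang_allison_test(x)))) {
    base <- f(d)
    expect_equal(f(relab)$chi_square, base$chi_square, tolerance = 1e-12)
    expect_equal(f(days)$chi_square, base$chi_square, tolerance = 1e-12)
  }
})

test_that("survival curves plot and empty cohorts error", {
  km <- survival_curve(sim_lifespan_cohort(20, seed = 2))
  expect_s3_class(autoplot(km), "ggplot")
  expect_error(survival_curve(tibble::tibble(group = character(),
                                             lifespan = numeric())),
               class = "g1span_insufficient_data")
  expect_error(survival_curve(tibble::tibble(group = "a", lifespan = -1)),
               class = "g1span_invalid_parameter")
})
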