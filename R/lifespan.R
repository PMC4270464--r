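# Survival analysis of lifespan cohorts: Kaplan-Meier curves and summaries,
# percent lifespan extension, the Mantel-Cox log-rank test, and the
# Wang-Allison maximum-lifespan chi-square test (above vs at-or-below the
# pooled 90th-percentile lifespan). Units are divisions for yeast replicative
# lifespan or days for worms/flies; every statistic is unit-invariant.

lifespan_input <- function(data) {
  check_columns(data, c("group", "lifespan"))
  if (!"event" %in% names(data)) data$event <- 1L
  if (nrow(data) < 1) {
    abort("empty cohort.", class = "g1span_insufficient_data")
  }
  if (any(!is.finite(data$lifespan)) || any(data$lifespan <= 0)) {
    abort("lifespans must be positive and finite.",
          class = "g1span_invalid_parameter")
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death observed).",
          class = "g1span_invalid_parameter")
  }
  data
}

#' Kaplan-Meier survival curves for lifespan cohorts
#'
#' Product-limit estimate of the survivor function per group, honouring
#' right-censoring. With no censoring this equals the empirical survivor
#' function.
#'
#' @param data A tibble with columns `group`, `lifespan` and optionally
#'   `event` (1 = death observed, 0 = right-censored; defaults to all
#'   deaths, the yeast replicative-lifespan convention where every mother
#'   is followed to death).
#' @return A tibble of class `g1span_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' survival_curve(sim_lifespan_cohort(30, seed = 1))
#' @export
survival_curve <- function(data) {
  data <- lifespan_input(data)
  groups <- unique(data$group)
  out <- purrr::map_dfr(groups, function(g) {
    d <- data[data$group == g, ]
    sf <- survival::survfit(survival::Surv(lifespan, event) ~ 1, data = d)
    tibble(group = g, time = sf$time, n_risk = sf$n.risk,
           n_event = sf$n.event, n_censor = sf$n.censor,
           survival = sf$surv)
  })
  class(out) <- c("g1span_km", class(out))
  out
}

km_quantile <- function(time, surv, p) {
  # smallest event time at which survival has dropped to p or below
  i <- which(surv <= p + 1e-12)
  if (length(i) == 0) NA_real_ else time[i[1]]
}

#' Per-group lifespan summaries
#'
#' Reports, per group, the mean, median, maximum lifespan and the age of
#' 90% mortality (the smallest time by which survival has fallen to 0.10),
#' read from the Kaplan-Meier curve. With no censoring the mean is the
#' arithmetic mean of the observed lifespans; with censoring it is the
#' restricted mean up to the largest observed time and the row is flagged
#' as a lower bound.
#'
#' @inheritParams survival_curve
#' @return A tibble with columns `group`, `n`, `mean`, `median`, `max`,
#'   `age_90pct_mortality`, `censored` (flag: mean is a restricted-mean
#'   lower bound).
#' @examples
#' lifespan_summary(sim_lifespan_cohort(50, seed = 1))
#' @export
lifespan_summary <- function(data) {
  data <- lifespan_input(data)
  purrr::map_dfr(unique(data$group), function(g) {
    d <- data[data$group == g, ]
    has_cens <- any(d$event == 0)
    if (has_cens) {
      sf <- survival::survfit(survival::Surv(lifespan, event) ~ 1, data = d)
      mean_ls <- unname(summary(sf, rmean = max(d$lifespan))$table["rmean"])
    } else {
      mean_ls <- mean(d$lifespan)
    }
    km <- survival_curve(d)
    tibble(
      group = g,
      n = nrow(d),
      mean = mean_ls,
      median = km_quantile(km$time, km$survival, 0.5),
      max = max(d$lifespan),
      age_90pct_mortality = km_quantile(km$time, km$survival, 0.1),
      censored = has_cens
    )
  })
}

pick_two_groups <- function(data, control, treated) {
  groups <- unique(data$group)
  if (is.null(control) || is.null(treated)) {
    if (length(groups) != 2) {
      abort("`data` must contain exactly 2 groups unless `control` and `treated` are named.",
            class = "g1span_invalid_parameter")
    }
    control <- groups[1]; treated <- groups[2]
  }
  if (!all(c(control, treated) %in% groups)) {
    abort("`control`/`treated` not found among the groups.",
          class = "g1span_invalid_parameter")
  }
  data[data$group %in% c(control, treated), , drop = FALSE] |>
    dplyr::mutate(group = factor(.data$group, levels = c(control, treated)))
}

#' Percent lifespan extension of a treated over a control cohort
#'
#' `100 * (mean_treated - mean_control) / mean_control`, using the same
#' mean as [lifespan_summary()].
#'
#' @inheritParams survival_curve
#' @param control,treated Group labels; may be omitted when exactly two
#'   groups are present (first = control).
#' @return A single number (percent).
#' @export
percent_extension <- function(data, control = NULL, treated = NULL) {
  data <- lifespan_input(data)
  d <- pick_two_groups(data, control, treated)
  s <- lifespan_summary(d)
  s <- s[match(levels(d$group), s$group), ]
  100 * (s$mean[2] - s$mean[1]) / s$mean[1]
}

#' Mantel-Cox log-rank test between two lifespan cohorts
#'
#' Standard two-group log-rank (Mantel-Cox) test with hypergeometric
#' variance and the usual tie handling; the p-value comes from a chi-square
#' distribution with 1 degree of freedom.
#'
#' @inheritParams percent_extension
#' @return A `logrank_test` object with elements `chi_square`, `df`, `p`.
#' @examples
#' a <- sim_lifespan_cohort(40, group = "control", seed = 1)
#' b <- sim_lifespan_cohort(40, scale = 1.3, group = "treated", seed = 2)
#' logrank_test(dplyr::bind_rows(a, b))
#' @export
logrank_test <- function(data, control = NULL, treated = NULL) {
  data <- lifespan_input(data)
  d <- pick_two_groups(data, control, treated)
  if (sum(d$event) == 0) {
    abort("no observed deaths; the log-rank test is not estimable.",
          class = "g1span_not_estimable")
  }
  sd <- survival::survdiff(survival::Surv(lifespan, event) ~ group, data = d)
  chi <- unname(sd$chisq)
  new_g1span_fit(list(
    chi_square = chi,
    df = 1L,
    p = pchisq(chi, df = 1, lower.tail = FALSE)
  ), "logrank_test")
}

#' Wang-Allison maximum-lifespan test
#'
#' Tests for a difference in maximum lifespan: every animal is classified as
#' living above, versus at or below, the `q`-th quantile of the pooled
#' lifespans (the order statistic at `ceiling(q * n)`), and the resulting
#' 2x2 group-by-class table is tested with an ordinary Pearson chi-square
#' without continuity correction. A table with an empty class column is
#' degenerate and returns p = 1.
#'
#' @inheritParams percent_extension
#' @param q Pooled quantile defining "long-lived"; default 0.9.
#' @return A `wang_allison_test` object with elements `threshold`, `table`
#'   (2x2 counts), `chi_square`, `df`, `p`, `degenerate`.
#' @export
wang_allison_test <- function(data, control = NULL, treated = NULL, q = 0.9) {
  data <- lifespan_input(data)
  d <- pick_two_groups(data, control, treated)
  if (nrow(d) < 10) {
    abort("the Wang-Allison test needs a combined n of at least 10.",
          class = "g1span_insufficient_data")
  }
  threshold <- unname(quantile(d$lifespan, q, type = 1))
  cls <- factor(d$lifespan > threshold, levels = c(FALSE, TRUE),
                labels = c("at_or_below", "above"))
  tab <- table(group = d$group, class = cls)
  degenerate <- any(colSums(tab) == 0)
  if (degenerate) {
    chi <- 0; p <- 1
  } else {
    # small expected "above" counts are intrinsic to a 90th-percentile
    # classification; the plain Pearson statistic is what is reported
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  new_g1span_fit(list(
    threshold = threshold,
    table = tab,
    chi_square = chi,
    df = 1L,
    p = p,
    degenerate = degenerate
  ), "wang_allison_test")
}
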