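# Biochemical assay kinetics: first-order decay half-lives from
# cycloheximide-chase densitometry, uptake time-course summaries, and
# treated-vs-control amino-acid percentage differences.

#' Fit a first-order decay half-life from chase densitometry
#'
#' Target band densities are normalized pointwise by the loading control,
#' then rescaled to the value at the first time point, and
#' `ln(normalized density)` is regressed on time by ordinary least squares.
#' The decay constant is minus the slope and the half-life is
#' `ln(2) / lambda`. Log-linear least squares is deterministic and exact on
#' any noiseless exponential; a non-positive estimated decay constant is
#' returned as a `no_decay` flag with an infinite half-life.
#'
#' @param data A tibble with columns `time_min`, `target_density`,
#'   `loading_density`.
#' @return A `decay_fit` object with elements `lambda` (per minute),
#'   `t_half` (minutes, `ln(2)/lambda`), `r_squared`, `n_points`,
#'   `no_decay`, and the normalized `points` used.
#' @examples
#' fit_decay(sim_decay(t_half = 28, times = seq(0, 90, 10)))
#' @export
fit_decay <- function(data) {
  check_columns(data, c("time_min", "target_density", "loading_density"))
  d <- dplyr::arrange(data, .data$time_min)
  norm <- d$target_density / d$loading_density
  ok <- is.finite(norm) & norm > 0
  if (any(!ok)) {
    warn(sprintf("%d point(s) with non-positive normalized density dropped.",
                 sum(!ok)))
  }
  t <- d$time_min[ok]
  norm <- norm[ok]
  if (length(norm) < 2) {
    abort("fewer than 2 usable points for the decay fit.",
          class = "g1span_insufficient_data")
  }
  norm <- norm / norm[1]
  fit <- lm(log(norm) ~ t)
  lam <- -unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit))$r.squared  # noiseless series fit exactly
  no_decay <- !is.finite(lam) || lam <= 0
  new_g1span_fit(list(
    lambda = lam,
    t_half = if (no_decay) Inf else log(2) / lam,
    r_squared = r2,
    n_points = length(norm),
    no_decay = no_decay,
    points = tibble(time_min = t, normalized_density = norm)
  ), "decay_fit")
}

#' Summarize paired uptake time courses
#'
#' Computes the initial uptake rate (ordinary least squares slope over the
#' first `n_initial` time points) for the control and treated conditions,
#' and the percent inhibition `100 * (1 - treated / control)` at each shared
#' time point (missing where the control is zero).
#'
#' @param data A tibble with columns `condition`, `time_min`, `counts`
#'   containing a `"control"` and a `"treated"` condition on a shared grid.
#' @param n_initial Number of leading points in the initial-rate fit.
#' @return A list with `rates` (tibble: condition, initial rate) and
#'   `inhibition` (tibble: time, percent inhibition).
#' @export
uptake_summary <- function(data, n_initial = 3) {
  check_columns(data, c("condition", "time_min", "counts"))
  wide <- tidyr::pivot_wider(data, names_from = "condition",
                             values_from = "counts")
  check_columns(wide, c("control", "treated"),
                "`data` (after pivoting on condition)")
  wide <- dplyr::arrange(wide, .data$time_min)
  init_rate <- function(y) {
    m <- min(n_initial, nrow(wide))
    if (m < 2) return(NA_real_)
    unname(coef(lm(y[seq_len(m)] ~ wide$time_min[seq_len(m)]))[2])
  }
  list(
    rates = tibble(
      condition = c("control", "treated"),
      initial_rate = c(init_rate(wide$control), init_rate(wide$treated))
    ),
    inhibition = tibble(
      time_min = wide$time_min,
      percent_inhibition = ifelse(wide$control == 0, NA_real_,
                                  100 * (1 - wide$treated / wide$control))
    )
  )
}

#' Percent change in amino-acid levels, treated vs control
#'
#' Per amino acid and replicate, the percent difference is
#' `100 * (treated - control) / control`; the mean and sample SD are
#' reported across replicates. Replicates with a zero control level are
#' excluded with a warning.
#'
#' @param data A tibble with columns `amino_acid`, `replicate`,
#'   `control_nmol`, `treated_nmol`.
#' @return A tibble with columns `amino_acid`, `mean_pct_change`,
#'   `sd_pct_change`, `n`.
#' @examples
#' amino_acid_percent_change(sim_amino_acid_panel(seed = 1))
#' @export
amino_acid_percent_change <- function(data) {
  check_columns(data, c("amino_acid", "replicate", "control_nmol",
                        "treated_nmol"))
  bad <- data$control_nmol == 0
  if (any(bad)) {
    warn(sprintf("%d replicate(s) with zero control level excluded.",
                 sum(bad)))
    data <- data[!bad, ]
  }
  out <- data |>
    dplyr::mutate(pct = 100 * (.data$treated_nmol - .data$control_nmol) /
                    .data$control_nmol) |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(mean_pct_change = mean(.data$pct),
                     sd_pct_change = sd(.data$pct),
                     n = dplyr::n(), .groups = "drop")
  small <- out$n < 2
  if (any(small)) {
    warn(sprintf("amino acid(s) with fewer than 2 replicates: %s.",
                 paste(out$amino_acid[small], collapse = ", ")))
  }
  out
}
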