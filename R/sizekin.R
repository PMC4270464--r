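# Estimation of the three determinants of G1 length from synchronous-culture
# data: specific growth rate k (ln volume vs time), critical size Vc (volume
# at 50% budding) and birth size Vb (smallest-cell feature of a dividing
# population's volume histogram). T_G1 = ln(Vc/Vb)/k combines them.

new_g1span_fit <- function(x, class) {
  structure(x, class = c(class, "g1span_fit"))
}

#' @export
print.g1span_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- purrr::keep(unclass(x), ~ is.atomic(.x) && length(.x) <= 2)
  for (nm in names(flat)) {
    cat(" ", nm, ": ", paste(signif(unlist(flat[[nm]]), 5), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Fit the specific growth rate from an elutriation time course
#'
#' Ordinary least squares of `ln(mean volume)` on time over the pre-Start
#' window, i.e. the time points whose budded fraction does not exceed
#' `max_budded` (cultures past Start no longer represent G1 growth). The
#' slope is the specific rate of size increase k, assuming exponential
#' single-cell growth.
#'
#' @param data A tibble with columns `time_h`, `mean_volume_fl`,
#'   `budded_fraction` (one label at a time; see [estimate_g1_panel()] for
#'   panels).
#' @param max_budded Largest budded fraction a time point may have and still
#'   enter the fit.
#' @return A `growth_fit` object with elements `k` (per hour), `intercept`
#'   (ln fL), `r_squared`, `n_points`.
#' @examples
#' tc <- sim_elutriation(seq(0, 3, 0.5), vb = 40, k = 0.35, vc = 64)
#' fit_growth_rate(tc)
#' @export
fit_growth_rate <- function(data, max_budded = 0.5) {
  check_columns(data, c("time_h", "mean_volume_fl", "budded_fraction"))
  use <- data$budded_fraction <= max_budded & data$mean_volume_fl > 0
  d <- data[use, ]
  if (nrow(d) < 2) {
    abort("fewer than 2 time points with budded fraction <= `max_budded`.",
          class = "g1span_insufficient_data")
  }
  fit <- lm(log(mean_volume_fl) ~ time_h, data = d)
  s <- suppressWarnings(summary(fit))  # noiseless series fit exactly
  new_g1span_fit(list(
    k = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (is.null(s$r.squared)) NA_real_ else s$r.squared,
    n_points = nrow(d),
    max_budded = max_budded
  ), "growth_fit")
}

#' Estimate the critical size from a budding-index curve
#'
#' The critical size is the volume at which half of a synchronous culture
#' has budded. Points with budded fraction inside `window` (the
#' approximately linear portion of the sigmoidal rise) are fit by ordinary
#' least squares of budded fraction on mean volume, and Vc is the volume at
#' which the fitted line crosses 0.5.
#'
#' @inheritParams fit_growth_rate
#' @param window Budded-fraction bounds of the points used, default
#'   `c(0.1, 0.9)`.
#' @return A `critical_size` object with elements `vc` (fL), `window`,
#'   `n_points`.
#' @export
estimate_critical_size <- function(data, window = c(0.1, 0.9)) {
  check_columns(data, c("mean_volume_fl", "budded_fraction"))
  use <- data$budded_fraction >= window[1] & data$budded_fraction <= window[2]
  d <- data[use, ]
  if (nrow(d) < 2 || min(d$budded_fraction) > 0.5 ||
      max(d$budded_fraction) < 0.5) {
    abort("budded fractions inside the window must straddle 0.5.",
          class = "g1span_not_estimable")
  }
  fit <- lm(budded_fraction ~ mean_volume_fl, data = d)
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] == 0) {
    abort("budding index does not increase with volume in the window.",
          class = "g1span_not_estimable")
  }
  vc <- unname((0.5 - b[1]) / b[2])
  vc <- min(max(vc, min(d$mean_volume_fl)), max(d$mean_volume_fl))
  new_g1span_fit(list(
    vc = vc,
    window = window,
    n_points = nrow(d)
  ), "critical_size")
}

#' Estimate the birth size from a cell-volume histogram
#'
#' Daughters are born as the smallest cells of a dividing population, so the
#' default estimator (`"smallest_mode"`) smooths the histogram counts with a
#' cubic smoothing spline and returns the volume of the first local maximum
#' scanning from the smallest bin. If no local maximum is found, it falls
#' back to the `"percentile"` method (volume at cumulative fraction `p`,
#' linearly interpolated within the bin) with a warning.
#'
#' @param data A tibble with columns `bin_left_fl`, `bin_right_fl`, `count`.
#' @param method `"smallest_mode"` (default) or `"percentile"`.
#' @param bandwidth Spline smoothing bandwidth in fL; default 2 bin widths.
#' @param p Cumulative fraction for the percentile method.
#' @return A `birth_size` object with elements `vb` (fL), `method`,
#'   `bandwidth`.
#' @examples
#' h <- sim_size_histogram(vb = 30, seed = 1)
#' estimate_birth_size(h)
#' @export
estimate_birth_size <- function(data, method = c("smallest_mode", "percentile"),
                                bandwidth = NULL, p = 0.05) {
  method <- match.arg(method)
  check_columns(data, c("bin_left_fl", "bin_right_fl", "count"))
  if (nrow(data) < 1 || sum(data$count) <= 0) {
    abort("histogram has no counts.", class = "g1span_insufficient_data")
  }
  data <- dplyr::arrange(data, .data$bin_left_fl)
  widths <- data$bin_right_fl - data$bin_left_fl
  if (any(widths <= 0)) {
    abort("bin edges must be strictly increasing.",
          class = "g1span_invalid_parameter")
  }
  if (is.null(bandwidth)) bandwidth <- 2 * stats::median(widths)

  if (method == "smallest_mode") {
    vb <- smallest_mode(data, widths, bandwidth)
    if (is.na(vb)) {
      warn("no local maximum found by `smallest_mode`; falling back to the percentile method.")
      method <- "percentile"
    }
  }
  if (method == "percentile") {
    vb <- histogram_quantile(data, p)
  }
  new_g1span_fit(list(vb = vb, method = method, bandwidth = bandwidth),
                 "birth_size")
}

# First local maximum of the spline-smoothed density, scanning from the
# smallest volume. Returns NA when the smoothed density is monotone.
smallest_mode <- function(data, widths, bandwidth) {
  mid <- (data$bin_left_fl + data$bin_right_fl) / 2
  dens <- data$count / widths / sum(data$count)
  if (length(mid) < 4) return(NA_real_)
  df <- max(4, min(length(mid) - 1, diff(range(mid)) / bandwidth))
  sp <- smooth.spline(mid, dens, df = df)
  grid <- seq(min(mid), max(mid), length.out = max(512, 4 * length(mid)))
  y <- predict(sp, grid)$y
  # interior local maxima with a little prominence, so smoothing ripples in
  # the sparse tail are not mistaken for the newborn mode
  is_max <- which(diff(sign(diff(y))) < 0) + 1
  is_max <- is_max[y[is_max] > 0.05 * max(y)]
  if (length(is_max) == 0) return(NA_real_)
  grid[is_max[1]]
}

# volume at cumulative fraction p, linear within the containing bin
histogram_quantile <- function(data, p) {
  cum <- cumsum(data$count) / sum(data$count)
  i <- which(cum >= p)[1]
  lower <- if (i == 1) 0 else cum[i - 1]
  frac <- (p - lower) / (cum[i] - lower)
  data$bin_left_fl[i] + frac * (data$bin_right_fl[i] - data$bin_left_fl[i])
}

#' Combine birth size, critical size and growth rate into a G1 summary
#'
#' The relative G1 growth is `kT_G1 = ln(Vc / Vb)` and the absolute G1
#' duration is `T_G1 = ln(Vc / Vb) / k`: how small cells are born, how big
#' they must get to pass Start, and how fast they grow between the two set
#' the length of G1. When `Vc < Vb` (already past the critical size at
#' birth), `T_G1` is 0 and the row is flagged.
#'
#' @param vb Birth size, fL (vectorised).
#' @param vc Critical size, fL.
#' @param k Specific growth rate, per hour.
#' @return A tibble with columns `vb_fl`, `vc_fl`, `k_per_h`, `kt_g1`,
#'   `t_g1_h`, `negative_g1` (flag for `Vc < Vb`).
#' @examples
#' summarize_g1(vb = 30, vc = 60, k = log(2))
#' @export
summarize_g1 <- function(vb, vc, k) {
  check_positive(vb, "vb")
  check_positive(vc, "vc")
  check_positive(k, "k")
  kt <- log(vc / vb)
  tibble(
    vb_fl = vb,
    vc_fl = vc,
    k_per_h = k,
    kt_g1 = kt,
    t_g1_h = pmax(kt / k, 0),
    negative_g1 = vc < vb
  )
}

#' Run the full G1 estimation pipeline over a strain panel
#'
#' For each label present in `elutriation`, fits the growth rate and
#' critical size from the time course and the birth size from the matching
#' histogram, and returns one G1 summary row per strain.
#'
#' @param elutriation Long tibble of elutriation time courses with columns
#'   `label`, `time_h`, `mean_volume_fl`, `budded_fraction`.
#' @param histograms Long tibble of histograms with columns `label`,
#'   `bin_left_fl`, `bin_right_fl`, `count`.
#' @param max_budded,window,birth_method,bandwidth Estimator options passed
#'   through to the per-strain fits.
#' @return A tibble with one row per label: the [summarize_g1()] columns
#'   plus `label` and the growth-fit `r_squared`.
#' @examples
#' panel <- sim_strain_panel(n_strains = 4, seed = 1)
#' estimate_g1_panel(panel$elutriation, panel$histograms)
#' @export
estimate_g1_panel <- function(elutriation, histograms, max_budded = 0.5,
                              window = c(0.1, 0.9),
                              birth_method = "smallest_mode",
                              bandwidth = NULL) {
  check_columns(elutriation, c("label", "time_h", "mean_volume_fl",
                               "budded_fraction"), "`elutriation`")
  check_columns(histograms, c("label", "bin_left_fl", "bin_right_fl", "count"),
                "`histograms`")
  labels <- unique(elutriation$label)
  purrr::map_dfr(labels, function(lab) {
    tc <- dplyr::filter(elutriation, .data$label == lab)
    h <- dplyr::filter(histograms, .data$label == lab)
    if (nrow(h) == 0) {
      abort(sprintf("no histogram for label '%s'.", lab),
            class = "g1span_insufficient_data")
    }
    gf <- fit_growth_rate(tc, max_budded = max_budded)
    cs <- estimate_critical_size(tc, window = window)
    bs <- estimate_birth_size(h, method = birth_method, bandwidth = bandwidth)
    dplyr::mutate(summarize_g1(bs$vb, cs$vc, gf$k),
                  label = lab, r_squared = gf$r_squared,
                  .before = 1)
  })
}
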