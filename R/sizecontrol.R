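# Size-control efficiency: the slope of relative G1 growth kT_G1 against the
# natural log of normalized birth size. Slope 0 = timer (no size control),
# -1 = perfect sizer (critical size independent of birth size); wild-type
# daughters sit near -0.7. Natural logs on both axes keep the slope directly
# comparable with the generating size-control exponent.

#' Fit the size-control slope
#'
#' Ordinary least squares of `kT_G1` on `ln(Vb / Vref)` across strains or
#' single cells. `Vref` only shifts the intercept; the slope — the measure
#' of size-control efficiency — is invariant to it.
#'
#' @param data A tibble with one row per strain or cell.
#' @param birth_size,kt_g1 Columns holding birth size (fL) and relative G1
#'   growth (tidy evaluation; defaults `birth_size_fl`, `kt_g1`).
#' @param vref Normalization reference in fL; default the median birth size
#'   of the panel (a wild-type stand-in).
#' @return A `size_control_fit` object with elements `slope`, `intercept`,
#'   `slope_se`, `ci95`, `n`, `vref`, and a `points` tibble with residuals.
#' @examples
#' cells <- sim_daughter_cells(200, exponent = -0.7, seed = 1)
#' size_control_fit(cells)
#' @export
size_control_fit <- function(data, birth_size = .data$birth_size_fl,
                             kt_g1 = .data$kt_g1, vref = NULL) {
  vb <- dplyr::pull(dplyr::transmute(data, v = {{ birth_size }}), .data$v)
  kt <- dplyr::pull(dplyr::transmute(data, v = {{ kt_g1 }}), .data$v)
  keep <- is.finite(vb) & is.finite(kt)
  vb <- vb[keep]; kt <- kt[keep]
  if (length(vb) < 3) {
    abort("at least 3 points are required.",
          class = "g1span_insufficient_data")
  }
  check_positive(vb, "birth_size")
  if (is.null(vref)) vref <- stats::median(vb)
  check_positive(vref, "vref")
  x <- log(vb / vref)
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    abort("all birth sizes are equal; the slope is not estimable.",
          class = "g1span_not_estimable")
  }
  fit <- lm(kt ~ x)
  s <- suppressWarnings(summary(fit))$coefficients  # noiseless panels fit exactly
  slope <- s["x", "Estimate"]
  se <- s["x", "Std. Error"]
  new_g1span_fit(list(
    slope = unname(slope),
    intercept = unname(s["(Intercept)", "Estimate"]),
    slope_se = unname(se),
    ci95 = unname(slope + c(-1, 1) * qnorm(0.975) * se),
    n = length(vb),
    vref = vref,
    points = tibble(log_vb_norm = x, kt_g1 = kt,
                    residual = unname(stats::residuals(fit)))
  ), "size_control_fit")
}

#' Classify a size-control fit
#'
#' Labels the fitted slope by where its 95% confidence interval falls:
#' `"no_size_control"` if it contains 0 (a timer), `"perfect_sizer"` if it
#' contains -1 but not 0, `"partial_sizer"` if it lies strictly inside
#' `(-1, 0)` (the wild-type daughter regime), `"anomalous"` otherwise.
#'
#' @param fit A `size_control_fit` object.
#' @return A single character label.
#' @export
classify_size_control <- function(fit) {
  stopifnot(inherits(fit, "size_control_fit"))
  ci <- fit$ci95
  if (ci[1] <= 0 && ci[2] >= 0) return("no_size_control")
  if (ci[1] <= -1 && ci[2] >= -1) return("perfect_sizer")
  if (ci[1] > -1 && ci[2] < 0) return("partial_sizer")
  "anomalous"
}
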