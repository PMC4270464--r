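# broom-style tidy()/glance() methods for the package's fit objects.

#' @rdname g1span-tidiers
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("k", "intercept"),
         estimate = c(x$k, x$intercept))
}

#' @rdname g1span-tidiers
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points)
}

#' @rdname g1span-tidiers
#' @method tidy critical_size
#' @export
tidy.critical_size <- function(x, ...) {
  tibble(term = "vc", estimate = x$vc)
}

#' @rdname g1span-tidiers
#' @method tidy birth_size
#' @export
tidy.birth_size <- function(x, ...) {
  tibble(term = "vb", estimate = x$vb, method = x$method)
}

#' @rdname g1span-tidiers
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("lambda", "t_half"),
         estimate = c(x$lambda, x$t_half))
}

#' @rdname g1span-tidiers
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points, no_decay = x$no_decay)
}

#' @rdname g1span-tidiers
#' @method tidy size_control_fit
#' @export
tidy.size_control_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_se, NA_real_),
    conf.low = c(x$ci95[1], NA_real_),
    conf.high = c(x$ci95[2], NA_real_)
  )
}

#' @rdname g1span-tidiers
#' @method glance size_control_fit
#' @export
glance.size_control_fit <- function(x, ...) {
  tibble(nobs = x$n, vref = x$vref, label = classify_size_control(x))
}

#' @rdname g1span-tidiers
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$chi_square, df = x$df, p.value = x$p,
         method = "log-rank (Mantel-Cox)")
}

#' @rdname g1span-tidiers
#' @method tidy wang_allison_test
#' @export
tidy.wang_allison_test <- function(x, ...) {
  tibble(statistic = x$chi_square, df = x$df, p.value = x$p,
         threshold = x$threshold, degenerate = x$degenerate,
         method = "Wang-Allison maximum-lifespan chi-square")
}

#' Tidiers for g1span fit objects
#'
#' [tidy()] returns the estimates of a fitted object as one row per term;
#' [glance()] returns a one-row model-level summary.
#'
#' @name g1span-tidiers
#' @rdname g1span-tidiers
#' @method tidy logistic_rank
#' @export
tidy.logistic_rank <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "std_error",
                statistic = "wald_z", p.value = "wald_p")
}

#' @rdname g1span-tidiers
#' @method glance logistic_rank
#' @export
glance.logistic_rank <- function(x, ...) {
  tibble(converged = x$converged, separation = x$separation,
         n_iter = x$n_iter, nobs = x$n_used, n_dropped = x$n_dropped)
}
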