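# Long-lived (LL) vs not-long-lived (NLL) strain-panel comparisons:
# Mann-Whitney and Welch t tests per cell-cycle variable, and
# logistic-regression ranking of the variables as predictors of the LL
# class.

#' Two-sided Mann-Whitney U test
#'
#' Reports the U statistic for the first sample and a two-sided p-value:
#' exact (from the null U distribution) when `min(nx, ny) <= exact_max` and
#' there are no ties, otherwise a normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `min(nx, ny)` for which the exact branch is
#'   used.
#' @return A list with elements `U`, `p`, `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) {
    abort("both samples must be non-empty.",
          class = "g1span_insufficient_data")
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (min(nx, ny) <= exact_max && !has_ties) {
    p <- if (u > nx * ny / 2) {
      2 * pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    } else {
      2 * pwilcox(u, nx, ny)
    }
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(U = unname(u), p = min(unname(p), 1), method = method)
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided. When
#' both groups have zero variance the test is degenerate: p = 1 if the
#' means are equal, otherwise the result is flagged and p = 0.
#'
#' @param x,y Numeric samples of size at least 2.
#' @return A list with elements `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("both samples must have at least 2 values.",
          class = "g1span_insufficient_data")
  }
  if (var(x) == 0 && var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (equal) 0 else Inf, df = NA_real_,
                p = if (equal) 1 else 0, degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

cohort_classes <- function(data, class_col) {
  check_columns(data, class_col)
  cls <- data[[class_col]]
  if (length(unique(cls[!is.na(cls)])) != 2) {
    abort("exactly two classes are required.",
          class = "g1span_invalid_parameter")
  }
  cls
}

#' Compare LL and NLL strain classes on each variable
#'
#' For every variable, runs the Mann-Whitney and Welch t tests between the
#' two strain classes on non-missing values (dropped pairwise per
#' variable), and reports group means and sizes. A variable entirely
#' missing in one class is skipped with a warning.
#'
#' @param data A strain table with a two-level class column.
#' @param variables Character vector of numeric columns to compare.
#' @param class_col Name of the class column (default `"rls_class"`).
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment across variables.
#' @return A tibble with one row per variable: `variable`, group means and
#'   sizes, `mw_U`, `mw_p`, `t_stat`, `t_p`.
#' @examples
#' tab <- sim_strain_table(n_ll = 50, n_nll = 200, seed = 1)
#' compare_groups(tab)
#' @export
compare_groups <- function(data,
                           variables = c("fitness", "mean_size_fl",
                                         "birth_size_fl", "g1_dna_fraction"),
                           class_col = "rls_class",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cls <- cohort_classes(data, class_col)
  levels <- sort(unique(cls[!is.na(cls)]))
  check_columns(data, variables)
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]][cls == levels[1]]
    y <- data[[v]][cls == levels[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0 || length(y) == 0) {
      warn(sprintf("variable '%s' has no data in one class; skipped.", v))
      return(NULL)
    }
    mw <- mann_whitney(x, y)
    wt <- if (length(x) >= 2 && length(y) >= 2) welch_t(x, y) else
      list(t = NA_real_, p = NA_real_)
    tibble(
      variable = v,
      mean_1 = mean(x), mean_2 = mean(y),
      n_1 = length(x), n_2 = length(y),
      mw_U = mw$U, mw_p = mw$p,
      t_stat = wt$t, t_p = wt$p
    )
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", levels[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", levels[2])
  names(out)[names(out) == "n_1"] <- paste0("n_", levels[1])
  names(out)[names(out) == "n_2"] <- paste0("n_", levels[2])
  if (adjust == "BH" && nrow(out) > 0) {
    out$mw_p_adj <- stats::p.adjust(out$mw_p, "BH")
    out$t_p_adj <- stats::p.adjust(out$t_p, "BH")
  }
  out
}

#' Rank predictors of the long-lived class by logistic regression
#'
#' Fits a binary logistic regression of class membership on the given
#' predictors by maximum likelihood (iteratively reweighted least squares;
#' convergence when the deviance change is below 1e-8, at most 100
#' iterations) and reports Wald z statistics and two-sided p-values, with
#' predictors ordered by increasing Wald p. Predictors are z-score
#' standardized by default so the ranking is scale-free; Wald p-values are
#' unchanged by this rescaling.
#'
#' @inheritParams compare_groups
#' @param outcome Class level coded as 1 (default `"LL"`).
#' @param predictors Character vector of predictor columns.
#' @param standardize Z-score the predictors before fitting.
#' @return A `logistic_rank` object with elements `coefficients` (tibble:
#'   `term`, `estimate`, `std_error`, `wald_z`, `wald_p`, predictors in
#'   increasing `wald_p`, intercept last), `converged`, `n_iter`,
#'   `n_used`, `n_dropped`, `separation`.
#' @examples
#' tab <- sim_strain_table(n_ll = 60, n_nll = 300, seed = 1)
#' logistic_rank(tab)
#' @export
logistic_rank <- function(data, outcome = "LL",
                          predictors = c("fitness", "mean_size_fl",
                                         "birth_size_fl", "g1_dna_fraction"),
                          class_col = "rls_class", standardize = TRUE) {
  cls <- cohort_classes(data, class_col)
  check_columns(data, predictors)
  if (!outcome %in% cls) {
    abort(sprintf("outcome class '%s' not present.", outcome),
          class = "g1span_invalid_parameter")
  }
  X <- data[predictors]
  ok <- complete.cases(X) & !is.na(cls)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  y <- as.integer(cls[ok] == outcome)
  if (length(unique(y)) != 2) {
    abort("both outcome classes must remain after dropping missing rows.",
          class = "g1span_invalid_parameter")
  }
  if (standardize) {
    X <- dplyr::mutate(X, dplyr::across(
      dplyr::everything(),
      ~ if (sd(.x) > 0) (.x - mean(.x)) / sd(.x) else .x - mean(.x)
    ))
  }
  df <- dplyr::bind_cols(tibble(.y = y), X)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)$coefficients
  co <- tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    wald_z = unname(s[, "z value"]),
    wald_p = unname(s[, "Pr(>|z|)"])
  )
  is_int <- co$term == "(Intercept)"
  co <- dplyr::bind_rows(dplyr::arrange(co[!is_int, ], .data$wald_p),
                         co[is_int, ])
  co$term <- sub("^`(.*)`$", "\\1", co$term)
  new_g1span_fit(list(
    coefficients = co,
    converged = fit$converged && !separation,
    separation = separation,
    n_iter = fit$iter,
    n_used = length(y),
    n_dropped = n_dropped
  ), "logistic_rank")
}
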