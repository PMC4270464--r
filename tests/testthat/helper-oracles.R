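# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for the Mann-Whitney
# null distribution and closed-form formulas elsewhere.

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (no ties assumed).
mw_enumeration_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r_obs <- rank(c(x, y))[seq_len(nx)]
  u_obs <- sum(r_obs) - nx * (nx + 1) / 2
  sets <- utils::combn(n, nx)
  u_all <- colSums(matrix(seq_len(n)[sets], nrow = nx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Closed-form OLS slope of y on x.
ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

# Two-cohort lifespan table from bare vectors.
cohort_tbl <- function(a, b, ea = 1, eb = 1) {
  dplyr::bind_rows(
    tibble::tibble(group = "a", lifespan = a, event = ea),
    tibble::tibble(group = "b", lifespan = b, event = eb)
  )
}
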