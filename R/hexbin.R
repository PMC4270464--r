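# 2-D hexagonal binning and 1-D kernel-density summaries for visualising
# dense strain-panel scatters (many overlapping points) and per-variable
# distributions.

#' Hexagonal binning of a 2-D point cloud
#'
#' Assigns points to a regular pointy-top hexagonal tiling of the bounding
#' box with `gridsize` hexagons across the x range (the classic two-offset-
#' lattice construction), and returns the occupied hexagon centres with
#' their counts. Counts are conserved and invariant to translation of the
#' point cloud.
#'
#' @param data A tibble containing the two coordinate columns.
#' @param x,y Coordinate columns (tidy evaluation).
#' @param gridsize Number of hexagons across the x range.
#' @return A tibble of class `g1span_hexbin` with columns `hex_x`, `hex_y`,
#'   `count` (only occupied hexagons), and attributes `gridsize` and `n`.
#' @examples
#' tab <- sim_strain_table(n_ll = 50, n_nll = 200, seed = 1)
#' hexbin_summary(tab, birth_size_fl, fitness, gridsize = 15)
#' @export
hexbin_summary <- function(data, x, y, gridsize = 30) {
  xv <- dplyr::pull(dplyr::transmute(data, v = {{ x }}), .data$v)
  yv <- dplyr::pull(dplyr::transmute(data, v = {{ y }}), .data$v)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 1) {
    abort("at least one finite point is required.",
          class = "g1span_insufficient_data")
  }
  check_positive(gridsize, "gridsize")
  xr <- range(xv); yr <- range(yv)
  dx <- if (diff(xr) > 0) diff(xr) else 1
  dy <- if (diff(yr) > 0) diff(yr) else 1
  nx <- gridsize
  ny <- max(1, round(nx / sqrt(3)))
  tx <- (xv - xr[1]) / dx * nx
  ty <- (yv - yr[1]) / dy * ny
  # nearest centre on either of the two offset rectangular lattices
  ix1 <- round(tx); iy1 <- round(ty)
  ix2 <- floor(tx) + 0.5; iy2 <- floor(ty) + 0.5
  d1 <- (tx - ix1)^2 + 3 * (ty - iy1)^2
  d2 <- (tx - ix2)^2 + 3 * (ty - iy2)^2
  use2 <- d2 < d1
  cx <- ifelse(use2, ix2, ix1)
  cy <- ifelse(use2, iy2, iy1)
  out <- tibble(cx = cx, cy = cy) |>
    dplyr::count(.data$cx, .data$cy, name = "count") |>
    dplyr::transmute(
      hex_x = xr[1] + .data$cx * dx / nx,
      hex_y = yr[1] + .data$cy * dy / ny,
      count = .data$count
    )
  attr(out, "gridsize") <- gridsize
  attr(out, "n") <- n
  attr(out, "cell") <- c(x = dx / nx, y = dy / ny)
  class(out) <- c("g1span_hexbin", class(out))
  out
}

#' Gaussian kernel-density summary of one variable
#'
#' Kernel density estimate on a regular grid; the returned density
#' integrates to 1 (trapezoid rule) to within 1e-3. A zero-variance input
#' is flagged as a spike rather than smoothed.
#'
#' @param data A tibble containing the variable.
#' @param var Variable column (tidy evaluation).
#' @param bw Bandwidth rule or numeric bandwidth, passed to
#'   [stats::density()].
#' @param n_grid Number of grid points.
#' @return A `kde_summary` object with elements `curve` (tibble: `grid`,
#'   `density`), `bw`, `n`, `spike`.
#' @export
kde_summary <- function(data, var, bw = "nrd0", n_grid = 512) {
  xv <- dplyr::pull(dplyr::transmute(data, v = {{ var }}), .data$v)
  xv <- xv[is.finite(xv)]
  if (length(xv) < 2) {
    abort("at least 2 finite values are required.",
          class = "g1span_insufficient_data")
  }
  if (sd(xv) == 0) {
    return(new_g1span_fit(list(
      curve = tibble(grid = xv[1], density = Inf),
      bw = NA_real_, n = length(xv), spike = TRUE
    ), "kde_summary"))
  }
  d <- density(xv, bw = bw, n = n_grid)
  new_g1span_fit(list(
    curve = tibble(grid = d$x, density = d$y),
    bw = d$bw, n = length(xv), spike = FALSE
  ), "kde_summary")
}
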