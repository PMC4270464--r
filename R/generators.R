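# Seeded generators for every input the pipeline consumes. Each one is a pure
# function of its arguments and `seed` (withr::with_seed; the caller's RNG
# stream is untouched). With all noise terms zero the downstream estimators
# recover the generating parameters exactly -- the round-trip property the
# test suite asserts per estimator.

#' Simulate an elutriation time course
#'
#' Generates the mean cell volume and budded fraction of a synchronous
#' early-G1 culture growing exponentially from birth size `vb` at specific
#' rate `k`, budding around the critical size `vc`. The budding-versus-size
#' transition is a logistic in volume centred at `vc` with scale
#' `budding_width` (fL), matching the sigmoidal rise of budding index seen in
#' synchronous cultures.
#'
#' @param times Sampling times in hours, ascending, at least 3 points.
#' @param vb Birth size (mean volume at t = 0), fL.
#' @param k Specific growth rate, per hour.
#' @param vc Critical size (volume at which half the cells have budded), fL.
#' @param budding_width Scale of the logistic budding transition, fL.
#' @param meas_cv Multiplicative measurement noise CV on volumes; the budded
#'   fraction receives additive noise with sd `meas_cv / 2`, clamped to
#'   `[0, 1]`. `meas_cv = 0` gives a deterministic output.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param label Strain/treatment label carried in the output.
#' @return A tibble with columns `label`, `time_h`, `mean_volume_fl`,
#'   `budded_fraction`.
#' @examples
#' sim_elutriation(seq(0, 3, 0.5), vb = 40, k = 0.35, vc = 64)
#' @export
sim_elutriation <- function(times, vb = 40, k = 0.35, vc = 64,
                            budding_width = 8, meas_cv = 0,
                            seed = NULL, label = "sim") {
  check_positive(vb, "vb")
  check_positive(k, "k")
  check_positive(vc, "vc")
  check_positive(budding_width, "budding_width")
  check_nonneg(meas_cv, "meas_cv")
  if (length(times) < 3 || is.unsorted(times)) {
    abort("`times` must be ascending with at least 3 points.",
          class = "g1span_invalid_parameter")
  }
  with_seed_if(seed, {
    vol <- vb * exp(k * times) * (1 + rnorm(length(times), 0, meas_cv))
    f <- stats::plogis((vol - vc) / budding_width) +
      rnorm(length(times), 0, meas_cv / 2)
    tibble(
      label = label,
      time_h = as.numeric(times),
      mean_volume_fl = vol,
      budded_fraction = pmin(pmax(f, 0), 1)
    )
  })
}

#' Simulate a cell-volume histogram of a dividing population
#'
#' The distribution is a two-component lognormal mixture: a tight newborn
#' component whose mode sits at the birth size `vb` (the "smallest cells"
#' feature the birth-size estimator reads), and a broader component for the
#' rest of the dividing population with mode at `pop_scale * vb`.
#'
#' @param vb Birth size, fL; the mode of the newborn component.
#' @param n_cells Number of cells counted.
#' @param bin_width Histogram bin width, fL.
#' @param newborn_frac Mixture weight of the newborn component.
#' @param newborn_sdlog,pop_sdlog Log-scale spreads of the two components.
#' @param pop_scale Mode of the dividing-population component relative to `vb`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param label Label carried in the output.
#' @return A tibble with columns `label`, `bin_left_fl`, `bin_right_fl`,
#'   `count`.
#' @export
sim_size_histogram <- function(vb = 40, n_cells = 20000, bin_width = 1,
                               newborn_frac = 0.25, newborn_sdlog = 0.06,
                               pop_sdlog = 0.30, pop_scale = 1.8,
                               seed = NULL, label = "sim") {
  check_positive(vb, "vb")
  check_positive(n_cells, "n_cells")
  check_positive(bin_width, "bin_width")
  check_fraction(newborn_frac, "newborn_frac")
  check_nonneg(newborn_sdlog, "newborn_sdlog")
  check_nonneg(pop_sdlog, "pop_sdlog")
  check_positive(pop_scale, "pop_scale")
  with_seed_if(seed, {
    n_new <- round(n_cells * newborn_frac)
    # lognormal mode = exp(meanlog - sdlog^2); shift meanlog so the mode is vb
    v <- c(
      rlnorm(n_new, log(vb) + newborn_sdlog^2, newborn_sdlog),
      rlnorm(n_cells - n_new, log(pop_scale * vb) + pop_sdlog^2, pop_sdlog)
    )
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    edges <- seq(lo, hi, by = bin_width)
    if (edges[length(edges)] < hi) edges <- c(edges, hi)
    counts <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
    tibble(
      label = label,
      bin_left_fl = edges[-length(edges)],
      bin_right_fl = edges[-1],
      count = counts
    )
  })
}

#' Simulate a strain panel of elutriation time courses and size histograms
#'
#' Each strain draws a birth size `Vb_i` lognormally around `vref`, and its
#' relative G1 growth obeys the size-control law
#' `ln(Vc_i / Vb_i) = intercept + exponent * ln(Vb_i / vref) + noise`.
#' `exponent = 0` is a timer (no size control), `-1` a perfect sizer, and
#' `-0.7` the partial sizer typical of wild-type daughters. Each strain gets
#' a full elutriation time course and a volume histogram whose smallest-cell
#' mode encodes `Vb_i`, so the whole estimation pipeline can be exercised.
#'
#' @param n_strains Number of strains (at least 2).
#' @param exponent Size-control exponent b.
#' @param intercept Intercept a of the size-control law (natural-log units);
#'   the default `log(1.6)` reproduces the base condition Vc/Vb = 64/40.
#' @param noise_sd SD of the noise on `ln(Vc/Vb)`.
#' @param vref Reference (wild-type) birth size, fL.
#' @param vb_sdlog Between-strain log-scale spread of birth size.
#' @param k Specific growth rate shared by the panel, per hour.
#' @param budding_width,meas_cv Passed to [sim_elutriation()].
#' @param times Elutriation sampling times, hours.
#' @param hist_cells,bin_width Passed to [sim_size_histogram()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with tibbles `strains` (strain, true Vb, Vc, kT_G1),
#'   `elutriation` (long, one block per strain) and `histograms`.
#' @examples
#' panel <- sim_strain_panel(n_strains = 5, seed = 1)
#' head(panel$strains)
#' @export
sim_strain_panel <- function(n_strains = 20, exponent = -0.7,
                             intercept = log(1.6), noise_sd = 0.05,
                             vref = 40, vb_sdlog = 0.15, k = 0.35,
                             budding_width = 8, meas_cv = 0,
                             times = seq(0, 4, by = 0.25),
                             hist_cells = 20000, bin_width = 1,
                             seed = NULL) {
  if (n_strains < 2) {
    abort("`n_strains` must be at least 2.", class = "g1span_invalid_parameter")
  }
  check_nonneg(noise_sd, "noise_sd")
  check_positive(vref, "vref")
  check_positive(k, "k")
  with_seed_if(seed, {
    vb <- rlnorm(n_strains, log(vref), vb_sdlog)
    kt <- intercept + exponent * log(vb / vref) + rnorm(n_strains, 0, noise_sd)
    vc <- vb * exp(kt)
    ids <- sprintf("strain_%02d", seq_len(n_strains))
    tcs <- purrr::pmap(
      list(ids, vb, vc),
      function(id, b, c) {
        sim_elutriation(times, vb = b, k = k, vc = c,
                        budding_width = budding_width, meas_cv = meas_cv,
                        label = id)
      }
    )
    hists <- purrr::map2(
      ids, vb,
      function(id, b) {
        sim_size_histogram(vb = b, n_cells = hist_cells,
                           bin_width = bin_width, label = id)
      }
    )
    list(
      strains = tibble(label = ids, vb_true_fl = vb, vc_true_fl = vc,
                       kt_g1_true = kt),
      elutriation = dplyr::bind_rows(tcs),
      histograms = dplyr::bind_rows(hists)
    )
  })
}

#' Simulate single daughter cells under a size-control law
#'
#' Per-cell relative G1 growth:
#' `kT_G1,i = intercept + exponent * ln(Vb_i / vref) + noise`; the absolute
#' G1 duration is `T_G1,i = kT_G1,i / k`, floored at zero.
#'
#' @inheritParams sim_strain_panel
#' @param n Number of daughter cells.
#' @param noise_sd SD of the noise on `kT_G1`.
#' @return A tibble with columns `cell`, `birth_size_fl`, `kt_g1`, `t_g1_h`.
#' @export
sim_daughter_cells <- function(n = 1000, exponent = -0.7,
                               intercept = log(1.6), noise_sd = 0.1,
                               vref = 40, vb_sdlog = 0.15, k = 0.35,
                               seed = NULL) {
  check_positive(n, "n")
  check_nonneg(noise_sd, "noise_sd")
  check_positive(vref, "vref")
  check_positive(k, "k")
  with_seed_if(seed, {
    vb <- rlnorm(n, log(vref), vb_sdlog)
    kt <- intercept + exponent * log(vb / vref) + rnorm(n, 0, noise_sd)
    tibble(
      cell = seq_len(n),
      birth_size_fl = vb,
      kt_g1 = kt,
      t_g1_h = pmax(kt / k, 0)
    )
  })
}

#' Simulate a cycloheximide-chase decay series
#'
#' Target band density decays as `exp(-ln(2) * t / t_half)`; the loading
#' control is constant at 1 up to the same multiplicative noise.
#'
#' @param t_half Half-life, minutes.
#' @param times Sampling times, minutes.
#' @param noise_cv Multiplicative noise CV on both densities.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param label Label carried in the output.
#' @return A tibble with columns `label`, `time_min`, `target_density`,
#'   `loading_density`.
#' @examples
#' sim_decay(t_half = 28, times = seq(0, 90, 10))
#' @export
sim_decay <- function(t_half = 28, times = seq(0, 90, by = 10),
                      noise_cv = 0, seed = NULL, label = "sim") {
  check_positive(t_half, "t_half")
  check_nonneg(noise_cv, "noise_cv")
  with_seed_if(seed, {
    tibble(
      label = label,
      time_min = as.numeric(times),
      target_density = exp(-log(2) * times / t_half) *
        (1 + rnorm(length(times), 0, noise_cv)),
      loading_density = 1 + rnorm(length(times), 0, noise_cv)
    )
  })
}

#' Simulate a lifespan cohort under a discrete Gompertz hazard
#'
#' Lifespans (divisions for yeast replicative lifespan, or days) are drawn
#' from the discrete hazard `q(d) = 1 - exp(-q0 * exp(g * d))` by inverting
#' the cumulative hazard; `scale` multiplies the sampled lifespan (a
#' treatment effect), and a fraction `censor_frac` of records is
#' right-censored at a uniform fraction of its lifespan.
#'
#' @param n Cohort size.
#' @param q0 Baseline hazard, per division (or day).
#' @param g Hazard growth rate (Gompertz slope), per division; `g = 0` gives
#'   a geometric lifespan with success probability `1 - exp(-q0)`.
#' @param scale Multiplier on sampled lifespans.
#' @param censor_frac Fraction of records right-censored, in `[0, 1)`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param group Group label carried in the output.
#' @return A tibble with columns `group`, `lifespan`, `event` (1 = death
#'   observed, 0 = censored).
#' @examples
#' sim_lifespan_cohort(50, seed = 1)
#' @export
sim_lifespan_cohort <- function(n = 100, q0 = 0.005, g = 0.15, scale = 1,
                                censor_frac = 0, seed = NULL,
                                group = "control") {
  check_positive(n, "n")
  check_positive(q0, "q0")
  check_nonneg(g, "g")
  check_positive(scale, "scale")
  check_fraction(censor_frac, "censor_frac", open_upper = TRUE)
  with_seed_if(seed, {
    e <- rexp(n)
    # smallest integer d with cumulative hazard q0*e^g*(e^{g d}-1)/(e^g-1) >= E
    d <- if (g > 0) {
      ceiling(log1p(e * (exp(g) - 1) / (q0 * exp(g))) / g)
    } else {
      ceiling(e / q0)
    }
    d <- pmax(d, 1)
    lifespan <- d * scale
    event <- rep(1L, n)
    n_cens <- round(censor_frac * n)
    if (n_cens > 0) {
      idx <- sample.int(n, n_cens)
      event[idx] <- 0L
      lifespan[idx] <- lifespan[idx] * runif(n_cens, min = .Machine$double.eps)
    }
    tibble(group = group, lifespan = lifespan, event = event)
  })
}

#' Simulate a genome-wide strain table with LL and NLL classes
#'
#' Emulates a deletion-mutant panel annotated with competitive fitness, mean
#' cell size, daughter birth size and G1 DNA-content fraction, split into
#' long-lived (LL) and not-long-lived (NLL) classes. LL rows have birth size
#' and fitness multiplied by `1 + shift`; mean size and G1 DNA fraction are
#' drawn from the same distribution in both classes unless shifted.
#'
#' @param n_ll,n_nll Class sizes (`n_ll + n_nll >= 4`).
#' @param birth_size_shift,fitness_shift,mean_size_shift Relative mean shifts
#'   applied to the LL class (e.g. `-0.05` = 5% smaller).
#' @param within_sd Relative within-class SD shared by all variables.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `strain_id`, `fitness`, `mean_size_fl`,
#'   `birth_size_fl`, `g1_dna_fraction`, `rls_class`.
#' @export
sim_strain_table <- function(n_ll = 137, n_nll = 3842,
                             birth_size_shift = -0.05,
                             fitness_shift = -0.02,
                             mean_size_shift = 0,
                             within_sd = 0.10, seed = NULL) {
  if (n_ll + n_nll < 4 || n_ll < 1 || n_nll < 1) {
    abort("`n_ll + n_nll` must be at least 4 with both classes present.",
          class = "g1span_invalid_parameter")
  }
  check_nonneg(within_sd, "within_sd")
  base <- c(fitness = 1, mean_size_fl = 60, birth_size_fl = 40,
            g1_dna_fraction = 0.35)
  with_seed_if(seed, {
    n <- n_ll + n_nll
    cls <- rep(c("LL", "NLL"), c(n_ll, n_nll))
    shift <- function(var, s) {
      mu <- base[[var]] * ifelse(cls == "LL", 1 + s, 1)
      mu * (1 + rnorm(n, 0, within_sd))
    }
    tibble(
      strain_id = sprintf("strain_%05d", seq_len(n)),
      fitness = shift("fitness", fitness_shift),
      mean_size_fl = shift("mean_size_fl", mean_size_shift),
      birth_size_fl = shift("birth_size_fl", birth_size_shift),
      g1_dna_fraction = pmin(pmax(shift("g1_dna_fraction", 0), 0), 1),
      rls_class = cls
    )
  })
}

#' Simulate paired tryptophan-uptake time courses
#'
#' Control retained counts follow a saturating first-order uptake curve
#' `U(t) = umax * (1 - exp(-rate * t))`; the treated culture retains a fixed
#' fraction `1 - inhibition_frac` of the control at every time.
#'
#' @param times Sampling times, minutes.
#' @param rate First-order uptake rate, per minute.
#' @param umax Plateau of retained counts.
#' @param inhibition_frac Fractional inhibition in the treated culture,
#'   in `[0, 1]`.
#' @param noise_cv Multiplicative noise CV on counts.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `condition` (`"control"`/`"treated"`),
#'   `time_min`, `counts`.
#' @export
sim_uptake <- function(times = seq(0, 20, by = 2), rate = 0.15, umax = 100,
                       inhibition_frac = 0.4, noise_cv = 0, seed = NULL) {
  check_positive(rate, "rate")
  check_positive(umax, "umax")
  check_fraction(inhibition_frac, "inhibition_frac")
  check_nonneg(noise_cv, "noise_cv")
  with_seed_if(seed, {
    u <- umax * (1 - exp(-rate * times))
    m <- length(times)
    tibble(
      condition = rep(c("control", "treated"), each = m),
      time_min = rep(as.numeric(times), 2),
      counts = pmax(c(u * (1 + rnorm(m, 0, noise_cv)),
                      u * (1 - inhibition_frac) * (1 + rnorm(m, 0, noise_cv))),
                    0)
    )
  })
}

#' Simulate a paired amino-acid level panel
#'
#' Per amino acid and replicate, the treated level is the control level
#' times `1 + delta` up to multiplicative noise, emulating paired
#' intracellular amino-acid measurements in treated and untreated cultures.
#'
#' @param deltas Named numeric vector of relative changes per amino acid
#'   (e.g. `c(Trp = -0.175)`).
#' @param reps Number of replicates (at least 2).
#' @param noise_cv Multiplicative noise CV.
#' @param base_nmol Baseline control level per amino acid (recycled).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `amino_acid`, `replicate`, `control_nmol`,
#'   `treated_nmol`.
#' @export
sim_amino_acid_panel <- function(deltas = c(Trp = -0.175, Leu = 0, His = 0),
                                 reps = 6, noise_cv = 0.02, base_nmol = 10,
                                 seed = NULL) {
  if (reps < 2) {
    abort("`reps` must be at least 2.", class = "g1span_invalid_parameter")
  }
  if (is.null(names(deltas)) || any(!nzchar(names(deltas)))) {
    abort("`deltas` must be a named vector.", class = "g1span_invalid_parameter")
  }
  check_nonneg(noise_cv, "noise_cv")
  check_positive(base_nmol, "base_nmol")
  with_seed_if(seed, {
    grid <- tidyr::expand_grid(amino_acid = names(deltas),
                               replicate = seq_len(reps))
    n <- nrow(grid)
    base <- rep_len(base_nmol, length(deltas))[match(grid$amino_acid,
                                                     names(deltas))]
    control <- base * (1 + rnorm(n, 0, noise_cv))
    treated <- control * (1 + deltas[grid$amino_acid]) *
      (1 + rnorm(n, 0, noise_cv))
    dplyr::mutate(grid, control_nmol = control,
                  treated_nmol = as.numeric(treated))
  })
}

#' Named generator presets
#'
#' Parameter sets for the conditions the pipeline is calibrated against:
#' `"daughter-sizer"` (size-control exponent -0.7, the wild-type daughter
#' value), `"timer"` (exponent 0, no size control), `"perfect-sizer"`
#' (exponent -1), `"decay-untreated"` (half-life 28 min) and
#' `"decay-ibuprofen"` (half-life 10 min).
#'
#' @param name Preset name.
#' @return A named list of generator arguments to splice into
#'   [sim_strain_panel()], [sim_daughter_cells()] or [sim_decay()].
#' @examples
#' do.call(sim_decay, c(g1span_preset("decay-untreated"), list(seed = 1)))
#' @export
g1span_preset <- function(name = c("daughter-sizer", "timer", "perfect-sizer",
                                   "decay-untreated", "decay-ibuprofen")) {
  name <- match.arg(name)
  switch(name,
    "daughter-sizer" = list(exponent = -0.7, intercept = log(1.6), vref = 40),
    "timer" = list(exponent = 0, intercept = log(1.6), vref = 40),
    "perfect-sizer" = list(exponent = -1, intercept = log(1.6), vref = 40),
    "decay-untreated" = list(t_half = 28),
    "decay-ibuprofen" = list(t_half = 10)
  )
}
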