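test_that("noiseless elutriation is an exact exponential with a logistic budding curve", {
  tc <- sim_elutriation(c(0, 1, 2), vb = 40, k = 0.35, vc = 60)
  expect_equal(tc$mean_volume_fl, 40 * exp(0.35 * c(0, 1, 2)))
  expect_equal(tc$mean_volume_fl[3], 80.5496, tolerance = 1e-4)
  # with a vanishing transition width the budded fraction steps at Vc
  steep <- sim_elutriation(seq(0, 4, 0.1), vb = 40, k = 0.35, vc = 60,
                           budding_width = 1e-9)
  expect_true(all(steep$budded_fraction[steep$mean_volume_fl < 60] < 0.5))
  expect_true(all(steep$budded_fraction[steep$mean_volume_fl > 60] > 0.5))
})

test_that("generators are bit-identical under a fixed seed and leave the caller's RNG alone", {
  gens <- list(
    function() sim_elutriation(0:3, meas_cv = 0.05, seed = 7),
    function() sim_size_histogram(vb = 35, n_cells = 2000, seed = 7),
    function() sim_strain_panel(n_strains = 3, times = seq(0, 3, 0.5),
                                hist_cells = 2000, seed = 7),
    function() sim_daughter_cells(50, seed = 7),
    function() sim_decay(noise_cv = 0.05, seed = 7),
    function() sim_lifespan_cohort(50, censor_frac = 0.1, seed = 7),
    function() sim_strain_table(n_ll = 10, n_nll = 30, seed = 7),
    function() sim_uptake(noise_cv = 0.05, seed = 7),
    function() sim_amino_acid_panel(seed = 7)
  )
  for (g in gens) expect_identical(g(), g())
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(sim_daughter_cells(10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("generated fractions, volumes and lifespans respect their ranges", {
  for (s in 1:5) {
    tc <- sim_elutriation(seq(0, 5, 0.5), meas_cv = 0.2, seed = s)
    expect_true(all(tc$budded_fraction >= 0 & tc$budded_fraction <= 1))
    ls <- sim_lifespan_cohort(200, censor_frac = 0.2, seed = s)
    expect_true(all(ls$lifespan > 0))
    expect_true(all(ls$event %in% 0:1))
    h <- sim_size_histogram(vb = 40, n_cells = 5000, seed = s)
    expect_true(all(h$count >= 0) && sum(h$count) == 5000)
  }
})

test_that("strain panels realize the programmed size-control law exactly when noiseless", {
  # timer: ln(Vc/Vb) identical across strains
  timer <- sim_strain_panel(n_strains = 5, exponent = 0, noise_sd = 0,
                            times = seq(0, 3, 0.5), hist_cells = 500, seed = 1)
  expect_equal(var(timer$strains$kt_g1_true), 0, tolerance = 1e-20)
  # perfect sizer: Vc identical across strains
  sizer <- sim_strain_panel(n_strains = 5, exponent = -1, noise_sd = 0,
                            times = seq(0, 3, 0.5), hist_cells = 500, seed = 1)
  expect_equal(diff(range(sizer$strains$vc_true_fl)), 0, tolerance = 1e-9)
  # partial sizer: closed-form OLS on the generated pairs returns the exponent
  part <- sim_strain_panel(n_strains = 5, exponent = -0.7, noise_sd = 0,
                           times = seq(0, 3, 0.5), hist_cells = 500, seed = 1)
  sl <- ols_slope(log(part$strains$vb_true_fl / 40), part$strains$kt_g1_true)
  expect_equal(sl, -0.7, tolerance = 1e-9)
})

test_that("single-cell daughters obey the sizer law and its limits", {
  # timer: kT_G1 independent of birth size
  tim <- sim_daughter_cells(500, exponent = 0, noise_sd = 0, seed = 2)
  expect_equal(var(tim$kt_g1), 0, tolerance = 1e-20)
  # perfect sizer: Vb * exp(kT_G1) constant
  per <- sim_daughter_cells(500, exponent = -1, noise_sd = 0, seed = 2)
  expect_equal(diff(range(per$birth_size_fl * exp(per$kt_g1))), 0,
               tolerance = 1e-9)
  # noisy partial sizer: OLS recovers the exponent within sampling error
  d <- sim_daughter_cells(1000, exponent = -0.7, noise_sd = 0.1, seed = 2)
  expect_equal(ols_slope(log(d$birth_size_fl / 40), d$kt_g1), -0.7,
               tolerance = 0.05)
  expect_true(all(d$t_g1_h >= 0))
})

test_that("decay series halve on schedule", {
  d <- sim_decay(t_half = 10, times = c(0, 10, 20, 30))
  expect_equal(d$target_density, c(1, 0.5, 0.25, 0.125))
  expect_equal(sim_decay(t_half = 28, times = 28)$target_density, 0.5)
  expect_error(sim_decay(t_half = -1), class = "g1span_invalid_parameter")
})

test_that("lifespan generator matches its analytic geometric special case and scales linearly", {
  # g = 0: lifespans are geometric with p = 1 - exp(-q0)
  q0 <- 0.2
  d <- sim_lifespan_cohort(1e5, q0 = q0, g = 0, seed = 4)
  expect_equal(mean(d$lifespan), 1 / (1 - exp(-q0)), tolerance = 0.02)
  expect_true(all(d$event == 1))
  # a survival-time scale of 1.2 scales the mean by 1.2
  s1 <- sim_lifespan_cohort(1e5, scale = 1, seed = 5)
  s2 <- sim_lifespan_cohort(1e5, scale = 1.2, seed = 5)
  expect_equal(mean(s2$lifespan) / mean(s1$lifespan), 1.2, tolerance = 1e-9)
  cens <- sim_lifespan_cohort(1000, censor_frac = 0.25, seed = 6)
  expect_equal(sum(cens$event == 0), 250)
})

test_that("strain tables realize the programmed class shifts", {
  null_tab <- sim_strain_table(n_ll = 2000, n_nll = 2000, birth_size_shift = 0,
                               fitness_shift = 0, within_sd = 0.05, seed = 8)
  m <- tapply(null_tab$birth_size_fl, null_tab$rls_class, mean)
  expect_equal(unname(m["LL"] / m["NLL"]), 1, tolerance = 0.01)
  shifted <- sim_strain_table(n_ll = 5000, n_nll = 5000,
                              birth_size_shift = -0.05, fitness_shift = 0,
                              within_sd = 0.01, seed = 8)
  m2 <- tapply(shifted$birth_size_fl, shifted$rls_class, mean)
  expect_equal(unname(m2["LL"] / m2["NLL"]), 0.95, tolerance = 0.002)
})

test_that("uptake and amino-acid generators reproduce their stated identities", {
  u <- sim_uptake(times = c(0, 5, 10, 1000), inhibition_frac = 0.4)
  wide <- tidyr::pivot_wider(u, names_from = condition, values_from = counts)
  expect_equal(wide$treated, 0.6 * wide$control)
  expect_equal(wide$control[4], 100, tolerance = 1e-9)
  blocked <- sim_uptake(inhibition_frac = 1)
  expect_true(all(blocked$counts[blocked$condition == "treated"] == 0))
  aa <- sim_amino_acid_panel(deltas = c(Trp = -0.2), reps = 4, noise_cv = 0)
  expect_equal(aa$treated_nmol, 0.8 * aa$control_nmol)
})

test_that("invalid generator parameters are rejected", {
  expect_error(sim_elutriation(c(0, 1), vb = 40), class = "g1span_invalid_parameter")
  expect_error(sim_elutriation(0:3, vb = -1), class = "g1span_invalid_parameter")
  expect_error(sim_lifespan_cohort(10, q0 = 0), class = "g1span_invalid_parameter")
  expect_error(sim_lifespan_cohort(10, censor_frac = 1), class = "g1span_invalid_parameter")
  expect_error(sim_strain_table(n_ll = 1, n_nll = 1), class = "g1span_invalid_parameter")
  expect_error(sim_uptake(inhibition_frac = 1.2), class = "g1span_invalid_parameter")
  expect_error(sim_amino_acid_panel(reps = 1), class = "g1span_invalid_parameter")
})
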