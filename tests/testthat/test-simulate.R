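# Synthetic-data generators: determinism, conservation, and forward-model
# bookkeeping.

test_that("diffusion movie has the acquisition geometry of the experiment", {
  # 300 um needle channel -> r = 150 um; frames every 2 s for 5 min
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$vessel_radius, 150)
  s <- simulate_vessel_diffusion(cfg)
  expect_equal(nrow(s), 151L)
  expect_equal(diff(s$time_s)[1], 2)
  expect_true(all(s$I_ECM >= 0) && all(s$I_vessel >= 0))
})

test_that("zero permeability leaves the matrix at background forever", {
  s <- simulate_vessel_diffusion(sim_config(true_permeability = 0))
  expect_true(all(s$I_ECM == 0))
  expect_true(all(diff(s$I_vessel) == 0))
})

test_that("total tracer is conserved with reflecting boundaries", {
  for (P in c(0.5, 5)) {
    s <- simulate_vessel_diffusion(sim_config(true_permeability = P))
    tot <- attr(s, "total_tracer")
    expect_lt((max(tot) - min(tot)) / tot[1], 1e-3)
  }
})

test_that("early-time matrix mass gain per wall area equals P * c_vessel", {
  cfg <- sim_config(true_permeability = 1, frame_interval = 0.1, duration = 1)
  s <- simulate_vessel_diffusion(cfg, intensity_scale = 1)
  R <- 150
  m <- s$I_ECM * pi * R^2                     # tracer amount per unit length
  J0 <- (m[2] - m[1]) / 0.1 / (2 * pi * R)    # flux per unit wall area
  expect_lt(abs(J0 - 1 * 1) / 1, 0.02)        # P = 1, c_vessel(0) = 1
})

test_that("halving the radial grid changes I_ECM by less than 1%", {
  cfg <- sim_config(true_permeability = 1)
  a <- simulate_vessel_diffusion(cfg, nr = 160)
  b <- simulate_vessel_diffusion(cfg, nr = 80)
  rel <- abs(b$I_ECM[-1] - a$I_ECM[-1]) / pmax(a$I_ECM[-1], 1e-9)
  expect_lt(max(rel), 0.01)
})

test_that("invalid physical parameters are rejected", {
  expect_error(sim_config(vessel_radius = -1), "positive")
  expect_error(sim_config(true_permeability = -1), ">= 0")
  expect_error(sim_config(flim_params = c(a1 = 1.5, tau1 = 1, tau2 = 2)),
               "a1")
  expect_error(sim_config(flim_params = c(a1 = 0.5, tau1 = 3, tau2 = 2)),
               "tau")
})

test_that("generators are bit-reproducible for a fixed config", {
  cfg <- sim_config(seed = 42, noise_levels = list(diffusion = 0.05,
                                                   metabolite = 0.02))
  expect_identical(simulate_vessel_diffusion(cfg),
                   simulate_vessel_diffusion(cfg))
  f1 <- simulate_invasion_field(cfg, n_cells = 30)
  f2 <- simulate_invasion_field(cfg, n_cells = 30)
  expect_identical(f1$mask, f2$mask)
  expect_identical(simulate_flim_decays(cfg, n_pixels = 3),
                   simulate_flim_decays(cfg, n_pixels = 3))
  expect_identical(simulate_metabolite_timecourse(cfg),
                   simulate_metabolite_timecourse(cfg))
})

test_that("unbiased invasion fields have zero mean displacement", {
  f <- simulate_invasion_field(sim_config(seed = 11), n_cells = 100,
                               bias = 0)
  d <- f$cells$x_um - f$edge_x
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("impossible cell densities raise a generation error", {
  expect_error(
    simulate_invasion_field(sim_config(seed = 1), n_cells = 500,
                            field_width = 200, field_height = 150),
    "non-overlapping")
})

test_that("mono-exponential decays are log-linear with slope -1/tau", {
  cfg <- sim_config(seed = 3, photon_budget = 1e5,
                    flim_params = c(a1 = 1, tau1 = 1.0, tau2 = 2.5))
  d <- simulate_flim_decays(cfg, n_pixels = 1)[[1]]
  mids <- (d$bin_edges[-1] + d$bin_edges[-length(d$bin_edges)]) / 2
  keep <- d$counts > 20                        # avoid log of tiny counts
  fit <- lm(log(d$counts[keep]) ~ mids[keep])
  expect_equal(unname(coef(fit)[2]), -1 / 1.0, tolerance = 0.03)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("total photon count matches the budget within Poisson error", {
  cfg <- sim_config(seed = 4, photon_budget = 1e5)
  d <- simulate_flim_decays(cfg, n_pixels = 5)
  for (h in d)
    expect_lt(abs(sum(h$counts) - 1e5), 3 * sqrt(1e5))
})

test_that("tiny photon budgets warn about unstable fits", {
  expect_warning(simulate_flim_decays(sim_config(photon_budget = 50)),
                 "unstable")
})

test_that("metabolite timepoints default to the 0/24/48 h collection", {
  ts <- simulate_metabolite_timecourse(sim_config(seed = 5))
  expect_equal(sort(unique(ts$time_h)), c(0, 24, 48))
  expect_true(all(c("conc_mM", "cell_count", "volume_mL", "is_blank")
                  %in% names(ts)))
})

test_that("null exchange rates give flat series up to noise", {
  cfg <- sim_config(seed = 6,
                    true_exchange_rates = default_exchange_rates("null"),
                    growth_rate = 0,
                    noise_levels = list(metabolite = 0.02))
  ts <- simulate_metabolite_timecourse(cfg)
  l2 <- log2_fold_change(blank_correct(ts))
  expect_true(all(abs(l2$log2fc) < 0.15))
})

test_that("consumption cannot drive concentrations negative", {
  rates <- default_exchange_rates("null")
  rates[["glucose"]] <- -1e5                  # absurd consumption
  cfg <- sim_config(seed = 7, true_exchange_rates = rates,
                    noise_levels = list(metabolite = 0))
  ts <- simulate_metabolite_timecourse(cfg)
  expect_true(all(ts$conc_mM >= 0))
  expect_true(any(ts$clipped[ts$metabolite == "glucose"]))
})
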