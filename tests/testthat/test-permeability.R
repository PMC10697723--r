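# Permeability estimation from intensity traces.

flat_series <- function() {
  intensity_series(seq(0, 20, 2), rep(100, 11), rep(3, 11), r_vessel = 150)
}

test_that("flat matrix trace gives slope 0 with r-squared reported as 0", {
  fit <- fit_ecm_slope(flat_series())
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  p <- diffusive_permeability(flat_series(), fit)
  expect_equal(p$P_D, 0)
})

test_that("an exact line is recovered with zero standard error", {
  t <- 0:10
  s <- intensity_series(t, rep(50, 11), 5 + 2 * t, r_vessel = 100)
  fit <- fit_ecm_slope(s, window = c(0, 10))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("OLS slope on the auto window matches a two-point finite
           difference within its uncertainty", {
  s <- simulate_vessel_diffusion(sim_config(seed = 2, true_permeability = 1))
  fit <- fit_ecm_slope(s)
  i0 <- which(s$time_s == fit$window[1]); i1 <- which(s$time_s == fit$window[2])
  fd <- (s$I_ECM[i1] - s$I_ECM[i0]) / (s$time_s[i1] - s$time_s[i0])
  # noiseless but curved: OLS and secant agree to within a few percent
  expect_lt(abs(fit$slope - fd) / fd, 0.05)
})

test_that("window and degenerate-input errors are raised", {
  s <- flat_series()
  expect_error(fit_ecm_slope(s, window = c(0, 2)), "fewer than 3")
  expect_error(intensity_series(c(0, 1), c(1, 1), c(0, 0), 150), "3 frames")
  expect_error(intensity_series(c(0, 1, 1), rep(1, 3), rep(0, 3), 150),
               "increasing")
  expect_error(intensity_series(0:2, rep(1, 3), rep(0, 3), -5), "r_vessel")
  bad <- intensity_series(0:4, rep(0, 5), 1:5, r_vessel = 150)
  expect_error(diffusive_permeability(bad), "baseline")
})

test_that("P_D is invariant to intensity units and linear in radius", {
  s <- simulate_vessel_diffusion(sim_config(seed = 3, true_permeability = 1))
  p1 <- diffusive_permeability(s)
  s2 <- intensity_series(s$time_s, 2 * s$I_vessel, 2 * s$I_ECM,
                         r_vessel = attr(s, "r_vessel"))
  p2 <- diffusive_permeability(s2)
  expect_equal(p1$P_D, p2$P_D, tolerance = 1e-12)
  s3 <- intensity_series(s$time_s, s$I_vessel, s$I_ECM,
                         r_vessel = 2 * attr(s, "r_vessel"))
  p3 <- diffusive_permeability(s3)
  expect_equal(p3$P_D, 2 * p1$P_D, tolerance = 1e-12)
})

test_that("noiseless generator truth is recovered across three decades", {
  for (P in c(0.1, 1, 10)) {
    s <- simulate_vessel_diffusion(sim_config(seed = 4, true_permeability = P))
    est <- estimate_permeability(s)
    expect_lt(abs(est$P_D - P) / P, 0.15)
  }
})

test_that("P = 1 um/s noiseless recovery lands in [0.85, 1.15]", {
  s <- simulate_vessel_diffusion(sim_config(seed = 5, true_permeability = 1))
  est <- estimate_permeability(s)
  expect_gt(est$P_D, 0.85)
  expect_lt(est$P_D, 1.15)
})

test_that("group comparison recovers the true permeability ordering", {
  truth <- c(0.2, 0.6, 2.0)
  res <- list(); grp <- character()
  for (i in seq_along(truth)) for (r in 1:3) {
    s <- simulate_vessel_diffusion(
      sim_config(seed = 10 * i + r, true_permeability = truth[i],
                 noise_levels = list(diffusion = 0.03)))
    res <- c(res, list(estimate_permeability(s)))
    grp <- c(grp, paste0("P", truth[i]))
  }
  cmp <- compare_permeability(res, grp)
  expect_equal(cmp$ordering, c("P0.2", "P0.6", "P2"))
})

test_that("identical replicates give SD 0; singletons are flagged", {
  cmp <- compare_permeability(list(1.5, 1.5, 2.0), c("a", "a", "b"))
  expect_equal(cmp$table$sd[cmp$table$group == "a"], 0)
  expect_true(cmp$table$single_replicate[cmp$table$group == "b"])
  expect_equal(cmp$table$mean[cmp$table$group == "b"], 2.0)
})

test_that("trace CSV round trip preserves the series", {
  s <- simulate_vessel_diffusion(sim_config(seed = 6))
  tf <- tempfile(fileext = ".csv")
  write_traces(s, tf)
  s2 <- read_traces(tf)
  expect_equal(s$I_ECM, s2$I_ECM)
  expect_equal(attr(s, "r_vessel"), attr(s2, "r_vessel"))
})
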