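# Constraint construction, FBA solving, and the uncertainty ensemble.

test_that("the default omit list is the eight amino acids, leaving 12
           constrained", {
  expect_setequal(omitted_amino_acids(),
                  c("glycine", "leucine", "lysine", "phenylalanine",
                    "threonine", "tryptophan", "tyrosine", "valine"))
  net <- toy_core_network()
  cs <- build_constraints(condition_rate_table("control"), net)
  aa <- cs$exchanges[cs$exchanges$metabolite %in% amino_acid_names(), ]
  expect_equal(sum(!aa$omitted), 12L)
  expect_equal(sum(aa$omitted), 8L)
  expect_setequal(aa$metabolite[aa$omitted], omitted_amino_acids())
  # omitted metabolites keep the default network bounds
  net2 <- vesselflux:::apply_constraints(net, cs)
  for (m in omitted_amino_acids()) {
    ex <- net$exchange_map[[m]]
    expect_equal(net2$lb[[ex]], net$lb[[ex]])
    expect_equal(net2$ub[[ex]], net$ub[[ex]])
  }
})

test_that("a zero rate with zero SD pins the exchange to [0, 0]", {
  net <- toy_core_network()
  rates <- data.frame(metabolite = "alanine", rate = 0, sd = 0)
  cs <- build_constraints(rates, net)
  expect_equal(cs$exchanges$lb, 0)
  expect_equal(cs$exchanges$ub, 0)
})

test_that("measured metabolites without an exchange reaction are named", {
  net <- toy_core_network()
  rates <- data.frame(metabolite = c("glucose", "unobtainium"),
                      rate = c(-1, 1), sd = 0)
  expect_error(build_constraints(rates, net), "unobtainium")
})

test_that("optimal solutions satisfy mass balance and bounds", {
  net <- toy_core_network()
  for (cond in c("control", "huvec_cm")) {
    cs <- condition_constraints(cond, net)
    sol <- solve_fba(net, cs)
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(net$S %*% sol$fluxes)), 1e-8)
    net2 <- vesselflux:::apply_constraints(net, cs)
    expect_true(all(sol$fluxes >= net2$lb - 1e-9))
    expect_true(all(sol$fluxes <= net2$ub + 1e-9))
  }
})

test_that("the parsimonious stage preserves the optimal objective", {
  net <- toy_core_network()
  cs <- condition_constraints("control", net)
  s1 <- solve_fba(net, cs, parsimonious = FALSE)
  s2 <- solve_fba(net, cs, parsimonious = TRUE)
  expect_equal(s2$objective_value, s1$objective_value, tolerance = 1e-9)
  expect_lte(sum(abs(s2$fluxes)), sum(abs(s1$fluxes)) + 1e-6)
})

test_that("without glucose (and with other carbon sources shut), HA
           production is impossible", {
  net <- toy_core_network()
  # carbon only through glucose: close all other exchanges to secretion,
  # keeping the carbon-free inputs (O2, ammonium) open
  for (ex in net$exchange_map) net$lb[[ex]] <- 0
  o2 <- tagged_reaction(net, "o2_exchange")
  net$lb[[o2]] <- -1000; net$ub[[o2]] <- 0
  net$lb[[net$exchange_map[["ammonium"]]]] <- -1000
  net$lb[["ATPM"]] <- 0
  glc <- net$exchange_map[["glucose"]]
  with_glc <- net; with_glc$lb[[glc]] <- -10
  expect_gt(solve_fba(with_glc)$objective_value, 0)
  no_glc <- net; no_glc$lb[[glc]] <- 0
  sol <- solve_fba(no_glc)
  expect_lt(abs(sol$objective_value), 1e-9)
})

test_that("relaxing an upper bound never decreases the optimum", {
  net <- toy_core_network()
  cs <- condition_constraints("control", net)
  base <- solve_fba(net, cs, parsimonious = FALSE)$objective_value
  for (m in c("glucose", "glutamine", "serine", "isoleucine")) {
    cs2 <- cs
    i <- which(cs2$exchanges$metabolite == m)
    cs2$exchanges$ub[i] <- cs2$exchanges$ub[i] + 5
    relaxed <- solve_fba(net, cs2, parsimonious = FALSE)$objective_value
    expect_gte(relaxed, base - 1e-9)
  }
})

test_that("a zero-SD ensemble degenerates to the point solve", {
  net <- toy_core_network()
  rates <- condition_rate_table("control")
  rates$sd <- 0
  cs <- build_constraints(rates, net, growth_rate = 0.025, growth_sd = 0,
                          ocr = 220, ocr_sd = 0)
  sol <- solve_fba(net, cs)
  ens <- ensemble_fba(net, cs, n = 5, seed = 7)
  expect_equal(nrow(ens$fluxes), 5L)
  for (i in 1:5)
    expect_equal(unname(ens$fluxes[i, ]), unname(sol$fluxes),
                 tolerance = 1e-9)
})

test_that("ensembles are bit-reproducible under a fixed seed", {
  net <- toy_core_network()
  cs <- condition_constraints("control", net)
  e1 <- ensemble_fba(net, cs, n = 8, seed = 11)
  e2 <- ensemble_fba(net, cs, n = 8, seed = 11)
  expect_identical(e1$fluxes, e2$fluxes)
  e3 <- ensemble_fba(net, cs, n = 8, seed = 12)
  expect_false(identical(e1$fluxes, e3$fluxes))
})

test_that("the ensemble mean objective is consistent with the solve at the
           mean constraints", {
  net <- toy_core_network()
  rates <- condition_rate_table("control")
  rates$sd <- abs(rates$rate) * 0.05 + 0.1
  cs <- build_constraints(rates, net, growth_rate = 0.025,
                          growth_sd = 0.00125, ocr = 220, ocr_sd = 11)
  point <- solve_fba(net, cs)$objective_value
  ens <- ensemble_fba(net, cs, n = 60, seed = 21)
  sem <- sd(ens$objective_values) / sqrt(length(ens$objective_values))
  expect_lt(abs(mean(ens$objective_values) - point), max(2 * sem, 0.02 * point))
})

test_that("identical ensembles compare as all-zero differences", {
  net <- toy_core_network()
  cs <- condition_constraints("control", net)
  e <- ensemble_fba(net, cs, n = 6, seed = 3)
  cmp <- compare_flux_conditions(e, e)
  expect_true(all(cmp$difference == 0))
  expect_true(all(cmp$direction == "equal"))
  one <- compare_flux_conditions(e, e, reactions = "HAS")
  expect_equal(nrow(one), 1L)
  expect_error(compare_flux_conditions(e, e, reactions = "NOPE"), "unknown")
})

test_that("conditioned-media constraints raise HA and ATP-demand fluxes", {
  net <- toy_core_network()
  ea <- ensemble_fba(net, condition_constraints("huvec_cm", net),
                     n = 30, seed = 5, condition = "huvec_cm")
  eb <- ensemble_fba(net, condition_constraints("control", net),
                     n = 30, seed = 6, condition = "control")
  cmp <- compare_flux_conditions(ea, eb)
  ha <- cmp[cmp$reaction == tagged_reaction(net, "ha_synthesis"), ]
  atp <- cmp[cmp$reaction == tagged_reaction(net, "atp_demand"), ]
  expect_equal(ha$direction, "higher_in_a")
  expect_equal(atp$direction, "higher_in_a")
})
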