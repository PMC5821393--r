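test_that("effective adherence combines trial adherence and dropout", {
  # SSRI and TCA effective adherence, printed rounded as 57% / 49%
  expect_equal(effective_adherence(0.70, 0.18), 0.574)
  expect_equal(effective_adherence(0.70, 0.30), 0.49)
  expect_equal(effective_adherence(0.70, 0), 0.70)
  expect_equal(round(100 * effective_adherence(0.70, 0.18)), 57)
  expect_equal(round(100 * effective_adherence(0.70, 0.30)), 49)

  expect_error(effective_adherence(1.2, 0.1), "base_adherence")
  expect_error(effective_adherence(0.5, -0.1), "dropout")

  # monotone decreasing in dropout; agrees with direct multiplication
  # over an exhaustive grid
  grid <- expand.grid(base = seq(0, 1, by = 0.1),
                      dropout = seq(0, 1, by = 0.1))
  got <- effective_adherence(grid$base, grid$dropout)
  expect_equal(got, grid$base * (1 - grid$dropout))
  for (b in unique(grid$base)) {
    e <- got[grid$base == b]
    expect_true(all(diff(e) <= 0))
  }
})

test_that("societal state costs sum the three cost categories", {
  econ <- default_parameters()$state_econ
  cost <- aggregate_state_cost(econ)
  expect_equal(unname(cost["PD"]), 666 + 858 + 16771)      # 18295
  expect_equal(unname(cost["STHPD"]), 1503 + 494 + 9741)   # 11738
  expect_equal(unname(cost["PF"]), 340 + 99 + 6643)
  expect_equal(unname(cost["DEAD"]), 0)

  econ0 <- econ
  econ0[, c("cost_direct_medical", "cost_direct_nonmedical",
            "cost_indirect_nonmedical")] <- 0
  expect_equal(unname(aggregate_state_cost(econ0)), rep(0, 4))
  econ$cost_direct_medical[1] <- -1
  expect_error(aggregate_state_cost(econ), "negative")
})

test_that("utility uncorrection divides disease states by the PF utility", {
  p <- uncorrect_utilities(default_parameters())
  u <- setNames(p$state_econ$utility, p$state_econ$state)
  expect_equal(unname(u["STHPD"]), 0.730 / 0.869, tolerance = 1e-12)
  expect_equal(unname(u["STHPD"]), 0.84005, tolerance = 1e-4)
  expect_equal(unname(u["PD"]), 0.660 / 0.869, tolerance = 1e-12)
  expect_equal(unname(u["PD"]), 0.75949, tolerance = 1e-4)
  expect_equal(unname(u["PF"]), 0.869)
  expect_false(p$settings$utilities_corrected)

  # double-uncorrection and degenerate PF utility are rejected
  expect_error(uncorrect_utilities(p), "already")
  bad <- default_parameters()
  bad$state_econ$utility[1] <- 0
  expect_error(uncorrect_utilities(bad), "PF utility")
})

test_that("initial occupancy follows the prevalence mix and sums to one", {
  p <- default_parameters()
  occ <- initial_occupancy(p, "mixed")
  expect_equal(unname(occ["STHPD"]), 0.019 / 0.041, tolerance = 1e-12)
  expect_equal(unname(occ["STHPD"]), 0.46341, tolerance = 1e-4)
  expect_equal(unname(occ["PD"]), 0.53659, tolerance = 1e-4)
  expect_equal(unname(occ[c("PF", "DEAD")]), c(0, 0))
  expect_equal(sum(occ), 1)

  expect_equal(unname(initial_occupancy(p, "sthpd_only")),
               c(0, 1, 0, 0))

  p$settings$prevalence_sthpd <- 0.02
  p$settings$prevalence_pd <- 0.02
  expect_equal(unname(initial_occupancy(p, "mixed")), c(0, 0.5, 0.5, 0))

  # property: sums to exactly 1 for arbitrary positive prevalences
  set.seed(42)
  for (i in 1:25) {
    p$settings$prevalence_sthpd <- runif(1, 0.001, 0.2)
    p$settings$prevalence_pd <- runif(1, 0.001, 0.2)
    expect_equal(sum(initial_occupancy(p, "mixed")), 1)
  }
})

test_that("default parameters reproduce the published inputs", {
  p <- default_parameters()
  iv <- p$interventions
  expect_equal(iv$uptake_usual, c(0.088, 0.092, 0.024, 0.090, 0))
  expect_equal(iv$uptake_alt, c(0.088, 0.092, 0.024, 0.090, 0.10))
  expect_equal(iv$annual_cost, c(1176, 1128, 1200, 2315, 905))
  expect_equal(iv$utility_gain, c(0.0327, 0.0450, 0.0445, 0.0568, 0.0655))
  expect_equal(iv$transition_rr[iv$name == "early_intervention"], 0.538)
  expect_equal(p$state_econ$utility, c(0.869, 0.730, 0.660, 0))
  expect_equal(p$state_econ$utility_se, c(0.0054, 0.037, 0.030, 0))
  expect_equal(unlist(p$transitions, use.names = FALSE),
               c(0.0016, 0.0815, 0.6037, 0.5214, 0.0028))
  expect_equal(p$settings$horizon, 5L)
  expect_equal(p$settings$discount_rate_costs, 0.04)
  expect_equal(p$settings$discount_rate_effects, 0.015)
  expect_equal(p$settings$wtp_threshold, 20000)
})

test_that("parameter validation rejects out-of-range inputs", {
  p <- default_parameters()
  p$interventions$uptake_alt[1] <- 1.3
  expect_error(validate_parameters(p), "uptake_alt")

  p <- default_parameters()
  p$transitions$p_sthpd_pd <- 0.95  # exits would exceed 1
  expect_error(validate_parameters(p), "STHPD exit")

  p <- default_parameters()
  p$state_econ$utility[4] <- 0.1    # death must stay at zero
  expect_error(validate_parameters(p), "DEAD")

  p <- default_parameters()
  p$settings$discount_rate_costs <- -0.01
  expect_error(validate_parameters(p), "discount_rate_costs")
})

test_that("scenario specifications resolve uptakes per arm", {
  p <- default_parameters()
  uc <- scenario_spec(p, "usual_care")
  ei <- scenario_spec(p, "early_intervention")
  early <- function(s) s$interventions$uptake[
    s$interventions$name == "early_intervention"]
  expect_equal(early(uc), 0)
  expect_equal(early(ei), 0.10)
  # the four PD interventions are identical between arms
  pd <- uc$interventions$target == "PD"
  expect_equal(uc$interventions$uptake[pd], ei$interventions$uptake[pd])
  expect_equal(early(scenario_spec(p, "early_intervention",
                                   early_uptake = 0.05)), 0.05)
  # scaling PD uptakes to 100% keeps them within bounds
  s100 <- scenario_spec(p, "early_intervention",
                        pd_uptake_scale = 1 / 0.294)
  expect_equal(sum(s100$interventions$uptake[pd]), 1, tolerance = 1e-12)
  expect_error(scenario_spec(p, "usual_care", pd_uptake_scale = 12),
               "uptake")
})

test_that("configuration files round-trip every default value unchanged", {
  p <- default_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_config(p, path)
  p2 <- read_config(path)
  expect_equal(p2$interventions, p$interventions)
  expect_equal(p2$state_econ, p$state_econ)
  expect_equal(p2$transitions, p$transitions)
  expect_equal(p2$settings, p$settings)

  # the packaged default config equals the in-code defaults
  expect_equal(read_config(default_config_path())$state_econ, p$state_econ)

  expect_error(read_config(file.path(tempdir(), "nope.json")),
               "not found")
  writeLines('{"interventions": []}', path)
  expect_error(read_config(path), "missing top-level block")
})
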