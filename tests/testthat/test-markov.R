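test_that("transition matrix reproduces the published structure", {
  p <- default_parameters()
  P <- build_transition_matrix(p, scenario_spec(p, "usual_care"))

  expect_equal(unname(P["STHPD", ]), c(0.0815, 0.3120, 0.6037, 0.0028))
  expect_equal(unname(P["PF", ]), c(1 - 0.0016 - 0.0028, 0.0016, 0, 0.0028))
  expect_equal(unname(P["PD", ]), c(0, 0.5214, 1 - 0.5214 - 0.0028, 0.0028))
  expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 1))
  # structurally forbidden jumps are exactly zero
  expect_identical(P["PF", "PD"], 0)
  expect_identical(P["PD", "PF"], 0)
  expect_equal(rowSums(P), setNames(rep(1, 4), health_states()))
})

test_that("the early intervention lowers STHPD-to-PD by the blended RR", {
  p <- default_parameters()
  P <- build_transition_matrix(p, scenario_spec(p, "early_intervention"))
  # p * (1 - u a (1 - RR)) with u = 0.10, a = 0.70, RR = 0.538
  expect_equal(P["STHPD", "PD"], 0.6037 * (1 - 0.10 * 0.70 * (1 - 0.538)))
  expect_equal(P["STHPD", "PD"], 0.58418, tolerance = 1e-5)
  # removed mass flows to the stay probability
  expect_equal(P["STHPD", "STHPD"], 0.33152, tolerance = 1e-4)
  expect_equal(P["STHPD", "PF"], 0.0815)
  expect_equal(sum(P["STHPD", ]), 1)

  # no-effect reductions leave the matrix identical to usual care
  P0 <- build_transition_matrix(p, scenario_spec(p, "usual_care"))
  expect_identical(
    build_transition_matrix(
      p, scenario_spec(p, "early_intervention", early_uptake = 0)), P0)
  p_rr1 <- p
  p_rr1$interventions$transition_rr[5] <- 1
  expect_identical(
    build_transition_matrix(p_rr1,
                            scenario_spec(p_rr1, "early_intervention")), P0)
})

test_that("cohort projection matches a step-by-step oracle", {
  p <- default_parameters()
  P <- build_transition_matrix(p, scenario_spec(p, "usual_care"))
  init <- initial_occupancy(p, "mixed")
  traj <- project_cohort(init, P, 1)
  # STHPD occupancy after one cycle: 0.46341 x 0.3120 + 0.53659 x 0.5214
  expect_equal(unname(traj["1", "STHPD"]), 0.42436, tolerance = 1e-4)

  I4 <- diag(4)
  dimnames(I4) <- list(health_states(), health_states())
  expect_equal(project_cohort(init, I4, 5),
               matrix(init, 6, 4, byrow = TRUE,
                      dimnames = list(0:5, health_states())))
  dead <- c(0, 0, 0, 1)
  expect_true(all(project_cohort(dead, P, 10)[, "DEAD"] == 1))

  # random small matrices against the explicit-loop oracle
  set.seed(11)
  for (i in 1:20) {
    Q <- random_stochastic_matrix(4)
    dimnames(Q) <- list(health_states(), health_states())
    v <- stats::rexp(4); v <- v / sum(v)
    expect_equal(unname(project_cohort(v, Q, 7)),
                 project_oracle(v, Q, 7), tolerance = 1e-12)
  }
  expect_error(project_cohort(c(0.5, 0.5), P, 5), "dimension")
  expect_error(project_cohort(c(0.6, 0.6, 0, 0) , diag(4), 2), "sum to 1")
})

test_that("occupancy is conserved and death mass non-decreasing everywhere", {
  p <- default_parameters()
  variants <- list(
    scenario_spec(p, "usual_care"),
    scenario_spec(p, "early_intervention"),
    scenario_spec(p, "early_intervention", early_uptake = 0.15),
    scenario_spec(p, "early_intervention", rr_multiplier = 0.9),
    scenario_spec(p, "early_intervention", rr_multiplier = 1.1),
    scenario_spec(p, "usual_care", pd_uptake_scale = 1 / 0.294)
  )
  for (scen in variants) {
    P <- build_transition_matrix(p, scen)
    for (cohort in c("mixed", "sthpd_only")) {
      traj <- project_cohort(initial_occupancy(p, cohort), P, 10)
      expect_equal(rowSums(traj), setNames(rep(1, 11), 0:10),
                   tolerance = 1e-12)
      expect_true(all(diff(traj[, "DEAD"]) >= 0))
      expect_true(all(traj >= 0))
    }
  }
})

test_that("cycle rewards blend state values with intervention terms", {
  p <- default_parameters()
  uc <- scenario_spec(p, "usual_care")
  ei <- scenario_spec(p, "early_intervention")

  v_uc <- state_values(p, uc)
  # PD occupants under usual care: state utility plus the four
  # uptake x adherence x gain terms
  expect_equal(unname(v_uc$utility["PD"]),
               0.660 + 0.088 * 0.70 * 0.0327 + 0.092 * 0.574 * 0.0450 +
                 0.024 * 0.49 * 0.0445 + 0.090 * 0.70 * 0.0568)
  expect_equal(unname(v_uc$utility["PD"]), 0.66849, tolerance = 1e-5)
  # PD costs: societal cost plus uptake-weighted intervention costs,
  # independent of adherence
  expect_equal(unname(v_uc$cost["PD"]),
               18295 + 0.088 * 1176 + 0.092 * 1128 + 0.024 * 1200 +
                 0.090 * 2315)
  expect_equal(unname(v_uc$cost["PD"]), 18739.41, tolerance = 1e-2)

  v_ei <- state_values(p, ei)
  expect_equal(unname(v_ei$utility["STHPD"]), 0.730 + 0.10 * 0.70 * 0.0655)
  expect_equal(unname(v_ei$utility["STHPD"]), 0.73459, tolerance = 1e-5)
  # the one-off course cost is kept separate from recurring state costs
  expect_equal(unname(v_ei$cost["STHPD"]), 11738)
  expect_equal(unname(v_ei$cost_once["STHPD"]), 0.10 * 905)
  # death contributes nothing
  expect_equal(unname(v_uc$utility["DEAD"]), 0)
  expect_equal(unname(v_uc$cost["DEAD"]), 0)

  # zero uptake everywhere leaves the bare state values
  p0 <- p
  p0$interventions$uptake_usual <- rep(0, 5)
  v0 <- state_values(p0, scenario_spec(p0, "usual_care"))
  expect_equal(unname(v0$utility["STHPD"]), 0.730)
  expect_equal(unname(v0$cost["STHPD"]), 11738)

  # reward stream shape and one-off charge in the first cycle only
  traj <- project_cohort(initial_occupancy(p, "mixed"),
                         build_transition_matrix(p, ei), 5)
  rw <- cycle_rewards(traj, p, ei)
  expect_equal(rw$cycle, 1:5)
  expect_equal(rw$cost[1],
               sum(traj["1", ] * v_ei$cost) +
                 traj["1", "STHPD"] * 0.10 * 905)
  expect_equal(rw$cost[3], sum(traj["3", ] * v_ei$cost))
  expect_equal(rw$df_effects, 1.015^-(1:5))
})

test_that("discounting matches the closed-form geometric sum", {
  expect_equal(discounted_total(rep(1, 5), 0), 5)
  # oracle: annuity factor (1 - (1+r)^-n) / r
  expect_equal(discounted_total(rep(1, 5), 0.04),
               (1 - 1.04^-5) / 0.04)
  expect_equal(discounted_total(rep(1, 5), 0.04), 4.451822, tolerance = 1e-6)
  expect_equal(discounted_total(rep(1, 5), 0.015),
               (1 - 1.015^-5) / 0.015)
  expect_equal(discounted_total(rep(1, 5), 0.015), 4.782645,
               tolerance = 1e-6)
  # start-of-cycle attribution shifts exponents to 0..n-1
  expect_equal(discounted_total(rep(1, 5), 0.04, timing = "start"),
               1.04 * discounted_total(rep(1, 5), 0.04))
  expect_error(discounted_total(1:3, -0.1), "non-negative")

  # zero rate equals the plain sum; totals decrease in the rate
  set.seed(5)
  v <- stats::runif(8, 0, 2)
  expect_equal(discounted_total(v, 0), sum(v))
  rates <- seq(0, 0.2, by = 0.02)
  totals <- vapply(rates, function(r) discounted_total(v, r), numeric(1))
  expect_true(all(diff(totals) < 0))
})
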