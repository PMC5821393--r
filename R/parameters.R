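#' Health states of the panic disorder Markov model
#'
#' The model distinguishes four mutually exclusive states: panic-free
#' (`PF`), subthreshold panic disorder (`STHPD`), full-blown panic disorder
#' (`PD`) and death (`DEAD`). `DEAD` is absorbing, and `STHPD` is the
#' obligatory intermediate between `PF` and `PD` in both directions.
#'
#' @return Character vector of the four state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() c("PF", "STHPD", "PD", "DEAD")

#' Default model parameters
#'
#' Builds the complete Dutch base-case parameter set: intervention profiles
#' (uptake under each scenario arm, adherence, dropout, per-person cost
#' with its timing — the four PD treatments are priced per treatment year
#' and recur, the early intervention is a one-off group course charged in
#' the first cycle —, per-cycle utility gain for adherent patients, and
#' the risk ratio the early intervention applies to the STHPD-to-PD
#' transition), per-state
#' annual cost categories and utilities with their standard errors, annual
#' transition probabilities, and run settings (5-year horizon, 1-year
#' cycles, 4% / 1.5% discounting of costs / effects, EUR 20,000
#' willingness-to-pay, STHPD / PD prevalences 1.9% / 2.2%).
#'
#' Spreads that the source evidence does not report are explicit modelling
#' assumptions exposed here: every cost parameter carries a coefficient of
#' variation (`cost_cv`, default 0.25) for gamma sampling, and each utility
#' gain a standard error of `gain_se_frac` (default 0.20) times its mean.
#'
#' @param cost_cv Coefficient of variation applied to every cost parameter
#'   in probabilistic sampling.
#' @param gain_se_frac Standard error of each intervention utility gain,
#'   as a fraction of its mean.
#' @return An object of class `paniccea_parameters`: a list with elements
#'   `interventions`, `state_econ`, `transitions` and `settings`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$transitions$p_sthpd_pd
default_parameters <- function(cost_cv = 0.25, gain_se_frac = 0.20) {
  interventions <- data.frame(
    name = c("CBT", "SSRI", "TCA", "combination", "early_intervention"),
    target = c("PD", "PD", "PD", "PD", "STHPD"),
    uptake_usual = c(0.088, 0.092, 0.024, 0.090, 0),
    uptake_alt = c(0.088, 0.092, 0.024, 0.090, 0.10),
    base_adherence = c(0.70, 0.70, 0.70, 0.70, 0.70),
    dropout = c(0, 0.18, 0.30, 0, 0),
    annual_cost = c(1176, 1128, 1200, 2315, 905),
    cost_timing = c("recurring", "recurring", "recurring", "recurring",
                    "once"),
    cost_cv = rep(cost_cv, 5),
    utility_gain = c(0.0327, 0.0450, 0.0445, 0.0568, 0.0655),
    transition_rr = c(NA, NA, NA, NA, 0.538),
    stringsAsFactors = FALSE
  )
  interventions$gain_se <- gain_se_frac * interventions$utility_gain

  state_econ <- data.frame(
    state = health_states(),
    utility = c(0.869, 0.730, 0.660, 0),
    utility_se = c(0.0054, 0.037, 0.030, 0),
    cost_direct_medical = c(340, 1503, 666, 0),
    cost_direct_nonmedical = c(99, 494, 858, 0),
    cost_indirect_nonmedical = c(6643, 9741, 16771, 0),
    cost_cv = c(cost_cv, cost_cv, cost_cv, 0),
    stringsAsFactors = FALSE
  )

  transitions <- list(
    p_pf_sthpd = 0.0016,
    p_sthpd_pf = 0.0815,
    p_sthpd_pd = 0.6037,
    p_pd_sthpd = 0.5214,
    p_death = 0.0028
  )

  settings <- list(
    horizon = 5L,
    cycle_length = 1,
    discount_rate_costs = 0.04,
    discount_rate_effects = 0.015,
    wtp_threshold = 20000,
    prevalence_sthpd = 0.019,
    prevalence_pd = 0.022,
    utilities_corrected = TRUE,
    psa_iterations = 10000L,
    reward_timing = "end"
  )

  params <- structure(
    list(interventions = interventions, state_econ = state_econ,
         transitions = transitions, settings = settings),
    class = "paniccea_parameters"
  )
  validate_parameters(params)
  params
}

#' Validate a model parameter set
#'
#' Checks range and structural invariants: probabilities and rates within
#' bounds, non-negative costs and utility gains, utilities in \[0, 1\] with
#' the death state fixed at zero utility and cost, the four canonical
#' states present, and per-state exit probabilities summing to less than
#' one so that a non-negative stay probability remains.
#'
#' @param params A `paniccea_parameters` object (or a plain list with the
#'   same shape, e.g. fresh from [read_config()]).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameters: %s (%s)", field, msg), call. = FALSE)
  }
  for (el in c("interventions", "state_econ", "transitions", "settings")) {
    if (is.null(params[[el]])) fail(el, "missing element")
  }

  iv <- params$interventions
  need_iv <- c("name", "target", "uptake_usual", "uptake_alt",
               "base_adherence", "dropout", "annual_cost", "cost_timing",
               "utility_gain")
  missing_iv <- setdiff(need_iv, names(iv))
  if (length(missing_iv) > 0)
    fail(paste0("interventions$", missing_iv[1]), "missing column")
  for (col in c("uptake_usual", "uptake_alt", "base_adherence", "dropout")) {
    if (any(iv[[col]] < 0 | iv[[col]] > 1))
      fail(paste0("interventions$", col), "probability outside [0, 1]")
  }
  if (any(iv$annual_cost < 0))
    fail("interventions$annual_cost", "negative cost")
  if (!all(iv$cost_timing %in% c("recurring", "once")))
    fail("interventions$cost_timing", "must be 'recurring' or 'once'")
  if (any(iv$utility_gain < 0))
    fail("interventions$utility_gain", "negative utility gain")
  if (!all(iv$target %in% c("STHPD", "PD")))
    fail("interventions$target", "target must be STHPD or PD")
  rr <- iv$transition_rr[!is.na(iv$transition_rr)]
  if (any(rr <= 0 | rr > 1))
    fail("interventions$transition_rr", "risk ratio outside (0, 1]")

  se <- params$state_econ
  if (!identical(se$state, health_states()))
    fail("state_econ$state", "states must be PF, STHPD, PD, DEAD in order")
  if (any(se$utility < 0 | se$utility > 1))
    fail("state_econ$utility", "utility outside [0, 1]")
  if (any(se$utility_se < 0))
    fail("state_econ$utility_se", "negative standard error")
  cost_cols <- c("cost_direct_medical", "cost_direct_nonmedical",
                 "cost_indirect_nonmedical")
  for (col in cost_cols) {
    if (any(se[[col]] < 0)) fail(paste0("state_econ$", col), "negative cost")
  }
  dead <- se[se$state == "DEAD", ]
  if (dead$utility != 0 || dead$utility_se != 0 ||
      any(dead[, cost_cols] != 0))
    fail("state_econ[DEAD]", "death must carry zero utility and cost")

  tr <- params$transitions
  for (nm in c("p_pf_sthpd", "p_sthpd_pf", "p_sthpd_pd", "p_pd_sthpd",
               "p_death")) {
    v <- tr[[nm]]
    if (is.null(v) || v < 0 || v > 1)
      fail(paste0("transitions$", nm), "probability outside [0, 1]")
  }
  if (tr$p_pf_sthpd + tr$p_death >= 1)
    fail("transitions", "PF exit probabilities must sum below 1")
  if (tr$p_sthpd_pf + tr$p_sthpd_pd + tr$p_death >= 1)
    fail("transitions", "STHPD exit probabilities must sum below 1")
  if (tr$p_pd_sthpd + tr$p_death >= 1)
    fail("transitions", "PD exit probabilities must sum below 1")

  st <- params$settings
  if (st$horizon < 1) fail("settings$horizon", "horizon must be >= 1")
  for (nm in c("discount_rate_costs", "discount_rate_effects")) {
    if (st[[nm]] < 0 || st[[nm]] >= 1)
      fail(paste0("settings$", nm), "rate outside [0, 1)")
  }
  if (st$prevalence_sthpd <= 0 || st$prevalence_pd <= 0)
    fail("settings$prevalence", "prevalences must be positive")
  if (!st$reward_timing %in% c("end", "start"))
    fail("settings$reward_timing", "must be 'end' or 'start'")

  invisible(params)
}

#' Effective adherence after treatment dropout
#'
#' Adherence observed in practice is the trial adherence rate thinned by
#' treatment-specific dropout: patients who drop out realise no benefit.
#' For SSRI (dropout 18%) this yields 0.70 x 0.82 = 0.574 (printed as
#' 57%), for TCA (dropout 30%) 0.49.
#'
#' @param base_adherence Adherence probability before dropout.
#' @param dropout Dropout probability.
#' @return `base_adherence * (1 - dropout)`. Vectorised.
#' @export
#' @examples
#' effective_adherence(0.70, 0.18)  # 0.574
effective_adherence <- function(base_adherence, dropout) {
  if (any(base_adherence < 0 | base_adherence > 1))
    stop("base_adherence must lie in [0, 1]", call. = FALSE)
  if (any(dropout < 0 | dropout > 1))
    stop("dropout must lie in [0, 1]", call. = FALSE)
  base_adherence * (1 - dropout)
}

#' Annual societal cost of each health state
#'
#' Societal costs sum the direct medical, direct non-medical and indirect
#' non-medical (productivity) annual cost categories.
#'
#' @param state_econ The `state_econ` data.frame of a parameter set.
#' @return Named numeric vector of annual societal cost (EUR) per state.
#' @export
#' @examples
#' aggregate_state_cost(default_parameters()$state_econ)
aggregate_state_cost <- function(state_econ) {
  cols <- c("cost_direct_medical", "cost_direct_nonmedical",
            "cost_indirect_nonmedical")
  m <- as.matrix(state_econ[, cols])
  if (any(m < 0)) stop("negative category costs are invalid", call. = FALSE)
  stats::setNames(rowSums(m), state_econ$state)
}

#' Remove the general-population utility correction
#'
#' In the base case the STHPD and PD utilities are the disease-specific
#' values multiplied by the general-population (PF) utility, so that
#' recovery to PF reflects the burden-of-disease utility gain. The
#' "uncorrected utilities" sensitivity scenario undoes that correction by
#' dividing the STHPD and PD utilities by the PF utility; PF itself is the
#' reference state and is left unchanged.
#'
#' @param params A corrected parameter set (`settings$utilities_corrected`
#'   must be `TRUE`).
#' @return The parameter set with uncorrected STHPD / PD utilities and
#'   `settings$utilities_corrected = FALSE`.
#' @export
#' @examples
#' uncorrect_utilities(default_parameters())$state_econ$utility
uncorrect_utilities <- function(params) {
  if (!isTRUE(params$settings$utilities_corrected))
    stop("utilities are already uncorrected", call. = FALSE)
  se <- params$state_econ
  u_pf <- se$utility[se$state == "PF"]
  if (u_pf <= 0) stop("PF utility must be positive", call. = FALSE)
  idx <- se$state %in% c("STHPD", "PD")
  se$utility[idx] <- se$utility[idx] / u_pf
  if (any(se$utility > 1))
    stop("uncorrected utility exceeds 1", call. = FALSE)
  params$state_econ <- se
  params$settings$utilities_corrected <- FALSE
  params
}

#' Initial cohort occupancy
#'
#' The modelled cohort is the prevalent Dutch adult STHPD + PD population.
#' For the `mixed` cohort the mass is split between STHPD and PD in
#' proportion to the annual prevalences (1.9% and 2.2%); `sthpd_only`
#' places the whole cohort in STHPD. Nobody starts panic-free or dead.
#'
#' @param params Parameter set (prevalences are read from `settings`).
#' @param cohort `"mixed"` or `"sthpd_only"`.
#' @return Named occupancy vector over [health_states()], summing to 1.
#' @export
#' @examples
#' initial_occupancy(default_parameters(), "mixed")
initial_occupancy <- function(params, cohort = c("mixed", "sthpd_only")) {
  cohort <- match.arg(cohort)
  st <- params$settings
  occ <- stats::setNames(numeric(4), health_states())
  if (cohort == "mixed") {
    total <- st$prevalence_sthpd + st$prevalence_pd
    occ["STHPD"] <- st$prevalence_sthpd / total
    occ["PD"] <- st$prevalence_pd / total
  } else {
    occ["STHPD"] <- 1
  }
  occ
}

#' Build a scenario specification
#'
#' A scenario fixes the uptake of every intervention. The `usual_care` arm
#' offers the four PD interventions at their observed uptakes and no early
#' intervention; the `early_intervention` arm adds the CBT-based early
#' intervention for STHPD occupants at 10% uptake (Table 1). Sensitivity
#' variants adjust the early-intervention uptake, scale the PD-intervention
#' uptakes, or modify the treated STHPD-to-PD transition via
#' `rr_multiplier`.
#'
#' @param params Parameter set.
#' @param arm `"usual_care"` or `"early_intervention"`.
#' @param early_uptake Override for the early-intervention uptake in the
#'   `early_intervention` arm (default: the Table 1 value, 0.10).
#' @param pd_uptake_scale Multiplier applied to the four PD-intervention
#'   uptakes (used by the "uptake rate PD interventions 100%" scenario).
#' @param rr_multiplier Multiplier on the early intervention's risk ratio
#'   for the STHPD-to-PD transition (1 = as published).
#' @return A `paniccea_scenario`: list with `name`, an `interventions`
#'   data.frame carrying a resolved `uptake` and `eff_adherence` column,
#'   and `rr_multiplier`.
#' @export
#' @examples
#' scenario_spec(default_parameters(), "early_intervention")$interventions
scenario_spec <- function(params,
                          arm = c("usual_care", "early_intervention"),
                          early_uptake = NULL,
                          pd_uptake_scale = 1,
                          rr_multiplier = 1) {
  arm <- match.arg(arm)
  iv <- params$interventions
  iv$uptake <- if (arm == "usual_care") iv$uptake_usual else iv$uptake_alt
  if (!is.null(early_uptake) && arm == "early_intervention") {
    iv$uptake[iv$name == "early_intervention"] <- early_uptake
  }
  pd <- iv$target == "PD"
  iv$uptake[pd] <- iv$uptake[pd] * pd_uptake_scale
  if (any(iv$uptake < 0 | iv$uptake > 1))
    stop("scenario uptake outside [0, 1]", call. = FALSE)
  iv$eff_adherence <- effective_adherence(iv$base_adherence, iv$dropout)
  structure(
    list(name = arm, interventions = iv, rr_multiplier = rr_multiplier),
    class = "paniccea_scenario"
  )
}

#' @export
print.paniccea_parameters <- function(x, ...) {
  cat("Model parameters (", length(health_states()), " states, horizon ",
      x$settings$horizon, " years)\n", sep = "")
  cat("Interventions:\n")
  print(x$interventions[, c("name", "target", "uptake_usual", "uptake_alt",
                            "annual_cost", "utility_gain")], row.names = FALSE)
  cat("State economics:\n")
  print(x$state_econ, row.names = FALSE)
  invisible(x)
}

#' @export
print.paniccea_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  print(x$interventions[, c("name", "target", "uptake", "eff_adherence")],
        row.names = FALSE)
  invisible(x)
}
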