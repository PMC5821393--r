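#' Build the annual transition matrix for a scenario
#'
#' Structural rules: only adjacent states connect (PF <-> STHPD <-> PD;
#' the direct PF <-> PD transitions are structurally zero because STHPD is
#' the obligatory intermediate), death is reachable from every alive state
#' at the same background probability, is absorbing, and at most one switch
#' happens per cycle — each state's stay probability is one minus its exit
#' probabilities.
#'
#' The early intervention lowers the STHPD-to-PD progression probability by
#' risk ratio `RR` for the treated-and-adherent fraction. With uptake `u`
#' and effective adherence `a`, the cohort-level blended probability is
#' `p * (1 - u * a * (1 - RR))`; the removed mass is added to the STHPD
#' stay probability (the intervention prevents progression rather than
#' inducing remission).
#'
#' @param params Parameter set.
#' @param scenario A [scenario_spec()] object.
#' @return 4 x 4 row-stochastic matrix with dimnames [health_states()].
#' @export
#' @examples
#' p <- default_parameters()
#' build_transition_matrix(p, scenario_spec(p, "early_intervention"))
build_transition_matrix <- function(params, scenario) {
  tr <- params$transitions
  st <- health_states()
  d <- tr$p_death

  p_sp <- tr$p_sthpd_pd
  iv <- scenario$interventions
  mod <- which(iv$target == "STHPD" & !is.na(iv$transition_rr))
  for (i in mod) {
    rr_eff <- iv$transition_rr[i] * scenario$rr_multiplier
    p_sp <- p_sp * (1 - iv$uptake[i] * iv$eff_adherence[i] * (1 - rr_eff))
  }

  P <- matrix(0, 4, 4, dimnames = list(st, st))
  P["PF", "STHPD"] <- tr$p_pf_sthpd
  P["PF", "DEAD"] <- d
  P["PF", "PF"] <- 1 - tr$p_pf_sthpd - d
  P["STHPD", "PF"] <- tr$p_sthpd_pf
  P["STHPD", "PD"] <- p_sp
  P["STHPD", "DEAD"] <- d
  P["STHPD", "STHPD"] <- 1 - tr$p_sthpd_pf - p_sp - d
  P["PD", "STHPD"] <- tr$p_pd_sthpd
  P["PD", "DEAD"] <- d
  P["PD", "PD"] <- 1 - tr$p_pd_sthpd - d
  P["DEAD", "DEAD"] <- 1

  if (any(P < 0) || any(P > 1))
    stop("transition matrix entry outside [0, 1]", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  P
}

#' Project cohort occupancy over the model horizon
#'
#' Left-multiplies the initial occupancy vector by the transition matrix
#' once per cycle, recording the occupancy at every cycle point 0..horizon.
#'
#' @param initial Occupancy vector over [health_states()], summing to 1.
#' @param matrix Row-stochastic transition matrix.
#' @param horizon Number of annual cycles (>= 1).
#' @return `(horizon + 1) x 4` matrix; row `t + 1` is the occupancy after
#'   `t` cycles, rownames `"0"` ... `"horizon"`.
#' @export
project_cohort <- function(initial, matrix, horizon) {
  if (length(initial) != ncol(matrix) || nrow(matrix) != ncol(matrix))
    stop("dimension mismatch between initial vector and matrix",
         call. = FALSE)
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial occupancy must sum to 1", call. = FALSE)
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  traj <- matrix(0, horizon + 1, ncol(matrix),
                 dimnames = list(0:horizon, colnames(matrix)))
  occ <- as.numeric(initial)
  traj[1, ] <- occ
  for (t in seq_len(horizon)) {
    occ <- occ %*% matrix
    traj[t + 1, ] <- occ
  }
  traj
}

#' Per-state utility and cost including intervention terms
#'
#' Each cycle, state occupants accrue the state utility plus, for every
#' intervention targeting the state, `uptake * effective adherence *
#' utility gain` (non-adherent patients realise no benefit). Costs accrue
#' the aggregated societal state cost plus `uptake * intervention cost` —
#' full intervention costs are incurred for non-adherent patients, so the
#' cost term is weighted by uptake alone. Interventions priced per
#' treatment year (`cost_timing == "recurring"`) contribute every cycle;
#' one-off courses (`"once"`, the early intervention) are returned
#' separately and charged by [cycle_rewards()] in the first model cycle
#' only. Death contributes zero.
#'
#' @param params Parameter set.
#' @param scenario A [scenario_spec()] object.
#' @return List with named per-state vectors `utility`, `cost` (state cost
#'   plus recurring intervention cost) and `cost_once` (uptake-weighted
#'   one-off intervention cost).
#' @export
state_values <- function(params, scenario) {
  se <- params$state_econ
  u <- stats::setNames(se$utility, se$state)
  cost <- aggregate_state_cost(se)
  cost_once <- stats::setNames(numeric(4), se$state)
  iv <- scenario$interventions
  for (i in seq_len(nrow(iv))) {
    s <- iv$target[i]
    u[s] <- u[s] + iv$uptake[i] * iv$eff_adherence[i] * iv$utility_gain[i]
    charge <- iv$uptake[i] * iv$annual_cost[i]
    if (iv$cost_timing[i] == "recurring") {
      cost[s] <- cost[s] + charge
    } else {
      cost_once[s] <- cost_once[s] + charge
    }
  }
  u["DEAD"] <- 0
  cost["DEAD"] <- 0
  cost_once["DEAD"] <- 0
  list(utility = u, cost = cost, cost_once = cost_once)
}

#' Undiscounted per-cycle reward streams
#'
#' Multiplies the occupancy trajectory into the per-state utility and cost
#' values; one-off intervention course costs are charged in the first
#' model cycle. Rewards are attributed at cycle end by default (occupancy after
#' each annual transition, discount exponents 1..horizon, no half-cycle
#' correction); `settings$reward_timing = "start"` switches to
#' start-of-cycle attribution (occupancy before each transition, exponents
#' 0..horizon-1).
#'
#' @param trajectory Occupancy trajectory from [project_cohort()].
#' @param params Parameter set (timing and discount rates come from
#'   `settings`).
#' @param scenario A [scenario_spec()] object.
#' @return data.frame with one row per model cycle: `cycle` (the discount
#'   exponent), undiscounted `utility` and `cost`, and the discount
#'   factors `df_effects` and `df_costs`.
#' @export
cycle_rewards <- function(trajectory, params, scenario) {
  horizon <- nrow(trajectory) - 1
  vals <- state_values(params, scenario)
  timing <- params$settings$reward_timing
  rows <- if (timing == "end") 2:(horizon + 1) else 1:horizon
  cycles <- if (timing == "end") seq_len(horizon) else seq_len(horizon) - 1
  occ <- trajectory[rows, , drop = FALSE]
  cost <- as.numeric(occ %*% vals$cost)
  cost[1] <- cost[1] + as.numeric(occ[1, ] %*% vals$cost_once)
  data.frame(
    cycle = cycles,
    utility = as.numeric(occ %*% vals$utility),
    cost = cost,
    df_effects = (1 + params$settings$discount_rate_effects)^(-cycles),
    df_costs = (1 + params$settings$discount_rate_costs)^(-cycles)
  )
}

#' Discounted total of a per-cycle value stream
#'
#' @param values Per-cycle values, one per model cycle.
#' @param rate Annual discount rate (>= 0).
#' @param timing `"end"` discounts at exponents 1..n (cycle-end
#'   attribution); `"start"` at 0..n-1.
#' @return Scalar discounted sum.
#' @export
#' @examples
#' discounted_total(rep(1, 5), 0.04)  # 4.451822
discounted_total <- function(values, rate, timing = c("end", "start")) {
  timing <- match.arg(timing)
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  n <- length(values)
  expo <- if (timing == "end") seq_len(n) else seq_len(n) - 1
  sum(values / (1 + rate)^expo)
}
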