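#' Evaluate a scenario into per-patient discounted QALYs and costs
#'
#' Composes the full deterministic pipeline: initial occupancy, scenario
#' transition matrix, cohort projection over the horizon, per-cycle reward
#' accrual, and discounting (effects at 1.5%/year, costs at 4%/year by
#' default).
#'
#' @param params Parameter set.
#' @param scenario A [scenario_spec()] object.
#' @param cohort `"mixed"` (STHPD + PD prevalence mix) or `"sthpd_only"`.
#' @return A `scenario_result`: list with `scenario`, `cohort`, `qaly`
#'   (discounted QALYs per patient) and `cost` (discounted societal EUR
#'   per patient).
#' @export
#' @examples
#' p <- default_parameters()
#' evaluate_scenario(p, scenario_spec(p, "usual_care"), "mixed")
evaluate_scenario <- function(params, scenario,
                              cohort = c("mixed", "sthpd_only")) {
  cohort <- match.arg(cohort)
  st <- params$settings
  init <- initial_occupancy(params, cohort)
  P <- build_transition_matrix(params, scenario)
  traj <- project_cohort(init, P, st$horizon)
  rw <- cycle_rewards(traj, params, scenario)
  structure(
    list(
      scenario = scenario$name,
      cohort = cohort,
      qaly = sum(rw$utility * rw$df_effects),
      cost = sum(rw$cost * rw$df_costs)
    ),
    class = "scenario_result"
  )
}

#' Incremental comparison of two scenario results
#'
#' Deltas are alternative minus base. The ICER is the cost difference per
#' QALY difference, undefined (NA) when the QALY difference is zero. The
#' cost-effectiveness-plane quadrant is classified from the delta signs:
#' `dominant` (more effect, no more cost), `dominated` (less effect, no
#' less cost), `NE` (more effect at more cost), `SW` (less effect at less
#' cost), `undefined` (both deltas zero).
#'
#' @param base,alt `scenario_result` objects for the same cohort.
#' @return An `incremental_result`: list with `delta_qaly`, `delta_cost`,
#'   `icer` and `quadrant`.
#' @export
incremental <- function(base, alt) {
  if (!identical(base$cohort, alt$cohort))
    stop("scenario results compare different cohorts", call. = FALSE)
  dq <- alt$qaly - base$qaly
  dc <- alt$cost - base$cost
  icer <- if (dq != 0) dc / dq else NA_real_
  quadrant <-
    if (dq > 0 && dc > 0) "NE"
    else if (dq < 0 && dc < 0) "SW"
    else if (dq >= 0 && dc <= 0 && (dq > 0 || dc < 0)) "dominant"
    else if (dq <= 0 && dc >= 0 && (dq < 0 || dc > 0)) "dominated"
    else "undefined"
  structure(
    list(base = base$scenario, alt = alt$scenario, cohort = base$cohort,
         delta_qaly = dq, delta_cost = dc, icer = icer, quadrant = quadrant),
    class = "incremental_result"
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost`: the monetised health gain at the
#' willingness-to-pay threshold minus the incremental cost. A positive NMB
#' means the alternative is cost-effective at that threshold.
#'
#' @param delta_qaly,delta_cost Incremental effects and costs.
#' @param wtp Willingness-to-pay threshold (EUR per QALY, >= 0).
#' @return Net monetary benefit in EUR. Vectorised.
#' @export
net_monetary_benefit <- function(delta_qaly, delta_cost, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the alternative
#' is cost-effective: the fraction of PSA iterations with positive net
#' monetary benefit.
#'
#' @param deltas data.frame (or list) with per-iteration `delta_qaly` and
#'   `delta_cost`.
#' @param wtp_grid Willingness-to-pay grid (EUR per QALY).
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(deltas, wtp_grid = seq(0, 80000, by = 1000)) {
  dq <- deltas$delta_qaly
  dc <- deltas$delta_cost
  if (length(dq) == 0) stop("no PSA iterations supplied", call. = FALSE)
  prob <- vapply(
    wtp_grid,
    function(w) mean(net_monetary_benefit(dq, dc, w) > 0),
    numeric(1)
  )
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("%s (%s cohort): %.4f QALYs, EUR %.2f per patient\n",
              x$scenario, x$cohort, x$qaly, x$cost))
  invisible(x)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s cohort)\n", x$alt, x$base, x$cohort))
  cat(sprintf("  delta QALYs %.5f, delta cost EUR %.2f\n",
              x$delta_qaly, x$delta_cost))
  if (is.na(x$icer)) {
    cat("  ICER undefined (no QALY difference);", x$quadrant, "\n")
  } else {
    cat(sprintf("  ICER EUR %.0f per QALY (%s)\n", x$icer, x$quadrant))
  }
  invisible(x)
}
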