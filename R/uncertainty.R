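#' Truncated normal sampling by rejection
#'
#' Redraws out-of-range values until all draws fall inside the bounds.
#' Used for utilities (bounded to \[0, 1\]) and utility gains (bounded
#' below at 0); with the model's means several standard errors away from
#' the bounds, rejection is rare and the mean distortion negligible.
#'
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Mean-preserving gamma draw parameterised by coefficient of variation
#'
#' `shape = 1 / cv^2`, `scale = mean * cv^2`, so the distribution keeps the
#' specified mean and relative spread. A zero mean or zero CV degenerates
#' to the point value.
#'
#' @noRd
rgamma_cv <- function(mean, cv) {
  cv <- rep_len(cv, length(mean))
  out <- mean
  live <- mean > 0 & cv > 0
  if (any(live)) {
    out[live] <- stats::rgamma(sum(live), shape = 1 / cv[live]^2,
                               scale = mean[live] * cv[live]^2)
  }
  out
}

#' Draw one probabilistic parameter set
#'
#' One joint draw for the probabilistic sensitivity analysis, with all
#' parameters sampled independently following their assigned families:
#' state utilities are normal (Table-2 standard errors) truncated to
#' \[0, 1\] by resampling; intervention utility gains are normal (standard
#' error `gain_se`) truncated at 0; every cost parameter — the nine
#' per-state cost categories and the five intervention costs — is gamma
#' with `shape = 1/CV^2`, `scale = mean * CV^2`. Transition probabilities,
#' uptake/adherence and discount rates are fixed. Zero spreads reproduce
#' the deterministic values exactly.
#'
#' @param params Parameter set with uncertainty annotations (`utility_se`,
#'   `cost_cv`, `gain_se`).
#' @return A `paniccea_parameters` draw.
#' @export
sample_parameters <- function(params) {
  se <- params$state_econ
  if (any(se$utility_se < 0) || any(se$cost_cv < 0))
    stop("negative spread values are invalid", call. = FALSE)
  alive <- se$utility_se > 0
  se$utility[alive] <- rtrunc_norm(sum(alive), se$utility[alive],
                                   se$utility_se[alive], 0, 1)
  for (col in c("cost_direct_medical", "cost_direct_nonmedical",
                "cost_indirect_nonmedical")) {
    se[[col]] <- rgamma_cv(se[[col]], se$cost_cv)
  }
  params$state_econ <- se

  iv <- params$interventions
  if (any(iv$gain_se < 0) || any(iv$cost_cv < 0))
    stop("negative spread values are invalid", call. = FALSE)
  g <- iv$gain_se > 0
  iv$utility_gain[g] <- rtrunc_norm(sum(g), iv$utility_gain[g],
                                    iv$gain_se[g], lower = 0)
  iv$annual_cost <- rgamma_cv(iv$annual_cost, iv$cost_cv)
  params$interventions <- iv
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` joint parameter sets and evaluates both scenario arms on
#' each draw (common random numbers: the two arms share every iteration's
#' draw). Summaries report means and 2.5% / 97.5% percentiles of QALYs and
#' costs per arm, the incremental means, the summary ICER as the ratio of
#' mean incremental cost to mean incremental QALY (per-iteration ICERs are
#' unstable near zero QALY difference), the 2.5% / 97.5% percentiles of the
#' per-iteration ICERs (which reproduce the wide, sign-crossing published
#' intervals), and the cost-effectiveness acceptability curve.
#'
#' @param params Parameter set with uncertainty annotations.
#' @param scenario_base,scenario_alt [scenario_spec()] objects; default the
#'   usual-care and added-early-intervention arms.
#' @param cohort `"mixed"` or `"sthpd_only"`.
#' @param n_iter Number of PSA iterations (default
#'   `settings$psa_iterations`, 10,000).
#' @param seed Integer seed; re-running with the same seed is
#'   bit-identical.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @return A `psa_result`: list with per-iteration data.frame `iterations`,
#'   one-row data.frame `summary`, data.frame `ceac`, and `seed`.
#' @export
run_psa <- function(params,
                    scenario_base = scenario_spec(params, "usual_care"),
                    scenario_alt = scenario_spec(params, "early_intervention"),
                    cohort = c("mixed", "sthpd_only"),
                    n_iter = params$settings$psa_iterations,
                    seed = NULL,
                    wtp_grid = seq(0, 80000, by = 1000)) {
  cohort <- match.arg(cohort)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  qaly_base <- cost_base <- qaly_alt <- cost_alt <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    draw <- sample_parameters(params)
    r0 <- evaluate_scenario(draw, scenario_base, cohort)
    r1 <- evaluate_scenario(draw, scenario_alt, cohort)
    qaly_base[i] <- r0$qaly
    cost_base[i] <- r0$cost
    qaly_alt[i] <- r1$qaly
    cost_alt[i] <- r1$cost
  }
  dq <- qaly_alt - qaly_base
  dc <- cost_alt - cost_base
  iterations <- data.frame(
    iteration = seq_len(n_iter),
    qaly_base = qaly_base, cost_base = cost_base,
    qaly_alt = qaly_alt, cost_alt = cost_alt,
    delta_qaly = dq, delta_cost = dc
  )

  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  iter_icer <- dc[dq != 0] / dq[dq != 0]
  summary <- data.frame(
    cohort = cohort,
    n_iter = n_iter,
    mean_qaly_base = mean(qaly_base),
    qaly_base_lo = q(qaly_base, 0.025), qaly_base_hi = q(qaly_base, 0.975),
    mean_qaly_alt = mean(qaly_alt),
    qaly_alt_lo = q(qaly_alt, 0.025), qaly_alt_hi = q(qaly_alt, 0.975),
    mean_cost_base = mean(cost_base),
    cost_base_lo = q(cost_base, 0.025), cost_base_hi = q(cost_base, 0.975),
    mean_cost_alt = mean(cost_alt),
    cost_alt_lo = q(cost_alt, 0.025), cost_alt_hi = q(cost_alt, 0.975),
    mean_delta_qaly = mean(dq),
    mean_delta_cost = mean(dc),
    icer = mean(dc) / mean(dq),
    icer_mean_of_ratios = mean(iter_icer),
    icer_lo = q(iter_icer, 0.025),
    icer_hi = q(iter_icer, 0.975)
  )

  structure(
    list(iterations = iterations, summary = summary,
         ceac = ceac(iterations, wtp_grid),
         seed = if (is.null(seed)) NA_integer_ else seed),
    class = "psa_result"
  )
}

#' The shipped one-way deterministic sensitivity scenarios
#'
#' Eight scenarios, one per published sensitivity row: horizons of 1 and 10
#' years, early-intervention uptake 5% and 15%, the treated STHPD-to-PD
#' transition 10% lower / higher (multipliers 0.9 / 1.1 on the
#' post-risk-ratio probability), all PD-intervention uptakes scaled
#' proportionally so they total 100% (from the base total of 29.4%), and
#' uncorrected utility values.
#'
#' @return Named list of override lists; each element carries a `label`
#'   plus any of `horizon`, `early_uptake`, `rr_multiplier`,
#'   `pd_uptake_scale`, `uncorrected`.
#' @export
dsa_scenarios <- function() {
  base_pd_uptake <- 0.088 + 0.092 + 0.024 + 0.090
  list(
    horizon_1 = list(label = "Time horizon 1 year", horizon = 1L),
    horizon_10 = list(label = "Time horizon 10 years", horizon = 10L),
    early_uptake_5 = list(label = "Early intervention 5% uptake rate",
                          early_uptake = 0.05),
    early_uptake_15 = list(label = "Early intervention 15% uptake rate",
                           early_uptake = 0.15),
    transition_lower = list(
      label = "Early intervention transition from STHPD to PD 10% lower",
      rr_multiplier = 0.9),
    transition_higher = list(
      label = "Early intervention transition from STHPD to PD 10% higher",
      rr_multiplier = 1.1),
    pd_uptake_100 = list(label = "Uptake rate PD interventions 100%",
                         pd_uptake_scale = 1 / base_pd_uptake),
    uncorrected_utilities = list(label = "Uncorrected utility values",
                                 uncorrected = TRUE)
  )
}

#' Resolve a sensitivity override against the base parameters
#'
#' @noRd
apply_dsa_overrides <- function(params, overrides) {
  known <- c("label", "horizon", "early_uptake", "rr_multiplier",
             "pd_uptake_scale", "uncorrected")
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown sensitivity override: %s", unknown[1]),
         call. = FALSE)
  if (!is.null(overrides$horizon))
    params$settings$horizon <- as.integer(overrides$horizon)
  if (isTRUE(overrides$uncorrected)) params <- uncorrect_utilities(params)
  rr_mult <- if (is.null(overrides$rr_multiplier)) 1 else overrides$rr_multiplier
  pd_scale <- if (is.null(overrides$pd_uptake_scale)) 1 else overrides$pd_uptake_scale
  list(
    params = params,
    base = scenario_spec(params, "usual_care", pd_uptake_scale = pd_scale,
                         rr_multiplier = rr_mult),
    alt = scenario_spec(params, "early_intervention",
                        early_uptake = overrides$early_uptake,
                        pd_uptake_scale = pd_scale,
                        rr_multiplier = rr_mult)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Runs the full probabilistic analysis once per sensitivity scenario
#' (reference case first, then each override), reseeding identically for
#' every scenario so that scenarios differ only through their overrides.
#'
#' @param params Base parameter set.
#' @param scenarios Named list of override lists, as [dsa_scenarios()].
#' @param cohort Cohort label.
#' @param n_iter PSA iterations per scenario.
#' @param seed Integer seed, re-applied before every scenario.
#' @param include_reference Prepend the reference case row.
#' @return data.frame with one row per scenario: `scenario`, mean
#'   incremental QALYs / costs, summary ICER and the 2.5% / 97.5%
#'   percentiles of per-iteration ICERs.
#' @export
run_dsa <- function(params, scenarios = dsa_scenarios(),
                    cohort = "mixed",
                    n_iter = params$settings$psa_iterations,
                    seed = NULL,
                    include_reference = TRUE) {
  run_one <- function(label, overrides) {
    resolved <- apply_dsa_overrides(params, overrides)
    psa <- run_psa(resolved$params, resolved$base, resolved$alt,
                   cohort = cohort, n_iter = n_iter, seed = seed)
    s <- psa$summary
    data.frame(
      scenario = label,
      mean_delta_qaly = s$mean_delta_qaly,
      mean_delta_cost = s$mean_delta_cost,
      icer = s$icer,
      icer_lo = s$icer_lo,
      icer_hi = s$icer_hi,
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  if (include_reference) {
    rows[["reference"]] <- run_one("Reference case", list())
  }
  for (nm in names(scenarios)) {
    ov <- scenarios[[nm]]
    label <- if (is.null(ov$label)) nm else ov$label
    rows[[nm]] <- run_one(label, ov)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA (%d iterations, %s cohort, seed %s)\n",
              s$n_iter, s$cohort, x$seed))
  cat(sprintf("  usual care: %.3f QALYs, EUR %.0f\n",
              s$mean_qaly_base, s$mean_cost_base))
  cat(sprintf("  + early intervention: %.3f QALYs, EUR %.0f\n",
              s$mean_qaly_alt, s$mean_cost_alt))
  cat(sprintf("  mean dQALY %.5f, mean dCost EUR %.1f, ICER EUR %.0f\n",
              s$mean_delta_qaly, s$mean_delta_cost, s$icer))
  at20 <- x$ceac$probability[x$ceac$wtp == 20000]
  if (length(at20) == 1)
    cat(sprintf("  P(cost-effective | WTP 20000) = %.3f\n", at20))
  invisible(x)
}
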