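#' Assemble a run configuration
#'
#' Bundles everything a reporting command needs: where the parameters come
#' from, where tables go, and the run options. Every command writes a
#' `manifest.json` to the output directory recording the resolved
#' configuration, seed and package version, which suffices to re-run the
#' result; outputs are byte-identical given the same configuration and
#' seed.
#'
#' @param config_path Path to a JSON parameter configuration, or `NULL`
#'   for the packaged defaults.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param iterations PSA iterations (`NULL`: the configured default).
#' @param cohort `"mixed"` or `"sthpd_only"`.
#' @param microsim_n Persons for the microsimulation command.
#' @param wtp_grid Willingness-to-pay grid for CEAC tables.
#' @param dsa Names of sensitivity scenarios to run (`NULL`: all, see
#'   [dsa_scenarios()]).
#' @return A `run_config` list.
#' @export
run_config <- function(config_path = NULL, out_dir, seed = 1L,
                       iterations = NULL,
                       cohort = c("mixed", "sthpd_only"),
                       microsim_n = 200000L,
                       wtp_grid = seq(0, 80000, by = 1000),
                       dsa = NULL) {
  structure(
    list(config_path = config_path, out_dir = out_dir,
         seed = as.integer(seed), iterations = iterations,
         cohort = match.arg(cohort), microsim_n = as.integer(microsim_n),
         wtp_grid = wtp_grid, dsa = dsa),
    class = "run_config"
  )
}

#' @noRd
resolve_config <- function(config) {
  params <- if (is.null(config$config_path)) {
    default_parameters()
  } else {
    read_config(config$config_path)
  }
  if (!is.null(config$iterations))
    params$settings$psa_iterations <- as.integer(config$iterations)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop(sprintf("cannot create output directory: %s", config$out_dir),
         call. = FALSE)
  params
}

#' @noRd
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' @noRd
write_manifest <- function(config, params, command) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("paniccea")),
    seed = config$seed,
    cohort = config$cohort,
    config_path = if (is.null(config$config_path)) "packaged defaults"
                  else config$config_path,
    settings = params$settings
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @noRd
write_table <- function(df, config, name) {
  path <- file.path(config$out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  log_msg("wrote %s (%d rows)", path, nrow(df))
  path
}

#' Deterministic base-case tables
#'
#' Evaluates both scenario arms for the mixed and STHPD-only cohorts at the
#' deterministic parameter values and writes `scenario_results.csv` (four
#' rows) and `incremental.csv` (one row per cohort).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the two tables.
#' @export
cmd_base_case <- function(config) {
  params <- resolve_config(config)
  arms <- c("usual_care", "early_intervention")
  cohorts <- c("mixed", "sthpd_only")
  results <- list()
  rows <- list()
  for (co in cohorts) {
    for (arm in arms) {
      r <- evaluate_scenario(params, scenario_spec(params, arm), co)
      results[[paste(co, arm, sep = ".")]] <- r
      rows[[length(rows) + 1]] <- data.frame(
        scenario = arm, cohort = co, qaly = r$qaly, cost = r$cost)
    }
  }
  scen_tab <- do.call(rbind, rows)
  inc_tab <- do.call(rbind, lapply(cohorts, function(co) {
    inc <- incremental(results[[paste(co, "usual_care", sep = ".")]],
                       results[[paste(co, "early_intervention", sep = ".")]])
    data.frame(cohort = co, delta_qaly = inc$delta_qaly,
               delta_cost = inc$delta_cost, icer = inc$icer,
               quadrant = inc$quadrant)
  }))
  write_table(scen_tab, config, "scenario_results")
  write_table(inc_tab, config, "incremental")
  write_manifest(config, params, "base")
  invisible(list(scenario_results = scen_tab, incremental = inc_tab))
}

#' Probabilistic sensitivity analysis tables
#'
#' Runs the paired PSA and writes `psa_iterations.csv`, `psa_summary.csv`,
#' `ceac.csv` and the cost-effectiveness plane `ce_plane.csv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the `psa_result`.
#' @export
cmd_psa <- function(config) {
  params <- resolve_config(config)
  log_msg("PSA: %d iterations, %s cohort, seed %d",
          params$settings$psa_iterations, config$cohort, config$seed)
  psa <- run_psa(params, cohort = config$cohort, seed = config$seed,
                 wtp_grid = config$wtp_grid)
  write_table(psa$iterations, config, "psa_iterations")
  write_table(psa$summary, config, "psa_summary")
  write_table(psa$ceac, config, "ceac")
  write_table(psa$iterations[, c("iteration", "delta_qaly", "delta_cost")],
              config, "ce_plane")
  write_manifest(config, params, "psa")
  invisible(psa)
}

#' One-way sensitivity analysis table
#'
#' Runs the reference case plus the selected sensitivity scenarios and
#' writes `dsa.csv` (nine rows for the full set).
#'
#' @param config A [run_config()]; `config$dsa` selects scenarios by name.
#' @return Invisibly, the sensitivity table.
#' @export
cmd_dsa <- function(config) {
  params <- resolve_config(config)
  scen <- dsa_scenarios()
  if (!is.null(config$dsa)) {
    unknown <- setdiff(config$dsa, names(scen))
    if (length(unknown) > 0)
      stop(sprintf("unknown sensitivity scenario: %s", unknown[1]),
           call. = FALSE)
    scen <- scen[config$dsa]
  }
  include_ref <- is.null(config$dsa)
  log_msg("sensitivity analysis: %d scenario(s)%s",
          length(scen), if (include_ref) " + reference case" else "")
  tab <- run_dsa(params, scen, cohort = config$cohort,
                 seed = config$seed, include_reference = include_ref)
  write_table(tab, config, "dsa")
  write_manifest(config, params, "dsa")
  invisible(tab)
}

#' Microsimulation validation tables
#'
#' Runs the individual-level microsimulation and the cohort model for both
#' arms and writes `microsim.csv` comparing the two, with a pass / fail
#' equivalence verdict at three Monte-Carlo standard errors.
#'
#' @param config A [run_config()]; `config$microsim_n` sets the population
#'   size.
#' @return Invisibly, the comparison table.
#' @export
cmd_microsim <- function(config) {
  params <- resolve_config(config)
  if (config$microsim_n < 1) stop("microsim_n must be >= 1", call. = FALSE)
  rows <- lapply(c("usual_care", "early_intervention"), function(arm) {
    scen <- scenario_spec(params, arm)
    det <- evaluate_scenario(params, scen, config$cohort)
    log_msg("microsimulation: %s, n = %d", arm, config$microsim_n)
    ms <- simulate_population(params, scen, config$cohort,
                              n = config$microsim_n, seed = config$seed)
    data.frame(
      scenario = arm, cohort = config$cohort, n = ms$n,
      cohort_qaly = det$qaly, microsim_qaly = ms$mean_qaly,
      qaly_se = ms$se_qaly,
      qaly_diff_se = (ms$mean_qaly - det$qaly) / ms$se_qaly,
      cohort_cost = det$cost, microsim_cost = ms$mean_cost,
      cost_se = ms$se_cost,
      cost_diff_se = (ms$mean_cost - det$cost) / ms$se_cost,
      verdict = ifelse(abs(ms$mean_qaly - det$qaly) < 3 * ms$se_qaly &
                         abs(ms$mean_cost - det$cost) < 3 * ms$se_cost,
                       "pass", "fail")
    )
  })
  tab <- do.call(rbind, rows)
  write_table(tab, config, "microsim")
  write_manifest(config, params, "microsim")
  invisible(tab)
}
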