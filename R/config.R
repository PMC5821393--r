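#' Write a parameter set to a JSON configuration file
#'
#' The configuration is a hierarchical JSON document with the same four
#' blocks as the in-memory parameter object (`interventions`, `state_econ`,
#' `transitions`, `settings`). Values round-trip exactly through
#' [read_config()] (full double precision, no rounding).
#'
#' @param params A validated `paniccea_parameters` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_parameters(params)
  jsonlite::write_json(
    list(
      interventions = params$interventions,
      state_econ = params$state_econ,
      transitions = params$transitions,
      settings = params$settings
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a parameter set from a JSON configuration file
#'
#' Parses and validates a configuration written by [write_config()] (or by
#' hand in the same layout). JSON syntax errors surface with the parser's
#' position diagnostics; schema violations name the offending field.
#'
#' @param path Path to the configuration file.
#' @return A validated `paniccea_parameters` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (el in c("interventions", "state_econ", "transitions", "settings")) {
    if (is.null(raw[[el]]))
      stop(sprintf("configuration %s: missing top-level block '%s'",
                   path, el), call. = FALSE)
  }
  settings <- as.list(raw$settings)
  settings$horizon <- as.integer(settings$horizon)
  settings$psa_iterations <- as.integer(settings$psa_iterations)
  params <- structure(
    list(
      interventions = as.data.frame(raw$interventions),
      state_econ = as.data.frame(raw$state_econ),
      transitions = as.list(raw$transitions),
      settings = settings
    ),
    class = "paniccea_parameters"
  )
  validate_parameters(params)
  params
}

#' Path of the packaged default configuration
#'
#' The shipped configuration reproduces the published base-case inputs
#' exactly; `read_config(default_config_path())` equals
#' [default_parameters()].
#'
#' @return Path to `default_config.json` inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "paniccea",
              mustWork = TRUE)
}
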