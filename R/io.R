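## Readers and writers for frames, survey data, status series, and fits.
## All writes are atomic (tempfile in the target directory, then rename).

#' Write / read a population frame as CSV
#'
#' Columns: `site_id`, `x`, `y`, `elevation`, `stratum`, `cost_class`
#' (latent site effects are regenerated, not serialized).
#'
#' @param frame A [build_frame()] result.
#' @param path File path.
#' @return `read_frame_csv` returns a `population_frame`; the writer
#'   returns `path` invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "population_frame"))
  cols <- c("site_id", "x", "y", "elevation", "stratum", "cost_class")
  atomic_write(function(tmp) utils::write.csv(frame[, cols], tmp, row.names = FALSE),
               path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "elevation", "stratum", "cost_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("frame file missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id values in frame file")
  df$a_i <- df$t_i <- 0
  class(df) <- c("population_frame", "data.frame")
  df
}

#' Write / read long-format survey data as CSV
#'
#' The long format carries one record per site visit: `site_id`, `year`,
#' `y`, `pi_site`, `pi_panel`, `panel_id`, plus optional `stratum`,
#' `cost_class`, `coord_x`, `coord_y`. Total weights are recomputed on read
#' if absent. Inclusion probabilities are validated to lie in (0, 1] and
#' offending row numbers are reported.
#'
#' @param survey A `survey_data` data.frame.
#' @param path File path.
#' @return `read_survey_csv` returns a validated `survey_data`; the writer
#'   returns `path` invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(is.data.frame(survey))
  atomic_write(function(tmp) utils::write.csv(survey, tmp, row.names = FALSE), path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "y", "pi_site", "pi_panel", "panel_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey file missing columns: ", paste(miss, collapse = ", "))
  for (col in c("pi_site", "pi_panel")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0 | df[[col]] > 1)
    if (length(bad)) {
      stop(sprintf("%s outside (0, 1] at rows: %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  if (!"weight" %in% names(df)) df$weight <- 1 / (df$pi_site * df$pi_panel)
  if (!"stratum" %in% names(df)) df$stratum <- "all"
  class(df) <- c("survey_data", "data.frame")
  df
}

#' Serialize a trend fit to JSON
#'
#' @param fit A `trend_fit`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_trend_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "trend_fit"))
  payload <- fit[c("method", "gamma1_hat", "se", "df", "ci", "conf_level",
                   "statistic", "p_value", "n_years", "n_sites", "converged",
                   "notes")]
  payload$ci <- as.list(payload$ci)
  if (!is.null(fit$varcomp)) payload$varcomp <- as.list(fit$varcomp)
  if (!is.null(fit$strata)) payload$strata <- fit$strata
  atomic_write(function(tmp) jsonlite::write_json(payload, tmp,
                                                  auto_unbox = TRUE,
                                                  digits = NA, pretty = TRUE),
               path)
}

#' Read a scenario grid from YAML
#'
#' The YAML file holds a list of scenario cells under `scenarios:`, each
#' with the fields of [scenario_spec()] (missing fields use the defaults).
#'
#' @param path YAML file path.
#' @return List of `scenario_spec` objects.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cells <- if (!is.null(cfg$scenarios)) cfg$scenarios else cfg
  lapply(cells, function(cell) do.call(scenario_spec, cell))
}

# Minimal run manifest written next to CLI outputs.
write_manifest <- function(path, command, seed, outputs) {
  payload <- list(command = command, seed = seed,
                  timestamp = format(Sys.time(), tz = "UTC"),
                  outputs = as.list(outputs))
  atomic_write(function(tmp) jsonlite::write_json(payload, tmp,
                                                  auto_unbox = TRUE),
               path)
}
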