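#' Build the idealized emission scenario
#'
#' Generates the annual CO2 emission series used to force the model: an
#' exponentially growing curve `E(y) = end_rate * exp(growth * (y -
#' stop_year))` over `start_year..stop_year`, calibrated by two parameters
#' (the growth rate and the end-of-2020 emission rate), and identically zero
#' for every year after `stop_year`.  This stands in for the tabulated
#' historical plus high-emission (RCP8.5-like) series, so that no external
#' data are needed; a real series can be supplied instead via
#' [read_emissions_csv()].
#'
#' @param params A list with elements `emission_growth_rate` (1/yr, > 0) and
#'   `emission_end_rate_gtco2` (Gt CO2/yr at `stop_year`, >= 0); the
#'   `scenario` block of [default_config()] works directly.
#' @param stop_year Last year with non-zero emissions (default 2020).
#' @param start_year,end_year Year range of the returned series.
#' @return A tibble of class `emission_scenario` with columns `year` and
#'   `emissions_gtco2` (Gt CO2/yr), and attributes `cumulative_gtco2` and
#'   `cumulative_gtc` holding the summed 'start..stop' emissions.
#' @export
#' @examples
#' em <- build_emissions(default_config()$scenario)
#' attr(em, "cumulative_gtco2")
build_emissions <- function(params, stop_year = 2020,
                            start_year = 1765, end_year = 3000) {
  g <- params$emission_growth_rate
  e_end <- params$emission_end_rate_gtco2
  if (!is.numeric(g) || g <= 0) {
    abort("`emission_growth_rate` must be a positive number.", class = "o2c_parameter_error")
  }
  if (!is.numeric(e_end) || e_end < 0) {
    abort("`emission_end_rate_gtco2` must be non-negative.", class = "o2c_parameter_error")
  }
  if (stop_year < start_year || stop_year > end_year) {
    abort("`stop_year` must lie within the scenario year range.", class = "o2c_range_error")
  }
  years <- start_year:end_year
  em <- ifelse(years <= stop_year, e_end * exp(g * (years - stop_year)), 0)
  out <- tibble::tibble(year = years, emissions_gtco2 = em)
  class(out) <- c("emission_scenario", class(out))
  attr(out, "cumulative_gtco2") <- sum(em)
  attr(out, "cumulative_gtc") <- sum(em) / GTCO2_PER_GTC
  out
}

# molar mass ratio CO2:C
GTCO2_PER_GTC <- 44.009 / 12.011

#' Read an emission scenario from CSV
#'
#' Reads a two-column CSV (`year`, `GtCO2_per_yr`, header required) and
#' validates the scenario invariants: contiguous strictly increasing years
#' and non-negative emissions.
#'
#' @param path Path to the CSV file.
#' @param stop_year Years after `stop_year` are forced to zero (the
#'   zero-emission-commitment design); use `Inf` to keep the series as read.
#' @return An `emission_scenario` tibble as in [build_emissions()].
#' @export
read_emissions_csv <- function(path, stop_year = 2020) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("year", "GtCO2_per_yr") %in% names(raw))) {
    abort("emission CSV must have columns `year` and `GtCO2_per_yr`.",
          class = "o2c_parameter_error")
  }
  if (any(diff(raw$year) != 1)) {
    abort("emission years must be contiguous and strictly increasing.",
          class = "o2c_parameter_error")
  }
  if (any(raw$GtCO2_per_yr < 0)) {
    abort("emissions must be non-negative.", class = "o2c_parameter_error")
  }
  out <- tibble::tibble(
    year = raw$year,
    emissions_gtco2 = ifelse(raw$year > stop_year, 0, raw$GtCO2_per_yr)
  )
  class(out) <- c("emission_scenario", class(out))
  attr(out, "cumulative_gtco2") <- sum(out$emissions_gtco2)
  attr(out, "cumulative_gtc") <- sum(out$emissions_gtco2) / GTCO2_PER_GTC
  out
}
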