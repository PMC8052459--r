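#' Tidy the annual series of a commitment run
#'
#' @param x An `o2_run`.
#' @param ... Unused.
#' @return The annual diagnostics tibble, one row per year.
#' @export
tidy.o2_run <- function(x, ...) x$series

#' One-row summary of a commitment run
#'
#' Computes the headline accounting of the run between the configured
#' baseline, stop and evaluation years: atmospheric pCO2 and SAT anomaly at
#' the stop year, realized/committed/total oxygen loss, the solubility
#' share of the loss, the fraction of the committed loss below 2000 m, the
#' relative loss of sub-2000 m oxygen content, the deep Indo-Pacific
#' ideal-age increase, realized and committed ocean heat uptake, and the
#' relative export change over the committed phase.
#'
#' @param x An `o2_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.o2_run <- function(x, ...) {
  sc <- x$config$scenario
  s <- x$series
  at <- function(col, y) s[[col]][match(y, s$year)]
  y0 <- sc$baseline_year; y1 <- sc$stop_year; y2 <- sc$evaluation_year
  cs <- commitment_summary(
    tibble::tibble(year = s$year, inventory = s$o2_pmol),
    stop_year = y1, eval_year = y2, baseline_year = y0
  )
  share <- solubility_share(s, window = c(y0, y2))
  # committed per-box changes and the depth split
  f1 <- box_field(x, y1); f2 <- box_field(x, y2); f0 <- box_field(x, y0)
  d_mol <- (f2$o2 - f1$o2) * 1e-3 * f1$volume
  deep <- f1$depth2000 == "below 2000 m"
  frac_deep <- sum(d_mol[deep]) / sum(d_mol)
  deep_content0 <- sum(f0$o2[deep] * 1e-3 * f0$volume[deep])
  deep_content2 <- sum(f2$o2[deep] * 1e-3 * f2$volume[deep])
  deep_rel_loss <- (deep_content0 - deep_content2) / deep_content0
  i_dip <- match("deep_ip", x$geometry$boxes$box)
  age_rise <- x$archive[match(y2, s$year), i_dip, "age"] -
    x$archive[match(y1, s$year), i_dip, "age"]
  tibble::tibble(
    pco2_stop = at("pco2", y1),
    sat_anom_stop = at("sat_anom", y1),
    realized_pmol = cs$realized,
    committed_pmol = cs$committed,
    total_pmol = cs$total,
    ratio_committed_realized = cs$ratio_committed_realized,
    fraction_realized = cs$fraction_realized,
    solubility_share = share,
    frac_committed_below_2000m = frac_deep,
    deep_rel_loss = deep_rel_loss,
    deep_ip_age_rise_yr = age_rise,
    heat_realized_j = at("heat_j", y1) - at("heat_j", y0),
    heat_committed_j = at("heat_j", y2) - at("heat_j", y1),
    export_change_frac = at("export_molp_yr", y2) / at("export_molp_yr", y1) - 1,
    ocean_mean_t_stop = at("ocean_mean_t", y1),
    ocean_mean_t_eval = at("ocean_mean_t", y2)
  )
}

#' Plot the temporal evolution of a commitment run
#'
#' Four stacked panels: atmospheric pCO2, surface air temperature anomaly,
#' and the changes in the oxygen inventory (with its abiotic component) and
#' ocean heat content relative to the baseline year.  Dashed verticals mark
#' the emission stop and the evaluation year.
#'
#' @param object An `o2_run`.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.o2_run <- function(object, ...) {
  s <- object$series
  sc <- object$config$scenario
  base <- function(col) col - col[match(sc$baseline_year, s$year)]
  long <- dplyr::bind_rows(
    tibble::tibble(year = s$year, panel = "pCO2 (uatm)", value = s$pco2),
    tibble::tibble(year = s$year, panel = "SAT anomaly (C)", value = s$sat_anom),
    tibble::tibble(year = s$year, panel = "dO2 inventory (Pmol)",
                   value = base(s$o2_pmol), series = "total"),
    tibble::tibble(year = s$year, panel = "dO2 inventory (Pmol)",
                   value = base(s$abiotic_pmol), series = "abiotic"),
    tibble::tibble(year = s$year, panel = "dHeat (1e24 J)",
                   value = base(s$heat_j) / 1e24)
  )
  long$series[is.na(long$series)] <- "total"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(sc$stop_year, sc$evaluation_year),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an oxygen-binned volume census
#'
#' @param object An `o2_census` from [volume_census()].
#' @param ... Unused.
#' @return A `ggplot` bar chart of volume (1e15 m3) per oxygen bin.
#' @export
autoplot.o2_census <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_left +
                                         attr(object, "bin_width") / 2,
                                       y = .data$volume / 1e15)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9) +
    ggplot2::labs(x = "O2 (mmol m-3)", y = "volume (1e15 m3)") +
    ggplot2::theme_minimal()
}

#' Plot a latitude--depth section of a gridded field
#'
#' @param object An `o2_field`.
#' @param ... Unused.
#' @param variable Column to map (default `"o2"`).
#' @param basin Basin to section (default the first present).
#' @return A `ggplot` tile section.
#' @export
autoplot.o2_field <- function(object, ..., variable = "o2", basin = NULL) {
  basin <- basin %||% object$basin[1]
  d <- object[object$basin == basin, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lat, y = .data$depth,
                                  fill = .data[[variable]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "latitude", y = "depth (m)", fill = variable,
                  title = basin) +
    ggplot2::theme_minimal()
}

#' Write the annual diagnostics of a run to tidy CSV
#'
#' One row per year per metric (`year`, `metric`, `value`).
#'
#' @param run An `o2_run`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_run_csv <- function(run, path) {
  long <- tidyr::pivot_longer(run$series, -"year", names_to = "metric",
                              values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}

#' Write a volume census to CSV
#'
#' Columns `bin_left_edge` (mmol/m3) and `volume_1e15_m3`.
#'
#' @param census An `o2_census`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_census_csv <- function(census, path) {
  readr::write_csv(
    tibble::tibble(bin_left_edge = census$bin_left,
                   volume_1e15_m3 = census$volume / 1e15),
    path
  )
  invisible(path)
}
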