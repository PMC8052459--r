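#' Oxygen-binned volume census
#'
#' Bins water volume by oxygen concentration into uniform bins anchored at
#' zero, left-closed and right-open (`[k*w, (k+1)*w)`), so a value lying
#' exactly on an edge is assigned to the upper bin.  Total volume is
#' conserved exactly.
#'
#' @param field A data frame with columns `o2` (mmol/m3, finite and >= 0)
#'   and `volume` (m3, > 0); both [generate_base_field()] output and
#'   [box_field()] output qualify.
#' @param bin_width Bin width in mmol/m3 (default 10).
#' @return A tibble of class `o2_census` with columns `bin_left`,
#'   `bin_right` and `volume`, covering all bins from 0 to the maximum
#'   observed concentration (empty bins included).
#' @export
#' @examples
#' volume_census(tibble::tibble(o2 = c(5, 65, 250), volume = c(1, 2, 3) * 1e15))
volume_census <- function(field, bin_width = 10) {
  o2 <- field$o2
  if (any(!is.finite(o2)) || any(o2 < 0)) {
    abort("`o2` must be finite and non-negative.", class = "o2c_domain_error")
  }
  if (any(field$volume <= 0)) {
    abort("cell volumes must be positive.", class = "o2c_domain_error")
  }
  idx <- floor(o2 / bin_width)
  n_bin <- max(idx) + 1
  vols <- vapply(seq_len(n_bin) - 1, function(k) sum(field$volume[idx == k]),
                 numeric(1))
  out <- tibble::tibble(
    bin_left = (seq_len(n_bin) - 1) * bin_width,
    bin_right = seq_len(n_bin) * bin_width,
    volume = vols
  )
  class(out) <- c("o2_census", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Hypoxic and suboxic water volumes
#'
#' Volumes of water with oxygen strictly below the hypoxic and suboxic
#' thresholds.  The comparison is strict (`O2 < threshold`), so the suboxic
#' volume is always nested inside the hypoxic volume.
#'
#' @inheritParams volume_census
#' @param thresholds Named numeric thresholds (mmol/m3).
#' @return A tibble with columns `threshold_name`, `threshold` and `volume`.
#' @export
threshold_volumes <- function(field, thresholds = c(hypoxic = 70, suboxic = 5)) {
  if (any(!is.finite(field$o2)) || any(field$o2 < 0)) {
    abort("`o2` must be finite and non-negative.", class = "o2c_domain_error")
  }
  tibble::tibble(
    threshold_name = names(thresholds),
    threshold = unname(thresholds),
    volume = unname(vapply(thresholds,
                           function(th) sum(field$volume[field$o2 < th]),
                           numeric(1)))
  )
}

#' Realized versus committed change accounting
#'
#' Decomposes an inventory time series around an emission stop year:
#' realized loss = inventory(baseline) - inventory(stop); committed loss =
#' inventory(stop) - inventory(evaluation); total = realized + committed.
#' Also reports total/realized and committed/realized ratios and the
#' fraction of the total already realized.  For a flat series the losses
#' are zero, the ratios are returned as `NaN` and `degenerate` is flagged.
#'
#' @param inventory A data frame with columns `year` and `inventory` (any
#'   units; losses are reported in the same units).
#' @param stop_year,eval_year,baseline_year The three accounting years; all
#'   must be present in `inventory$year`.
#' @return A one-row tibble with `realized`, `committed`, `total`,
#'   `ratio_total_realized`, `ratio_committed_realized`,
#'   `fraction_realized`, and `degenerate`.
#' @export
#' @examples
#' inv <- tibble::tibble(year = c(1770, 2020, 2650), inventory = c(274, 269, 253.7))
#' commitment_summary(inv)
commitment_summary <- function(inventory, stop_year = 2020, eval_year = 2650,
                               baseline_year = 1770) {
  yrs <- c(baseline_year, stop_year, eval_year)
  if (!all(yrs %in% inventory$year)) {
    abort("inventory series must cover baseline, stop and evaluation years.",
          class = "o2c_parameter_error")
  }
  inv_at <- function(y) inventory$inventory[match(y, inventory$year)]
  realized <- inv_at(baseline_year) - inv_at(stop_year)
  committed <- inv_at(stop_year) - inv_at(eval_year)
  total <- realized + committed
  degenerate <- realized == 0
  tibble::tibble(
    realized = realized,
    committed = committed,
    total = total,
    ratio_total_realized = if (degenerate) NaN else total / realized,
    ratio_committed_realized = if (degenerate) NaN else committed / realized,
    fraction_realized = if (total == 0) NaN else realized / total,
    degenerate = degenerate
  )
}

#' Ocean heat gain to oxygen loss ratio
#'
#' Relates the oxygen inventory decline to the ocean heat content rise over
#' a window: the ordinary least-squares slope of -(O2 anomaly) against the
#' heat anomaly (both relative to the window start), in nmol/J with its
#' standard error, plus the endpoint ratio -(delta O2)/(delta heat).
#'
#' @param series A data frame with columns `year`, `o2_pmol` (Pmol O2) and
#'   `heat_j` (J).
#' @param window Length-2 numeric year range (inclusive).
#' @return A one-row tibble with `slope_nmol_j`, `se_nmol_j`,
#'   `endpoint_nmol_j` and `n_years`.
#' @export
o2_heat_ratio <- function(series, window = c(1770, 2650)) {
  w <- series[series$year >= window[1] & series$year <= window[2], ]
  if (nrow(w) < 3) abort("need at least 3 points in the window.",
                         class = "o2c_parameter_error")
  d_heat <- w$heat_j - w$heat_j[1]
  d_o2 <- -(w$o2_pmol - w$o2_pmol[1]) * 1e15 * 1e9 # Pmol -> nmol
  if (max(abs(d_heat)) == 0) {
    abort("heat change is zero over the window; ratio undefined.",
          class = "o2c_parameter_error")
  }
  fit <- lm(d_o2 ~ d_heat)
  est <- summary(fit)$coefficients
  endpoint <- tail(d_o2, 1) / tail(d_heat, 1)
  tibble::tibble(
    slope_nmol_j = est["d_heat", "Estimate"],
    se_nmol_j = est["d_heat", "Std. Error"],
    endpoint_nmol_j = endpoint,
    n_years = nrow(w)
  )
}

#' Share of an inventory change carried by its solubility component
#'
#' Ratio of the abiotic (solubility-only) tracer's inventory change to the
#' total oxygen inventory change over a window.
#'
#' @param series A data frame with columns `year`, `o2_pmol` and
#'   `abiotic_pmol`.
#' @param window Length-2 year range.
#' @return The fraction (dimensionless).
#' @export
solubility_share <- function(series, window = c(1770, 2650)) {
  at <- function(col, y) series[[col]][match(y, series$year)]
  if (any(is.na(match(window, series$year)))) {
    abort("series must cover the window endpoints.", class = "o2c_parameter_error")
  }
  d_total <- at("o2_pmol", window[2]) - at("o2_pmol", window[1])
  d_abio <- at("abiotic_pmol", window[2]) - at("abiotic_pmol", window[1])
  if (d_total == 0) abort("total change is zero; share undefined.",
                          class = "o2c_parameter_error")
  d_abio / d_total
}

#' Regional by depth-class oxygen change table
#'
#' Aggregates per-cell oxygen changes between two epochs into a region by
#' depth-class table in Tmol, with a `Global Ocean` row computed from all
#' cells (independently of the regional rows).  Both fields must be on the
#' same grid; the mask columns (`region`, `depth_class`) must partition the
#' cells identically in both.
#'
#' @param field_t0,field_t1 Data frames with columns `o2`, `volume`, and the
#'   mask columns named by `region` and `depth_class`.
#' @param region,depth_class Names of the mask columns.
#' @return A tibble with columns `region`, `depth_class` and `d_o2_tmol`,
#'   plus the `Global Ocean` rows per depth class and overall.
#' @export
regional_depth_table <- function(field_t0, field_t1, region = "region",
                                 depth_class = "depth_class") {
  if (nrow(field_t0) != nrow(field_t1) ||
      !identical(field_t0[[region]], field_t1[[region]]) ||
      !identical(field_t0[[depth_class]], field_t1[[depth_class]]) ||
      !isTRUE(all.equal(field_t0$volume, field_t1$volume))) {
    abort("fields must share grid, volumes and masks.", class = "o2c_parameter_error")
  }
  d <- tibble::tibble(
    region = field_t0[[region]],
    depth_class = field_t0[[depth_class]],
    d_mol = (field_t1$o2 - field_t0$o2) * 1e-3 * field_t0$volume
  )
  by_mask <- d |>
    dplyr::group_by(.data$region, .data$depth_class) |>
    dplyr::summarise(d_o2_tmol = sum(.data$d_mol) * 1e-12, .groups = "drop")
  global <- d |>
    dplyr::group_by(.data$depth_class) |>
    dplyr::summarise(d_o2_tmol = sum(.data$d_mol) * 1e-12, .groups = "drop") |>
    dplyr::mutate(region = "Global Ocean") |>
    dplyr::select("region", "depth_class", "d_o2_tmol")
  global_all <- tibble::tibble(
    region = "Global Ocean", depth_class = "all",
    d_o2_tmol = sum(d$d_mol) * 1e-12
  )
  dplyr::bind_rows(by_mask, global, global_all)
}
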