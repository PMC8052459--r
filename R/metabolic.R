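#' Relative change of the metabolic index
#'
#' Evaluates the relative change of the metabolic index Phi -- the ratio of
#' oxygen supply to the temperature-dependent resting oxygen demand of a
#' marine ectotherm -- between a reference time and a later time:
#'
#' \deqn{\Delta\Phi/\Phi_0 = \frac{pO_2(t)}{pO_2(t_0)}
#'   \exp\!\left(\frac{E_0}{k_B}\left[\frac{1}{T(t)} - \frac{1}{T(t_0)}\right]\right) - 1}
#'
#' where `E0` (eV) is the temperature sensitivity of the critical pO2
#' (hypoxia vulnerability) and `kB` the Boltzmann constant.  Only pO2 and
#' temperature ratios enter, so the result is invariant under a common
#' rescaling of both pO2 arguments.  `E0 = 0.4` eV is a cross-species
#' average; a negative `E0` (e.g. -0.2 eV, observed at oxygen-minimum-zone
#' oxyclines) flips the sign of the temperature term.
#'
#' @param po2_t,po2_t0 Oxygen partial pressures at the two times (any common
#'   units, > 0 for `po2_t0`).
#' @param temp_t,temp_t0 Temperatures at the two times.
#' @param e0 Hypoxia-vulnerability temperature sensitivity (eV).
#' @param temp_unit `"celsius"` (converted to Kelvin internally, default) or
#'   `"kelvin"`.
#' @return Relative change of Phi (dimensionless); 0 when nothing changed.
#' @export
#' @examples
#' metabolic_index_change(0.1, 0.2, 10, 10)  # pO2 halved -> -0.5
#' metabolic_index_change(0.1, 0.1, 276.15, 275.15, temp_unit = "kelvin")
metabolic_index_change <- function(po2_t, po2_t0, temp_t, temp_t0, e0 = 0.4,
                                   temp_unit = c("celsius", "kelvin")) {
  temp_unit <- match.arg(temp_unit)
  if (any(po2_t0 <= 0)) {
    abort("`po2_t0` must be positive.", class = "o2c_domain_error")
  }
  tk_t <- if (temp_unit == "celsius") temp_t + 273.15 else temp_t
  tk_t0 <- if (temp_unit == "celsius") temp_t0 + 273.15 else temp_t0
  if (any(tk_t <= 0) || any(tk_t0 <= 0)) {
    abort("temperatures must be positive in Kelvin.", class = "o2c_domain_error")
  }
  po2_t / po2_t0 * exp(e0 / K_BOLTZMANN_EV * (1 / tk_t - 1 / tk_t0)) - 1
}

#' Metabolic-index change map between two gridded fields
#'
#' Per-cell evaluation of [metabolic_index_change()] between two fields on
#' the same grid, with pO2 computed from dissolved oxygen via the
#' surface-referenced saturation ([po2_from_o2()]).
#'
#' @param field_t0,field_t1 Gridded fields (see [generate_base_field()])
#'   with columns `t`, `o2`, `s` and grid/mask columns.
#' @param e0 Temperature sensitivity (eV).
#' @param hold_t,hold_o2 Hold temperature (or oxygen) at its `t0` value to
#'   isolate the oxygen-only (or temperature-only) contribution.
#' @return `field_t0` with an added `dphi` column.
#' @export
metabolic_index_map <- function(field_t0, field_t1, e0 = 0.4,
                                hold_t = FALSE, hold_o2 = FALSE) {
  if (nrow(field_t0) != nrow(field_t1)) {
    abort("fields must share a grid.", class = "o2c_parameter_error")
  }
  t1 <- if (hold_t) field_t0$t else field_t1$t
  o1 <- if (hold_o2) field_t0$o2 else field_t1$o2
  po2_0 <- po2_from_o2(field_t0$o2, field_t0$t, field_t0$s)
  po2_1 <- po2_from_o2(o1, t1, field_t0$s)
  out <- field_t0
  # cells with zero reference pO2 carry no defined change
  ok <- po2_0 > 0
  out$dphi <- NA_real_
  out$dphi[ok] <- metabolic_index_change(po2_1[ok], po2_0[ok], t1[ok],
                                         field_t0$t[ok], e0 = e0)
  out
}
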