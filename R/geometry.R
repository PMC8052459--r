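#' Default box geometry and transport operator
#'
#' Builds the shipped twelve-box geometry of the world ocean (four surface
#' boxes, three thermocline boxes, two mid-depth and three deep/abyssal
#' boxes; total volume 1.3e18 m3) together with its conservative transport
#' operator: two closed overturning cells (a North Atlantic cell and a
#' Southern-sourced abyssal cell) plus symmetric background mixing.
#'
#' Depth classes are assigned from the box midpoint: `0-1200 m` versus
#' `>1200 m` for the regional budget tables, and above/below 2000 m for the
#' committed-loss depth split.
#'
#' @param config A configuration list; only the `geometry` block is used.
#' @return An object of class `o2_geometry`: a list with `boxes` (a tibble of
#'   box properties), `cells`, `mixing`, `columns`, and the base
#'   [transport_operator()].
#' @export
#' @examples
#' geom <- default_geometry()
#' geom$boxes[, c("box", "volume", "depth_class")]
default_geometry <- function(config = default_config()) {
  gc <- config$geometry
  boxes <- purrr::map_dfr(gc$boxes, tibble::as_tibble)
  boxes$depth_mid <- (boxes$depth_top + boxes$depth_bottom) / 2
  boxes$depth_class <- ifelse(boxes$depth_mid <= 1200, "0-1200 m", ">1200 m")
  boxes$depth2000 <- ifelse(boxes$depth_mid <= 2000, "above 2000 m", "below 2000 m")
  stopifnot(all(boxes$volume > 0))
  total <- sum(boxes$volume)
  if (abs(total - 1.3e18) / 1.3e18 > 0.1) {
    abort("total ocean volume must be within 10% of 1.3e18 m3.",
          class = "o2c_parameter_error")
  }
  geom <- structure(
    list(boxes = boxes, cells = gc$cells, mixing = gc$mixing,
         columns = gc$columns, lowlat_atl_share = gc$lowlat_atl_share),
    class = "o2_geometry"
  )
  geom$base_op <- transport_operator(geom)
  geom
}

#' @export
print.o2_geometry <- function(x, ...) {
  cat("<o2_geometry> ", nrow(x$boxes), " boxes, total volume ",
      format(sum(x$boxes$volume), digits = 4), " m3\n", sep = "")
  print(x$boxes[, c("box", "basin", "depth_top", "depth_bottom", "volume")])
  invisible(x)
}

#' Build a transport operator from a geometry
#'
#' Assembles the pairwise volume-flux matrix (m3/yr) from the directed
#' overturning cells (each a closed loop of strength psi) and the symmetric
#' mixing exchanges, optionally scaling individual cell strengths.  The
#' operator conserves volume by construction: the net volume flux into every
#' box is zero, so a spatially uniform tracer is a fixed point.
#'
#' @param geom An `o2_geometry`.
#' @param cell_scale Named numeric scaling factors for cell strengths, e.g.
#'   `c(amoc = 1, so_abyssal = 0.8)`; missing names default to 1.  Negative
#'   results are never produced: scales are floored at 0.
#' @return An object of class `transport_op`: list with `flux` (n x n matrix,
#'   `flux[i, j]` = volume flux from box i to box j, m3/yr), `rate` (the
#'   tracer tendency matrix `A` with `dC/dt = A %*% C`), `volumes`, and the
#'   applied `cell_scale`.
#' @export
transport_operator <- function(geom, cell_scale = NULL) {
  boxes <- geom$boxes
  n <- nrow(boxes)
  ids <- boxes$box
  flux <- matrix(0, n, n, dimnames = list(ids, ids))
  sv <- 1e6 * SECONDS_PER_YEAR # Sv -> m3/yr
  scales <- setNames(rep(1, length(geom$cells)),
                     purrr::map_chr(geom$cells, "name"))
  if (!is.null(cell_scale)) {
    bad <- setdiff(names(cell_scale), names(scales))
    if (length(bad)) abort(paste0("unknown cell(s): ", paste(bad, collapse = ", ")),
                           class = "o2c_parameter_error")
    scales[names(cell_scale)] <- pmax(cell_scale, 0)
  }
  for (cell in geom$cells) {
    psi <- cell$psi_sv * sv * scales[[cell$name]]
    p <- cell$path
    for (k in seq_len(length(p) - 1)) {
      flux[p[k], p[k + 1]] <- flux[p[k], p[k + 1]] + psi
    }
  }
  for (mx in geom$mixing) {
    if (mx$sv < 0) abort("mixing exchanges must be non-negative.",
                         class = "o2c_parameter_error")
    f <- mx$sv * sv
    flux[mx$from, mx$to] <- flux[mx$from, mx$to] + f
    flux[mx$to, mx$from] <- flux[mx$to, mx$from] + f
  }
  net <- colSums(flux) - rowSums(flux)
  if (max(abs(net)) > 1e-6 * max(flux)) {
    abort("transport does not conserve volume (open cell path?).",
          class = "o2c_parameter_error")
  }
  rate <- sweep(t(flux), 1, boxes$volume, "/")
  diag(rate) <- diag(rate) - rowSums(flux) / boxes$volume
  structure(list(flux = flux, rate = rate, volumes = boxes$volume,
                 cell_scale = scales, boxes = ids),
            class = "transport_op")
}

#' Warming-driven modulation of the overturning
#'
#' Scales the two overturning cells in response to surface warming: the
#' Southern-sourced abyssal cell weakens linearly with the Southern Ocean
#' surface temperature anomaly (floored at a configured fraction of its
#' base strength), while the North Atlantic cell follows a dip-then-recovery
#' response -- an initial weakening proportional to the instantaneous North
#' Atlantic anomaly that relaxes, as the time-integrated anomaly grows, into
#' a strengthening above baseline.  The returned operator still conserves
#' volume exactly.
#'
#' @param geom An `o2_geometry`.
#' @param t_surf_anomaly Named numeric of surface-box temperature anomalies
#'   (degrees C vs pre-industrial); must include `surf_so` and `surf_natl`.
#' @param params The `transport` block of the configuration.
#' @param na_integral Time-integrated North Atlantic surface anomaly
#'   (degree C yr), accumulated by the runner.
#' @return A `transport_op` with scaled cell strengths.
#' @export
modulate_overturning <- function(geom, t_surf_anomaly, params, na_integral = 0) {
  floor_frac <- params$psi_floor_frac
  dt_so <- t_surf_anomaly[["surf_so"]]
  dt_na <- t_surf_anomaly[["surf_natl"]]
  s_so <- 1 - params$alpha_so_per_k * dt_so
  if (s_so < floor_frac) {
    warn("Southern cell scale hit its floor; clipping.")
    s_so <- floor_frac
  }
  w <- 1 - exp(-max(na_integral, 0) / params$amoc_integral_scale_k_yr)
  s_na <- 1 - params$amoc_dip_per_k * dt_na * (1 - w) + params$amoc_recovery_gain * w
  if (s_na < floor_frac) {
    warn("Atlantic cell scale hit its floor; clipping.")
    s_na <- floor_frac
  }
  transport_operator(geom, cell_scale = c(amoc = s_na, so_abyssal = s_so))
}
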