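#' Generate a seeded gridded temperature/oxygen field
#'
#' Builds a latitude x depth x basin field with the gross structure of the
#' observed ocean: a warm, well-oxygenated surface; cold deep water; an
#' oxygen minimum at low-latitude mid-depth with configurable amplitude
#' (able to produce suboxic values); and seeded Gaussian noise.  Cell
#' volumes follow `cos(latitude)` times layer thickness times basin share
#' and are normalised to the configured total ocean volume.  Identical
#' arguments and seed give bitwise-identical fields.
#'
#' @param n_lat,n_depth Grid resolution (default 36 latitude bands, 19
#'   depth levels with thickness growing from 50 m to 500 m).
#' @param total_volume Total ocean volume (m3).
#' @param omz_amplitude Relative depth of the oxygen-minimum zone in
#'   \[0, 1\]; 0 produces no water below the hypoxic threshold.
#' @param aou_deep Deep-water apparent oxygen utilization scale (mmol/m3).
#' @param noise_sd_t,noise_sd_o2 Noise standard deviations (C, mmol/m3).
#' @param salinity Constant salinity (psu).
#' @param seed Integer seed.
#' @return A tibble of class `o2_field` with columns `lat`, `depth`,
#'   `basin`, `region`, `depth_class`, `depth2000`, `volume`, `t`, `s`,
#'   `o2`.
#' @export
#' @examples
#' f <- generate_base_field(seed = 1)
#' sum(f$volume)
generate_base_field <- function(n_lat = 36, n_depth = 19,
                                total_volume = 1.3e18,
                                omz_amplitude = 0.85, aou_deep = 120,
                                noise_sd_t = 0.05, noise_sd_o2 = 2,
                                salinity = 34.7, seed = 1) {
  if (n_lat < 2 || n_depth < 2) {
    abort("resolution must be at least 2 x 2.", class = "o2c_parameter_error")
  }
  lat <- seq(-90 + 180 / n_lat / 2, 90 - 180 / n_lat / 2, length.out = n_lat)
  thick <- seq(50, 500, length.out = n_depth)
  edges <- c(0, cumsum(thick))
  depth <- (head(edges, -1) + tail(edges, -1)) / 2
  basins <- c("Atlantic", "Indo-Pacific", "Southern")
  grid <- tidyr::expand_grid(lat = lat, depth = depth, basin = basins)
  grid$dz <- thick[match(grid$depth, depth)]
  # basin shares: the Southern basin holds everything south of 50S
  share <- ifelse(grid$basin == "Southern", ifelse(grid$lat < -50, 1, 0),
                  ifelse(grid$lat < -50, 0,
                         ifelse(grid$basin == "Atlantic", 0.3, 0.7)))
  w <- cos(grid$lat * pi / 180) * grid$dz * share
  grid <- grid[w > 0, ]
  w <- w[w > 0]
  grid$volume <- w / sum(w) * total_volume
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_surf <- -1 + 29 * cos(grid$lat * pi / 180)^2
  grid$t <- 1.2 + (t_surf - 1.2) * exp(-grid$depth / 400) +
    rnorm(nrow(grid), sd = noise_sd_t)
  grid$t <- pmax(grid$t, -1.8)
  grid$s <- salinity
  sat <- o2_saturation(grid$t, grid$s)
  aou <- aou_deep * (1 - exp(-grid$depth / 600)) +
    omz_amplitude * sat * exp(-(grid$lat / 18)^2 - ((grid$depth - 450) / 350)^2)
  grid$o2 <- pmax(sat - aou + rnorm(nrow(grid), sd = noise_sd_o2), 0)
  out <- add_field_masks(dplyr::select(grid, -"dz"))
  class(out) <- c("o2_field", class(out))
  out
}

# latitude-band regions used by the regional budget table
LAT_BANDS <- c(-90, -50, -15, 15, 60, 90)
LAT_BAND_LABELS <- c("90S-50S", "50S-15S", "15S-15N", "15N-60N", "60N-90N")

add_field_masks <- function(grid) {
  band <- cut(grid$lat, LAT_BANDS, labels = LAT_BAND_LABELS, right = FALSE)
  grid$region <- ifelse(as.character(band) == "90S-50S", "Southern Ocean (90S-50S)",
                        paste0(grid$basin, " (", band, ")"))
  grid$depth_class <- ifelse(grid$depth <= 1200, "0-1200 m", ">1200 m")
  grid$depth2000 <- ifelse(grid$depth <= 2000, "above 2000 m", "below 2000 m")
  grid
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply per-mask linear trends to a gridded field
#'
#' Adds `rate * years / 100` anomalies to temperature and oxygen per mask
#' row plus seeded noise.  Oxygen is floored at zero; when the floor is hit
#' the returned field carries attribute `o2_floored = TRUE`.
#'
#' @param base An `o2_field` from [generate_base_field()].
#' @param trend A data frame of per-mask rates with any subset of the mask
#'   columns (`region`, `depth_class`, `depth2000`, `basin`) plus
#'   `dt_per_century` (C/100 yr) and `do2_per_century` (mmol/m3 per 100 yr).
#'   Cells matching no row keep zero rates.
#' @param years Duration over which the trend acts (yr).
#' @param noise_sd_t,noise_sd_o2 Noise standard deviations added on top.
#' @param seed Integer seed for the noise.
#' @return The trended `o2_field`.
#' @export
apply_trend <- function(base, trend, years, noise_sd_t = 0, noise_sd_o2 = 0,
                        seed = 1) {
  mask_cols <- intersect(c("region", "depth_class", "depth2000", "basin"),
                         names(trend))
  if (!length(mask_cols)) {
    abort("`trend` must carry at least one mask column.", class = "o2c_parameter_error")
  }
  joined <- dplyr::left_join(base, trend, by = mask_cols)
  dt_rate <- dplyr::coalesce(joined$dt_per_century, 0)
  do2_rate <- dplyr::coalesce(joined$do2_per_century, 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- base
  out$t <- base$t + dt_rate * years / 100 +
    if (noise_sd_t > 0) rnorm(nrow(base), sd = noise_sd_t) else 0
  o2 <- base$o2 + do2_rate * years / 100 +
    if (noise_sd_o2 > 0) rnorm(nrow(base), sd = noise_sd_o2) else 0
  floored <- any(o2 < 0)
  out$o2 <- pmax(o2, 0)
  attr(out, "o2_floored") <- floored
  out
}
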