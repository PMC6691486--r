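#' Solar position for a UTC instant
#'
#' NOAA-style series solution: fractional-year expansion of declination,
#' equation of time and Earth-Sun distance, then hour angle, zenith and
#' azimuth. Accuracy is a few hundredths of a degree over the satellite era
#' — far inside the sub-0.5 degree requirement for hourly terrain work.
#'
#' @param timestamp A `POSIXct` instant (UTC).
#' @param latitude,longitude Site coordinates in degrees (east positive).
#' @return A `solar_position` list: `zenith`, `elevation`, `azimuth`
#'   (degrees, azimuth clockwise from north), `declination`, `hour_angle`
#'   (degrees), `earth_sun_factor` (squared-distance eccentricity
#'   correction) and `timestamp`.
#' @export
solar_position <- function(timestamp, latitude, longitude) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90")
  t <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- t$yday + 1L
  frac_hour <- t$hour + t$min / 60 + t$sec / 3600
  n_year <- ifelse((t$year + 1900) %% 4 == 0, 366, 365)
  g <- 2 * pi / n_year * (doy - 1 + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
             0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
             0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) * 180 / pi
  esf <- 1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
  tst <- frac_hour * 60 + eqtime + 4 * longitude # true solar time, minutes
  ha <- tst / 4 - 180
  ha <- ((ha + 180) %% 360) - 180
  lat_r <- latitude * pi / 180
  dec_r <- decl * pi / 180
  ha_r <- ha * pi / 180
  cos_zen <- sin(lat_r) * sin(dec_r) + cos(lat_r) * cos(dec_r) * cos(ha_r)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen) * 180 / pi
  # azimuth clockwise from north
  az <- atan2(sin(ha_r),
              cos(ha_r) * sin(lat_r) - tan(dec_r) * cos(lat_r)) * 180 / pi
  az <- (az + 180) %% 360
  structure(list(zenith = zen, elevation = 90 - zen, azimuth = az,
                 declination = decl, hour_angle = ha,
                 earth_sun_factor = esf, timestamp = timestamp),
            class = "solar_position")
}

#' Split global irradiance into direct and diffuse components
#'
#' Clearness-index partitioning: the clearness index `kt` is measured GHI
#' over extraterrestrial horizontal irradiance, and the diffuse fraction
#' follows the Erbs piecewise correlation. DNI is recovered from the direct
#' horizontal remainder with the zenith cosine floored at
#' `cos_zenith_floor` to avoid blow-up near sunrise/sunset.
#'
#' @param ghi Global horizontal irradiance, W m^-2 (>= 0).
#' @param position A [solar_position].
#' @param coefficients Optional list overriding the Erbs coefficients:
#'   `kt_low`, `kt_high`, `poly` (degree-4 coefficients, constant first),
#'   `f_low_slope`, `f_high`.
#' @param cos_zenith_floor Floor on cos(zenith) in the DNI division.
#' @return An `irradiance_components` list: `ghi`, `dni`, `dhi`,
#'   `clearness_index`.
#' @export
partition_direct_diffuse <- function(ghi, position, coefficients = NULL,
                                     cos_zenith_floor = 0.01) {
  if (ghi < 0) stop("'ghi' must be non-negative")
  cf <- coefficients %||% list(
    kt_low = 0.22, kt_high = 0.80,
    f_low_slope = 0.09,
    poly = c(0.9511, -0.1604, 4.388, -16.638, 12.336),
    f_high = 0.165)
  cz <- cos(position$zenith * pi / 180)
  if (cz <= 0 || ghi == 0) {
    return(structure(list(ghi = ghi, dni = 0, dhi = ghi, clearness_index = 0),
                     class = "irradiance_components"))
  }
  e0 <- SOLAR_CONSTANT * position$earth_sun_factor * cz
  kt <- ghi / e0
  fd <- if (kt <= cf$kt_low) {
    1 - cf$f_low_slope * kt
  } else if (kt <= cf$kt_high) {
    sum(cf$poly * kt^(0:4))
  } else {
    cf$f_high
  }
  fd <- min(1, max(0, fd))
  dhi <- fd * ghi
  dni <- max(0, (ghi - dhi) / max(cz, cos_zenith_floor))
  structure(list(ghi = ghi, dni = dni, dhi = dhi, clearness_index = kt),
            class = "irradiance_components")
}

#' Cast-shadow mask from terrain horizon angles
#'
#' A cell is shadowed when the terrain horizon angle toward the sun's
#' azimuth (interpolated linearly between the two adjacent search
#' directions) is at least the solar elevation. The whole grid is shadowed
#' when the sun is below the astronomical horizon.
#'
#' @param derivatives `terrain_derivatives` with horizon angles.
#' @param position A [solar_position].
#' @return Logical matrix, `TRUE` = shadowed (`NA` on nodata cells).
#' @export
cast_shadow_mask <- function(derivatives, position) {
  h <- derivatives$horizon_angles
  if (is.null(h)) stop("horizon angles missing; run compute_horizon_angles()")
  nr <- dim(h)[1]; nc <- dim(h)[2]; nd <- dim(h)[3]
  nodata <- is.na(h[, , 1])
  if (position$elevation <= 0) {
    m <- matrix(TRUE, nr, nc); m[nodata] <- NA
    return(m)
  }
  step <- 360 / nd
  pos_idx <- position$azimuth / step      # fractional direction index, 0-based
  i0 <- floor(pos_idx) %% nd
  w <- pos_idx - floor(pos_idx)
  i1 <- (i0 + 1) %% nd
  h_sun <- (1 - w) * h[, , i0 + 1] + w * h[, , i1 + 1]
  m <- h_sun >= position$elevation
  m[nodata] <- NA
  m
}

#' Downscale irradiance to per-cell incident shortwave flux
#'
#' Direct beam projected onto each tilted cell (zeroed in cast shadow),
#' plus isotropic diffuse weighted by the sky view factor, plus ground
#' reflection from the obstructed part of the hemisphere:
#' `flux = dni * cos(theta_i) * (1 - shadow) + dhi * svf
#'         + ghi * ground_albedo * (1 - svf)`
#' with `cos(theta_i)` the beam/surface-normal cosine, clamped at 0.
#'
#' @param components An `irradiance_components` (from
#'   [partition_direct_diffuse]).
#' @param derivatives Complete `terrain_derivatives` (slope, aspect, svf,
#'   horizon angles).
#' @param position A [solar_position].
#' @param ground_albedo Reflectivity of the surrounding terrain
#'   (dimensionless; 0.15 = dark rock).
#' @param shadow Optional precomputed shadow mask (logical matrix); computed
#'   from the horizon angles when `NULL`.
#' @return An `incident_field` list: `flux` (W m^-2 matrix), `shadow`
#'   (logical matrix), `position`, `components`.
#' @export
incident_shortwave <- function(components, derivatives, position,
                               ground_albedo = 0.15, shadow = NULL) {
  if (is.null(derivatives$svf)) stop("svf missing; run compute_svf()")
  if (is.null(shadow)) shadow <- cast_shadow_mask(derivatives, position)
  zen_r <- position$zenith * pi / 180
  slope_r <- derivatives$slope * pi / 180
  daz_r <- (position$azimuth - derivatives$aspect) * pi / 180
  cos_inc <- cos(zen_r) * cos(slope_r) + sin(zen_r) * sin(slope_r) * cos(daz_r)
  cos_inc <- pmax(cos_inc, 0)
  sunlit <- !shadow & position$elevation > 0
  sunlit[is.na(sunlit)] <- FALSE
  flux <- components$dni * cos_inc * sunlit +
    components$dhi * derivatives$svf +
    components$ghi * ground_albedo * (1 - derivatives$svf)
  flux[is.na(derivatives$svf) | is.na(derivatives$slope)] <- NA
  structure(list(flux = flux, shadow = shadow, position = position,
                 components = components),
            class = "incident_field")
}

#' Clear-sky global horizontal irradiance
#'
#' Simple Beer-law clear-sky curve for synthetic forcing:
#' `ghi = S0 * earth_sun_factor * tau^(1/cos(zenith)) * cos(zenith)`,
#' zero when the sun is below the horizon. The exponent's cosine is floored
#' to keep the optical path finite at grazing incidence.
#'
#' @param position A [solar_position].
#' @param transmittance Broadband atmospheric transmittance in (0, 1].
#' @param cos_zenith_floor Floor on cos(zenith) in the air-mass exponent.
#' @return GHI in W m^-2.
#' @export
clear_sky_ghi <- function(position, transmittance = 0.75,
                          cos_zenith_floor = 0.01) {
  if (transmittance <= 0 || transmittance > 1) {
    stop("'transmittance' must be in (0, 1]")
  }
  cz <- cos(position$zenith * pi / 180)
  if (cz <= 0) return(0)
  SOLAR_CONSTANT * position$earth_sun_factor *
    transmittance^(1 / max(cz, cos_zenith_floor)) * cz
}
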