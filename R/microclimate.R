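# ISO-8601 UTC parser tolerant of "T" separators and a trailing "Z"
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) stop("unparseable UTC timestamp(s)")
  out
}

#' Read hourly weather forcing from CSV
#'
#' Expected columns: `timestamp` (ISO-8601, UTC), `air_temperature_C`,
#' `wind_speed_ms`, `ghi_wm2`, `water_temperature_C`.
#'
#' @param path CSV path.
#' @return Data frame with columns `timestamp` (POSIXct UTC),
#'   `air_temperature`, `wind_speed`, `ghi`, `water_temperature`.
#' @export
read_weather_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "air_temperature_C", "wind_speed_ms", "ghi_wm2",
            "water_temperature_C")
  if (!all(need %in% names(d))) {
    stop("weather CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    timestamp = parse_utc(d$timestamp),
    air_temperature = d$air_temperature_C,
    wind_speed = d$wind_speed_ms,
    ghi = d$ghi_wm2,
    water_temperature = d$water_temperature_C)
  validate_weather(out)
  out
}

validate_weather <- function(w) {
  if (any(w$wind_speed < 0, na.rm = TRUE)) stop("wind_speed must be >= 0")
  if (any(w$ghi < 0, na.rm = TRUE)) stop("ghi must be >= 0")
  if (is.unsorted(w$timestamp, strictly = TRUE)) {
    stop("weather timestamps must be strictly increasing")
  }
  invisible(w)
}

#' Write hourly weather forcing to CSV
#' @param weather Weather data frame (see [read_weather_csv] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  out <- data.frame(
    timestamp = format(weather$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    air_temperature_C = weather$air_temperature,
    wind_speed_ms = weather$wind_speed,
    ghi_wm2 = weather$ghi,
    water_temperature_C = weather$water_temperature)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a still-tide water-level series from CSV
#'
#' Expected columns: `timestamp` (ISO-8601, UTC) and `level_m` (metres
#' above the elevation datum).
#'
#' @param path CSV path.
#' @return Data frame with `timestamp` (POSIXct UTC) and `level`.
#' @export
read_tide_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "level_m") %in% names(d))) {
    stop("tide CSV must have columns: timestamp, level_m")
  }
  out <- data.frame(timestamp = parse_utc(d$timestamp),
                    level = d$level_m)
  if (is.unsorted(out$timestamp, strictly = TRUE)) {
    stop("tide timestamps must be strictly increasing")
  }
  out
}

#' Write a tide series to CSV
#' @param tide Tide data frame (`timestamp`, `level`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tide_csv <- function(tide, path) {
  out <- data.frame(
    timestamp = format(tide$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    level_m = tide$level)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Heat-budget parameter set
#'
#' Parameters of the steady-state rock-surface energy balance. Defaults are
#' standard biophysical values for dark intertidal rock; every one is a knob.
#'
#' @param shortwave_absorptivity Shortwave absorptivity alpha in (0, 1].
#' @param emissivity Thermal (longwave) emissivity epsilon in (0, 1].
#' @param conv_a,conv_b,conv_h0 Convection coefficient model
#'   `h_c = conv_h0 + conv_a * wind_speed^conv_b` (W m^-2 K^-1); `conv_h0`
#'   is the still-air floor.
#' @param substrate_conductance Linear conductance g_k to the deep substrate
#'   (W m^-2 K^-1).
#' @param substrate_temperature `"trailing_mean"` (trailing 24 h mean air
#'   temperature) or a fixed number in degrees C.
#' @param sky_emissivity `"swinbank"` (clear-sky emissivity
#'   `9.37e-6 * T_a[K]^2`) or a fixed number in (0, 1].
#' @param ground_albedo Terrain reflectivity used for the reflected
#'   shortwave term.
#' @return A `heat_budget_params` list.
#' @export
heat_budget_params <- function(shortwave_absorptivity = 0.75,
                               emissivity = 0.95,
                               conv_a = 4, conv_b = 0.8, conv_h0 = 5,
                               substrate_conductance = 10,
                               substrate_temperature = "trailing_mean",
                               sky_emissivity = "swinbank",
                               ground_albedo = 0.15) {
  stopifnot(shortwave_absorptivity > 0, shortwave_absorptivity <= 1,
            emissivity > 0, emissivity <= 1,
            conv_a >= 0, conv_h0 >= 0, substrate_conductance >= 0)
  if (is.numeric(sky_emissivity) &&
      (sky_emissivity <= 0 || sky_emissivity > 1)) {
    stop("numeric 'sky_emissivity' must be in (0, 1]")
  }
  structure(list(shortwave_absorptivity = shortwave_absorptivity,
                 emissivity = emissivity,
                 conv_a = conv_a, conv_b = conv_b, conv_h0 = conv_h0,
                 substrate_conductance = substrate_conductance,
                 substrate_temperature = substrate_temperature,
                 sky_emissivity = sky_emissivity,
                 ground_albedo = ground_albedo),
            class = "heat_budget_params")
}

sky_emissivity_value <- function(params, air_temperature_c) {
  if (is.numeric(params$sky_emissivity)) return(params$sky_emissivity)
  # Swinbank clear-sky correlation; ghi forcing already carries clouds
  9.37e-6 * (air_temperature_c + 273.15)^2
}

#' Emersion mask from a still tide level
#'
#' Still-water approximation: a cell is aerially exposed iff its elevation
#' exceeds the tide level. No wave runup or splash.
#'
#' @param dem An [elevation_grid].
#' @param tide_level Still water level, metres above the DEM's datum.
#' @return Logical matrix, `TRUE` = exposed (`NA` on nodata cells).
#' @export
exposure_mask <- function(dem, tide_level) {
  if (!is.finite(tide_level)) stop("'tide_level' must be finite")
  dem$values > tide_level
}

# Energy-balance residual (W m^-2) at surface temperature ts_k (kelvin),
# vectorised over cells. Positive residual => surface below equilibrium.
heat_budget_residual <- function(ts_k, absorbed_sw, ta_k, tsub_k, svf,
                                 eps_sky, h_c, params) {
  eps <- params$emissivity
  lw_in <- eps * SIGMA_SB * (svf * eps_sky * ta_k^4 + (1 - svf) * ta_k^4)
  absorbed_sw + lw_in - eps * SIGMA_SB * ts_k^4 -
    h_c * (ts_k - ta_k) - params$substrate_conductance * (ts_k - tsub_k)
}

#' Solve the steady-state surface heat budget
#'
#' Each exposed cell balances absorbed shortwave, sky and terrain longwave
#' (weighted by the sky view factor, surroundings radiating at air
#' temperature), its own thermal emission, wind-driven convection and
#' linear conduction to the substrate:
#' \deqn{\alpha I + \epsilon\sigma[s\,\epsilon_{sky}T_a^4 + (1-s)T_a^4]
#'   - \epsilon\sigma T_s^4 - h_c (T_s - T_a) - g_k (T_s - T_{sub}) = 0}
#' The root is bracketed in `[T_a - 30, T_a + 60]` K and found by bisection
#' to an interval width of 1e-4 K, which keeps the residual at the returned
#' root below 0.1 W m^-2. Submerged cells are set to water temperature
#' exactly.
#'
#' @param incident An `incident_field` (or bare flux matrix, W m^-2).
#' @param weather One row of a weather data frame (list with
#'   `air_temperature`, `wind_speed`, `water_temperature`, all scalar).
#' @param derivatives `terrain_derivatives` with `svf`.
#' @param params A [heat_budget_params].
#' @param exposure Logical exposure matrix (from [exposure_mask]).
#' @param substrate_temperature Scalar substrate temperature in degrees C;
#'   required when `params$substrate_temperature` is `"trailing_mean"` and
#'   the caller has the trailing mean at hand (e.g. [run_simulation]);
#'   defaults to air temperature when `NULL`.
#' @return A `temperature_field`: list with `timestamp`, `values` (degrees C
#'   matrix; water temperature on submerged cells, `NA` on nodata/edge
#'   cells), `exposure` (logical matrix).
#' @export
solve_surface_temperature <- function(incident, weather, derivatives, params,
                                      exposure,
                                      substrate_temperature = NULL) {
  flux <- if (inherits(incident, "incident_field")) incident$flux else incident
  svf <- derivatives$svf
  if (is.null(svf)) stop("svf missing; run compute_svf()")
  if (!all(dim(flux) == dim(svf)) || !all(dim(exposure) == dim(svf))) {
    stop("flux, svf and exposure grids must be congruent")
  }
  ta <- weather$air_temperature
  ta_k <- ta + 273.15
  tsub_c <- if (!is.null(substrate_temperature)) {
    substrate_temperature
  } else if (is.numeric(params$substrate_temperature)) {
    params$substrate_temperature
  } else {
    ta
  }
  tsub_k <- tsub_c + 273.15
  eps_sky <- sky_emissivity_value(params, ta)
  h_c <- params$conv_h0 + params$conv_a * weather$wind_speed^params$conv_b

  solve_mask <- exposure & !is.na(flux) & !is.na(svf)
  solve_mask[is.na(solve_mask)] <- FALSE
  out <- matrix(NA_real_, nrow(flux), ncol(flux))
  submerged <- !exposure
  submerged[is.na(submerged)] <- FALSE
  out[submerged] <- weather$water_temperature

  if (any(solve_mask)) {
    a_sw <- params$shortwave_absorptivity * flux[solve_mask]
    s <- svf[solve_mask]
    lo <- rep(ta_k - 30, length(a_sw))
    hi <- rep(ta_k + 60, length(a_sw))
    f_lo <- heat_budget_residual(lo, a_sw, ta_k, tsub_k, s, eps_sky, h_c, params)
    f_hi <- heat_budget_residual(hi, a_sw, ta_k, tsub_k, s, eps_sky, h_c, params)
    bad <- f_lo < 0 | f_hi > 0  # root not bracketed (residual decreasing in T)
    while (max(hi - lo) > 1e-4) {
      mid <- (lo + hi) / 2
      f_mid <- heat_budget_residual(mid, a_sw, ta_k, tsub_k, s, eps_sky, h_c,
                                    params)
      take_hi <- f_mid > 0  # root above mid
      lo <- ifelse(take_hi, mid, lo)
      hi <- ifelse(take_hi, hi, mid)
    }
    ts <- (lo + hi) / 2 - 273.15
    ts[bad] <- NA_real_
    if (any(bad)) {
      warning(sprintf("heat-budget root not bracketed for %d cell(s); set to NA",
                      sum(bad)))
    }
    out[solve_mask] <- ts
  }
  structure(list(timestamp = weather$timestamp %||% NA, values = out,
                 exposure = exposure),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  ex <- x$exposure & !is.na(x$values)
  cat(sprintf("<temperature_field> %s: %d exposed cells, %.1f..%.1f degC\n",
              format(x$timestamp), sum(ex, na.rm = TRUE),
              suppressWarnings(min(x$values[ex], na.rm = TRUE)),
              suppressWarnings(max(x$values[ex], na.rm = TRUE))))
  invisible(x)
}

# trailing 24 h mean air temperature up to and including hour i
trailing_mean_air <- function(weather, i, window_h = 24) {
  j <- max(1L, i - window_h + 1L)
  mean(weather$air_temperature[j:i])
}

#' Run an hourly microclimate simulation
#'
#' The full per-hour chain: solar position, direct/diffuse split, cast
#' shadows, per-cell incident flux, tide exposure mask, heat-budget surface
#' temperature. Forcing must cover every requested hour exactly (no silent
#' interpolation).
#'
#' @param dem An [elevation_grid].
#' @param derivatives Complete `terrain_derivatives` for `dem`.
#' @param weather Hourly weather data frame (see [read_weather_csv]).
#' @param tide Hourly tide data frame (see [read_tide_csv]).
#' @param params A [heat_budget_params].
#' @param latitude,longitude Site coordinates, degrees.
#' @param times POSIXct vector of hours to simulate; default every weather
#'   timestamp.
#' @return List of `temperature_field`, one per hour, with attribute
#'   `provenance` (parameters and software version).
#' @export
run_simulation <- function(dem, derivatives, weather, tide, params,
                           latitude, longitude, times = weather$timestamp) {
  validate_weather(weather)
  wi <- match(times, weather$timestamp)
  ti <- match(times, tide$timestamp)
  if (anyNA(wi)) stop("missing weather forcing for ",
                      format(times[which(is.na(wi))[1]]))
  if (anyNA(ti)) stop("missing tide forcing for ",
                      format(times[which(is.na(ti))[1]]))
  fields <- vector("list", length(times))
  for (k in seq_along(times)) {
    i <- wi[k]
    w <- weather[i, ]
    pos <- solar_position(times[k], latitude, longitude)
    comp <- partition_direct_diffuse(w$ghi, pos)
    inc <- incident_shortwave(comp, derivatives, pos,
                              ground_albedo = params$ground_albedo)
    expo <- exposure_mask(dem, tide$level[ti[k]])
    tsub <- if (identical(params$substrate_temperature, "trailing_mean")) {
      trailing_mean_air(weather, i)
    } else {
      params$substrate_temperature
    }
    fields[[k]] <- solve_surface_temperature(inc, w, derivatives, params,
                                             expo,
                                             substrate_temperature = tsub)
  }
  attr(fields, "provenance") <- list(
    package_version = as.character(packageVersion("thermalscape")),
    latitude = latitude, longitude = longitude,
    params = unclass(params),
    n_hours = length(times),
    times = format(times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  fields
}
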