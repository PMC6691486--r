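# Run expr with a private RNG stream: seed locally, restore global state
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic DEM generator
#'
#' Deterministic test terrains for every pipeline stage:
#' \describe{
#'   \item{plane}{`z = base + slope_x * x + slope_y * y` (northing up).}
#'   \item{sinusoid}{`z = base + amplitude * sin(2 pi x / wavelength)`.}
#'   \item{gaussian_field}{Self-affine random surface by spectral synthesis
#'     (power-law amplitude spectrum `|k|^(spectral_exponent/2)`), rescaled
#'     so its plane-detrended roughness matches `target_rq` when given.}
#'   \item{pit}{A flat plane with a square depression of depth `amplitude`
#'     in the centre.}
#'   \item{step}{Flat plane with the eastern half raised by `amplitude`
#'     (a wall for shadow/horizon geometry).}
#' }
#'
#' @param kind Terrain kind (see above).
#' @param shape `c(rows, cols)`, at least 3x3.
#' @param cell_size Cell edge length, metres.
#' @param base Base elevation above the tidal datum, metres.
#' @param amplitude Relief parameter, metres (sinusoid/pit/step).
#' @param wavelength Sinusoid wavelength, metres.
#' @param slope_x,slope_y Plane gradients (m per m, east / north).
#' @param target_rq Target plane-detrended Rq, metres (gaussian_field).
#' @param spectral_exponent Power-spectrum exponent (gaussian_field;
#'   -2 = rock-like self-affine relief).
#' @param seed Integer seed (gaussian_field); same seed, same grid.
#' @return An [elevation_grid].
#' @export
synthetic_dem <- function(kind = c("plane", "sinusoid", "gaussian_field",
                                   "pit", "step"),
                          shape = c(48, 48), cell_size = 0.02,
                          base = 0, amplitude = 0.5, wavelength = 0.5,
                          slope_x = 0, slope_y = 0,
                          target_rq = NULL, spectral_exponent = -2,
                          seed = 1) {
  kind <- match.arg(kind)
  if (any(shape < 3)) stop("'shape' must be at least 3x3")
  nr <- shape[1]; nc <- shape[2]
  x <- matrix((seq_len(nc) - 1) * cell_size, nr, nc, byrow = TRUE)
  # row 1 is the northern edge: northing decreases with row index
  y <- matrix((nr - seq_len(nr)) * cell_size, nr, nc)
  z <- switch(kind,
    plane = base + slope_x * x + slope_y * y,
    sinusoid = base + amplitude * sin(2 * pi * x / wavelength),
    pit = {
      m <- matrix(base, nr, nc)
      ri <- seq(floor(nr / 3), ceiling(2 * nr / 3))
      ci <- seq(floor(nc / 3), ceiling(2 * nc / 3))
      m[ri, ci] <- base - amplitude
      m
    },
    step = {
      m <- matrix(base, nr, nc)
      m[, seq(ceiling(nc / 2 + 1), nc)] <- base + amplitude
      m
    },
    gaussian_field = base + gaussian_surface(nr, nc, spectral_exponent, seed))
  g <- elevation_grid(z, cell_size)
  if (kind == "gaussian_field" && !is.null(target_rq)) {
    rq0 <- surface_roughness_rq(g)
    # Rq scales linearly with the field, so one rescale of the detrended
    # relief hits the set-point exactly
    fit_plane <- z - residual_field(g)
    g$values <- fit_plane + residual_field(g) * (target_rq / rq0)
  }
  g
}

# plane-detrended residual field of an elevation grid
residual_field <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  X <- cbind(1, idx$col * dem$cell_size, idx$row * dem$cell_size)
  fit <- lm.fit(X, as.vector(z))
  matrix(fit$residuals, nr, nc)
}

# spectral synthesis of a zero-mean self-affine surface
gaussian_surface <- function(nr, nc, spectral_exponent, seed) {
  with_private_seed(seed, {
    fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
    fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
    k <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- ifelse(k > 0, k^(spectral_exponent / 2), 0)
    phase <- matrix(runif(nr * nc, 0, 2 * pi), nr, nc)
    spec <- amp * exp(1i * phase)
    z <- Re(fft(spec, inverse = TRUE)) / (nr * nc)
    z - mean(z)
  })
}

#' Forcing specification for synthetic weather and tide
#'
#' Collects the knobs of a clear-sky diurnal weather cycle and a harmonic
#' tide. Defaults describe a warm mid-latitude summer day at a New England
#' rocky shore.
#'
#' @param start UTC start instant (`POSIXct` or ISO-8601 string); hourly
#'   records begin here.
#' @param n_days Number of simulated days (>= 1).
#' @param latitude,longitude Site coordinates, degrees.
#' @param air_mean Mean air temperature, degrees C.
#' @param air_amplitude Diurnal half-range of air temperature, degrees C
#'   (peak mid-afternoon local solar time).
#' @param transmittance Clear-sky atmospheric transmittance (0, 1].
#' @param wind_mean Mean wind speed, m s^-1.
#' @param wind_ar1 AR(1) coefficient for hourly wind anomalies in `[0, 1)`;
#'   0 gives constant wind.
#' @param wind_sd Innovation s.d. of the wind anomaly, m s^-1.
#' @param water_temperature Sea water temperature, degrees C (constant).
#' @param tide_amplitude Tidal half-range, metres.
#' @param tide_period Tidal period, hours (12.42 = principal lunar
#'   semidiurnal).
#' @param tide_phase Phase offset, radians.
#' @param datum_offset Mean water level above the elevation datum, metres.
#' @param seed Integer seed for the stochastic parts (wind).
#' @return A `forcing_spec` list.
#' @export
forcing_spec <- function(start = "2017-06-22 00:00:00", n_days = 1,
                         latitude = 42.508, longitude = -70.843,
                         air_mean = 24, air_amplitude = 4,
                         transmittance = 0.75,
                         wind_mean = 2, wind_ar1 = 0, wind_sd = 0.5,
                         water_temperature = 16,
                         tide_amplitude = 1.5, tide_period = 12.42,
                         tide_phase = 0, datum_offset = 0, seed = 1) {
  if (n_days < 1) stop("'n_days' must be >= 1")
  if (air_amplitude < 0 || tide_amplitude < 0) {
    stop("amplitudes must be >= 0")
  }
  start <- as.POSIXct(start, tz = "UTC")
  structure(list(start = start, n_days = n_days,
                 latitude = latitude, longitude = longitude,
                 air_mean = air_mean, air_amplitude = air_amplitude,
                 transmittance = transmittance,
                 wind_mean = wind_mean, wind_ar1 = wind_ar1,
                 wind_sd = wind_sd,
                 water_temperature = water_temperature,
                 tide_amplitude = tide_amplitude,
                 tide_period = tide_period, tide_phase = tide_phase,
                 datum_offset = datum_offset, seed = seed),
            class = "forcing_spec")
}

forcing_times <- function(spec) {
  spec$start + 3600 * (seq_len(spec$n_days * 24) - 1)
}

#' Synthetic hourly weather series
#'
#' Clear-sky GHI from the solar geometry at the spec's site, a sinusoidal
#' diurnal air-temperature cycle peaking mid-afternoon local solar time,
#' constant or AR(1) wind, constant water temperature. Deterministic for a
#' fixed seed.
#'
#' @param spec A [forcing_spec].
#' @return Hourly weather data frame (columns as in [read_weather_csv]).
#' @export
synthetic_weather <- function(spec) {
  times <- forcing_times(spec)
  ghi <- vapply(seq_along(times), function(i) {
    clear_sky_ghi(solar_position(times[i], spec$latitude, spec$longitude),
                  spec$transmittance)
  }, numeric(1))
  # local solar hour; diurnal peak at 15:00
  solar_hour <- (as.numeric(times) / 3600 + spec$longitude / 15) %% 24
  air <- spec$air_mean +
    spec$air_amplitude * sin(2 * pi * (solar_hour - 9) / 24)
  wind <- if (spec$wind_ar1 > 0) {
    with_private_seed(spec$seed + 1L, {
      n <- length(times)
      a <- numeric(n)
      innov <- rnorm(n, 0, spec$wind_sd)
      for (i in 2:n) a[i] <- spec$wind_ar1 * a[i - 1] + innov[i]
      pmax(0, spec$wind_mean + a)
    })
  } else {
    rep(spec$wind_mean, length(times))
  }
  data.frame(timestamp = times, air_temperature = air, wind_speed = wind,
             ghi = ghi, water_temperature = spec$water_temperature)
}

#' Synthetic harmonic tide series
#'
#' `level(t) = datum_offset + tide_amplitude * sin(2 pi t / period + phase)`
#' sampled hourly from the spec's start; `t` is hours since the start.
#'
#' @param spec A [forcing_spec].
#' @return Tide data frame (`timestamp`, `level`).
#' @export
synthetic_tide <- function(spec) {
  times <- forcing_times(spec)
  t_h <- as.numeric(times - spec$start, units = "hours")
  data.frame(timestamp = times,
             level = spec$datum_offset + spec$tide_amplitude *
               sin(2 * pi * t_h / spec$tide_period + spec$tide_phase))
}
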