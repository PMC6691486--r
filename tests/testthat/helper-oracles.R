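# Independent oracles and small fixture builders. Everything here is
# deliberately written the slow, obvious way, separate from the package's
# code paths.

# Fine-step horizon-angle scan in plain R: bilinear sampling every
# `step_frac` of a cell along each azimuth, out to max_radius, starting at
# `start_frac` cells from the centre (angles inside the first cell are below
# the method's resolution by construction).
oracle_horizon <- function(values, cell_size, n_directions, max_radius,
                           step_frac = 0.25, start_frac = step_frac) {
  nr <- nrow(values); nc <- ncol(values)
  bil <- function(r, c) {
    if (r < 1 || c < 1 || r > nr || c > nc) return(NA_real_)
    r0 <- min(floor(r), nr - 1); c0 <- min(floor(c), nc - 1)
    fr <- r - r0; fc <- c - c0
    z <- values[r0:(r0 + 1), c0:(c0 + 1)]
    if (anyNA(z)) return(NA_real_)
    z[1, 1] * (1 - fr) * (1 - fc) + z[1, 2] * (1 - fr) * fc +
      z[2, 1] * fr * (1 - fc) + z[2, 2] * fr * fc
  }
  out <- array(NA_real_, c(nr, nc, n_directions))
  fracs <- seq(start_frac, max_radius / cell_size + 1e-9, by = step_frac)
  for (k in seq_len(n_directions)) {
    az <- 2 * pi * (k - 1) / n_directions
    de <- sin(az); dn <- cos(az)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      z0 <- values[i, j]
      if (is.na(z0)) next
      best <- 0
      for (f in fracs) {
        d <- f * cell_size
        zp <- bil(i - dn * f, j + de * f)
        if (is.na(zp)) break
        best <- max(best, atan2(zp - z0, d))
      }
      out[i, j, k] <- best * 180 / pi
    }
  }
  out
}

# Exhaustive shadow ray-trace toward the sun for one cell: shadowed if any
# finely sampled point along the sun azimuth rises above the beam.
oracle_shadow <- function(values, cell_size, sun_azimuth, sun_elevation,
                          max_radius, step_frac = 0.25) {
  nr <- nrow(values); nc <- ncol(values)
  az <- sun_azimuth * pi / 180
  de <- sin(az); dn <- cos(az)
  n_steps <- floor(max_radius / (cell_size * step_frac) + 1e-9)
  out <- matrix(NA, nr, nc)
  bil <- function(r, c) {
    if (r < 1 || c < 1 || r > nr || c > nc) return(NA_real_)
    r0 <- min(floor(r), nr - 1); c0 <- min(floor(c), nc - 1)
    fr <- r - r0; fc <- c - c0
    z <- values[r0:(r0 + 1), c0:(c0 + 1)]
    if (anyNA(z)) return(NA_real_)
    z[1, 1] * (1 - fr) * (1 - fc) + z[1, 2] * (1 - fr) * fc +
      z[2, 1] * fr * (1 - fc) + z[2, 2] * fr * fc
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    z0 <- values[i, j]
    if (is.na(z0)) next
    shadowed <- FALSE
    for (s in seq_len(n_steps)) {
      d <- s * step_frac * cell_size
      zp <- bil(i - dn * s * step_frac, j + de * s * step_frac)
      if (is.na(zp)) break
      if (atan2(zp - z0, d) * 180 / pi >= sun_elevation) {
        shadowed <- TRUE
        break
      }
    }
    out[i, j] <- shadowed
  }
  out
}

# Heat-budget equilibrium by exhaustive residual scan (independent of the
# package's bisection): minimises |residual| on a fine temperature grid.
oracle_surface_temperature <- function(absorbed_sw, ta_c, tsub_c, svf,
                                       eps_sky, h_c, alpha_ignored = NULL,
                                       emissivity = 0.95, g_k = 10,
                                       step = 5e-4) {
  sigma <- 5.670374419e-8
  ta <- ta_c + 273.15
  tsub <- tsub_c + 273.15
  ts <- seq(ta - 30, ta + 60, by = step)
  res <- absorbed_sw +
    emissivity * sigma * (svf * eps_sky * ta^4 + (1 - svf) * ta^4) -
    emissivity * sigma * ts^4 - h_c * (ts - ta) - g_k * (ts - tsub)
  ts[which.min(abs(res))] - 273.15
}

# Erbs diffuse fraction, written out directly
oracle_erbs <- function(kt) {
  if (kt <= 0.22) return(1 - 0.09 * kt)
  if (kt <= 0.80) {
    return(0.9511 - 0.1604 * kt + 4.388 * kt^2 - 16.638 * kt^3 +
             12.336 * kt^4)
  }
  0.165
}

# temperature_field built by hand
make_temp_field <- function(values, exposure = NULL,
                            timestamp = as.POSIXct("2017-06-22 16:00",
                                                   tz = "UTC")) {
  values <- as.matrix(values)
  if (is.null(exposure)) exposure <- !is.na(values)
  structure(list(timestamp = timestamp, values = values,
                 exposure = exposure),
            class = "temperature_field")
}

utc <- function(x) as.POSIXct(x, tz = "UTC")
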