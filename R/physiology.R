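#' Thermal performance curve
#'
#' An asymmetric TPC, the shape thermal ecologists typically fit: a slow
#' Gaussian rise below the optimum and a fast quadratic collapse above it,
#' \deqn{P(T) = e^{-((T - T_{opt})/(2\sigma))^2}, \quad T \le T_{opt}}
#' \deqn{P(T) = 1 - ((T - T_{opt})/(T_{opt} - T_{lethal}))^2, \quad
#'   T_{opt} < T < T_{lethal}}
#' and `P = 0` at and above the lethal temperature. Stress categories are
#' assigned by the temperature breakpoints, not by the performance value,
#' so category maps are invariant to the curve-shape choice.
#'
#' @param t_opt Optimal temperature (degrees C), where P = 1.
#' @param t_lethal Lethal temperature (degrees C); P = 0 at and above.
#' @param break_suboptimal Suboptimal/optimal boundary (degrees C).
#' @param break_sublethal Optimal/sublethal boundary (degrees C).
#' @param sigma Rise width of the suboptimal ascent (degrees C, > 0).
#' @param label Species or role name.
#' @return A `thermal_performance_curve` list.
#' @export
thermal_performance_curve <- function(t_opt, t_lethal,
                                      break_suboptimal, break_sublethal,
                                      sigma = 7, label = "generic") {
  if (!(break_suboptimal < t_opt && t_opt < break_sublethal)) {
    stop("breakpoints must straddle t_opt: break_suboptimal < t_opt < break_sublethal")
  }
  if (t_lethal < break_sublethal) stop("t_lethal must be >= break_sublethal")
  if (sigma <= 0) stop("'sigma' must be > 0")
  structure(list(t_opt = t_opt, t_lethal = t_lethal,
                 break_suboptimal = break_suboptimal,
                 break_sublethal = break_sublethal,
                 sigma = sigma, label = label),
            class = "thermal_performance_curve")
}

#' Packaged TPC presets
#'
#' `"generic_intertidal"` is the broad intertidal ectotherm curve used
#' throughout the examples: suboptimal below 21.2 degC, optimal 21.2-30.1
#' degC with the optimum at 28 degC, sublethal 30.1-35 degC, lethal above
#' 35 degC. `"generic_predator"` is the cooler-adapted dominant species
#' (optimum 25 degC, lethal 32 degC) used for two-species interaction maps.
#'
#' @param name Preset name.
#' @return A [thermal_performance_curve].
#' @export
tpc_preset <- function(name = c("generic_intertidal", "generic_predator")) {
  name <- match.arg(name)
  switch(name,
    generic_intertidal = thermal_performance_curve(
      t_opt = 28, t_lethal = 35,
      break_suboptimal = 21.2, break_sublethal = 30.1,
      sigma = 7, label = "generic_intertidal"),
    generic_predator = thermal_performance_curve(
      t_opt = 25, t_lethal = 32,
      break_suboptimal = 18.2, break_sublethal = 27.1,
      sigma = 7, label = "generic_predator"))
}

#' Read a TPC from a key-value CSV
#'
#' Two columns, `key` and `value`, with keys `t_opt`, `t_lethal`,
#' `break_suboptimal`, `break_sublethal`, `sigma` and optionally `label`.
#'
#' @param path CSV path.
#' @return A [thermal_performance_curve].
#' @export
read_tpc <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(d))) {
    stop("TPC file must have columns 'key' and 'value'")
  }
  kv <- stats::setNames(d$value, d$key)
  num <- function(k) as.numeric(kv[[k]])
  thermal_performance_curve(
    t_opt = num("t_opt"), t_lethal = num("t_lethal"),
    break_suboptimal = num("break_suboptimal"),
    break_sublethal = num("break_sublethal"),
    sigma = if ("sigma" %in% names(kv)) num("sigma") else 7,
    label = if ("label" %in% names(kv)) kv[["label"]] else "from_file")
}

#' Write a TPC to a key-value CSV
#' @param tpc A [thermal_performance_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpc <- function(tpc, path) {
  d <- data.frame(
    key = c("t_opt", "t_lethal", "break_suboptimal", "break_sublethal",
            "sigma", "label"),
    value = c(tpc$t_opt, tpc$t_lethal, tpc$break_suboptimal,
              tpc$break_sublethal, tpc$sigma, tpc$label))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative performance at a body temperature
#'
#' @param temperature Body temperature(s), degrees C (vector or matrix).
#' @param tpc A [thermal_performance_curve].
#' @return Relative performance in `[0, 1]`, same shape as `temperature`.
#' @export
relative_performance <- function(temperature, tpc) {
  t_opt <- tpc$t_opt; t_let <- tpc$t_lethal
  p <- ifelse(temperature <= t_opt,
              exp(-((temperature - t_opt) / (2 * tpc$sigma))^2),
              pmax(0, 1 - ((temperature - t_opt) / (t_opt - t_let))^2))
  p[temperature >= t_let] <- 0
  p
}

#' Thermal-stress category at a body temperature
#'
#' Interval assignment (left-closed, right-open, except lethal which is
#' strictly above the lethal temperature): suboptimal below the lower
#' breakpoint; optimal up to the upper breakpoint; sublethal up to and
#' including the lethal temperature; lethal above it.
#'
#' @inheritParams relative_performance
#' @return Character vector/matrix with values `"suboptimal"`, `"optimal"`,
#'   `"sublethal"`, `"lethal"` (`NA` preserved).
#' @export
classify_performance <- function(temperature, tpc) {
  out <- ifelse(temperature < tpc$break_suboptimal, "suboptimal",
         ifelse(temperature < tpc$break_sublethal, "optimal",
         ifelse(temperature <= tpc$t_lethal, "sublethal", "lethal")))
  if (is.matrix(temperature)) dim(out) <- dim(temperature)
  out
}

#' Performance categories as integer codes
#'
#' Legend used in exported rasters: 0 suboptimal, 1 optimal, 2 sublethal,
#' 3 lethal.
#' @export
performance_category_levels <- function() {
  c(suboptimal = 0L, optimal = 1L, sublethal = 2L, lethal = 3L)
}

#' Performance field from a temperature field
#'
#' Element-wise TPC evaluation over the grid. Exposed cells carry
#' performance at the modelled surface temperature; submerged cells carry
#' performance at water temperature (their `values` already hold it) and
#' remain distinguishable through the `exposure` mask.
#'
#' @param temps A `temperature_field`.
#' @param tpc A [thermal_performance_curve].
#' @return A `performance_field`: `timestamp`, `performance` (matrix in
#'   `[0,1]`), `category` (character matrix), `exposure`, `tpc`.
#' @export
performance_field <- function(temps, tpc) {
  p <- relative_performance(temps$values, tpc)
  cat_ <- classify_performance(temps$values, tpc)
  structure(list(timestamp = temps$timestamp, performance = p,
                 category = cat_, exposure = temps$exposure, tpc = tpc),
            class = "performance_field")
}
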