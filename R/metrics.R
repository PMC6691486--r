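exposed_values <- function(field_values, exposure, include_submerged = FALSE) {
  keep <- if (include_submerged) !is.na(field_values) else {
    exposure & !is.na(field_values)
  }
  keep[is.na(keep)] <- FALSE
  field_values[keep]
}

#' Thermal roughness RqT
#'
#' Root mean square of spatial deviations in surface temperature from the
#' site's spatial mean at one timestamp — the thermal analogue of surface
#' roughness Rq. Computed over aerially exposed cells only by default
#' (submerged cells sit at water temperature and would dilute the
#' statistic); no plane detrending, since a temperature field has no
#' geometric trend to remove.
#'
#' @param temps A `temperature_field`.
#' @param include_submerged Include submerged cells (at water temperature).
#' @return RqT in degrees C.
#' @export
thermal_roughness <- function(temps, include_submerged = FALSE) {
  v <- exposed_values(temps$values, temps$exposure, include_submerged)
  if (length(v) < 2L) stop("need at least 2 exposed cells")
  sqrt(mean((v - mean(v))^2))
}

#' Performance roughness RqP
#'
#' As [thermal_roughness], applied to relative performance (dimensionless).
#'
#' @param perf A `performance_field`.
#' @param include_submerged Include submerged cells.
#' @return RqP, dimensionless.
#' @export
performance_roughness <- function(perf, include_submerged = FALSE) {
  v <- exposed_values(perf$performance, perf$exposure, include_submerged)
  if (length(v) < 2L) stop("need at least 2 exposed cells")
  sqrt(mean((v - mean(v))^2))
}

#' Micro-refugia area under a temperature threshold
#'
#' A refugium is an exposed cell whose surface temperature is strictly
#' below the threshold. Optionally, patches smaller than
#' `min_patch_cells` (4-connected) are dropped, a crude body-size filter;
#' off by default.
#'
#' @param temps A `temperature_field`.
#' @param threshold Temperature threshold, degrees C.
#' @param cell_size Cell edge length, metres.
#' @param min_patch_cells Minimum 4-connected patch size kept (1 = keep all).
#' @return A `refugia_result`: `threshold`, `refugium_mask`, `refugia_area`
#'   (m^2), `exposed_area` (m^2), `fraction`.
#' @export
refugia_area <- function(temps, threshold, cell_size,
                         min_patch_cells = 1L) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  exposed <- temps$exposure & !is.na(temps$values)
  exposed[is.na(exposed)] <- FALSE
  if (!any(exposed)) stop("no exposed cells")
  mask <- exposed & temps$values < threshold
  mask[is.na(mask)] <- FALSE
  if (min_patch_cells > 1L) mask <- drop_small_patches(mask, min_patch_cells)
  a_cell <- cell_size^2
  refa <- sum(mask) * a_cell
  expa <- sum(exposed) * a_cell
  structure(list(threshold = threshold, refugium_mask = mask,
                 refugia_area = refa, exposed_area = expa,
                 fraction = refa / expa),
            class = "refugia_result")
}

# label 4-connected patches and drop those below min_cells
drop_small_patches <- function(mask, min_cells) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c0 <- p[2]
      if (r < 1 || r > nr || c0 < 1 || c0 > nc) next
      if (!mask[r, c0] || lab[r, c0] > 0L) next
      lab[r, c0] <- nxt
      stack <- c(stack, list(c(r - 1L, c0), c(r + 1L, c0),
                             c(r, c0 - 1L), c(r, c0 + 1L)))
    }
  }
  keep <- which(tabulate(lab) >= min_cells)
  mask & matrix(lab %in% keep, nr, nc)
}

#' Thermal-corridor map between two timestamps
#'
#' Compares the spatial footprint of one stress category (default:
#' optimal) at two hours: cells where it persists, where it is lost and
#' where it is gained. Lost/gained areas are the potential corridors and
#' barriers for mobile species moving with the shifting thermal landscape.
#'
#' @param perf_t1,perf_t2 `performance_field`s on congruent grids,
#'   `perf_t2` later.
#' @param category Category tracked (`"optimal"` by default).
#' @param cell_size Cell edge length, metres.
#' @return A `corridor_result`: logical grids `persistent`, `lost`,
#'   `gained` and their areas in m^2.
#' @export
corridor_map <- function(perf_t1, perf_t2, category = "optimal",
                         cell_size) {
  if (!all(dim(perf_t1$performance) == dim(perf_t2$performance))) {
    stop("performance fields must be congruent")
  }
  m1 <- category_mask(perf_t1, category)
  m2 <- category_mask(perf_t2, category)
  a <- cell_size^2
  structure(list(category = category,
                 persistent = m1 & m2, lost = m1 & !m2, gained = !m1 & m2,
                 persistent_area = sum(m1 & m2) * a,
                 lost_area = sum(m1 & !m2) * a,
                 gained_area = sum(!m1 & m2) * a),
            class = "corridor_result")
}

category_mask <- function(perf, category) {
  m <- perf$exposure & !is.na(perf$category) & perf$category == category
  m[is.na(m)] <- FALSE
  m
}

#' Two-species interaction map
#'
#' Partitions exposed cells by thermal favourability to a dominant
#' (predator / competitive dominant) and a subordinate (prey) species.
#' A cell is favourable to a species when its stress category is in
#' `favourable_categories` — by default every non-lethal category, i.e.
#' survivable. "Prey-only refugia" are cells favourable to the subordinate
#' but not to the dominant: the microhabitats where the subordinate escapes
#' its predator/competitor.
#'
#' @param temps A `temperature_field`.
#' @param tpc_dominant,tpc_subordinate [thermal_performance_curve]s.
#' @param favourable_categories Categories counted as favourable.
#' @param cell_size Cell edge length (m) for the per-class areas.
#' @return An `interaction_map`: `class` (character matrix with values
#'   `"both"`, `"prey_only"`, `"predator_only"`, `"neither"`, `NA` off the
#'   exposed area) and named `areas` (m^2).
#' @export
species_interaction_map <- function(temps, tpc_dominant, tpc_subordinate,
                                    favourable_categories =
                                      c("suboptimal", "optimal", "sublethal"),
                                    cell_size = 1) {
  exposed <- temps$exposure & !is.na(temps$values)
  exposed[is.na(exposed)] <- FALSE
  fav <- function(tpc) {
    f <- matrix(classify_performance(temps$values, tpc) %in%
                  favourable_categories,
                nrow(temps$values), ncol(temps$values))
    f & exposed
  }
  fd <- fav(tpc_dominant)
  fs <- fav(tpc_subordinate)
  cls <- matrix(NA_character_, nrow(temps$values), ncol(temps$values))
  cls[exposed] <- "neither"
  cls[fd & !fs] <- "predator_only"
  cls[!fd & fs] <- "prey_only"
  cls[fd & fs] <- "both"
  a <- cell_size^2
  areas <- c(both = sum(fd & fs), prey_only = sum(!fd & fs),
             predator_only = sum(fd & !fs),
             neither = sum(exposed & !fd & !fs)) * a
  structure(list(class = cls, areas = areas,
                 dominant = tpc_dominant$label,
                 subordinate = tpc_subordinate$label),
            class = "interaction_map")
}

#' Frequency distribution over exposed cells
#'
#' Histogram of a temperature or performance field over half-open bins
#' `[e_i, e_{i+1})`. Values outside the edge range are not counted, so for
#' conservation the edges should cover the field's range.
#'
#' @param field A `temperature_field` or `performance_field`.
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @return Data frame with `bin_left`, `bin_right`, `count`.
#' @export
frequency_distribution <- function(field, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("'bin_edges' must be strictly increasing")
  }
  v <- if (inherits(field, "performance_field")) {
    exposed_values(field$performance, field$exposure)
  } else {
    exposed_values(field$values, field$exposure)
  }
  k <- length(bin_edges) - 1L
  idx <- findInterval(v, bin_edges, left.open = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx <= k &
                           v < bin_edges[length(bin_edges)]], nbins = k)
  data.frame(bin_left = bin_edges[-length(bin_edges)],
             bin_right = bin_edges[-1], count = counts)
}

#' Tidy metrics table for a simulated hour sequence
#'
#' One row per (timestamp, metric): RqT, RqP, refugia area and fraction at
#' each requested threshold, exposed area. Hours with fewer than two
#' exposed cells contribute `NA` metrics (with a warning) rather than
#' aborting the table.
#'
#' @param fields List of `temperature_field` (from [run_simulation]).
#' @param tpc A [thermal_performance_curve].
#' @param cell_size Cell edge length, metres.
#' @param thresholds Refugia thresholds, degrees C.
#' @return Data frame `timestamp`, `metric`, `value`.
#' @export
landscape_metrics_table <- function(fields, tpc, cell_size,
                                    thresholds = 28) {
  rows <- list()
  for (f in fields) {
    ts <- format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ex <- f$exposure & !is.na(f$values)
    ex[is.na(ex)] <- FALSE
    n_ex <- sum(ex)
    add <- function(metric, value) {
      rows[[length(rows) + 1L]] <<- data.frame(timestamp = ts,
                                               metric = metric,
                                               value = value)
    }
    add("exposed_area_m2", n_ex * cell_size^2)
    if (n_ex >= 2L) {
      add("rqt_c", thermal_roughness(f))
      add("rqp", performance_roughness(performance_field(f, tpc)))
      for (th in thresholds) {
        r <- refugia_area(f, th, cell_size)
        add(sprintf("refugia_area_m2_lt%g", th), r$refugia_area)
        add(sprintf("refugia_fraction_lt%g", th), r$fraction)
      }
    } else {
      warning("fewer than 2 exposed cells at ", ts,
              "; roughness/refugia metrics skipped")
      add("rqt_c", NA_real_)
      add("rqp", NA_real_)
    }
  }
  do.call(rbind, rows)
}
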