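#' Construct an elevation grid
#'
#' The basic raster container for a site's digital elevation model (DEM):
#' a rectangular matrix of elevations on square cells, with `NA` marking
#' nodata (e.g. permanently submerged cells). Row 1 is the northern edge of
#' the grid; columns run west to east.
#'
#' @param values Numeric matrix of elevations (m above the tidal datum, e.g.
#'   MLLW). `NA` marks nodata cells.
#' @param cell_size Cell edge length in metres (> 0; cells are square).
#' @param origin Numeric length-2 `(easting, northing)` of the north-west
#'   cell corner, in metres. Defaults to `c(0, 0)`.
#' @return An object of class `elevation_grid`: a list with elements
#'   `values`, `cell_size`, `origin`.
#' @export
elevation_grid <- function(values, cell_size, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("'cell_size' must be a single positive number (metres)")
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("'origin' must be a finite (easting, northing) pair")
  }
  if (any(is.infinite(values))) stop("elevations must be finite or NA")
  if (all(is.na(values))) stop("all cells are nodata")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elevation_grid> %d x %d cells @ %.4g m (%d nodata)\n",
              nrow(v), ncol(v), x$cell_size, sum(is.na(v))))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  elevation %.3f .. %.3f m; origin (%.2f, %.2f)\n",
              rng[1], rng[2], x$origin[1], x$origin[2]))
  invisible(x)
}

#' Nodata mask of an elevation grid
#'
#' @param dem An [elevation_grid].
#' @return Logical matrix, `TRUE` where no elevation exists.
#' @export
nodata_mask <- function(dem) is.na(dem$values)

#' Read a DEM from file
#'
#' Reads a single-band elevation raster. Two formats are supported:
#' ESRI-style ASCII grids (`.asc`/`.grd`/`.txt`, header with `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`)
#' and single-band float TIFF (`.tif`/`.tiff`, via the `tiff` package; TIFF
#' carries no grid geometry here, so `cell_size` must be supplied).
#'
#' @param path Path to the raster file.
#' @param format `"auto"` (by extension), `"ascii"` or `"tiff"`.
#' @param cell_size Cell size in metres; required for TIFF, ignored for
#'   ASCII (taken from the header).
#' @param origin North-west corner `(easting, northing)`; TIFF only.
#' @return An [elevation_grid].
#' @export
read_dem <- function(path, format = c("auto", "ascii", "tiff"),
                     cell_size = NULL, origin = c(0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("DEM file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii"
  }
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    if (is.null(cell_size)) stop("'cell_size' is required when reading TIFF")
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) == 3L) {
      if (dim(v)[3] != 1L) stop("expected a single-band TIFF")
      v <- v[, , 1L]
    }
    return(elevation_grid(v, cell_size, origin))
  }
  read_ascii_grid(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header must declare ncols, nrows and cellsize")
  }
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy) {
    stop("non-square cells are not supported")
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) # row 1 = north
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  if (all(is.na(m))) stop("all cells are nodata")
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  # origin is the NW corner; the header gives the SW (lower-left) corner
  elevation_grid(m, hdr$cellsize, c(xll, yll + nr * hdr$cellsize))
}

#' Write a grid to an ESRI-style ASCII raster
#'
#' Works for an [elevation_grid] or any numeric matrix sharing its geometry.
#'
#' @param x An [elevation_grid], or a numeric matrix (then `cell_size` and
#'   `origin` must be given).
#' @param path Output path.
#' @param cell_size,origin Grid geometry when `x` is a bare matrix.
#' @param nodata Value written for `NA` cells (default -9999).
#' @param digits Significant digits to print (default 10).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cell_size = NULL, origin = NULL,
                             nodata = -9999, digits = 10) {
  if (inherits(x, "elevation_grid")) {
    m <- x$values; cell_size <- x$cell_size; origin <- x$origin
  } else {
    m <- as.matrix(x)
    if (is.null(cell_size)) stop("'cell_size' required for a bare matrix")
    if (is.null(origin)) origin <- c(0, 0)
  }
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2] - nr * cell_size),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %.10g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(formatC(r, digits = digits,
                                                 format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Slope and aspect from a DEM
#'
#' Per-cell surface inclination and downslope direction by Horn's 3x3
#' finite-difference kernel, the standard GIS estimator and robust to
#' centimetre-scale noise. Border cells and cells adjacent to nodata are
#' masked (`NA`) rather than extrapolated, so later radiation and
#' temperature stages never see half-informed gradients.
#'
#' @param dem An [elevation_grid] with at least 3x3 cells.
#' @return A `terrain_derivatives` list with matrices `slope` (degrees from
#'   horizontal, 0-90) and `aspect` (degrees clockwise from north of the
#'   downslope direction, `[0, 360)`; flat cells get aspect 0 and are marked
#'   in the logical matrix `flat`), plus the grid geometry.
#' @export
compute_slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3 cells")
  cs <- dem$cell_size
  # 3x3 neighbourhood shifts; row 1 = north so row index grows southward
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- (1 + max(0, dr)):(nr + min(0, dr))
    cls <- (1 + max(0, dc)):(nc + min(0, dc))
    out[rs - dr, cls - dc] <- z[rs, cls]
    out
  }
  znw <- sh(-1, -1); zn <- sh(-1, 0); zne <- sh(-1, 1)
  zw  <- sh(0, -1);                  ze  <- sh(0, 1)
  zsw <- sh(1, -1);  zs <- sh(1, 0);  zse <- sh(1, 1)
  dzdx <- ((zne + 2 * ze + zse) - (znw + 2 * zw + zsw)) / (8 * cs) # east+
  dzdy <- ((znw + 2 * zn + zne) - (zsw + 2 * zs + zse)) / (8 * cs) # north+
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  slope[is.na(z)] <- NA_real_   # nodata cells carry no derivatives
  aspect[is.na(z)] <- NA_real_
  flat <- !is.na(slope) & slope == 0
  aspect[flat] <- 0
  structure(list(slope = slope, aspect = aspect, flat = flat,
                 horizon_angles = NULL, svf = NULL,
                 azimuths = NULL, n_directions = NULL, max_radius = NULL,
                 cell_size = cs, origin = dem$origin),
            class = "terrain_derivatives")
}

#' Horizon angles by radial scanning
#'
#' For each cell and each of `n_directions` equally spaced azimuths
#' (clockwise from north), the elevation angle of the local horizon: the
#' maximum of `atan((z_p - z_cell)/distance)` over points sampled every cell
#' size along the ray out to `max_radius`, floored at 0. Elevations along
#' rays are interpolated bilinearly; rays truncate on leaving the grid or
#' entering nodata. Defaults follow common fine-scale practice: 32 search
#' vectors, 5 m search radius.
#'
#' @param dem An [elevation_grid].
#' @param derivatives Optional `terrain_derivatives` (from
#'   [compute_slope_aspect]) to fill in place; a fresh one is made otherwise.
#' @param n_directions Number of azimuthal search directions (>= 4).
#' @param max_radius Search radius in metres (>= one cell size).
#' @return `terrain_derivatives` with `horizon_angles` (array
#'   rows x cols x n_directions, degrees in `[0, 90]`) and `azimuths` filled.
#' @export
compute_horizon_angles <- function(dem, derivatives = NULL,
                                   n_directions = 32, max_radius = 5) {
  if (n_directions < 4L) stop("'n_directions' must be at least 4")
  if (max_radius < dem$cell_size) {
    stop("'max_radius' must be at least one cell size")
  }
  h <- horizon_scan_cpp(dem$values, dem$cell_size,
                        as.integer(n_directions), max_radius)
  if (is.null(derivatives)) derivatives <- compute_slope_aspect(dem)
  derivatives$horizon_angles <- h
  derivatives$azimuths <- 360 * (seq_len(n_directions) - 1L) / n_directions
  derivatives$n_directions <- as.integer(n_directions)
  derivatives$max_radius <- max_radius
  derivatives
}

#' Sky view factor from horizon angles
#'
#' Fraction of the sky hemisphere visible from each cell, 0 (fully
#' obstructed) to 1 (fully open), under an isotropic-radiance sky:
#' `SVF = mean over directions of cos^2(horizon angle)`.
#'
#' @param derivatives `terrain_derivatives` with `horizon_angles` present.
#' @return `derivatives` with matrix `svf` filled.
#' @export
compute_svf <- function(derivatives) {
  h <- derivatives$horizon_angles
  if (is.null(h)) stop("horizon angles missing; run compute_horizon_angles()")
  derivatives$svf <- apply(cos(h * pi / 180)^2, c(1, 2), mean)
  derivatives
}

#' Full terrain derivative set
#'
#' Convenience wrapper: slope/aspect, horizon angles and SVF in one call.
#'
#' @inheritParams compute_horizon_angles
#' @return Complete `terrain_derivatives`.
#' @export
compute_terrain <- function(dem, n_directions = 32, max_radius = 5) {
  d <- compute_slope_aspect(dem)
  d <- compute_horizon_angles(dem, d, n_directions, max_radius)
  compute_svf(d)
}

#' Surface roughness Rq
#'
#' Root mean square of elevation deviations about the best-fit (least
#' squares) plane — the standard metrology roughness statistic applied to a
#' site's DEM. `detrend = "mean"` subtracts the mean elevation instead of a
#' fitted plane.
#'
#' @param dem An [elevation_grid] with at least 3 valid, non-collinear cells.
#' @param detrend `"plane"` (default) or `"mean"`.
#' @return Rq in metres.
#' @export
surface_roughness_rq <- function(dem, detrend = c("plane", "mean")) {
  detrend <- match.arg(detrend)
  z <- dem$values
  ok <- !is.na(z)
  if (sum(ok) < 3L) stop("need at least 3 valid cells")
  zl <- z[ok]
  if (detrend == "mean") return(sqrt(mean((zl - mean(zl))^2)))
  idx <- which(ok, arr.ind = TRUE)
  x <- idx[, "col"] * dem$cell_size
  y <- idx[, "row"] * dem$cell_size
  if (qr(cbind(1, x, y))$rank < 3L) {
    stop("valid cells are collinear; cannot fit a plane")
  }
  fit <- lm.fit(cbind(1, x, y), zl)
  sqrt(mean(fit$residuals^2))
}
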