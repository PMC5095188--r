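#' Read a 1 Hz GPS track from a Movebank-style CSV
#'
#' Reads, validates and orders GPS fixes for one or more individuals and
#' partitions them into bursts of contiguous 1 Hz sampling. Any timestamp
#' gap greater than 1 s starts a new burst; duplicate timestamps within a
#' burst keep the first fix. Rows with unparseable or out-of-range
#' coordinates are dropped and counted.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the internal names
#'   `timestamp`, `lon`, `lat`, `altitude`, `individual`, `air_density`
#'   to the CSV headers. Defaults follow Movebank export headers; the
#'   `air_density` column (kg m^-3) is optional.
#' @return A `soar_track`: a data frame with columns `individual`,
#'   `timestamp` (POSIXct UTC, whole seconds), `lon`, `lat`, `altitude`,
#'   `air_density` (NA when the file has no density column) and `burst`
#'   (integer id, unique across individuals), ordered by individual and
#'   time. Attribute `dropped` counts discarded rows.
#' @export
read_track <- function(path, column_map = movebank_columns()) {
  if (!file.exists(path)) stop("track file not found: ", path)
  needed <- c("timestamp", "lon", "lat", "altitude", "individual")
  if (!all(needed %in% names(column_map)))
    stop("column_map must name: ", paste(needed, collapse = ", "))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols) > 0)
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))

  ts <- parse_utc(raw[[column_map["timestamp"]]])
  lon <- suppressWarnings(as.numeric(raw[[column_map["lon"]]]))
  lat <- suppressWarnings(as.numeric(raw[[column_map["lat"]]]))
  alt <- suppressWarnings(as.numeric(raw[[column_map["altitude"]]]))
  ind <- as.character(raw[[column_map["individual"]]])
  dens_col <- column_map["air_density"]
  rho <- if (!is.na(dens_col) && dens_col %in% names(raw))
    suppressWarnings(as.numeric(raw[[dens_col]])) else rep(NA_real_, nrow(raw))
  rho[!is.na(rho) & (rho <= 0.1 | rho >= 1.6)] <- NA_real_

  ok <- !is.na(ts) & !is.na(lon) & !is.na(lat) & !is.na(alt) &
    lat >= -90 & lat <= 90 & lon > -180 & lon <= 180 &
    alt >= -500 & alt <= 12000
  dropped <- sum(!ok)
  fixes <- data.frame(individual = ind[ok], timestamp = ts[ok],
                      lon = lon[ok], lat = lat[ok], altitude = alt[ok],
                      air_density = rho[ok], stringsAsFactors = FALSE)
  if (nrow(fixes) == 0) stop("no valid GPS fixes in ", path)

  fixes <- fixes[order(fixes$individual, fixes$timestamp), , drop = FALSE]
  dup <- stats::ave(as.numeric(fixes$timestamp), fixes$individual,
                    FUN = function(t) duplicated(t)) > 0
  n_dup <- sum(dup)
  fixes <- fixes[!dup, , drop = FALSE]

  gap <- stats::ave(as.numeric(fixes$timestamp), fixes$individual,
                    FUN = function(t) c(Inf, diff(t)))
  fixes$burst <- cumsum(gap > 1)
  rownames(fixes) <- NULL
  structure(fixes, dropped = dropped, duplicates = n_dup,
            class = c("soar_track", "data.frame"))
}

#' Default Movebank column mapping
#' @return named character vector accepted by [read_track()].
#' @export
movebank_columns <- function() {
  c(timestamp = "timestamp", lon = "location-long", lat = "location-lat",
    altitude = "height-above-msl", individual = "individual-local-identifier",
    air_density = "air-density")
}

# Parse UTC timestamps, truncated to whole seconds. Accepts Movebank
# "YYYY-mm-dd HH:MM:SS[.fff]" and ISO 8601 "T" separators.
parse_utc <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  as.POSIXct(floor(as.numeric(ts)), tz = "UTC", origin = "1970-01-01")
}

#' @export
print.soar_track <- function(x, ...) {
  cat(sprintf("GPS track: %d fixes, %d individual(s), %d burst(s)",
              nrow(x), length(unique(x$individual)),
              length(unique(x$burst))), "\n")
  if (!is.null(attr(x, "dropped")) && attr(x, "dropped") > 0)
    cat(sprintf("  %d row(s) dropped at read", attr(x, "dropped")), "\n")
  invisible(x)
}

#' Project a 31-fix window onto a local tangent plane
#'
#' Equirectangular projection centred on the window centroid:
#' x = R cos(lat0) dlon, y = R dlat (radians), with the spherical Earth
#' radius. Over the few hundred metres a thermalling circle covers, the
#' projection error is negligible; centring per window keeps it so.
#'
#' @param fixes data frame of 31 consecutive fixes (columns `timestamp`,
#'   `lon`, `lat`, `altitude`) spanning exactly 30 s at 1 Hz.
#' @return a `planar_window`: list with reference `lon0`/`lat0` (degrees),
#'   `x` (m east), `y` (m north), `z` (altitude, m), `t` (seconds from the
#'   first fix, 0..30) and `start` (POSIXct of the first fix).
#' @export
project_window <- function(fixes) {
  if (nrow(fixes) != 31) stop("a loop window must hold exactly 31 fixes")
  t <- as.numeric(fixes$timestamp) - as.numeric(fixes$timestamp[1])
  if (!isTRUE(all.equal(t, 0:30)))
    stop("a loop window must span exactly 30 s at 1 Hz")
  lon0 <- mean(fixes$lon); lat0 <- mean(fixes$lat)
  xy <- lonlat_to_xy(fixes$lon, fixes$lat, lon0, lat0)
  structure(list(lon0 = lon0, lat0 = lat0, x = xy$x, y = xy$y,
                 z = fixes$altitude, t = t, start = fixes$timestamp[1]),
            class = "planar_window")
}

#' Local tangent-plane conversions
#'
#' Forward and inverse equirectangular projection about a reference point.
#' `lonlat_to_xy` maps degrees to metres east/north; `xy_to_lonlat` is its
#' exact inverse and is used by the flight simulator to place planar paths
#' on the globe.
#'
#' @param lon,lat coordinates in degrees.
#' @param x,y planar coordinates in metres (east, north).
#' @param lon0,lat0 reference point in degrees.
#' @return list with `x`,`y` (m) or `lon`,`lat` (degrees).
#' @export
lonlat_to_xy <- function(lon, lat, lon0, lat0) {
  k <- pi / 180 * soar_constants$R_earth
  list(x = k * cos(lat0 * pi / 180) * (lon - lon0), y = k * (lat - lat0))
}

#' @rdname lonlat_to_xy
#' @export
xy_to_lonlat <- function(x, y, lon0, lat0) {
  k <- pi / 180 * soar_constants$R_earth
  list(lon = lon0 + x / (k * cos(lat0 * pi / 180)), lat = lat0 + y / k)
}

#' Ground-velocity series of a projected window
#'
#' Differentiates the planar track: central differences
#' (p[i+1] - p[i-1]) / 2 at interior fixes, one-sided differences at the two
#' ends. Central differencing of a uniformly rotating position is phase-true
#' but attenuates the rotation amplitude by sin(w dt)/(w dt); downstream
#' estimators correct for this (see [fit_loop_wind()]).
#'
#' @param window a `planar_window` from [project_window()].
#' @return data frame of 31 rows: `ve`, `vn` (m s^-1 east/north),
#'   `speed`, and `interior` (logical, FALSE for the two end fixes).
#' @export
ground_velocity <- function(window) {
  stopifnot(inherits(window, "planar_window"))
  n <- length(window$x)
  d <- function(p) {
    v <- c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1])
    v  # dt = 1 s
  }
  ve <- d(window$x); vn <- d(window$y)
  data.frame(ve = ve, vn = vn, speed = sqrt(ve^2 + vn^2),
             interior = c(FALSE, rep(TRUE, n - 2), FALSE))
}
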