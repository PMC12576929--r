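#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). Vectorised over all four coordinate arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Read a track table
#'
#' Reads a delimited text file of GPS fixes (CSV, or TSV when the file
#' extension is `.tsv`), maps columns to the canonical names, parses
#' ISO-8601 UTC timestamps, sorts by individual and time, and drops
#' exact duplicate rows.
#'
#' @param path Path to a delimited text file with a header.
#' @param col_map Named character vector mapping canonical names
#'   (`individual_id`, `colony_id`, `timestamp`, `lon`, `lat`) to the
#'   file's column names. Defaults to the canonical header itself.
#' @return A `data.frame` with columns `individual_id`, `colony_id`,
#'   `timestamp` (POSIXct, UTC), `lon`, `lat`, sorted by
#'   (individual_id, timestamp). The number of dropped duplicate rows is
#'   reported via [message()] and stored in attribute `n_dropped`.
#' @export
read_tracks <- function(path, col_map = NULL) {
  canon <- c("individual_id", "colony_id", "timestamp", "lon", "lat")
  if (is.null(col_map)) col_map <- setNames(canon, canon)
  stopifnot(all(canon %in% names(col_map)))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  for (cn in canon) {
    if (!col_map[[cn]] %in% names(raw)) {
      stop("track file is missing required column '", col_map[[cn]],
           "' (", cn, ")", call. = FALSE)
    }
  }
  df <- data.frame(
    individual_id = raw[[col_map[["individual_id"]]]],
    colony_id = raw[[col_map[["colony_id"]]]],
    timestamp_raw = raw[[col_map[["timestamp"]]]],
    lon_raw = raw[[col_map[["lon"]]]],
    lat_raw = raw[[col_map[["lat"]]]],
    stringsAsFactors = FALSE
  )
  n0 <- nrow(df)
  df <- unique(df)
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0) {
    message("read_tracks: dropped ", n_dropped, " exact duplicate row(s)")
  }
  df$timestamp <- parse_utc(df$timestamp_raw)
  bad_t <- which(is.na(df$timestamp))
  if (length(bad_t)) {
    stop("unparsable timestamp at row(s): ",
         paste(head(bad_t, 5), collapse = ", "),
         " (expected ISO-8601 UTC, e.g. 2012-06-01T06:30:00Z)",
         call. = FALSE)
  }
  df$lon <- suppressWarnings(as.numeric(df$lon_raw))
  df$lat <- suppressWarnings(as.numeric(df$lat_raw))
  bad_c <- which(is.na(df$lon) | is.na(df$lat) |
                   abs(df$lon) > 180 | abs(df$lat) > 90)
  if (length(bad_c)) {
    stop("invalid coordinate at row(s): ",
         paste(head(bad_c, 5), collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$individual_id, df$timestamp), ,
           drop = FALSE]
  out <- df[, c("individual_id", "colony_id", "timestamp", "lon", "lat")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# strict ISO-8601 UTC parser; 'T' or space separator, optional trailing Z
parse_utc <- function(x) {
  x <- sub("Z$", "", x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  x2 <- sub("T", " ", x[ok], fixed = TRUE)
  out[ok] <- as.POSIXct(x2, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out
}

#' Write a track table
#'
#' Writes the canonical columns back to CSV so that reading and writing
#' a track table is lossless. Timestamps are formatted as ISO-8601 UTC.
#'
#' @param tracks Track `data.frame` as returned by [read_tracks()].
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks[, c("individual_id", "colony_id", "timestamp", "lon", "lat")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$lon <- sprintf("%.10f", out$lon)
  out$lat <- sprintf("%.10f", out$lat)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project fixes onto a local equal-area plane
#'
#' Lambert azimuthal equal-area projection (spherical form, radius
#' 6371.0088 km) centred on the colony. Equal-area is required because
#' downstream utilisation-distribution and key-area outputs are areas in
#' km². The colony maps to (0, 0); x points east and y north, both in
#' kilometres.
#'
#' @param fixes A `data.frame` with `lon` and `lat` columns (degrees).
#' @param colony A list or one-row data.frame with `lon` and `lat` (and
#'   optionally `colony_id`).
#' @param max_range_km Fixes farther than this from the colony are an
#'   error (default 2000 km; the projection is only validated to 500 km).
#' @return `fixes` with numeric columns `x` and `y` (km) appended.
#' @export
project_local <- function(fixes, colony, max_range_km = 2000) {
  d <- great_circle_km(fixes$lon, fixes$lat, colony$lon, colony$lat)
  if (any(d > max_range_km)) {
    stop("fix(es) beyond ", max_range_km, " km of colony: rows ",
         paste(head(which(d > max_range_km), 5), collapse = ", "),
         call. = FALSE)
  }
  to_rad <- pi / 180
  lam0 <- colony$lon * to_rad
  phi0 <- colony$lat * to_rad
  lam <- fixes$lon * to_rad
  phi <- fixes$lat * to_rad
  dlam <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  kp <- sqrt(2 / denom)
  fixes$x <- .EARTH_RADIUS_KM * kp * cos(phi) * sin(dlam)
  fixes$y <- .EARTH_RADIUS_KM * kp *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  fixes
}

#' Inverse of [project_local()]
#'
#' @param xy A `data.frame` (or matrix) with `x` and `y` columns in km.
#' @param colony Projection centre with `lon`, `lat` in degrees.
#' @return A `data.frame` with `lon` and `lat` columns in degrees.
#' @export
unproject_local <- function(xy, colony) {
  xy <- as.data.frame(xy)
  to_rad <- pi / 180
  lam0 <- colony$lon * to_rad
  phi0 <- colony$lat * to_rad
  rho <- sqrt(xy$x^2 + xy$y^2)
  c_ang <- 2 * asin(pmin(rho / (2 * .EARTH_RADIUS_KM), 1))
  lat <- phi0
  lon <- lam0
  nz <- rho > 0
  lat <- ifelse(nz,
    asin(cos(c_ang) * sin(phi0) + xy$y * sin(c_ang) * cos(phi0) / rho),
    phi0)
  lon <- ifelse(nz,
    lam0 + atan2(xy$x * sin(c_ang),
                 rho * cos(c_ang) * cos(phi0) -
                   xy$y * sin(c_ang) * sin(phi0)),
    lam0)
  data.frame(lon = lon / to_rad, lat = lat / to_rad)
}

#' Write polygons as GeoJSON
#'
#' Writes a FeatureCollection of (multi)polygons in WGS84. Each feature
#' is a list with elements `rings` (a list of two-column lon/lat
#' matrices; the first ring of a part is the outer boundary) and
#' `properties` (a named list, e.g. area in km²).
#'
#' @param features List of features as described above.
#' @param path Output path.
#' @export
write_geojson <- function(features, path) {
  feats <- lapply(features, function(f) {
    coords <- lapply(f$rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(
      type = "Feature",
      properties = f$properties,
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Export a gridded surface as CSV
#'
#' Writes one row per grid cell with columns `x`, `y`, `value` using full
#' binary precision so the file round-trips bit-exactly through
#' [read_grid_csv()].
#'
#' @param x,y Cell-centre coordinate vectors (km).
#' @param values Matrix of dimension `length(x)` by `length(y)`.
#' @param path Output path.
#' @export
write_grid_csv <- function(x, y, values, path) {
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  g <- expand.grid(x = x, y = y)
  df <- data.frame(
    x = sprintf("%.17g", g$x),
    y = sprintf("%.17g", g$y),
    value = sprintf("%.17g", as.vector(values))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param path Path to a CSV written by [write_grid_csv()].
#' @export
read_grid_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
             value = as.numeric(df$value))
}
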