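# Spherical-geometry primitives and the track data model.
#
# All geometry is great-circle on a sphere of radius 6371.0088 km (IUGG mean
# Earth radius): sub-0.5% error at basin scales, and simpler than an
# ellipsoid.  Bearings are degrees clockwise from true north in [0, 360);
# turning angles are signed degrees in (-180, 180], positive = clockwise.

#' Mean Earth radius used throughout, in km
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Normalise longitudes to (-180, 180]
#'
#' @param lon numeric vector of longitudes in degrees east.
#' @return numeric vector in (-180, 180].
#' @export
wrapLon <- function(lon) {
  out <- lon %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Great-circle (haversine) distance in km
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees; vectors recycle.
#' @return distances in km.
#' @export
greatCircleDistance <- function(lat1, lon1, lat2, lon2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing in degrees clockwise from north, [0, 360)
#'
#' Undefined for coincident points: those are an error.
#'
#' @inheritParams greatCircleDistance
#' @return bearings in degrees.
#' @export
initialBearing <- function(lat1, lon1, lat2, lon2) {
  if (any(lat1 == lat2 & wrapLon(lon1) == wrapLon(lon2))) {
    stop("initialBearing is undefined for coincident points")
  }
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  .rad2deg(atan2(y, x)) %% 360
}

#' Great-circle destination point
#'
#' @param lat,lon start coordinates in degrees.
#' @param bearing initial bearing, degrees clockwise from north.
#' @param distance_km great-circle distance, km (>= 0).
#' @return list with components `lat` and `lon` (degrees, lon in (-180, 180]).
#' @export
destinationPoint <- function(lat, lon, bearing, distance_km) {
  if (any(distance_km < 0)) stop("distance_km must be >= 0")
  d <- distance_km / EARTH_RADIUS_KM
  p1 <- .deg2rad(lat); l1 <- .deg2rad(lon); th <- .deg2rad(bearing)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  list(lat = .rad2deg(p2), lon = wrapLon(.rad2deg(l2)))
}

#' Signed turning angle between two bearings
#'
#' Returns `next_bearing - prev_bearing` wrapped to (-180, 180]; positive is
#' a clockwise (rightward) turn.
#'
#' @param prev_bearing,next_bearing bearings in degrees.
#' @return signed angles in degrees, (-180, 180].
#' @export
signedTurningAngle <- function(prev_bearing, next_bearing) {
  d <- (next_bearing - prev_bearing) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# ---- track data model ------------------------------------------------------

#' Construct a validated track table
#'
#' A track set is a data.frame with columns `track_id` (character), `date`
#' (Date, one fix per day, strictly increasing within a track; gaps allowed),
#' `lat`, `lon` (degrees) and `ci95_km` (non-negative 95% positional
#' confidence radius in km; NA means the position is exact).
#'
#' @param track_id,date,lat,lon,ci95_km column vectors (recycled as usual).
#' @return a `tracks` data.frame.
#' @export
makeTracks <- function(track_id, date, lat, lon, ci95_km = NA_real_) {
  df <- data.frame(track_id = as.character(track_id), date = as.Date(date),
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   ci95_km = as.numeric(ci95_km), stringsAsFactors = FALSE)
  validateTracks(df)
}

#' Validate a track table
#'
#' Enforces the track invariants: valid coordinates, >= 2 fixes per track,
#' strictly increasing dates, non-negative confidence radii.  Longitudes are
#' normalised to (-180, 180].
#'
#' @param df a data.frame with the track columns (see [makeTracks()]).
#' @return the validated data.frame with class `tracks`.
#' @export
validateTracks <- function(df) {
  need <- c("track_id", "date", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("track table missing columns: ", paste(miss, collapse = ", "))
  if (!"ci95_km" %in% names(df)) df$ci95_km <- NA_real_
  df$date <- as.Date(df$date)
  bad <- which(!is.finite(df$lat) | df$lat < -90 | df$lat > 90)
  if (length(bad)) stop("invalid latitude at row ", bad[1], " (", df$lat[bad[1]], ")")
  if (any(!is.finite(df$lon))) stop("non-finite longitude at row ",
                                    which(!is.finite(df$lon))[1])
  df$lon <- wrapLon(df$lon)
  if (any(!is.na(df$ci95_km) & df$ci95_km < 0)) {
    stop("negative ci95_km at row ", which(!is.na(df$ci95_km) & df$ci95_km < 0)[1])
  }
  for (id in unique(df$track_id)) {
    rows <- which(df$track_id == id)
    if (length(rows) < 2) stop("track '", id, "' has fewer than 2 fixes")
    d <- df$date[rows]
    if (anyNA(d)) stop("track '", id, "' has an unparseable date")
    if (any(diff(as.integer(d)) <= 0)) {
      i <- rows[which(diff(as.integer(d)) <= 0)[1] + 1]
      stop("track '", id, "' has non-increasing or duplicate dates at row ", i)
    }
  }
  class(df) <- unique(c("tracks", class(df)))
  df
}

#' Read tracks from a CSV file
#'
#' Expects a UTF-8 CSV with header `track_id,date,lat,lon,ci95_km`
#' (`ci95_km` optional), dates ISO-8601 `YYYY-MM-DD`.
#'
#' @param path file path.
#' @return a validated `tracks` data.frame.
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateTracks(df)
}

#' Write tracks to CSV
#'
#' @param tracks a `tracks` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  tracks <- validateTracks(as.data.frame(tracks))
  out <- tracks[, c("track_id", "date", "lat", "lon", "ci95_km")]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
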