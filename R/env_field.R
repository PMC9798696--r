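# Gridded SST data model: NetCDF I/O, the 8-day backward rolling mean,
# point and uncertainty-weighted sampling, and the warmest-cell bearing
# search used by the biased random walk.

#' Construct a gridded environmental (SST) field
#'
#' @param times ordered vector of calendar days (Date).
#' @param lats,lons strictly monotone, regularly spaced axes of cell centres
#'   (degrees).
#' @param sst numeric array of dim `(time, lat, lon)`, degrees C, NA = missing.
#' @param cell_size_km nominal grid resolution in km (metadata only).
#' @return an `env_field` object.
#' @export
makeEnvField <- function(times, lats, lons, sst, cell_size_km = NULL) {
  times <- as.Date(times)
  if (is.unsorted(as.integer(times), strictly = TRUE)) {
    stop("time axis must be strictly increasing")
  }
  .check_axis <- function(ax, name, lo = -Inf, hi = Inf) {
    if (length(ax) > 1) {
      d <- diff(ax)
      if (any(d <= 0)) stop(name, " axis must be strictly increasing")
      if (max(d) - min(d) > 1e-9) stop(name, " axis spacing is irregular")
    }
    if (any(ax < lo | ax > hi)) stop(name, " axis out of range")
  }
  .check_axis(lats, "lat", -90, 90)
  .check_axis(lons, "lon")
  if (!all(dim(sst) == c(length(times), length(lats), length(lons)))) {
    stop("sst dimensions do not match (time, lat, lon) axes")
  }
  if (is.null(cell_size_km)) {
    dlat <- if (length(lats) > 1) abs(lats[2] - lats[1]) else 0.0833
    cell_size_km <- dlat * pi / 180 * EARTH_RADIUS_KM
  }
  structure(list(times = times, lats = as.numeric(lats),
                 lons = as.numeric(lons), sst = sst,
                 cell_size_km = cell_size_km),
            class = "env_field")
}

#' @export
print.env_field <- function(x, ...) {
  cat("env_field:", length(x$times), "days x", length(x$lats), "lat x",
      length(x$lons), "lon cells\n")
  cat("  time:", format(x$times[1]), "to", format(x$times[length(x$times)]), "\n")
  cat("  lat:", min(x$lats), "to", max(x$lats), " lon:", min(x$lons), "to",
      max(x$lons), "\n")
  cat(sprintf("  cell size ~%.1f km; %.1f%% missing\n", x$cell_size_km,
              100 * mean(is.na(x$sst))))
  invisible(x)
}

#' Uncertainty model for positional error
#'
#' Positional error is an isotropic 2-D Gaussian whose standard deviation is
#' `sigma_fraction` times the 95% confidence radius of a fix (default 0.25),
#' truncated at `truncation_sigmas` standard deviations (default 3, which
#' keeps 98.9% of the mass).
#'
#' @param sigma_fraction positive multiplier of `ci95_km`.
#' @param truncation_sigmas positive cutoff radius in sigma units.
#' @return an `uncertainty_model` list.
#' @export
uncertaintyModel <- function(sigma_fraction = 0.25, truncation_sigmas = 3) {
  stopifnot(sigma_fraction > 0, truncation_sigmas > 0)
  structure(list(sigma_fraction = sigma_fraction,
                 truncation_sigmas = truncation_sigmas),
            class = "uncertainty_model")
}

# ---- NetCDF I/O ------------------------------------------------------------

#' Read an SST field from NetCDF
#'
#' Expects dims `time`, `lat`, `lon` and a variable `sst` in degrees C with a
#' fill value for missing cells; time as days since an epoch or date strings.
#'
#' @param path NetCDF file path.
#' @return an `env_field`.
#' @export
readEnvField <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!"sst" %in% names(nc$var)) {
    stop("NetCDF file has no 'sst' variable: ", path)
  }
  lats <- ncdf4::ncvar_get(nc, "lat")
  lons <- ncdf4::ncvar_get(nc, "lon")
  tvals <- ncdf4::ncvar_get(nc, "time")
  tunits <- ncdf4::ncatt_get(nc, "time", "units")
  if (tunits$hasatt && grepl("days since", tunits$value)) {
    origin <- as.Date(sub("days since\\s+(\\S+).*", "\\1", tunits$value))
    times <- origin + as.integer(round(tvals))
  } else {
    times <- as.Date(tvals, origin = "1970-01-01")
  }
  sst <- ncdf4::ncvar_get(nc, "sst", collapse_degen = FALSE)  # (lon, lat, time)
  sst <- aperm(sst, c(3, 2, 1))
  csz <- ncdf4::ncatt_get(nc, 0, "cell_size_km")
  makeEnvField(times, lats, lons, sst,
               cell_size_km = if (csz$hasatt) csz$value else NULL)
}

#' Write an SST field to NetCDF
#'
#' @param field an `env_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnvField <- function(field, path) {
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lats)
  dim_t <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.integer(field$times), unlim = TRUE)
  var_sst <- ncdf4::ncvar_def("sst", "degrees_C", list(dim_lon, dim_lat, dim_t),
                              missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, list(var_sst))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var_sst, aperm(field$sst, c(3, 2, 1)))
  ncdf4::ncatt_put(nc, 0, "cell_size_km", field$cell_size_km)
  invisible(path)
}

# ---- rolling mean ----------------------------------------------------------

#' Backward rolling mean of an SST field
#'
#' The value at day t is the mean of the non-missing values over the window
#' of days (t - window + 1) .. t, per cell; a cell is missing only when the
#' whole window is missing.  The time axis is unchanged.  This is the
#' compositing used to increase satellite SST coverage under cloud.
#'
#' @param field an `env_field`.
#' @param window_days window length in days (>= 1); default 8.
#' @return an `env_field` with the same axes.
#' @export
backwardRollingMean <- function(field, window_days = 8) {
  stopifnot(window_days >= 1)
  if (window_days == 1) return(field)
  nt <- length(field$times)
  dm <- dim(field$sst)
  vals <- field$sst
  vals[is.na(vals)] <- 0
  pres <- array(as.numeric(!is.na(field$sst)), dm)
  out <- array(NA_real_, dm)
  # cumulative sums along time make each window O(1)
  csum <- apply(vals, c(2, 3), cumsum)       # (time, lat, lon)
  cnum <- apply(pres, c(2, 3), cumsum)
  if (nt == 1) { csum <- array(csum, dm); cnum <- array(cnum, dm) }
  for (t in seq_len(nt)) {
    lo <- max(1, t - window_days + 1)
    s <- csum[t, , ] - if (lo > 1) csum[lo - 1, , ] else 0
    n <- cnum[t, , ] - if (lo > 1) cnum[lo - 1, , ] else 0
    v <- s / n
    v[n == 0] <- NA_real_
    out[t, , ] <- v
  }
  makeEnvField(field$times, field$lats, field$lons, out, field$cell_size_km)
}

# ---- sampling --------------------------------------------------------------

# Nearest-cell index on a regular axis; at an exact midpoint the lower index
# wins.  Returns NA outside the axis' outer cell edges.
.axis_index <- function(ax, x) {
  if (length(ax) == 1) {
    return(ifelse(abs(x - ax) <= Inf, 1L, NA_integer_))
  }
  d <- ax[2] - ax[1]
  pos <- (x - ax[1]) / d
  i0 <- floor(pos)
  frac <- pos - i0
  idx <- as.integer(i0 + ifelse(frac <= 0.5 + 1e-12, 0, 1)) + 1L
  idx[x < ax[1] - d / 2 | x > ax[length(ax)] + d / 2] <- NA_integer_
  pmin(pmax(idx, 1L), length(ax))
}

.time_index <- function(field, date) {
  date <- as.Date(date)
  it <- match(as.integer(date), as.integer(field$times))
  if (anyNA(it)) stop("date ", format(date[which(is.na(it))[1]]),
                      " outside the field's time axis")
  it
}

#' Sample the SST value at a point
#'
#' Returns the value of the grid cell containing the position (nearest cell
#' centre; exact midpoints go to the lower index) for the given day, or NA if
#' that cell is missing.
#'
#' @param field an `env_field`.
#' @param lat,lon position (degrees); vectors recycle against `date`.
#' @param date calendar day(s) within the field's span.
#' @return numeric vector of degrees C, NA where missing or out of domain.
#' @export
samplePoint <- function(field, lat, lon, date) {
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  date <- rep_len(as.Date(date), n)
  it <- .time_index(field, date)
  ilat <- .axis_index(field$lats, lat)
  ilon <- .axis_index(field$lons, lon)
  out <- rep(NA_real_, n)
  ok <- !is.na(ilat) & !is.na(ilon)
  if (any(ok)) out[ok] <- field$sst[cbind(it[ok], ilat[ok], ilon[ok])]
  out
}

# Indices and great-circle distances of cells whose centres lie within
# radius_km of (lat, lon).  Scans only the bounding index window.
.cells_within <- function(field, lat, lon, radius_km) {
  dlat_deg <- radius_km / (pi / 180 * EARTH_RADIUS_KM)
  dlat <- if (length(field$lats) > 1) field$lats[2] - field$lats[1] else 1
  dlon <- if (length(field$lons) > 1) field$lons[2] - field$lons[1] else 1
  coslat <- max(cos(.deg2rad(min(abs(lat) + dlat_deg, 89.9))), 1e-6)
  ilat <- which(field$lats >= lat - dlat_deg - abs(dlat) &
                field$lats <= lat + dlat_deg + abs(dlat))
  dlon_deg <- dlat_deg / coslat
  ilon <- which(field$lons >= lon - dlon_deg - abs(dlon) &
                field$lons <= lon + dlon_deg + abs(dlon))
  if (!length(ilat) || !length(ilon)) {
    return(data.frame(ilat = integer(), ilon = integer(), dist = numeric()))
  }
  g <- expand.grid(ilat = ilat, ilon = ilon)
  g$dist <- greatCircleDistance(lat, lon, field$lats[g$ilat], field$lons[g$ilon])
  g[g$dist <= radius_km, , drop = FALSE]
}

#' Gaussian-weighted SST sample under positional uncertainty
#'
#' With sigma = `sigma_fraction * ci95_km`, returns the weighted mean of the
#' non-missing cells whose centres lie within `truncation_sigmas * sigma` of
#' the position, with weights `exp(-d^2 / (2 sigma^2))` where d is the
#' great-circle distance to the cell centre.  When `ci95_km` is 0 (or sigma
#' is below half a cell) this degrades to [samplePoint()].
#'
#' @inheritParams samplePoint
#' @param ci95_km 95% confidence radius of the position, km (>= 0).
#' @param model an [uncertaintyModel()].
#' @return degrees C, or NA when no valid cell lies in the window.
#' @export
sampleWeighted <- function(field, lat, lon, date, ci95_km,
                           model = uncertaintyModel()) {
  stopifnot(length(lat) == 1)
  if (is.na(ci95_km)) ci95_km <- 0
  if (ci95_km < 0) stop("ci95_km must be >= 0")
  sigma <- model$sigma_fraction * ci95_km
  if (sigma < field$cell_size_km / 2) return(samplePoint(field, lat, lon, date))
  it <- .time_index(field, date)
  cells <- .cells_within(field, lat, lon, model$truncation_sigmas * sigma)
  if (!nrow(cells)) return(NA_real_)
  v <- field$sst[cbind(it, cells$ilat, cells$ilon)]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  w <- exp(-cells$dist[ok]^2 / (2 * sigma^2))
  sum(w * v[ok]) / sum(w)
}

#' Bearing to the warmest cell within a search radius
#'
#' Among non-missing cells whose centres lie within `radius_km` of the
#' position (great-circle, excluding the cell containing the position
#' itself), returns the initial bearing to the centre of the warmest cell.
#' Ties go to the nearest such cell, then to the lowest (lat, lon) index.
#'
#' @inheritParams samplePoint
#' @param radius_km search radius in km (> 0); 50 km in the biased walk.
#' @return bearing in degrees, or NA when no eligible cell exists.
#' @export
bearingToMaxSST <- function(field, lat, lon, date, radius_km = 50) {
  stopifnot(radius_km > 0, length(lat) == 1)
  it <- .time_index(field, date)
  cells <- .cells_within(field, lat, lon, radius_km)
  if (!nrow(cells)) return(NA_real_)
  home_lat <- .axis_index(field$lats, lat)
  home_lon <- .axis_index(field$lons, lon)
  if (!is.na(home_lat) && !is.na(home_lon)) {
    cells <- cells[!(cells$ilat == home_lat & cells$ilon == home_lon), ,
                   drop = FALSE]
  }
  if (!nrow(cells)) return(NA_real_)
  v <- field$sst[cbind(it, cells$ilat, cells$ilon)]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  cells <- cells[ok, , drop = FALSE]; v <- v[ok]
  ord <- order(-v, cells$dist, cells$ilat, cells$ilon)
  best <- cells[ord[1], ]
  initialBearing(lat, lon, field$lats[best$ilat], field$lons[best$ilon])
}

#' Match a track to SST samples
#'
#' For each fix, samples the field with [sampleWeighted()] when `ci95_km` is
#' present and [samplePoint()] otherwise.  Fixes with missing SST are dropped
#' and counted.
#'
#' @param track a `tracks` data.frame holding one or more tracks.
#' @param field an `env_field`.
#' @param model an [uncertaintyModel()].
#' @return data.frame with columns `track_id`, `date`, `sst`, plus attributes
#'   `n_dropped` (fixes with missing SST) and `n_total`.
#' @export
matchTrackToEnv <- function(track, field, model = uncertaintyModel()) {
  track <- as.data.frame(track)
  n <- nrow(track)
  sst <- rep(NA_real_, n)
  exact <- is.na(track$ci95_km) | track$ci95_km <= 0 |
    model$sigma_fraction * track$ci95_km < field$cell_size_km / 2
  if (any(exact)) {
    sst[exact] <- samplePoint(field, track$lat[exact], track$lon[exact],
                              track$date[exact])
  }
  for (i in which(!exact)) {
    sst[i] <- sampleWeighted(field, track$lat[i], track$lon[i], track$date[i],
                             track$ci95_km[i], model)
  }
  keep <- !is.na(sst)
  out <- data.frame(track_id = track$track_id[keep], date = track$date[keep],
                    sst = sst[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_total") <- n
  if (!nrow(out)) warning("all fixes had missing SST; empty sample")
  out
}
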