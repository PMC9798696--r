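# Synthetic SST-field generator.  Emulates the statistical structure of a
# basin-scale satellite SST product: a meridional gradient, mesoscale
# anomalies with finite space/time correlation scales, a seasonal cycle,
# white observation noise, and spatially clumped (cloud-like) missingness.

#' Configuration for the synthetic SST field
#'
#' Defaults describe a "northeast-Pacific-like" basin: 20-45 deg N,
#' 150-115 deg W, ~9 km cells, 22 degC at the southern edge cooling by
#' 0.35 degC per degree of latitude poleward, 1.5 degC mesoscale anomalies
#' with 150 km / 20 day correlation scales, a 2 degC seasonal cycle,
#' 0.2 degC noise, and 10% clumped missingness.
#'
#' @param lat_range,lon_range extents in degrees, c(min, max).
#' @param cell_size_deg grid spacing in degrees (0.0833 is about 9 km).
#' @param n_days number of daily time steps.
#' @param start_date first day of the field.
#' @param base_sst degC at the southern edge of the domain.
#' @param meridional_gradient degC per degree latitude (negative = cooler
#'   poleward in the northern hemisphere).
#' @param eddy_amplitude standard deviation of the mesoscale anomaly, degC.
#' @param eddy_length_scale_km spatial correlation scale of the anomaly.
#' @param eddy_time_scale_days temporal e-folding of the anomaly (AR(1)).
#' @param seasonal_amplitude amplitude of the annual sine, degC.
#' @param noise_sd white observation noise, degC.
#' @param missing_fraction fraction of cells masked, in [0, 1).
#' @param seed integer RNG seed.
#' @return a `synthetic_env_config` list.
#' @export
syntheticEnvConfig <- function(lat_range = c(20, 45), lon_range = c(-150, -115),
                               cell_size_deg = 0.0833, n_days = 90,
                               start_date = as.Date("2005-01-01"),
                               base_sst = 22, meridional_gradient = -0.35,
                               eddy_amplitude = 1.5, eddy_length_scale_km = 150,
                               eddy_time_scale_days = 20,
                               seasonal_amplitude = 2, noise_sd = 0.2,
                               missing_fraction = 0.1, seed = 1L) {
  stopifnot(diff(lat_range) > 0, diff(lon_range) > 0, cell_size_deg > 0,
            n_days >= 1, eddy_length_scale_km > 0, eddy_time_scale_days > 0,
            missing_fraction >= 0, missing_fraction < 1)
  structure(as.list(environment()), class = "synthetic_env_config")
}

# Smooth random field on (time, lat, lon): iid N(0,1) on a coarse grid with
# AR(1) innovation in time, lightly smoothed, bilinearly interpolated to the
# fine grid, and rescaled to unit variance.
.smooth_random_field <- function(lats, lons, n_days, length_scale_km,
                                 time_scale_days) {
  scale_deg <- length_scale_km / (pi / 180 * EARTH_RADIUS_KM)
  cl <- seq(min(lats) - scale_deg, max(lats) + scale_deg, by = scale_deg)
  cn <- seq(min(lons) - scale_deg, max(lons) + scale_deg, by = scale_deg)
  nlat <- length(cl); nlon <- length(cn)
  rho <- exp(-1 / time_scale_days)
  smooth2d <- function(m) {                 # 3x3 binomial smoothing, edge-padded
    p <- m[c(1, seq_len(nrow(m)), nrow(m)), c(1, seq_len(ncol(m)), ncol(m))]
    k <- c(1, 2, 1) / 4
    a <- k[1] * p[1:nrow(m), ] + k[2] * p[2:(nrow(m) + 1), ] +
      k[3] * p[3:(nrow(m) + 2), ]
    k[1] * a[, 1:ncol(m)] + k[2] * a[, 2:(ncol(m) + 1)] +
      k[3] * a[, 3:(ncol(m) + 2)]
  }
  out <- array(NA_real_, c(n_days, length(lats), length(lons)))
  # bilinear interpolation weights from coarse to fine, precomputed per axis
  interp_idx <- function(cax, fax) {
    pos <- (fax - cax[1]) / (cax[2] - cax[1])
    i0 <- pmin(pmax(floor(pos), 0), length(cax) - 2)
    list(i = as.integer(i0) + 1L, w = pos - i0)
  }
  ii <- interp_idx(cl, lats); jj <- interp_idx(cn, lons)
  z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  for (t in seq_len(n_days)) {
    if (t > 1) {
      z <- rho * z + sqrt(1 - rho^2) * matrix(stats::rnorm(nlat * nlon), nlat, nlon)
    }
    s <- smooth2d(z)
    s <- s / stats::sd(as.vector(s))
    a <- s[ii$i, jj$i] * (1 - ii$w) + s[ii$i + 1L, jj$i] * ii$w
    b <- s[ii$i, jj$i + 1L] * (1 - ii$w) + s[ii$i + 1L, jj$i + 1L] * ii$w
    out[t, , ] <- a * (1 - jj$w[col(a)]) + b * jj$w[col(b)]
  }
  out
}

#' Generate a synthetic SST field
#'
#' SST(t, lat, lon) = base + gradient * (lat - lat_min)
#'   + seasonal_amplitude * sin(2 pi doy / 365) + eddy(t, lat, lon) + noise,
#' where eddy is a smooth random field with the configured spatial and
#' temporal correlation scales.  Missing cells are drawn by thresholding a
#' second smooth field (clumped, cloud-like) at exactly `missing_fraction`
#' per day.  Fully reproducible from `config$seed`.
#'
#' @param config a [syntheticEnvConfig()].
#' @return an `env_field`.
#' @export
generateEnv <- function(config = syntheticEnvConfig()) {
  stopifnot(inherits(config, "synthetic_env_config"))
  lats <- seq(config$lat_range[1], config$lat_range[2], by = config$cell_size_deg)
  lons <- seq(config$lon_range[1], config$lon_range[2], by = config$cell_size_deg)
  times <- config$start_date + seq_len(config$n_days) - 1L
  nt <- config$n_days; nlat <- length(lats); nlon <- length(lons)
  doy <- as.integer(format(times, "%j"))
  base <- outer(rep(1, nt), config$base_sst +
                  config$meridional_gradient * (lats - config$lat_range[1]))
  sst <- array(rep(base, nlon), c(nt, nlat, nlon))
  sst <- sst + config$seasonal_amplitude * sin(2 * pi * doy / 365)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed %% .Machine$integer.max)
  if (config$eddy_amplitude > 0) {
    sst <- sst + config$eddy_amplitude *
      .smooth_random_field(lats, lons, nt, config$eddy_length_scale_km,
                           config$eddy_time_scale_days)
  }
  if (config$noise_sd > 0) {
    sst <- sst + array(stats::rnorm(length(sst), sd = config$noise_sd), dim(sst))
  }
  if (config$missing_fraction > 0) {
    cloud <- .smooth_random_field(lats, lons, nt, config$eddy_length_scale_km,
                                  3)
    for (t in seq_len(nt)) {
      thr <- stats::quantile(cloud[t, , ], config$missing_fraction)
      day <- sst[t, , ]
      day[cloud[t, , ] <= thr] <- NA_real_
      sst[t, , ] <- day
    }
  }
  makeEnvField(times, lats, lons, sst,
               cell_size_km = config$cell_size_deg * pi / 180 * EARTH_RADIUS_KM)
}

# Save/restore the global RNG state so generators can be seeded internally
# without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
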