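# Shared fixtures, built in code.  Fields are cached per session: several
# test files reuse the same synthetic ocean.

# Deterministic gradient-only field: SST = 10 + 0.5 * (lat - lat_min), no
# eddies, no noise, no seasonality, no missingness.
gradient_field <- function(lat_range = c(0, 10), lon_range = c(0, 10),
                           cell = 0.25, n_days = 10, gradient = 0.5,
                           base = 10) {
  cfg <- syntheticEnvConfig(lat_range = lat_range, lon_range = lon_range,
                            cell_size_deg = cell, n_days = n_days,
                            base_sst = base, meridional_gradient = gradient,
                            eddy_amplitude = 0, seasonal_amplitude = 0,
                            noise_sd = 0, missing_fraction = 0, seed = 1)
  generateEnv(cfg)
}

# The default-condition synthetic ocean used by the simulation-study tests:
# full basin extent and physics, coarsened to 0.25 degree cells to keep the
# suite fast (selection operates at the 50 km search radius, which spans
# several cells at either resolution).
study_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- syntheticEnvConfig(cell_size_deg = 0.25, n_days = 100, seed = 11)
      cache <<- backwardRollingMean(generateEnv(cfg), 8)
    }
    cache
  }
})

# A small observed-style track wandering on the sphere.
toy_track <- function(n = 30, start_date = as.Date("2005-01-05"), seed = 42) {
  set.seed(seed)
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- 30; lon[1] <- -130
  h <- 90
  for (i in 2:n) {
    h <- (h + runif(1, -60, 60)) %% 360
    p <- destinationPoint(lat[i - 1], lon[i - 1], h, rlnorm(1, 3.3, 0.6))
    lat[i] <- p$lat; lon[i] <- p$lon
  }
  makeTracks("toy", start_date + 0:(n - 1), lat, lon)
}
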