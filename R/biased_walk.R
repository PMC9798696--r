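# Synthetic presence simulator: a biased random walk whose turning angles
# follow a Von Mises distribution centred on the relative bearing of the
# warmest SST within a search radius.  The concentration kappa prescribes
# the strength of temperature selection: kappa = 0 is no selection, large
# kappa means the walker almost always turns toward the warmest water.

#' Draw from a Von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampling; kappa = 0 reduces to the uniform circular
#' distribution.  Results are wrapped to (-180, 180].
#'
#' @param n number of draws.
#' @param center_deg mean direction, degrees.
#' @param kappa concentration, >= 0.
#' @return angles in degrees, (-180, 180].
#' @export
sampleVonMises <- function(n, center_deg = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) {
    theta <- .runif_angle(n)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u1 <- stats::runif(1)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        c0 <- kappa * (r - f)
        u2 <- stats::runif(1)
        if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) break
      }
      theta[i] <- sign(stats::runif(1) - 0.5) * acos(f) * 180 / pi
    }
  }
  out <- (theta + center_deg) %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Configuration of the biased random walk
#'
#' Defaults mirror the synthetic-presence design: 80-day tracks with a fixed
#' 50 km daily step and a 50 km SST search radius.
#'
#' @param n_days track length in days (number of daily fixes).
#' @param step_km fixed daily step length, km.
#' @param search_radius_km radius of the warmest-SST search, km.
#' @param kappa Von Mises concentration (selection strength), >= 0.
#' @param start_lat,start_lon start position, degrees.
#' @param start_date first day of the track.
#' @return a `biased_walk_config` list.
#' @export
biasedWalkConfig <- function(n_days = 80, step_km = 50, search_radius_km = 50,
                             kappa = 0, start_lat, start_lon,
                             start_date) {
  stopifnot(n_days >= 1, step_km > 0, search_radius_km > 0, kappa >= 0)
  structure(list(n_days = n_days, step_km = step_km,
                 search_radius_km = search_radius_km, kappa = kappa,
                 start_lat = start_lat, start_lon = start_lon,
                 start_date = as.Date(start_date)),
            class = "biased_walk_config")
}

#' Simulate one SST-biased presence track
#'
#' Daily steps of exactly `step_km`.  At each step the Von Mises centre is
#' the relative bearing (target bearing minus current heading) of the
#' warmest SST cell within `search_radius_km`; the drawn turning angle is
#' added to the current heading.  When the SST search finds nothing (cloud
#' gap or domain edge) the centre is 0 degrees, i.e. the heading persists.
#' The first heading is uniform.  Positions are exact (`ci95_km` is NA): the
#' synthetic organism's location is perfectly known.
#'
#' @param config a [biasedWalkConfig()].
#' @param field an `env_field` spanning the track's dates.
#' @param track_id id for the output track.
#' @return a `tracks` data.frame with one track of `n_days` daily fixes.
#' @export
simulateBiasedTrack <- function(config, field, track_id = "synthetic") {
  stopifnot(inherits(config, "biased_walk_config"))
  if (config$start_lat < min(field$lats) || config$start_lat > max(field$lats) ||
      config$start_lon < min(field$lons) || config$start_lon > max(field$lons)) {
    stop("start position outside the field domain")
  }
  .time_index(field, config$start_date)  # errors if outside the field's span
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- config$start_lat; lon[1] <- config$start_lon
  heading <- .runif_angle()
  for (i in seq_len(n - 1)) {
    target <- bearingToMaxSST(field, lat[i], lon[i], dates[i],
                              config$search_radius_km)
    center <- if (is.na(target)) 0 else signedTurningAngle(heading, target)
    turn <- sampleVonMises(1, center, config$kappa)
    heading <- (heading + turn) %% 360
    p <- destinationPoint(lat[i], lon[i], heading, config$step_km)
    lat[i + 1] <- p$lat; lon[i + 1] <- p$lon
  }
  makeTracks(track_id, dates, lat, lon)
}

#' Simulate cohorts of biased tracks over a kappa grid
#'
#' For each kappa in the grid, simulates `n_tracks` independent tracks.
#' Start positions are drawn uniformly from `start_region` (default: the
#' central half of the field's domain, keeping room to roam) unless a fixed
#' start is given in the template.  Each (kappa, track) pair has its own
#' seeded RNG stream.
#'
#' @param field an `env_field`.
#' @param kappas numeric vector of concentrations; default the nine-value
#'   grid 0, 0.25, 0.5, 0.75, 1, 2, 5, 10, 20.
#' @param n_tracks tracks per kappa (default 100).
#' @param config a [biasedWalkConfig()] template (kappa and start fields are
#'   overridden per track unless `fixed_start = TRUE`).
#' @param seed master integer seed.
#' @param start_region list(lat = c(min, max), lon = c(min, max)) to draw
#'   starts from; NULL = central half of the domain.
#' @param fixed_start use the template's start position for every track?
#' @return a `tracks` data.frame with a `kappa` column.
#' @export
simulateCohort <- function(field, kappas = c(0, 0.25, 0.5, 0.75, 1, 2, 5, 10, 20),
                           n_tracks = 100,
                           config = NULL, seed = 1L, start_region = NULL,
                           fixed_start = FALSE) {
  if (is.null(config)) {
    config <- biasedWalkConfig(kappa = 0,
                               start_lat = mean(field$lats),
                               start_lon = mean(field$lons),
                               start_date = field$times[1])
  }
  if (is.null(start_region)) {
    latq <- stats::quantile(range(field$lats), c(0.25, 0.75), names = FALSE)
    lonq <- stats::quantile(range(field$lons), c(0.25, 0.75), names = FALSE)
    start_region <- list(lat = latq, lon = lonq)
  }
  out <- list()
  for (k in kappas) {
    for (j in seq_len(n_tracks)) {
      set.seed(.derive_seed(seed, "biased", format(k, digits = 10), j))
      cf <- config
      cf$kappa <- k
      if (!fixed_start) {
        cf$start_lat <- stats::runif(1, start_region$lat[1], start_region$lat[2])
        cf$start_lon <- stats::runif(1, start_region$lon[1], start_region$lon[2])
      }
      id <- sprintf("k%s.%03d", format(k), j)
      tr <- simulateBiasedTrack(cf, field, track_id = id)
      tr$kappa <- k
      out[[id]] <- tr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- unique(c("tracks", class(res)))
  res
}
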