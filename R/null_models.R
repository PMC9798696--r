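# The four environmentally naive null movement models — Brownian motion,
# truncated Levy flight, correlated random walk (CRW), and joint CRW — and
# the monthly-restart driver that turns an observed track into a cohort of
# date-aligned pseudo-absence tracks.

#' Truncated Levy flight parameters
#'
#' Steps follow a power law l^(-mu) truncated to [l_min, l_max].  Truncation
#' gives finite variance, so mu only needs to be positive (the classical
#' 1 < mu <= 3 is relaxed).
#'
#' @param mu power-law exponent, > 0.
#' @param l_min minimum step, km, > 0 (default 0.001 km = 1 m).
#' @param l_max maximum step, km, > l_min.
#' @return a `levy_params` list.
#' @export
levyParams <- function(mu = 2, l_min = 0.001, l_max = 500) {
  if (!(mu > 0)) stop("mu must be > 0")
  if (!(l_min > 0)) stop("l_min must be > 0")
  if (!(l_max > l_min)) stop("l_max must be > l_min")
  structure(list(mu = mu, l_min = l_min, l_max = l_max), class = "levy_params")
}

#' Default Levy truncation from observed steps
#'
#' l_max is set to three times the 99.5th percentile of the pooled observed
#' step lengths; mu and l_min keep their defaults.
#'
#' @param stats a `monthly_stats` object.
#' @param mu,l_min see [levyParams()].
#' @return a `levy_params` list.
#' @export
levyParamsFromStats <- function(stats, mu = 2, l_min = 0.001) {
  lmax <- 3 * stats::quantile(stats$pooled$steps, 0.995, names = FALSE)
  levyParams(mu = mu, l_min = l_min, l_max = lmax)
}

#' Truncated power-law step density
#'
#' Density per km: `(1 - mu) / (l_max^(1-mu) - l_min^(1-mu)) * l^(-mu)` for
#' mu != 1, and `l^(-1) / (ln l_max - ln l_min)` for mu = 1; zero outside
#' [l_min, l_max].
#'
#' @param l step length(s), km.
#' @param params a [levyParams()].
#' @return densities.
#' @export
levyPdf <- function(l, params) {
  stopifnot(inherits(params, "levy_params"))
  mu <- params$mu
  dens <- if (abs(mu - 1) < 1e-12) {
    l^(-mu) / (log(params$l_max) - log(params$l_min))
  } else {
    (1 - mu) / (params$l_max^(1 - mu) - params$l_min^(1 - mu)) * l^(-mu)
  }
  dens[l < params$l_min | l > params$l_max] <- 0
  dens
}

#' Inverse CDF of the truncated power law
#'
#' Closed-form inversion: for mu != 1,
#' `l = (l_min^(1-mu) + u (l_max^(1-mu) - l_min^(1-mu)))^(1/(1-mu))`; for
#' mu = 1, `l = l_min (l_max / l_min)^u`.  Monotone in u.
#'
#' @param u probabilities in [0, 1].
#' @param params a [levyParams()].
#' @return step lengths in km.
#' @export
levyInverseCdf <- function(u, params) {
  stopifnot(inherits(params, "levy_params"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  mu <- params$mu
  if (abs(mu - 1) < 1e-12) {
    params$l_min * (params$l_max / params$l_min)^u
  } else {
    a <- params$l_min^(1 - mu)
    b <- params$l_max^(1 - mu)
    (a + u * (b - a))^(1 / (1 - mu))
  }
}

#' Rescale a step length for an uneven time gap
#'
#' Diffusive scaling: step * sqrt(dt_new / dt_ref).
#'
#' @param step_km step length, km.
#' @param dt_new,dt_ref time gaps in days, > 0.
#' @return rescaled step, km.
#' @export
rescaleStep <- function(step_km, dt_new, dt_ref = 1) {
  if (any(dt_new <= 0) || any(dt_ref <= 0)) stop("time gaps must be positive")
  step_km * sqrt(dt_new / dt_ref)
}

.runif_angle <- function(n = 1) {
  # uniform on (-180, 180]
  180 - stats::runif(n) * 360
}

#' Simulate one environment-blind track segment
#'
#' Produces one position per date, starting exactly at `start`.  Per step of
#' gap dt days: Brownian motion draws an absolute bearing uniformly and a
#' lognormal step from the month's log moments, rescaled by sqrt(dt); the
#' truncated Levy flight draws a uniform bearing and an inverse-CDF step,
#' rescaled by sqrt(dt); the CRW accumulates empirical monthly turning
#' angles on the current heading and draws empirical monthly steps; the
#' joint CRW draws (angle, step) pairs jointly.  CRW/JCRW bridge date gaps
#' by repeating daily draws rather than rescaling.  The first heading of a
#' segment is uniform.  No model sees the environment.
#'
#' @param model one of "brownian", "levy", "crw", "jcrw".
#' @param start_lat,start_lon start position, degrees.
#' @param dates ordered vector of calendar days; the first is the anchor.
#' @param stats a `monthly_stats` object.
#' @param levy_params a [levyParams()] (Levy model only).
#' @param brownian_dist "lognormal" (default; moments are fitted on the log
#'   scale, guaranteeing positive steps) or "truncnorm" (Gaussian on the
#'   natural scale, truncated at zero by resampling).
#' @return data.frame with `date`, `lat`, `lon`.
#' @export
simulateSegment <- function(model, start_lat, start_lon, dates, stats,
                            levy_params = NULL,
                            brownian_dist = c("lognormal", "truncnorm")) {
  model <- match.arg(model, c("brownian", "levy", "crw", "jcrw"))
  brownian_dist <- match.arg(brownian_dist)
  dates <- as.Date(dates)
  n <- length(dates)
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- start_lat; lon[1] <- start_lon
  heading <- .runif_angle()
  if (n == 1) return(data.frame(date = dates, lat = lat, lon = lon))
  for (i in 2:n) {
    dt <- as.integer(dates[i] - dates[i - 1])
    month <- as.integer(format(dates[i], "%m"))
    if (model %in% c("brownian", "levy")) {
      heading <- .runif_angle()
      step <- if (model == "brownian") {
        m <- .month_stats(stats, month)
        if (brownian_dist == "lognormal") {
          exp(stats::rnorm(1, m$log_mean, m$log_sd))
        } else {
          mu <- mean(m$steps); sdv <- stats::sd(m$steps)
          s <- stats::rnorm(1, mu, sdv)
          while (s <= 0) s <- stats::rnorm(1, mu, sdv)
          s
        }
      } else {
        levyInverseCdf(stats::runif(1), levy_params)
      }
      step <- rescaleStep(step, dt, 1)
      p <- destinationPoint(lat[i - 1], lon[i - 1], heading, step)
      lat[i] <- p$lat; lon[i] <- p$lon
    } else {
      # CRW / JCRW: one daily draw per calendar day in the gap
      la <- lat[i - 1]; lo <- lon[i - 1]
      for (k in seq_len(dt)) {
        if (model == "crw") {
          ang <- sampleAngle(stats, month)
          step <- sampleStep(stats, month)
        } else {
          j <- sampleJoint(stats, month)
          ang <- j$turning_deg; step <- j$step_km
        }
        heading <- (heading + ang) %% 360
        p <- destinationPoint(la, lo, heading, step)
        la <- p$lat; lo <- p$lon
      }
      lat[i] <- la; lon[i] <- lo
    }
  }
  data.frame(date = dates, lat = lat, lon = lon)
}

# Deterministic 31-bit seed from a master seed and a label, via a polynomial
# string hash: reproducible and order-independent across cohorts.
.derive_seed <- function(master, ...) {
  label <- paste(..., sep = "|")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(master) * 2654435761) %% 2147483647)
}

#' Generate pseudo-absence tracks for one observed track
#'
#' The source track's date span is cut at calendar-month boundaries.  Each
#' month segment is simulated independently, starting exactly at the
#' observed animal position on the segment's first date (the deployment fix
#' for the first segment; thereafter the fix dated the 1st of the month, or
#' the earliest fix of that month when the 1st is missing).  Headings do not
#' carry across restarts.  Pseudo fixes are date-aligned one-to-one with the
#' source fixes.  Each (track, model, replicate) gets its own RNG stream
#' derived from `seed`.
#'
#' @param source a `tracks` data.frame holding exactly one track.
#' @param model "brownian", "levy", "crw" or "jcrw".
#' @param stats a `monthly_stats` object.
#' @param n_replicates number of pseudo tracks (100 in a full analysis).
#' @param seed master integer seed.
#' @param levy_params a [levyParams()]; defaults to
#'   [levyParamsFromStats()] when the model is "levy".
#' @param brownian_dist see [simulateSegment()].
#' @return a `tracks` data.frame with extra columns `source_track_id`,
#'   `model`, `replicate`; `ci95_km` inherited from the date-matched source
#'   fix.
#' @export
generatePseudoTracks <- function(source, model, stats, n_replicates = 100,
                                 seed = 1L, levy_params = NULL,
                                 brownian_dist = "lognormal") {
  source <- as.data.frame(source)
  if (length(unique(source$track_id)) != 1) {
    stop("generatePseudoTracks expects a single source track")
  }
  if (nrow(source) < 2) stop("source track needs at least 2 fixes")
  source <- source[order(source$date), ]
  if (model == "levy" && is.null(levy_params)) {
    levy_params <- levyParamsFromStats(stats)
  }
  ym <- format(source$date, "%Y-%m")
  seg_ids <- match(ym, unique(ym))
  segments <- lapply(unique(seg_ids), function(s) source[seg_ids == s, , drop = FALSE])
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(.derive_seed(seed, source$track_id[1], model, r))
    pieces <- lapply(segments, function(seg) {
      simulateSegment(model, seg$lat[1], seg$lon[1], seg$date, stats,
                      levy_params = levy_params, brownian_dist = brownian_dist)
    })
    piece <- do.call(rbind, pieces)
    piece$track_id <- paste0(source$track_id[1], ".", model, ".", r)
    piece$source_track_id <- source$track_id[1]
    piece$model <- model
    piece$replicate <- r
    piece$ci95_km <- source$ci95_km[match(piece$date, source$date)]
    reps[[r]] <- piece
  }
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  class(out) <- unique(c("tracks", class(out)))
  out
}

#' Generate pseudo-absence cohorts for a track set
#'
#' Convenience wrapper over [generatePseudoTracks()] for several source
#' tracks and models.
#'
#' @param tracks a `tracks` data.frame.
#' @param models character vector of model names, or "all".
#' @inheritParams generatePseudoTracks
#' @return one `tracks` data.frame with all pseudo tracks.
#' @export
generatePseudoCohort <- function(tracks, models = "all", stats,
                                 n_replicates = 100, seed = 1L,
                                 levy_params = NULL) {
  if (identical(models, "all")) models <- c("brownian", "levy", "crw", "jcrw")
  tracks <- as.data.frame(tracks)
  out <- list()
  for (id in unique(tracks$track_id)) {
    src <- tracks[tracks$track_id == id, , drop = FALSE]
    for (m in models) {
      out[[paste(id, m)]] <- generatePseudoTracks(
        src, m, stats, n_replicates = n_replicates, seed = seed,
        levy_params = levy_params)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
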