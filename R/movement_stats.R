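# Per-calendar-month step-length and turning-angle distributions extracted
# from observed tracks: the empirical basis of all four null movement
# models.  Step-length moments are computed on the log scale (step lengths
# are strongly right-skewed), pooled by month to absorb seasonal behaviour.

#' Extract step lengths and turning angles from tracks
#'
#' Step i is the great-circle distance from fix i-1 to fix i; turning angle
#' i is the signed difference between the bearings of steps i-1 and i (the
#' first step of a track has no turning angle).  Each step is stamped with
#' the calendar month of its arrival fix and the day gap to the previous
#' fix.  Zero-length steps are dropped (their bearing is undefined).
#'
#' @param tracks a `tracks` data.frame (one or more tracks).
#' @return data.frame with columns `track_id`, `date`, `month`, `dt_days`,
#'   `step_km`, `turning_deg` (NA for the first step of each track).
#' @export
extractStepsAngles <- function(tracks) {
  tracks <- as.data.frame(tracks)
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$date), ]
    n <- nrow(tr)
    if (n < 2) stop("track '", tr$track_id[1], "' has fewer than 2 fixes")
    step <- greatCircleDistance(tr$lat[-n], tr$lon[-n], tr$lat[-1], tr$lon[-1])
    keep <- step > 0
    i0 <- which(keep)          # indices into steps; fix i0 -> fix i0+1
    if (!length(i0)) return(NULL)
    brg <- initialBearing(tr$lat[i0], tr$lon[i0], tr$lat[i0 + 1], tr$lon[i0 + 1])
    ang <- c(NA_real_, signedTurningAngle(brg[-length(brg)], brg[-1]))
    data.frame(track_id = tr$track_id[1],
               date = tr$date[i0 + 1],
               month = as.integer(format(tr$date[i0 + 1], "%m")),
               dt_days = as.integer(tr$date[i0 + 1] - tr$date[i0]),
               step_km = step[i0],
               turning_deg = ang,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Fit monthly movement statistics
#'
#' Pools steps and turning angles across tracks by calendar month.  For each
#' month it records the mean and standard deviation of `ln(step_km)`, the
#' raw empirical step and angle samples, and the joint (angle, step) pairs
#' (only steps whose turning angle is defined enter the joint set).  Steps
#' spanning more than one day conflate multi-day displacement and are
#' excluded by default.
#'
#' @param tracks a `tracks` data.frame, or the output of
#'   [extractStepsAngles()].
#' @param include_multiday keep steps with `dt_days > 1`? Default FALSE.
#' @return a `monthly_stats` object: per-month list with elements
#'   `log_mean`, `log_sd`, `steps`, `angles`, `joint` (data.frame
#'   `turning_deg`, `step_km`), `n_steps`, `n_angles`; plus a pooled
#'   all-month fallback.
#' @export
fitMonthlyStats <- function(tracks, include_multiday = FALSE) {
  sa <- if (is.data.frame(tracks) && "step_km" %in% names(tracks)) {
    tracks
  } else {
    extractStepsAngles(tracks)
  }
  if (!include_multiday) sa <- sa[sa$dt_days == 1, , drop = FALSE]
  if (!nrow(sa)) stop("no usable steps (after the single-day filter)")
  per_month <- function(d) {
    lg <- log(d$step_km)
    ang <- d$turning_deg[!is.na(d$turning_deg)]
    jnt <- d[!is.na(d$turning_deg), c("turning_deg", "step_km"), drop = FALSE]
    rownames(jnt) <- NULL
    list(log_mean = mean(lg),
         log_sd = if (length(lg) > 1) stats::sd(lg) else 0,
         steps = d$step_km, angles = ang, joint = jnt,
         n_steps = nrow(d), n_angles = length(ang))
  }
  months <- lapply(1:12, function(m) {
    d <- sa[sa$month == m, , drop = FALSE]
    if (!nrow(d)) NULL else per_month(d)
  })
  structure(list(months = months, pooled = per_month(sa)),
            class = "monthly_stats")
}

#' @export
print.monthly_stats <- function(x, ...) {
  n <- vapply(x$months, function(m) if (is.null(m)) 0L else m$n_steps, integer(1))
  cat("monthly_stats:", sum(n), "steps;",
      sum(n > 0), "of 12 months populated\n")
  invisible(x)
}

# Month entry with the pooled fallback (warning once per call site is too
# chatty inside simulators; warn once per lookup).
.month_stats <- function(stats, month, fallback = TRUE) {
  m <- stats$months[[month]]
  if (is.null(m)) {
    if (!fallback) stop("no movement data for month ", month,
                        " and fallback disabled")
    warning("no movement data for month ", month,
            "; falling back to the all-month pool", call. = FALSE)
    m <- stats$pooled
  }
  m
}

#' Draw a step length from a month's empirical distribution
#'
#' @param stats a `monthly_stats` object.
#' @param month calendar month 1-12.
#' @param n number of draws.
#' @param fallback pool all months when the month has no data?
#' @return step lengths in km.
#' @export
sampleStep <- function(stats, month, n = 1, fallback = TRUE) {
  m <- .month_stats(stats, month, fallback)
  m$steps[sample.int(length(m$steps), n, replace = TRUE)]
}

#' Draw a turning angle from a month's empirical distribution
#'
#' @inheritParams sampleStep
#' @return turning angles in degrees, (-180, 180].
#' @export
sampleAngle <- function(stats, month, n = 1, fallback = TRUE) {
  m <- .month_stats(stats, month, fallback)
  if (!length(m$angles)) stop("month ", month, " has no turning angles")
  m$angles[sample.int(length(m$angles), n, replace = TRUE)]
}

#' Draw joint (turning angle, step length) pairs
#'
#' Resamples observed pairs, preserving the empirical correlation between
#' long steps and small turns.
#'
#' @inheritParams sampleStep
#' @return data.frame with columns `turning_deg`, `step_km`.
#' @export
sampleJoint <- function(stats, month, n = 1, fallback = TRUE) {
  m <- .month_stats(stats, month, fallback)
  if (!nrow(m$joint)) stop("month ", month, " has no joint pairs")
  m$joint[sample.int(nrow(m$joint), n, replace = TRUE), , drop = FALSE]
}

#' Serialise monthly statistics to JSON
#'
#' Stores per-month log moments and the raw empirical arrays so simulations
#' can be reproduced without the source tracks.
#'
#' @param stats a `monthly_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMonthlyStats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns", pretty = FALSE)
  invisible(path)
}

#' Read monthly statistics written by [writeMonthlyStats()]
#'
#' @param path JSON path.
#' @return a `monthly_stats` object.
#' @export
readMonthlyStats <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(m) {
    if (is.null(m) || length(m) == 0) return(NULL)
    list(log_mean = as.numeric(m$log_mean),
         log_sd = as.numeric(m$log_sd),
         steps = as.numeric(unlist(m$steps)),
         angles = as.numeric(unlist(m$angles)),
         joint = data.frame(
           turning_deg = as.numeric(unlist(m$joint$turning_deg)),
           step_km = as.numeric(unlist(m$joint$step_km))),
         n_steps = as.integer(m$n_steps),
         n_angles = as.integer(m$n_angles))
  }
  months <- lapply(seq_len(12), function(i) {
    if (i <= length(raw$months)) fix(raw$months[[i]]) else NULL
  })
  structure(list(months = months, pooled = fix(raw$pooled)),
            class = "monthly_stats")
}
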