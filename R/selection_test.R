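# One-sided two-sample Kolmogorov-Smirnov tests for warmer/colder SST
# selection, calendar aggregation of samples, outcome classification, and
# Bonferroni adjustment.

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' With Fp, Fa the right-continuous ECDFs of the presence and pseudo-absence
#' samples: direction "warmer" takes D = max over the pooled values of
#' (Fa - Fp) — rejecting means the presence CDF lies below the absence CDF,
#' i.e. presences sit at higher SST; direction "colder" takes
#' D = max(Fp - Fa).  D is floored at 0.  The p-value is the asymptotic
#' one-sided formula exp(-2 D^2 m n / (m + n)), capped at 1.
#'
#' @param presence,absence numeric samples (non-empty, finite).
#' @param direction "warmer" or "colder".
#' @return a `ks_result` list: `direction`, `D`, `p_value`, `n_presence`,
#'   `n_absence`.
#' @export
ksOneSided <- function(presence, absence, direction = c("warmer", "colder")) {
  direction <- match.arg(direction)
  if (!length(presence) || !length(absence)) stop("samples must be non-empty")
  if (any(!is.finite(presence)) || any(!is.finite(absence))) {
    stop("samples must be finite")
  }
  m <- length(presence); n <- length(absence)
  pooled <- sort(unique(c(presence, absence)))
  Fp <- findInterval(pooled, sort(presence)) / m
  Fa <- findInterval(pooled, sort(absence)) / n
  D <- if (direction == "warmer") max(Fa - Fp) else max(Fp - Fa)
  D <- max(D, 0)
  p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
  structure(list(direction = direction, D = D, p_value = p,
                 n_presence = m, n_absence = n),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("one-sided KS (%s): D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$direction, x$D, x$p_value, x$n_presence, x$n_absence))
  invisible(x)
}

#' Classify a pair of one-sided tests into a selection outcome
#'
#' "warmer" iff only the warmer-direction test is significant at `alpha`;
#' "colder" symmetrically; "both" when both are; "none" otherwise.
#'
#' @param p_warm,p_cold p-values of the warmer- and colder-direction tests.
#' @param alpha significance threshold in (0, 1) (or exactly 1 for sweeps).
#' @return a `selection_outcome` list: `class`, `alpha`, `p_warm`, `p_cold`.
#' @export
classifySelection <- function(p_warm, p_cold, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1, p_warm >= 0, p_warm <= 1,
            p_cold >= 0, p_cold <= 1)
  sw <- p_warm <= alpha; sc <- p_cold <= alpha
  cls <- if (sw && sc) "both" else if (sw) "warmer" else if (sc) "colder" else "none"
  structure(list(class = cls, alpha = alpha, p_warm = p_warm, p_cold = p_cold),
            class = "selection_outcome")
}

#' Run both one-sided tests and classify
#'
#' @inheritParams ksOneSided
#' @param alpha significance threshold.
#' @return a `selection_outcome` with the two `ks_result`s attached as
#'   `warm` and `cold`.
#' @export
testSelection <- function(presence, absence, alpha = 0.05) {
  w <- ksOneSided(presence, absence, "warmer")
  c_ <- ksOneSided(presence, absence, "colder")
  out <- classifySelection(w$p_value, c_$p_value, alpha)
  out$warm <- w; out$cold <- c_
  out
}

#' Aggregate dated SST samples at a calendar scale
#'
#' Pools samples by calendar period (pooled across years, mirroring
#' seasonal aggregation): "monthly" gives up to 12 pools, "bimonthly" 6,
#' "quarterly" 4, "semiannual" 2, and "yearly"/"all" a single pool.
#'
#' @param samples data.frame with columns `date` and `sst` (e.g. from
#'   [matchTrackToEnv()]).
#' @param grouping one of "all", "monthly", "bimonthly", "quarterly",
#'   "semiannual", "yearly".
#' @return named list of numeric vectors, one per non-empty group.
#' @export
aggregateSamples <- function(samples,
                             grouping = c("all", "monthly", "bimonthly",
                                          "quarterly", "semiannual", "yearly")) {
  grouping <- match.arg(grouping)
  mth <- as.integer(format(as.Date(samples$date), "%m"))
  key <- switch(grouping,
    all = , yearly = rep("all", length(mth)),
    monthly = sprintf("M%02d", mth),
    bimonthly = sprintf("B%d", (mth + 1) %/% 2),
    quarterly = sprintf("Q%d", (mth + 2) %/% 3),
    semiannual = sprintf("H%d", (mth + 5) %/% 6))
  out <- split(samples$sst, key)
  out[vapply(out, length, integer(1)) > 0]
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param k_tests number of tests (>= 1).
#' @return alpha / k_tests.
#' @export
bonferroniAlpha <- function(alpha, k_tests) {
  stopifnot(k_tests >= 1)
  alpha / k_tests
}
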