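# Simulation-study engine: fraction of significant KS tests versus
# selection strength (kappa), versus the number of aggregated tracks, and
# versus the p-value threshold, with percentile-bootstrap confidence
# intervals and a correct/incorrect classification of each outcome.

#' Is a selection outcome correct for a known kappa?
#'
#' For kappa > 0 (true selection for warmer water) only class "warmer" is
#' correct; for kappa = 0 (no selection) only class "none" is.
#'
#' @param kappa the prescribed selection strength, >= 0.
#' @param class outcome class: "warmer", "colder", "both" or "none" (or a
#'   `selection_outcome`).
#' @return logical.
#' @export
correctOutcome <- function(kappa, class) {
  stopifnot(kappa >= 0)
  if (inherits(class, "selection_outcome")) class <- class$class
  if (kappa > 0) class == "warmer" else class == "none"
}

#' Percentile bootstrap CI for a fraction
#'
#' Resamples the binary outcomes with replacement `n_bootstrap` times and
#' returns the 2.5% and 97.5% quantiles of the resampled means.
#'
#' @param outcomes logical/0-1 vector.
#' @param n_bootstrap bootstrap draws.
#' @param seed integer seed.
#' @return c(low, high).
#' @export
bootstrapFractionCi <- function(outcomes, n_bootstrap = 1000, seed = 1L) {
  stopifnot(length(outcomes) >= 1)
  outcomes <- as.numeric(outcomes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(outcomes)
  means <- vapply(seq_len(n_bootstrap), function(i) {
    mean(outcomes[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  stats::quantile(means, c(0.025, 0.975), names = FALSE)
}

# Tabulate stored per-test p-values into one row per (kappa, model, k, alpha).
.tabulate_tests <- function(tests, alphas, n_bootstrap = 1000, seed = 1L) {
  keys <- unique(tests[, c("kappa", "model", "k")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- tests$kappa == keys$kappa[i] & tests$model == keys$model[i] &
      tests$k == keys$k[i]
    tt <- tests[sel, , drop = FALSE]
    for (alpha in alphas) {
      sw <- tt$p_warm <= alpha
      sc <- tt$p_cold <= alpha
      cls <- ifelse(sw & sc, "both", ifelse(sw, "warmer",
                                            ifelse(sc, "colder", "none")))
      corr <- vapply(cls, function(cl) correctOutcome(keys$kappa[i], cl),
                     logical(1))
      ci_w <- bootstrapFractionCi(sw, n_bootstrap,
                                  .derive_seed(seed, "ci", i, alpha, "w"))
      ci_c <- bootstrapFractionCi(sc, n_bootstrap,
                                  .derive_seed(seed, "ci", i, alpha, "c"))
      ci_k <- bootstrapFractionCi(corr, n_bootstrap,
                                  .derive_seed(seed, "ci", i, alpha, "k"))
      rows[[length(rows) + 1]] <- data.frame(
        kappa = keys$kappa[i], null_model = keys$model[i],
        n_tracks_aggregated = keys$k[i], alpha = alpha,
        fraction_significant_warm = mean(sw),
        warm_ci_low = ci_w[1], warm_ci_high = ci_w[2],
        fraction_significant_cold = mean(sc),
        cold_ci_low = ci_c[1], cold_ci_high = ci_c[2],
        fraction_correct = mean(corr),
        correct_ci_low = ci_k[1], correct_ci_high = ci_k[2],
        n_replicates = nrow(tt))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the power/error-rate simulation grid
#'
#' For each kappa: simulates a cohort of biased presence tracks, fits
#' monthly movement statistics from that cohort, simulates pseudo-absence
#' cohorts under the requested null models with monthly restarts, matches
#' everything to the SST field, then — for each aggregation size k — draws
#' random track subsets, pools presence and (date-matched) pseudo-absence
#' SST samples, runs both one-sided KS tests, classifies the outcome at each
#' alpha, and tabulates fractions with bootstrap CIs.  All per-test p-values
#' are stored so thresholds can be swept afterwards without re-simulation.
#'
#' @param field an `env_field`.
#' @param kappas kappa grid.
#' @param n_tracks presence tracks per kappa.
#' @param models null models to simulate ("all" = the four).
#' @param pool_models pool all models into one absence sample per test
#'   (default) or test each model separately?
#' @param null_replicates pseudo tracks per (source track, model).
#' @param aggregation_sizes numbers of tracks pooled per test.
#' @param alphas significance thresholds to tabulate.
#' @param n_subsets random subsets drawn per aggregation size (size 1
#'   instead enumerates every track exactly once).
#' @param n_bootstrap bootstrap draws for the CIs.
#' @param seed master seed.
#' @param walk a [biasedWalkConfig()] template (see [simulateCohort()]).
#' @param stats optional `monthly_stats` for the null models; default is to
#'   fit them from each kappa's presence cohort.
#' @return a `power_grid` list: `grid` (one row per cell), `tests` (per-test
#'   p-values), `meta`.
#' @export
runPowerGrid <- function(field, kappas = c(0, 0.5, 2, 20), n_tracks = 50,
                         models = "brownian", pool_models = TRUE,
                         null_replicates = 20,
                         aggregation_sizes = c(1, 5, 15),
                         alphas = 0.05, n_subsets = 100, n_bootstrap = 1000,
                         seed = 1L, walk = NULL, stats = NULL) {
  if (identical(models, "all")) models <- c("brownian", "levy", "crw", "jcrw")
  if (any(aggregation_sizes > n_tracks)) {
    stop("aggregation size exceeds the cohort size")
  }
  tests <- list()
  for (k in kappas) {
    cohort <- simulateCohort(field, kappas = k, n_tracks = n_tracks,
                             config = walk, seed = .derive_seed(seed, "cohort", k))
    st <- if (is.null(stats)) fitMonthlyStats(cohort) else stats
    ids <- unique(cohort$track_id)
    pres <- vector("list", length(ids)); names(pres) <- ids
    abs_by_model <- lapply(models, function(m) {
      v <- vector("list", length(ids)); names(v) <- ids; v
    })
    names(abs_by_model) <- models
    for (id in ids) {
      src <- cohort[cohort$track_id == id, , drop = FALSE]
      pres[[id]] <- matchTrackToEnv(src, field)$sst
      for (m in models) {
        ps <- generatePseudoTracks(src, m, st, n_replicates = null_replicates,
                                   seed = .derive_seed(seed, "null", k, id))
        abs_by_model[[m]][[id]] <- matchTrackToEnv(ps, field)$sst
      }
    }
    groups <- if (pool_models) list(pooled = models) else
      stats::setNames(as.list(models), models)
    for (ksize in aggregation_sizes) {
      # k = 1 is the per-track case: enumerate every track exactly once
      n_sub <- if (ksize == 1) length(ids) else n_subsets
      for (s in seq_len(n_sub)) {
        set.seed(.derive_seed(seed, "subset", k, ksize, s))
        pick <- if (ksize == 1) ids[s] else ids[sample.int(length(ids), ksize)]
        p_sample <- unlist(pres[pick], use.names = FALSE)
        if (!length(p_sample)) next
        for (g in names(groups)) {
          a_sample <- unlist(lapply(groups[[g]], function(m) {
            unlist(abs_by_model[[m]][pick], use.names = FALSE)
          }), use.names = FALSE)
          if (!length(a_sample)) next
          w <- ksOneSided(p_sample, a_sample, "warmer")
          cd <- ksOneSided(p_sample, a_sample, "colder")
          tests[[length(tests) + 1]] <- data.frame(
            kappa = k, model = g, k = ksize, subset = s,
            n_presence = w$n_presence, n_absence = w$n_absence,
            D_warm = w$D, p_warm = w$p_value,
            D_cold = cd$D, p_cold = cd$p_value)
        }
      }
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  grid <- .tabulate_tests(tests, alphas, n_bootstrap, seed)
  structure(list(grid = grid, tests = tests,
                 meta = list(seed = seed, n_tracks = n_tracks,
                             models = models, pool_models = pool_models,
                             null_replicates = null_replicates,
                             n_subsets = n_subsets, alphas = alphas)),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat("power_grid:", nrow(x$grid), "cells from", nrow(x$tests), "tests\n")
  print(utils::head(x$grid[, c("kappa", "null_model", "n_tracks_aggregated",
                               "alpha", "fraction_significant_warm",
                               "fraction_significant_cold",
                               "fraction_correct")], 12))
  invisible(x)
}

#' Re-threshold a stored power grid
#'
#' Reclassifies the stored per-test p-values at new significance thresholds
#' without re-simulation.  Lowering alpha never adds significant tests.
#'
#' @param grid a `power_grid` (or its `tests` data.frame).
#' @param alphas thresholds to tabulate.
#' @param n_bootstrap,seed see [bootstrapFractionCi()].
#' @return a grid data.frame, one row per (kappa, model, k, alpha).
#' @export
thresholdSweep <- function(grid, alphas, n_bootstrap = 1000, seed = 1L) {
  tests <- if (inherits(grid, "power_grid")) grid$tests else grid
  .tabulate_tests(tests, alphas, n_bootstrap, seed)
}
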