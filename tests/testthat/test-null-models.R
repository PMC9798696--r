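# Truncated Levy machinery, the sqrt(dt) rescaling, the four simulators,
# and the monthly-restart driver.

test_that("truncated Levy pdf obeys its closed form and normalises", {
  p <- levyParams(mu = 2, l_min = 1, l_max = 100)
  expect_equal(levyPdf(0.5, p), 0)
  expect_equal(levyPdf(150, p), 0)
  for (mu in c(0.5, 1, 1.5, 2, 3)) {
    pp <- levyParams(mu = mu, l_min = 1, l_max = 100)
    q <- integrate(levyPdf, 1, 100, params = pp, rel.tol = 1e-10,
                   subdivisions = 500)
    expect_lt(abs(q$value - 1), 1e-8)
  }
  # mu = 1 branch evaluated analytically: ln(lmax) - ln(lmin) = 2
  p1 <- levyParams(mu = 1, l_min = 1, l_max = exp(2))
  expect_equal(levyPdf(1, p1), 1 / 2, tolerance = 1e-12)
  expect_error(levyParams(mu = 0), "mu")
  expect_error(levyParams(l_min = 0), "l_min")
  expect_error(levyParams(l_min = 5, l_max = 2), "l_max")
})

test_that("Levy inverse CDF matches numeric inversion of the pdf", {
  p <- levyParams(mu = 2, l_min = 1, l_max = 100)
  expect_equal(levyInverseCdf(0, p), 1)
  expect_equal(levyInverseCdf(1, p), 100)
  expect_equal(levyInverseCdf(0.5, p), 1 / (1 - 0.495), tolerance = 1e-9)
  p1 <- levyParams(mu = 1, l_min = 1, l_max = 100)
  expect_equal(levyInverseCdf(0.5, p1), 10, tolerance = 1e-12)
  expect_error(levyInverseCdf(1.2, p), "\\[0, 1\\]")
  # numeric CDF-inversion oracle at 100 u values, several mu
  for (mu in c(0.5, 1, 2)) {
    pp <- levyParams(mu = mu, l_min = 1, l_max = 100)
    cdf <- function(l) integrate(levyPdf, 1, l, params = pp,
                                 rel.tol = 1e-12)$value
    u <- seq(0.005, 0.995, length.out = 100)
    l_num <- vapply(u, function(ui) {
      uniroot(function(l) cdf(l) - ui, c(1, 100), tol = 1e-12)$root
    }, numeric(1))
    expect_equal(levyInverseCdf(u, pp), l_num, tolerance = 1e-8)
  }
  # monotone in u
  u <- seq(0, 1, length.out = 200)
  expect_true(all(diff(levyInverseCdf(u, p)) > 0))
})

test_that("Levy sampler ECDF matches the analytic CDF", {
  set.seed(10)
  for (mu in c(0.5, 1, 1.5, 2, 3)) {
    p <- levyParams(mu = mu, l_min = 1, l_max = 100)
    draws <- levyInverseCdf(runif(1e5), p)
    acdf <- if (abs(mu - 1) < 1e-12) {
      function(l) log(l) / log(100)
    } else {
      function(l) (l^(1 - mu) - 1) / (100^(1 - mu) - 1)
    }
    grid <- levyInverseCdf(seq(0.001, 0.999, length.out = 400), p)
    expect_lt(max(abs(ecdf(draws)(grid) - acdf(grid))), 0.005)
  }
})

test_that("step rescaling is exactly sqrt(dt) and composes", {
  expect_equal(rescaleStep(10, 1, 1), 10)
  expect_equal(rescaleStep(10, 4, 1), 20)
  expect_equal(rescaleStep(rescaleStep(7, 2, 1), 4, 2), rescaleStep(7, 4, 1))
  expect_error(rescaleStep(10, 0), "positive")
})

test_that("degenerate samplers give exactly the prescribed motion", {
  # lognormal with log_sd = 0: every Brownian step exactly 50 km
  st <- list(months = rep(list(NULL), 12),
             pooled = list(log_mean = log(50), log_sd = 0, steps = 50,
                           angles = 0,
                           joint = data.frame(turning_deg = 0, step_km = 50),
                           n_steps = 1, n_angles = 1))
  st$months[[6]] <- st$pooled
  class(st) <- "monthly_stats"
  dates <- as.Date("2005-06-01") + 0:20
  set.seed(11)
  seg <- simulateSegment("brownian", 30, -140, dates, st)
  steps <- greatCircleDistance(seg$lat[-21], seg$lon[-21],
                               seg$lat[-1], seg$lon[-1])
  expect_equal(steps, rep(50, 20), tolerance = 1e-9)
  # a single (0 deg, 50 km) joint pair: great-circle straight track
  seg2 <- simulateSegment("jcrw", 0, 0, dates, st)
  sa <- extractStepsAngles(makeTracks("j", dates, seg2$lat, seg2$lon))
  expect_equal(sa$step_km, rep(50, 20), tolerance = 1e-9)
  expect_equal(sa$turning_deg[-1], rep(0, 19), tolerance = 1e-6)
})

test_that("Brownian mean squared displacement grows linearly in step count", {
  st <- fitMonthlyStats(toy_track(31, seed = 3))
  dates <- as.Date("2005-01-02") + 0:30
  set.seed(12)
  n_rep <- 400
  disp2 <- matrix(NA_real_, n_rep, 30)
  for (r in seq_len(n_rep)) {
    seg <- simulateSegment("brownian", 30, -140, dates, st)
    disp2[r, ] <- greatCircleDistance(30, -140, seg$lat[-1], seg$lon[-1])^2
  }
  msd <- colMeans(disp2)
  fit <- lm(msd ~ seq_len(30))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("isotropic models show no preferred net-displacement bearing", {
  st <- fitMonthlyStats(toy_track(31, seed = 3))
  dates <- as.Date("2005-01-02") + 0:10
  rayleigh_p <- function(bearings) {
    th <- bearings * pi / 180
    n <- length(th)
    r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    exp(-n * r^2)
  }
  set.seed(13)
  for (model in c("brownian", "levy")) {
    br <- vapply(seq_len(800), function(i) {
      seg <- simulateSegment(model, 30, -140, dates, st,
                             levy_params = levyParamsFromStats(st))
      initialBearing(30, -140, seg$lat[11], seg$lon[11])
    }, numeric(1))
    expect_gt(rayleigh_p(br), 0.01)
  }
})

test_that("CRW and JCRW reproduce the source empirical marginals", {
  st <- fitMonthlyStats(toy_track(31, seed = 3))
  jan <- st$months[[1]]
  dates <- as.Date("2005-01-02") + 0:25
  set.seed(14)
  for (model in c("crw", "jcrw")) {
    segs <- lapply(seq_len(4000), function(i) {
      seg <- simulateSegment(model, 30, -140, dates, st)
      extractStepsAngles(makeTracks("x", dates, seg$lat, seg$lon))
    })
    sim <- do.call(rbind, segs)
    # the JCRW resamples (angle, step) pairs, so its step marginal is the
    # joint-pair step set (first steps, with undefined angles, are not in it)
    src_steps <- if (model == "jcrw") jan$joint$step_km else jan$steps
    # evaluate just above each atom: extraction recovers steps to 1e-6 km,
    # which would otherwise split atom mass across the ECDF jump
    at_s <- sort(src_steps) + 1e-5
    sup_step <- max(abs(ecdf(sim$step_km)(at_s) - ecdf(src_steps)(at_s)))
    expect_lt(sup_step, 0.02)
    ang <- sim$turning_deg[!is.na(sim$turning_deg)]
    at_a <- sort(jan$angles) + 1e-5
    sup_ang <- max(abs(ecdf(ang)(at_a) - ecdf(jan$angles)(at_a)))
    expect_lt(sup_ang, 0.02)
  }
})

test_that("monthly restarts re-anchor every segment at the observed fix", {
  tr <- toy_track(60, start_date = as.Date("2005-01-15"), seed = 5)
  st <- fitMonthlyStats(tr)
  ps <- suppressWarnings(
    generatePseudoTracks(tr, "crw", st, n_replicates = 5, seed = 7))
  # date alignment, every replicate
  for (r in 1:5) {
    expect_equal(ps$date[ps$replicate == r], tr$date)
  }
  # anchors: Jan 15 (deployment), Feb 1, Mar 1 — observed positions exactly
  anchors <- as.Date(c("2005-01-15", "2005-02-01", "2005-03-01"))
  for (a in as.list(anchors)) {
    src <- tr[tr$date == a, ]
    sub <- ps[ps$date == a, ]
    expect_equal(sub$lat, rep(src$lat, 5))
    expect_equal(sub$lon, rep(src$lon, 5))
  }
  # non-anchor positions differ across replicates
  mid <- ps[ps$date == as.Date("2005-02-10"), ]
  expect_gt(length(unique(mid$lat)), 1)
  # same master seed -> identical cohort
  ps2 <- suppressWarnings(
    generatePseudoTracks(tr, "crw", st, n_replicates = 5, seed = 7))
  expect_identical(ps, ps2)
  ps3 <- suppressWarnings(
    generatePseudoTracks(tr, "crw", st, n_replicates = 5, seed = 8))
  expect_false(identical(ps, ps3))
})

test_that("restart anchoring falls back to the earliest fix of a month", {
  # gap swallows Feb 1: anchor becomes Feb 3, the month's earliest fix
  d <- c(as.Date("2005-01-20") + 0:9, as.Date("2005-02-03") + 0:9)
  set.seed(15)
  tr <- makeTracks("g", d, 30 + cumsum(runif(20, 0.05, 0.3)),
                   -140 + cumsum(runif(20, 0.05, 0.3)))
  st <- fitMonthlyStats(tr)
  ps <- generatePseudoTracks(tr, "brownian", st, n_replicates = 3, seed = 1)
  feb3 <- tr[tr$date == as.Date("2005-02-03"), ]
  sub <- ps[ps$date == as.Date("2005-02-03"), ]
  expect_equal(sub$lat, rep(feb3$lat, 3))
  expect_equal(sub$lon, rep(feb3$lon, 3))
})
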