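# Gridded SST model: NetCDF round trip, rolling mean, sampling, and the
# warmest-cell search.

test_that("NetCDF round trip preserves grid, values, and missingness", {
  f <- gradient_field(n_days = 3, cell = 1)
  f$sst[2, 3, 4] <- NA
  path <- withr::local_tempfile(fileext = ".nc")
  writeEnvField(f, path)
  back <- readEnvField(path)
  expect_equal(back$times, f$times)
  expect_equal(back$lats, f$lats)
  expect_equal(back$lons, f$lons)
  expect_equal(back$sst, f$sst)
  expect_true(is.na(back$sst[2, 3, 4]))

  # a 2x2x2 toy grid is positionally identical after a round trip
  toy <- makeEnvField(as.Date("2005-01-01") + 0:1, c(0, 1), c(0, 1),
                      array(1:8, c(2, 2, 2)))
  writeEnvField(toy, path)
  expect_equal(readEnvField(path)$sst, toy$sst)
})

test_that("reading a file without an sst variable fails by name", {
  path <- withr::local_tempfile(fileext = ".nc")
  dim_x <- ncdf4::ncdim_def("lon", "degrees_east", 1:3)
  var <- ncdf4::ncvar_def("chlorophyll", "mg", list(dim_x), prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  ncdf4::ncvar_put(nc, var, 1:3)
  ncdf4::nc_close(nc)
  expect_error(readEnvField(path), "sst")
})

test_that("field construction rejects irregular axes", {
  expect_error(makeEnvField(as.Date("2005-01-01") + 0:1, c(0, 1, 3), 0:3,
                            array(0, c(2, 3, 4))), "irregular")
  expect_error(makeEnvField(as.Date("2005-01-01") + c(1, 0), c(0, 1), 0:1,
                            array(0, c(2, 2, 2))), "increasing")
})

test_that("backward rolling mean averages available days per cell", {
  f <- gradient_field(n_days = 3, cell = 1)
  f$sst[1, 2, 2] <- 10; f$sst[2, 2, 2] <- NA; f$sst[3, 2, 2] <- 16
  r <- backwardRollingMean(f, 3)
  expect_equal(r$sst[3, 2, 2], 13)            # mean of the available values
  expect_identical(backwardRollingMean(f, 1), f)
  f$sst[, 4, 4] <- NA
  expect_true(all(is.na(backwardRollingMean(f, 3)$sst[, 4, 4])))
  # bounds are preserved
  set.seed(4)
  one_day <- gradient_field(n_days = 6)
  one_day$sst <- one_day$sst + array(rnorm(length(one_day$sst)),
                                     dim(one_day$sst))
  rr <- backwardRollingMean(one_day, 4)
  expect_gte(min(rr$sst), min(one_day$sst))
  expect_lte(max(rr$sst), max(one_day$sst))
})

test_that("rolling mean agrees with a brute-force window mean", {
  set.seed(9)
  f <- gradient_field(n_days = 10, cell = 2)
  f$sst <- f$sst + array(rnorm(length(f$sst)), dim(f$sst))
  f$sst[sample(length(f$sst), 100)] <- NA
  r <- backwardRollingMean(f, 8)
  for (t in c(1, 5, 10)) for (i in c(1, 3)) for (j in c(2, 5)) {
    win <- f$sst[max(1, t - 7):t, i, j]
    want <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
    expect_equal(r$sst[t, i, j], want)
  }
})

test_that("point sampling hits the containing cell with a lower-index tie rule", {
  f <- gradient_field(cell = 1)  # centres at integer degrees
  d <- f$times[1]
  expect_equal(samplePoint(f, 4, 7, d), f$sst[1, 5, 8])
  expect_equal(samplePoint(f, 4.2, 6.8, d), f$sst[1, 5, 8])
  # exactly halfway between centres 4 and 5 -> lower index wins
  expect_equal(samplePoint(f, 4.5, 7, d), f$sst[1, 5, 8])
  f$sst[1, 5, 8] <- NA
  expect_true(is.na(samplePoint(f, 4, 7, d)))
  # outside the bounding box -> missing sample
  expect_true(is.na(samplePoint(f, 40, 7, d)))
  expect_error(samplePoint(f, 4, 7, as.Date("1999-01-01")), "time axis")
})

test_that("weighted sampling matches a brute-force Gaussian sum", {
  f <- gradient_field(cell = 0.25)
  d <- f$times[1]
  # constant field: any uncertainty still returns the constant
  cf <- f; cf$sst[] <- 15
  expect_equal(sampleWeighted(cf, 5, 5, d, ci95_km = 120), 15)
  # ci95 = 0 degrades to the point value
  expect_equal(sampleWeighted(f, 5.1, 5.1, d, ci95_km = 0),
               samplePoint(f, 5.1, 5.1, d))
  # brute force over all cells within the truncation radius
  model <- uncertaintyModel()
  ci <- 100; sigma <- 0.25 * ci
  dist <- outer(f$lats, f$lons,
                function(la, lo) greatCircleDistance(5, 5, la, lo))
  keep <- dist <= 3 * sigma
  w <- exp(-dist[keep]^2 / (2 * sigma^2))
  v <- f$sst[1, , ][keep]
  expect_equal(sampleWeighted(f, 5, 5, d, ci, model), sum(w * v) / sum(w),
               tolerance = 1e-12)
})

test_that("warmest-cell bearing finds the gradient and honours tie rules", {
  f <- gradient_field(cell = 0.1)  # warmer northward here (positive gradient)
  d <- f$times[1]
  b <- bearingToMaxSST(f, 5, 5, d, 50)
  expect_true(b <= 5 || b >= 355)   # within one cell's angular width of north
  # exhaustive scan oracle
  dist <- outer(f$lats, f$lons,
                function(la, lo) greatCircleDistance(5, 5, la, lo))
  elig <- dist <= 50 & dist > 0
  elig[which.min(abs(f$lats - 5)), which.min(abs(f$lons - 5))] <- FALSE
  sst <- f$sst[1, , ]
  cand <- which(elig & sst == max(sst[elig]), arr.ind = TRUE)
  # stated tie rules: nearest first, then lowest (lat, lon) index
  ord <- order(dist[cand], cand[, 1], cand[, 2])
  best <- cand[ord[1], ]
  expect_equal(b, initialBearing(5, 5, f$lats[best[1]], f$lons[best[2]]))

  # uniform field: the deterministic tie rule gives a repeatable answer
  uf <- f; uf$sst[] <- 7
  b1 <- bearingToMaxSST(uf, 5, 5, d, 50)
  expect_equal(b1, bearingToMaxSST(uf, 5, 5, d, 50))
  # all cells missing within the radius -> NA
  mf <- f; mf$sst[1, , ] <- NA
  expect_true(is.na(bearingToMaxSST(mf, 5, 5, d, 50)))
})

test_that("warmest-cell bearing rotates with the field near the equator", {
  f <- gradient_field(lat_range = c(-2, 2), lon_range = c(-2, 2), cell = 0.1,
                      gradient = 0.5, base = 10)
  d <- f$times[1]
  b_north <- bearingToMaxSST(f, 0, 0, d, 40)
  # rotate the field 90 degrees about the query point: make it warm eastward
  fe <- f
  fe$sst[1, , ] <- matrix(rep(10 + 0.5 * (f$lons + 2), each = length(f$lats)),
                          length(f$lats))
  b_east <- bearingToMaxSST(fe, 0, 0, d, 40)
  expect_equal((b_east - b_north) %% 360, 90, tolerance = 3)
})

test_that("track matching samples per fix and counts drops", {
  f <- gradient_field(cell = 0.5)
  tr <- makeTracks("t", f$times[1] + 0:4, seq(2, 4, 0.5), rep(5, 5))
  m <- matchTrackToEnv(tr, f)
  expect_equal(nrow(m), 5)
  expect_equal(m$sst, samplePoint(f, tr$lat, tr$lon, tr$date))
  # knock out the cell under fix 3
  f2 <- f
  f2$sst[, which.min(abs(f$lats - 3)), which.min(abs(f$lons - 5))] <- NA
  m2 <- matchTrackToEnv(tr, f2)
  expect_equal(nrow(m2), 4)
  expect_equal(attr(m2, "n_dropped"), 1)
  # constant field: all samples equal the constant
  cf <- f; cf$sst[] <- 15
  expect_equal(matchTrackToEnv(tr, cf)$sst, rep(15, 5))
})
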