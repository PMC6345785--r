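test_that("drifting gratings are calibrated, normalized and translate correctly", {
  mov <- make_drifting_grating(0.66, 0.25, duration = 3, frame_rate = 60,
                               size_px = 64, px_per_mm = 240)
  expect_equal(dim(mov$frames)[1], 180)
  expect_equal(range(mov$frames), c(0, 1))
  expect_equal(mov$b_sf, 0)
  # dominant temporal frequency = sf0 * speed, recovered from the movie
  expect_equal(measure_temporal_frequency(mov), 0.165, tolerance = 1e-9)

  # FFT-peak oracle on a single-pixel time course (tf on the DFT grid)
  mov2 <- make_drifting_grating(1.8, 1.0, duration = 5, frame_rate = 60,
                                size_px = 64, px_per_mm = 240)
  trace <- mov2$frames[, 32, 17] - mean(mov2$frames[, 32, 17])
  amp <- Mod(stats::fft(trace))
  freqs <- (seq_along(trace) - 1) / 5
  half <- 2:(length(trace) / 2)
  expect_equal(freqs[half][which.max(amp[half])], 1.8)

  # zero speed gives a static pattern
  mov0 <- make_drifting_grating(1.8, 0, duration = 0.5, size_px = 32)
  expect_true(all(apply(mov0$frames, c(2, 3), function(v) diff(range(v))) == 0))

  expect_error(make_drifting_grating(-1, 1), "invalid parameter")
  expect_error(make_drifting_grating(1, 1, duration = 0), "invalid parameter")
})

test_that("motion clouds are reproducible and carry the bandwidth presets", {
  mc1 <- make_motion_cloud(1.8, 1.0, b_sf = 0.72, duration = 1, size_px = 32,
                           px_per_mm = 40, seed = 7)
  mc2 <- make_motion_cloud(1.8, 1.0, b_sf = 0.72, duration = 1, size_px = 32,
                           px_per_mm = 40, seed = 7)
  expect_identical(mc1$frames, mc2$frames)
  expect_equal(range(mc1$frames), c(0, 1))

  mc3 <- make_motion_cloud(1.8, 1.0, b_sf = 0.72, duration = 1, size_px = 32,
                           px_per_mm = 40, seed = 8)
  expect_false(identical(mc1$frames, mc3$frames))

  grid <- condition_grid()
  broad <- grid[grid$kind == "mc_broad", ]
  expect_equal(broad$b_sf, broad$sf0)
  narrow <- unique(grid[grid$kind == "mc_narrow", c("sf0", "b_sf")])
  expect_equal(narrow$b_sf[order(narrow$sf0)],
               c(0.24, 0.36, 0.54, 0.72, 1.08, 1.5))
  expect_equal(grid$tf[grid$kind == "grating"],
               with(grid[grid$kind == "grating", ], sf0 * speed))

  # spectral envelope past Nyquist warns and records truncation
  expect_warning(
    mcw <- make_motion_cloud(8, 0.5, b_sf = 8, duration = 0.25, size_px = 16,
                             px_per_mm = 20, seed = 1),
    "Nyquist")
  expect_true(mcw$meta$alias_truncated)
})

test_that("cloud spectra sit on the speed plane with the requested centroid", {
  # oracle: FFT of generated movies; radial amplitude profile centroid and
  # least-squares slope of the temporal-frequency peak vs spatial frequency
  n_seeds <- 20
  ppm <- 40; npx <- 64; fr <- 60
  fx <- rgcspeed:::fft_freqs(npx) * ppm
  fr2d <- sqrt(outer(fx^2, fx^2, "+"))
  cents <- slopes <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    mc <- make_motion_cloud(1.8, 1.0, b_sf = 0.72, duration = 2,
                            size_px = npx, px_per_mm = ppm, seed = s)
    am <- 0
    for (t in seq_len(dim(mc$frames)[1])) {
      fm <- mc$frames[t, , ]
      am <- am + Mod(stats::fft(fm - mean(fm)))
    }
    bins <- cut(fr2d, breaks = seq(0, ceiling(max(fr2d)), by = 0.4))
    prof <- tapply(am, bins, mean)
    mids <- seq(0.2, ceiling(max(fr2d)) - 0.2, by = 0.4)
    keep <- !is.na(prof) & prof > 0.05 * max(prof, na.rm = TRUE)
    cents[s] <- sum(mids[keep] * prof[keep]) / sum(prof[keep])

    spec <- array(stats::fft(mc$frames), dim = dim(mc$frames))
    ptx <- apply(Mod(spec)^2, c(1, 3), sum)     # [f_t, f_x]
    ftv <- rgcspeed:::fft_freqs(dim(mc$frames)[1]) * fr
    sel <- which(fx > 0.5 & fx < 4)
    pk <- vapply(sel, function(i) ftv[which.max(ptx[, i])], numeric(1))
    slopes[s] <- stats::coef(stats::lm(pk ~ fx[sel]))[2]
  }
  expect_lt(abs(mean(cents) - 1.8) / 1.8, 0.1)
  expect_lt(abs(mean(slopes) - (-1.0)), 0.1)
})

test_that("the zero-bandwidth limit concentrates the spatial spectrum", {
  ppm <- 40; npx <- 64
  mc <- make_motion_cloud(1.8, 1.0, b_sf = 1.8 / 100, duration = 1,
                          size_px = npx, px_per_mm = ppm, seed = 5)
  fx <- rgcspeed:::fft_freqs(npx) * ppm
  fr2d <- sqrt(outer(fx^2, fx^2, "+"))
  pw <- 0
  for (t in seq_len(dim(mc$frames)[1])) {
    fm <- mc$frames[t, , ]
    pw <- pw + Mod(stats::fft(fm - mean(fm)))^2
  }
  in_band <- abs(fr2d - 1.8) <= 0.05 * 1.8
  expect_gt(sum(pw[in_band]) / sum(pw), 0.9)
})

test_that("checkerboards are binary block noise with the right statistics", {
  cb <- make_checkerboard(0.05, 35, duration = 2, seed = 1)
  expect_equal(dim(cb$frames)[2:3], c(35, 35))
  expect_true(all(cb$frames %in% c(0, 1)))
  expect_equal(cb$px_per_mm, 20)
  cb2 <- make_checkerboard(0.05, 35, duration = 2, seed = 2)
  expect_false(identical(cb$frames[1, , ], cb2$frames[1, , ]))

  # binomial oracle: long-run per-block mean 0.5 +/- 0.02
  long <- make_checkerboard(0.05, 12, duration = 10000 / 60, frame_rate = 60,
                            seed = 3)
  means <- apply(long$frames, c(2, 3), mean)
  expect_true(all(abs(means - 0.5) < 0.02))
})

test_that("contrast diagnostics separate gratings from broad clouds", {
  const <- rgcspeed:::new_stimulus_movie(array(0.5, c(4, 8, 8)), 60, 40,
                                         "grating", 1, 0, 0, 4 / 60)
  cp0 <- contrast_profile(const)
  expect_equal(cp0$michelson, 0)
  expect_equal(cp0$weber_min, 0)
  expect_equal(cp0$weber_max, 0)
  expect_equal(sum(cp0$weber_histogram$mass), 1)

  g <- make_drifting_grating(1.8, 1, duration = 1, size_px = 64, px_per_mm = 40)
  cpg <- contrast_profile(g)
  expect_equal(cpg$michelson, 1)
  expect_equal(sum(cpg$weber_histogram$mass), 1)

  mc <- make_motion_cloud(1.8, 1, b_sf = 1.8, duration = 1, size_px = 64,
                          px_per_mm = 40, seed = 4)
  cpm <- contrast_profile(mc)
  # gratings pile mass at the extremes (platykurtic Weber distribution),
  # broad clouds concentrate near zero (heavier-tailed)
  expect_lt(cpg$weber_kurtosis, 0)
  expect_gt(cpm$weber_kurtosis, cpg$weber_kurtosis)

  zero <- rgcspeed:::new_stimulus_movie(array(0, c(2, 4, 4)), 60, 40,
                                        "grating", 1, 0, 0, 2 / 60)
  expect_error(contrast_profile(zero), "undefined")
})

test_that("unit conversion round-trips to machine precision", {
  sf <- c(0.66, 0.9, 1.26, 1.8, 2.52, 3.6)
  expect_equal(convert_sf(convert_sf(sf, 240, "px"), 240, "mm"), sf)
})

test_that("movies round-trip through the on-disk format", {
  mov <- make_drifting_grating(1.8, 1, duration = 0.1, size_px = 8,
                               px_per_mm = 40)
  d <- withr::local_tempdir()
  path <- write_stimulus_movie(mov, d)
  back <- read_stimulus_movie(path)
  expect_equal(back$frames, mov$frames, tolerance = 1e-12)
  expect_equal(back$sf0, mov$sf0)
  expect_equal(back$kind, mov$kind)
})
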