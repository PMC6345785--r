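test_that("ellipse eccentricity matches its closed form", {
  expect_equal(ellipse_eccentricity(1, 1), 0)
  expect_equal(ellipse_eccentricity(2, 1), sqrt(1 - 0.25), tolerance = 1e-12)
  expect_equal(ellipse_eccentricity(5, 3), 0.8, tolerance = 1e-12)
  expect_warning(e <- ellipse_eccentricity(1, 2), "swapping")
  expect_equal(e, ellipse_eccentricity(2, 1))
  expect_error(ellipse_eccentricity(2, 0), "invalid parameter")
})

test_that("spike-triggered averages implement reverse correlation exactly", {
  cb <- make_checkerboard(0.05, 10, duration = 1, seed = 3)
  # one spike: STA equals the mean-subtracted preceding segment
  spike_t <- 30.5 / 60                      # spike in frame 31
  sta <- compute_sta(spike_t, cb, n_lags = 5)
  mu <- mean(cb$frames)
  for (j in 1:5) {
    expect_equal(sta$kernel[j, , ], cb$frames[31 - (j - 1), , ] - mu)
  }
  expect_error(compute_sta(numeric(0), cb, 5), "no usable spikes")

  # linearity: pooled spikes = count-weighted average of chunk STAs
  s1 <- c(20, 25, 33) / 60; s2 <- c(40, 45) / 60
  sta1 <- compute_sta(s1, cb, 5); sta2 <- compute_sta(s2, cb, 5)
  sta12 <- compute_sta(c(s1, s2), cb, 5)
  expect_equal(combine_sta(sta1, sta2)$kernel, sta12$kernel,
               tolerance = 1e-12)
})

test_that("stimulus-independent spikes give a vanishing STA", {
  cb <- make_checkerboard(0.05, 20, duration = 200, seed = 7)
  set.seed(8)
  spikes <- sort(stats::runif(10000, 0, 200))
  sta <- compute_sta(spikes, cb, n_lags = 10)
  stim_sd <- stats::sd(cb$frames)
  # pointwise null scale is sd/sqrt(n); the max over ~40k kernel entries
  # sits a few sigma higher but stays far below any real kernel amplitude
  expect_lt(max(abs(sta$kernel)), 6 * stim_sd / sqrt(sta$n_spikes))
  expect_lt(sqrt(mean(sta$kernel^2)), 1.5 * stim_sd / sqrt(sta$n_spikes))
})

test_that("a planted kernel is recovered from a simulated checkerboard run", {
  cell <- fixed_cell(gain = 250, baseline = 0.5, field = 0.8)
  run <- sta_checkerboard_run(cell, total_duration = 300, chunk_s = 60,
                              n_blocks = 16, n_lags = 15, seed = 21)
  expect_gt(run$n_spikes, 5000)
  expect_gt(stats::cor(as.numeric(run$sta$kernel),
                       as.numeric(run$planted$kernel)), 0.8)
  # polarity survives estimation
  fit <- fit_spatial_rf(run$sta)
  expect_equal(fit$polarity, "OFF")
})

test_that("spatial fits recover planted geometry and apply the discard rule", {
  # isotropic Gaussian, s.d. 0.05 mm on a 100 px/mm grid
  sta <- planted_sta(sx = 5, sy = 5, px_per_mm = 100)
  fit <- fit_spatial_rf(sta)
  expect_true(fit$valid)
  expect_lt(abs(fit$a - 0.05) / 0.05, 0.1)
  expect_lt(abs(fit$b - 0.05) / 0.05, 0.1)
  expect_lt(fit$eccentricity, 0.2)
  expect_equal(fit$polarity, "ON")
  expect_equal(fit$equivalent_radius, sqrt(fit$a * fit$b))

  off <- fit_spatial_rf(planted_sta(sign = -1))
  expect_equal(off$polarity, "OFF")

  # a/b = 3 -> eccentricity 0.943 > 0.9 -> invalid, not an error
  skinny <- fit_spatial_rf(planted_sta(sx = 9, sy = 3))
  expect_false(skinny$valid)
  expect_gt(skinny$eccentricity, 0.9)
})

test_that("temporal fits recover the planted cascade parameters", {
  sta <- planted_sta(p1 = 1, p2 = 0.8, tau1 = 4, tau2 = 6, n = 6)
  fit <- fit_temporal_profile(sta)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau1 - 4) / 4, 0.05)
  expect_lt(abs(fit$tau2 - 6) / 6, 0.05)
  expect_lt(abs(fit$n - 6) / 6, 0.05)
  # amplitudes are defined up to the peak normalization: compare the ratio
  expect_lt(abs(fit$p2 / fit$p1 - 0.8) / 0.8, 0.05)

  # fitted curve reproduces the sign sequence of a clean biphasic input
  # wherever the input is clearly non-zero
  tt <- seq_len(18) - 1
  w <- rgcspeed:::temporal_kernel(tt, 1, 0.8, 4, 6, 6)
  f <- predict_temporal_profile(fit, tt)
  big <- abs(w) > 0.05 * max(abs(w))
  expect_equal(sign(f)[big], sign(w)[big])
})

test_that("temporal markers locate the peak and first zero crossing", {
  # single cascade peaks at t = tau
  mono <- fit_temporal_profile(planted_sta(p1 = 1, p2 = 0, tau1 = 5,
                                           tau2 = 9, n = 6))
  mk <- temporal_markers(mono)
  expect_equal(mk$peak_time, 5 / 60, tolerance = 1e-3)
  expect_true(is.na(mk$zero_cross))       # monophasic: no sign change

  bi <- fit_temporal_profile(planted_sta(p1 = 1, p2 = 0.8, tau1 = 4,
                                         tau2 = 6, n = 6))
  mkb <- temporal_markers(bi)
  # oracle: dense-grid sign-change search on the generating curve
  tg <- seq(0.01, 30, by = 0.001)
  f <- rgcspeed:::temporal_kernel(tg, 1, 0.8, 4, 6, 6)
  ip <- which.max(f)
  zc_true <- tg[ip + which(f[(ip + 1):length(f)] <= 0)[1]]
  expect_equal(mkb$zero_cross * 60, zc_true, tolerance = 0.1)
  expect_equal(mkb$peak_time * 60, tg[ip], tolerance = 0.1)
})

test_that("zero-cross differences separate subpopulations where peak times do not", {
  # two groups share the tau1 distribution (which sets the peak time) but
  # differ in cascade order: narrower lobes cross zero earlier while the
  # peak-time distributions stay matched
  set.seed(42)
  markers <- function(ns) {
    t(vapply(ns, function(n) {
      tau1 <- stats::runif(1, 3.4, 4.6)
      tau2 <- stats::runif(1, 7, 8)
      fit <- fit_temporal_profile(planted_sta(p1 = 1, p2 = 0.7, tau1 = tau1,
                                              tau2 = tau2, n = n))
      mk <- temporal_markers(fit)
      c(mk$peak_time, mk$zero_cross)
    }, numeric(2)))
  }
  grp_a <- markers(rep(4, 10))
  grp_b <- markers(rep(10, 10))
  ks_zc <- stats::ks.test(grp_a[, 2], grp_b[, 2])
  ks_pk <- stats::ks.test(grp_a[, 1], grp_b[, 1])
  expect_lt(ks_zc$p.value, 0.05)
  expect_gt(ks_pk$p.value, 0.05)
})

test_that("rf_table aggregates fits and flags invalid cells", {
  stas <- list(a = planted_sta(), b = planted_sta(sx = 9, sy = 3))
  tab <- rf_table(stas)
  expect_equal(tab$cell_id, c("a", "b"))
  expect_true(tab$valid[1])
  expect_false(tab$valid[2])
  expect_true(all(c("zero_cross", "peak_time", "tau1") %in% names(tab)))
})
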