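test_that("collapsing preserves separable structure and the x centroid", {
  pop <- fixed_cell()
  gt <- ground_truth_kernel(pop, 40, 40, 40, n_lags = 15)
  col <- collapse_rf(gt)
  expect_equal(dim(col$rf), c(40, 15))

  # separable kernel: collapsed = (mean spatial row profile) x time course
  sp <- rgcspeed:::cell_spatial_map(pop, 40, 40, 40)
  tk <- rgcspeed:::temporal_kernel(0:14, pop$p1, pop$p2, pop$tau1, pop$tau2,
                                   pop$n_cascade)
  expected <- outer(colMeans(sp[col$rows, , drop = FALSE]), tk)
  expect_equal(col$rf, expected, tolerance = 1e-12)

  # translation along the orthogonal axis leaves the collapse unchanged
  shifted <- pop; shifted$y <- pop$y + 0.1
  col2 <- collapse_rf(ground_truth_kernel(shifted, 40, 40, 40, n_lags = 15))
  expect_equal(max(abs(col2$rf - col$rf)) / max(abs(col$rf)), 0,
               tolerance = 0.05)

  # x centroid of the collapsed profile matches the planted centre
  prof <- abs(col$rf[, which.max(colSums(abs(col$rf)))])
  cx <- sum(seq_len(40) * prof) / sum(prof)
  expect_lt(abs(cx - pop$x * 40), 1)     # within one pixel of the centre
})

test_that("the linear reconstruction evaluates the decoding sum exactly", {
  rf <- matrix(stats::rnorm(20 * 6), 20, 6)
  kernels <- list(`1` = structure(list(rf = rf, frame_dt = 1 / 60,
                                       px_per_mm = 20),
                                  class = "collapsed_rf"))
  dt <- 1 / 60
  # one spike in bin k: I(x, k+j) = RF(x, j), offset 0
  k <- 10
  spk <- list(`1` = (k - 0.5) * dt)
  rec <- reconstruct_xt(spk, kernels, duration = 0.5, bin_dt = dt)
  for (j in 0:5) expect_equal(rec$intensity[, k + j], rf[, j + 1])
  expect_true(all(rec$intensity[, seq_len(k - 1)] == 0))

  # no spikes: identically the offset
  rec0 <- reconstruct_xt(list(`1` = numeric(0)), kernels, duration = 0.5,
                         offset = 0.5, bin_dt = dt)
  expect_true(all(rec0$intensity == 0.5))

  # linearity in the spike trains
  sa <- list(`1` = c(0.05, 0.21)); sb <- list(`1` = c(0.11, 0.30))
  ra <- reconstruct_xt(sa, kernels, 0.5, bin_dt = dt)
  rb <- reconstruct_xt(sb, kernels, 0.5, bin_dt = dt)
  rab <- reconstruct_xt(list(`1` = c(sa[[1]], sb[[1]])), kernels, 0.5,
                        bin_dt = dt)
  expect_equal(rab$intensity, ra$intensity + rb$intensity, tolerance = 1e-12)

  expect_error(reconstruct_xt(list(`2` = 0.1), kernels, 0.5, bin_dt = dt),
               "missing kernel")
})

test_that("the quadrature bank has the stated symmetries", {
  bank <- build_motion_energy_bank(c(0.25, 0.5, 1, 2, 4), 0.9, 40, 60)
  expect_length(bank$channels, 5)
  for (ch in bank$channels) {
    for (d in c("fwd", "bwd")) {
      expect_equal(mean(ch[[d]]$even), 0, tolerance = 1e-12)
      expect_equal(sum(ch[[d]]$even^2), 1, tolerance = 1e-9)
      expect_equal(sum(ch[[d]]$odd^2), 1, tolerance = 1e-9)
    }
    # mirror reversal in space maps forward onto backward
    expect_equal(ch$fwd$even[nrow(ch$fwd$even):1, ], ch$bwd$even,
                 tolerance = 1e-9)
  }
  expect_error(build_motion_energy_bank(c(1, 1), 0.9), "distinct")

  # quadrature pairs give time-constant energy on a matched sinusoid
  x_mm <- (1:128) / 40; t_s <- (1:180) / 60
  X <- outer(x_mm, t_s, function(x, t) sin(2 * pi * 0.9 * (x - 1 * t)))
  ch <- bank$channels[[3]]
  ce <- rgcspeed:::xcorr2_valid(X - mean(X), ch$fwd$even)
  co <- rgcspeed:::xcorr2_valid(X - mean(X), ch$fwd$odd)
  e_t <- colMeans(ce^2 + co^2)
  expect_lt((max(e_t) - min(e_t)) / mean(e_t), 0.05)
})

test_that("winner-takes-all decoding is exact on noiseless gratings", {
  speeds <- c(0.25, 0.5, 1, 2, 4)
  bank <- build_motion_energy_bank(speeds, 0.9, 40, 60)
  x_mm <- (1:128) / 40; t_s <- (1:180) / 60
  for (v in speeds) {
    X <- outer(x_mm, t_s, function(x, t) sin(2 * pi * 0.9 * (x - v * t)))
    d <- decode_speed(X, bank)
    expect_equal(d$chosen_speed, v)
    expect_equal(d$chosen_direction, 1)
  }

  # static pattern: opponent energies cancel exactly, no decision
  Xs <- outer(x_mm, t_s, function(x, t) sin(2 * pi * 0.9 * x))
  ds <- decode_speed(Xs, bank)
  expect_true(ds$no_decision)
  expect_lt(max(abs(ds$net)), 1e-10)

  # time reversal flips the decoded direction, not the speed
  X1 <- outer(x_mm, t_s, function(x, t) sin(2 * pi * 0.9 * (x - 1 * t)))
  dr <- decode_speed(X1[, ncol(X1):1], bank)
  expect_equal(dr$chosen_speed, 1)
  expect_equal(dr$chosen_direction, -1)

  # mirror reversal in space swaps the two opponent energies
  dm <- decode_speed(X1[nrow(X1):1, ], bank)
  d1 <- decode_speed(X1, bank)
  expect_equal(dm$energy_fwd, d1$energy_bwd, tolerance = 1e-6)
  expect_equal(dm$net, -d1$net, tolerance = 1e-6)
})

test_that("the closed loop decodes simulated gratings at high firing", {
  ppm <- 40; size_px <- 128
  pop <- make_ground_truth_population(20, on_fraction = 0.2,
                                      field_size = size_px / ppm,
                                      gain_range = c(150, 250), seed = 21)
  kernels <- lapply(seq_len(nrow(pop)), function(i)
    collapse_rf(ground_truth_kernel(pop[i, ], size_px, size_px, ppm)))
  names(kernels) <- as.character(pop$cell_id)
  bank <- build_motion_energy_bank(c(0.25, 0.5, 1, 2, 4), 0.9, ppm, 60)
  for (v in c(0.5, 2)) {
    mov <- make_drifting_grating(0.9, v, duration = 3, size_px = size_px,
                                 px_per_mm = ppm)
    spk <- simulate_ln_responses(pop, mov, seed = round(100 * v),
                                 deterministic = TRUE)
    d <- decode_speed(reconstruct_xt(spk, kernels, 3), bank)
    expect_equal(d$chosen_speed, v)
    expect_equal(d$chosen_direction, 1)
  }
})

test_that("decoding metrics follow the error-rate and cost formulas", {
  dec <- data.frame(kind = "grating", sf0 = 0.9, speed = 1, trial = 1:10,
                    chosen_speed = c(rep(1, 7), 2, NA, 4),
                    chosen_direction = c(rep(1, 7), 1, NA, 1))
  spk <- data.frame(kind = rep("grating", 1000))
  m <- decoding_metrics(dec, spk, n_cells = 100)
  expect_equal(m$per_condition$error_rate, 0.3)
  expect_equal(m$per_kind$accuracy_cost, 0.7 * 1000 / 100)

  dec$chosen_speed <- dec$speed; dec$chosen_direction <- 1
  expect_equal(decoding_metrics(dec, spk, 100)$per_kind$error_rate, 0)
})
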