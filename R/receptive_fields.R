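# Receptive-field estimation: spike-triggered averages, elliptical spatial
# fits, and difference-of-cascades temporal fits.

new_sta <- function(kernel, frame_dt, n_spikes, px_per_mm) {
  stopifnot(length(dim(kernel)) == 3, all(is.finite(kernel)))
  structure(list(kernel = kernel, n_lags = dim(kernel)[1],
                 frame_dt = frame_dt, n_spikes = n_spikes,
                 px_per_mm = px_per_mm),
            class = "sta")
}

#' @export
print.sta <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<sta> %d lags x %d x %d px, dt = %.4g s, %s spikes\n",
              d[1], d[2], d[3], x$frame_dt,
              ifelse(is.na(x$n_spikes), "?", x$n_spikes)))
  invisible(x)
}

#' Spike-triggered average from a checkerboard response
#'
#' Reverse correlation: `kernel[j, , ]` is the mean of the mean-luminance-
#' subtracted stimulus frames `j - 1` frames before each spike (lag 1 is the
#' spike frame itself), normalized by spike count. Spikes earlier than
#' `n_lags` frames into the movie are dropped.
#'
#' @param spikes numeric vector of spike times (s) or a `spike_data` table
#'   (all rows pooled).
#' @param movie the white-noise `stimulus_movie` that evoked the spikes.
#' @param n_lags kernel depth in frames (default 18, i.e. 0.3 s at 60 Hz).
#' @return an object of class `sta`.
#' @export
compute_sta <- function(spikes, movie, n_lags = 18) {
  stopifnot(inherits(movie, "stimulus_movie"), n_lags >= 1)
  st <- if (is.data.frame(spikes)) spikes$spike_time_s else spikes
  d <- dim(movie$frames)
  fi <- floor(st * movie$frame_rate) + 1L
  fi <- fi[fi >= n_lags & fi <= d[1]]
  if (length(fi) == 0) stop("STA undefined: no usable spikes", call. = FALSE)
  counts <- tabulate(fi, nbins = d[1])
  n <- sum(counts)
  frames_mat <- matrix(movie$frames, nrow = d[1]) - mean(movie$frames)
  kernel <- array(0, dim = c(n_lags, d[2], d[3]))
  for (j in seq_len(n_lags)) {
    w <- counts[j:d[1]]
    kernel[j, , ] <- crossprod(frames_mat[seq_len(d[1] - j + 1), , drop = FALSE],
                               w) / n
  }
  new_sta(kernel, 1 / movie$frame_rate, n, movie$px_per_mm)
}

#' Merge spike-triggered averages by spike-count weighting
#'
#' The STA of pooled spike sets equals the spike-count-weighted average of
#' the individual STAs; this merges chunked estimates exactly.
#'
#' @param ... `sta` objects over the same grid and lag depth.
#' @return a single merged `sta`.
#' @export
combine_sta <- function(...) {
  stas <- list(...)
  if (length(stas) == 1 && is.list(stas[[1]]) && !inherits(stas[[1]], "sta")) {
    stas <- stas[[1]]
  }
  stopifnot(length(stas) >= 1, all(vapply(stas, inherits, TRUE, "sta")))
  n <- vapply(stas, function(s) s$n_spikes, numeric(1))
  kernel <- Reduce(`+`, Map(function(s, w) s$kernel * w, stas, n)) / sum(n)
  new_sta(kernel, stas[[1]]$frame_dt, sum(n), stas[[1]]$px_per_mm)
}

#' Ellipse eccentricity
#'
#' `sqrt(1 - (b/a)^2)` for semi-axes `a >= b > 0`. Arguments given in the
#' wrong order are swapped with a warning.
#'
#' @param a,b semi-axes (any common length unit).
#' @return eccentricity in `[0, 1)`.
#' @export
#' @examples
#' ellipse_eccentricity(2, 1)
ellipse_eccentricity <- function(a, b) {
  if (any(b <= 0) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("invalid parameter: semi-axes must be finite and > 0", call. = FALSE)
  }
  if (any(b > a)) {
    warning("b > a: swapping major and minor axes", call. = FALSE)
    tmp <- pmax(a, b); b <- pmin(a, b); a <- tmp
  }
  sqrt(1 - (b / a)^2)
}

# 2-D elliptical Gaussian on a pixel grid; p = (amp, x0, y0, lsx, lsy, zrho)
gauss2d_pred <- function(p, xg, yg) {
  sx <- exp(p[4]); sy <- exp(p[5]); rho <- tanh(p[6])
  dx <- (xg - p[2]) / sx
  dy <- (yg - p[3]) / sy
  q <- (dx^2 - 2 * rho * dx * dy + dy^2) / (1 - rho^2)
  p[1] * exp(-0.5 * q)
}

#' Fit an elliptical Gaussian to the spatial receptive field
#'
#' Fits a 2-D Gaussian to the STA frame at the lag of maximum absolute
#' amplitude (ties broken by the earliest lag), draws the 1-standard-
#' deviation ellipse, and applies the eccentricity discard rule: fits with
#' `eccentricity > eps_max` (default 0.9) or degenerate widths are flagged
#' invalid rather than raising an error.
#'
#' @param sta an `sta` object.
#' @param eps_max eccentricity threshold for the validity flag.
#' @return list of class `spatial_rf_fit`: `center` (mm), semi-axes `a >= b`
#'   (mm), `angle` (radians), `amplitude`, `polarity` ("ON"/"OFF"),
#'   `equivalent_radius = sqrt(a*b)` (mm), `eccentricity`, `peak_lag`,
#'   `valid`.
#' @export
fit_spatial_rf <- function(sta, eps_max = 0.9) {
  stopifnot(inherits(sta, "sta"))
  k <- sta$kernel
  peak_lag <- which.max(apply(abs(k), 1, max))
  m <- k[peak_lag, , ]
  ny <- nrow(m); nx <- ncol(m)
  xg <- outer(rep(1, ny), seq_len(nx))
  yg <- outer(seq_len(ny), rep(1, nx))

  ipk <- which.max(abs(m))
  amp0 <- m[ipk]
  x0 <- xg[ipk]; y0 <- yg[ipk]
  w <- abs(m) * (abs(m) >= 0.5 * abs(amp0)) * (sign(m) == sign(amp0))
  sw <- sum(w)
  mx <- sum(w * xg) / sw; my <- sum(w * yg) / sw
  sx0 <- sqrt(max(sum(w * (xg - mx)^2) / sw, 0.25))
  sy0 <- sqrt(max(sum(w * (yg - my)^2) / sw, 0.25))

  obj <- function(p) sum((gauss2d_pred(p, xg, yg) - m)^2)
  fit <- try(stats::optim(c(amp0, mx, my, log(sx0), log(sy0), 0), obj,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
  degenerate <- inherits(fit, "try-error")
  if (!degenerate) {
    p <- fit$par
    sx <- exp(p[4]); sy <- exp(p[5]); rho <- tanh(p[6])
    C <- matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2, 2)
    eg <- eigen(C, symmetric = TRUE)
    a_px <- sqrt(max(eg$values[1], 0))
    b_px <- sqrt(max(eg$values[2], 0))
    degenerate <- !is.finite(a_px) || !is.finite(b_px) || b_px <= 0
  }
  if (degenerate) {
    return(structure(list(center = c(NA, NA), a = NA_real_, b = NA_real_,
                          angle = NA_real_, amplitude = NA_real_,
                          polarity = NA_character_,
                          equivalent_radius = NA_real_,
                          eccentricity = NA_real_, peak_lag = peak_lag,
                          valid = FALSE),
                     class = "spatial_rf_fit"))
  }
  ppm <- sta$px_per_mm
  eps <- ellipse_eccentricity(a_px, b_px)
  structure(list(center = c(x = p[2] / ppm, y = p[3] / ppm),
                 a = a_px / ppm, b = b_px / ppm,
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) %% pi,
                 amplitude = p[1],
                 polarity = if (p[1] >= 0) "ON" else "OFF",
                 equivalent_radius = sqrt(a_px * b_px) / ppm,
                 eccentricity = eps, peak_lag = peak_lag,
                 valid = is.finite(eps) && eps <= eps_max),
            class = "spatial_rf_fit")
}

#' Fit the temporal receptive-field profile
#'
#' Extracts the time course of the STA at the pixel of largest variance
#' across lags, zeroes the baseline (mean of the last three lags), flips
#' OFF profiles so the leading lobe is positive, normalizes the peak to 1,
#' and fits a difference of two low-pass filter cascades with shared order:
#' `f(t) = p1 (t/tau1)^n exp(-n(t/tau1 - 1)) - p2 (t/tau2)^n
#' exp(-n(t/tau2 - 1))`, `t` in frames before the spike; each cascade peaks
#' at its `tau`.
#'
#' @param sta an `sta` object with at least 6 lags.
#' @return list of class `temporal_rf_fit`: parameters `p1, p2, tau1, tau2,
#'   n` (frames), `polarity_sign`, the extracted `trace`, `fit_residual`
#'   (sum of squared residuals; `Inf` when the optimizer fails),
#'   `converged`, `frame_dt`.
#' @export
fit_temporal_profile <- function(sta) {
  stopifnot(inherits(sta, "sta"))
  L <- sta$n_lags
  if (L < 6) stop("need at least 6 lags for a temporal fit", call. = FALSE)
  v <- apply(sta$kernel, c(2, 3), stats::var)
  ipx <- which(v == max(v), arr.ind = TRUE)[1, ]
  trace <- sta$kernel[, ipx[1], ipx[2]]
  trace <- trace - mean(trace[(L - 2):L])
  s <- sign(trace[which.max(abs(trace))])
  if (s == 0) s <- 1
  w <- trace * s
  pk <- max(w)
  if (pk <= 0) {
    return(structure(list(p1 = NA, p2 = NA, tau1 = NA, tau2 = NA, n = NA,
                          polarity_sign = s, trace = trace,
                          fit_residual = Inf, converged = FALSE,
                          frame_dt = sta$frame_dt),
                     class = "temporal_rf_fit"))
  }
  w <- w / pk
  tt <- seq_len(L) - 1

  # variable projection: for fixed (tau1, tau2, n) the model is linear in
  # the lobe amplitudes, solved in closed form inside the nonlinear search
  # over the three shape parameters. A small ridge on the amplitudes
  # suppresses the degenerate tau1 -> tau2 solution, whose exploding
  # amplitudes mimic a cascade derivative.
  ridge <- 1e-5 * sqrt(sum(w^2))
  amp_solve <- function(theta) {
    # free intercept absorbs whatever the last-lags baseline estimate
    # missed when the second lobe has not fully decayed
    B <- cbind(cascade_filter(tt, theta[1], theta[3]),
               -cascade_filter(tt, theta[2], theta[3]), 1)
    Ba <- rbind(B, cbind(diag(ridge, 2), 0))
    p <- try(qr.solve(Ba, c(w, 0, 0)), silent = TRUE)
    if (inherits(p, "try-error") || any(!is.finite(p))) return(NULL)
    list(p = p, resid = as.numeric(B %*% p - w))
  }
  resid_fn <- function(theta) {
    a <- amp_solve(theta)
    if (is.null(a)) return(rep(1e3, length(w)))
    if (a$p[1] < 0) return(a$resid + 10 * abs(a$p[1]))  # keep lobe order
    c(a$resid, ridge * a$p[1:2])
  }
  tau1_0 <- max(tt[which.max(w)], 1.5)
  lower <- c(1.01, 1.01, 1)
  upper <- c(4 * L, 4 * L, 25)
  # coarse grid of shape parameters, then Levenberg-Marquardt polish from
  # the leading grid points
  grid <- expand.grid(t1 = unique(pmax(tau1_0 + c(-1.5, 0, 1.5), 1.2)),
                      ratio = c(1.3, 1.6, 2, 2.5, 3.2),
                      n0 = c(2, 4, 6, 8, 12))
  grid_ssr <- vapply(seq_len(nrow(grid)), function(i) {
    a <- amp_solve(c(grid$t1[i], grid$t1[i] * grid$ratio[i], grid$n0[i]))
    if (is.null(a) || a$p[1] < 0) return(Inf)
    sum(a$resid^2)
  }, numeric(1))
  top <- order(grid_ssr)[seq_len(min(4, nrow(grid)))]
  best <- NULL
  for (si in top) {
    fit <- try(minpack.lm::nls.lm(
      par = c(grid$t1[si], grid$t1[si] * grid$ratio[si], grid$n0[si]),
      lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    if (best$ssr < 1e-14) break
  }
  amps <- if (!is.null(best)) amp_solve(best$fit$par) else NULL
  if (is.null(amps)) {
    return(structure(list(p1 = NA, p2 = NA, tau1 = NA, tau2 = NA, n = NA,
                          polarity_sign = s, trace = trace,
                          fit_residual = Inf, converged = FALSE,
                          frame_dt = sta$frame_dt),
                     class = "temporal_rf_fit"))
  }
  th <- best$fit$par
  structure(list(p1 = amps$p[1], p2 = amps$p[2], tau1 = th[1], tau2 = th[2],
                 n = th[3], offset = amps$p[3], polarity_sign = s,
                 trace = trace, fit_residual = sum(amps$resid^2),
                 converged = TRUE, frame_dt = sta$frame_dt),
            class = "temporal_rf_fit")
}

#' Evaluate a fitted temporal profile on a time grid
#'
#' @param fit a converged `temporal_rf_fit`.
#' @param t_frames times in frames before the spike.
#' @return fitted (peak-normalized, leading-lobe-positive) curve values.
#' @export
predict_temporal_profile <- function(fit, t_frames) {
  stopifnot(inherits(fit, "temporal_rf_fit"), fit$converged)
  temporal_kernel(t_frames, fit$p1, fit$p2, fit$tau1, fit$tau2, fit$n)
}

#' Temporal markers: peak time and zero crossing
#'
#' `peak_time` is the time of the extremum of the fitted curve's leading
#' lobe; `zero_cross` is the first sign change after that peak, refined by
#' root bracketing on the continuous fitted curve. Monophasic fits (no sign
#' change) report `zero_cross = NA`.
#'
#' @param fit a converged `temporal_rf_fit`.
#' @return list with `peak_time` and `zero_cross`, seconds.
#' @export
temporal_markers <- function(fit) {
  stopifnot(inherits(fit, "temporal_rf_fit"))
  if (!fit$converged) stop("temporal fit did not converge", call. = FALSE)
  monophasic <- fit$p2 <= 1e-3 * fit$p1
  tmax <- 4 * max(fit$tau1, fit$tau2)
  tg <- seq(1e-3, tmax, by = 0.005)
  f <- predict_temporal_profile(fit, tg)
  ipk <- which.max(f)
  peak_time <- tg[ipk] * fit$frame_dt
  zero_cross <- NA_real_
  after <- which(tg > tg[ipk])
  flip <- if (monophasic) integer(0) else after[which(f[after] <= 0)]
  if (length(flip) > 0) {
    i2 <- flip[1]
    g <- function(t) predict_temporal_profile(fit, t)
    zero_cross <- stats::uniroot(g, c(tg[i2 - 1], tg[i2]))$root * fit$frame_dt
  }
  list(peak_time = peak_time, zero_cross = zero_cross)
}

#' Receptive-field summary table for a population of STAs
#'
#' Runs the spatial and temporal fits on each STA and assembles one row per
#' cell, applying the eccentricity discard rule via the `valid` column.
#'
#' @param stas named list of `sta` objects (names become `cell_id`).
#' @param eps_max eccentricity threshold.
#' @return data.frame with spatial-fit, temporal-fit and marker columns.
#' @export
rf_table <- function(stas, eps_max = 0.9) {
  rows <- lapply(seq_along(stas), function(i) {
    sf <- fit_spatial_rf(stas[[i]], eps_max = eps_max)
    tf <- fit_temporal_profile(stas[[i]])
    mk <- if (tf$converged) temporal_markers(tf) else
      list(peak_time = NA_real_, zero_cross = NA_real_)
    data.frame(cell_id = names(stas)[i] %||% as.character(i),
               x = sf$center[1], y = sf$center[2], a = sf$a, b = sf$b,
               angle = sf$angle, polarity = sf$polarity %||% NA_character_,
               equivalent_radius = sf$equivalent_radius,
               eccentricity = sf$eccentricity, valid = sf$valid,
               p1 = tf$p1, p2 = tf$p2, tau1 = tf$tau1, tau2 = tf$tau2,
               n = tf$n, fit_residual = tf$fit_residual,
               peak_time = mk$peak_time, zero_cross = mk$zero_cross,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
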