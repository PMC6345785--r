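# Speed-tuning quantification: PSTHs, standardized F1 modulation, the
# modulation screen, skewed log-Gaussian tuning fits, and bandwidth change.

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate per bin, in Hz. Spikes before `onset_discard`
#' (default 200 ms, discarding the onset transient) are excluded and the
#' first bin edge starts there.
#'
#' @param trials list of per-trial numeric spike-time vectors (s), or one
#'   numeric vector treated as a single trial.
#' @param duration trial length, s.
#' @param bin_width s.
#' @param onset_discard s.
#' @return list of class `psth`: `bin_edges`, `mids`, `rates` (Hz),
#'   `n_trials`, `onset_discard`, `bin_width`.
#' @export
#' @examples
#' compute_psth(list(c(0.1, 0.3)), duration = 1, bin_width = 0.2)$rates
compute_psth <- function(trials, duration, bin_width = 0.05,
                         onset_discard = 0.2) {
  stopifnot_positive(duration = duration, bin_width = bin_width)
  stopifnot_positive(onset_discard = onset_discard, .allow_zero = TRUE)
  if (is.numeric(trials)) trials <- list(trials)
  n_trials <- length(trials)
  edges <- seq(onset_discard, duration, by = bin_width)
  if (length(edges) < 2) stop("analysis window shorter than one bin",
                              call. = FALSE)
  counts <- numeric(length(edges) - 1)
  for (tr in trials) {
    tr <- tr[tr >= onset_discard & tr < edges[length(edges)]]
    if (length(tr) > 0) {
      counts <- counts + tabulate(findInterval(tr, edges,
                                               rightmost.closed = FALSE),
                                  nbins = length(counts))
    }
  }
  structure(list(bin_edges = edges, mids = edges[-length(edges)] + bin_width / 2,
                 rates = counts / (n_trials * bin_width),
                 n_trials = n_trials, onset_discard = onset_discard,
                 bin_width = bin_width),
            class = "psth")
}

#' Standardized F1 modulation score
#'
#' `zF1 = (F1 - mean(FFT)) / SD(FFT)` where `F1` is the amplitude of the
#' PSTH spectrum at the stimulus temporal frequency and the mean and SD are
#' taken over the amplitude spectrum from `1/T` (the lowest analysed
#' frequency, `T` the analysis-window length) to the Nyquist frequency. The
#' DC bin is excluded, so the score is invariant to adding a constant rate.
#'
#' @param psth a `psth`.
#' @param stimulus_tf stimulus temporal frequency, Hz; matched to the
#'   nearest analysed frequency bin (`f1_exact` records whether it fell
#'   within half a bin).
#' @return list of class `modulation_score`: `zf1`, `f1_amplitude`,
#'   `spectrum_mean`, `spectrum_sd`, `stimulus_tf`, `f1_freq`, `f1_exact`.
#' @export
zf1_score <- function(psth, stimulus_tf) {
  stopifnot(inherits(psth, "psth"))
  stopifnot_positive(stimulus_tf = stimulus_tf)
  x <- psth$rates
  n <- length(x)
  T_win <- n * psth$bin_width
  amp <- Mod(stats::fft(x)) / n
  freqs <- (seq_len(n) - 1) / T_win
  band <- 2:(floor(n / 2) + 1)              # 1/T .. Nyquist
  k <- band[which.min(abs(freqs[band] - stimulus_tf))]
  mu <- mean(amp[band])
  sd_ <- stats::sd(amp[band])
  if (!is.finite(sd_) || sd_ <= 1e-10 * (abs(mean(x)) + 1e-300)) {
    stop("zF1 undefined: flat amplitude spectrum", call. = FALSE)
  }
  structure(list(zf1 = (amp[k] - mu) / sd_, f1_amplitude = amp[k],
                 spectrum_mean = mu, spectrum_sd = sd_,
                 stimulus_tf = stimulus_tf, f1_freq = freqs[k],
                 f1_exact = abs(freqs[k] - stimulus_tf) <= 0.5 / T_win + 1e-12),
            class = "modulation_score")
}

#' Screen cells by zF1 - firing-rate correlation
#'
#' A cell is kept when its per-condition zF1 values correlate with the
#' corresponding mean firing rates (Pearson, p <= alpha); cells whose
#' modulation does not track their rate are discarded as unmodulated.
#'
#' @param zf1 numeric vector of zF1 scores, one per condition.
#' @param mean_rates matched mean firing rates, Hz.
#' @param alpha significance level (default 0.05).
#' @return list: `keep`, `r`, `p`, `n`, `reason` (`NA`, "degenerate" when a
#'   vector is constant, in which case the cell is discarded).
#' @export
screen_modulated <- function(zf1, mean_rates, alpha = 0.05) {
  stopifnot(length(zf1) == length(mean_rates))
  ok <- is.finite(zf1) & is.finite(mean_rates)
  zf1 <- zf1[ok]; mean_rates <- mean_rates[ok]
  if (length(zf1) < 3) {
    stop("need at least 3 paired conditions for the modulation screen",
         call. = FALSE)
  }
  if (stats::sd(zf1) == 0 || stats::sd(mean_rates) == 0) {
    return(list(keep = FALSE, r = NA_real_, p = NA_real_, n = length(zf1),
                reason = "degenerate"))
  }
  ct <- stats::cor.test(zf1, mean_rates, method = "pearson")
  list(keep = ct$p.value <= alpha, r = unname(ct$estimate), p = ct$p.value,
       n = length(zf1), reason = NA_character_)
}

#' Fit a skewed log-Gaussian speed-tuning curve
#'
#' Bounded multi-start least squares of [speed_tuning_curve()] in log2
#' speed on peak-normalized responses. Initial preferred speeds are taken
#' from every tested speed; the best sum of squared residuals wins, ties
#' going to the smallest width. `chi2` is the sum of squared residuals on
#' the peak-normalized scale, the quantity thresholded by the
#' speed-responsive criterion.
#'
#' @param responses mean response per speed (Hz or any common scale).
#' @param speeds tested speeds, mm/s (>= 4 values, all > 0).
#' @param sigma_bounds,zeta_bounds parameter box constraints.
#' @return list of class `speed_tuning_fit`: `A` (response scale), `V`
#'   (mm/s), `sigma_v`, `zeta`, `chi2`, `converged`, `bound_active`.
#' @export
fit_speed_tuning <- function(responses, speeds, sigma_bounds = c(0.05, 10),
                             zeta_bounds = c(-1, 1)) {
  stopifnot_positive(speeds = speeds)
  if (length(responses) != length(speeds) || length(speeds) < 4) {
    stop("need >= 4 paired (speed, response) values", call. = FALSE)
  }
  pk <- max(responses)
  if (pk <= 0) stop("all responses are <= 0; nothing to fit", call. = FALSE)
  y <- responses / pk
  u <- log2(speeds)
  mu_bounds <- c(log2(min(speeds) / 2), log2(max(speeds) * 2))

  resid_fn <- function(p) {
    # p = (A, mu, sigma, zeta) on normalized responses
    du <- u - p[2]
    denom <- p[3] + p[4] * du
    if (any(denom <= 1e-6)) return(rep(1e3, length(u)))
    floor_term <- if (p[4] == 0) 0 else exp(-1 / p[4]^2)
    p[1] * (exp(-du^2 / (2 * denom^2)) - floor_term) - y
  }

  best <- NULL
  for (v0 in speeds) {
    for (z0 in c(-0.1, 0, 0.1)) {
      fit <- try(minpack.lm::nls.lm(
        par = c(max(y), log2(v0), 1, z0),
        lower = c(1e-3, mu_bounds[1], sigma_bounds[1], zeta_bounds[1]),
        upper = c(3, mu_bounds[2], sigma_bounds[2], zeta_bounds[2]),
        fn = resid_fn, control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr - 1e-12 ||
          (abs(ssr - best$ssr) <= 1e-12 && fit$par[3] < best$par[3])) {
        best <- list(fit = fit, ssr = ssr, par = fit$par)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NA, V = NA, sigma_v = NA, zeta = NA,
                          chi2 = Inf, converged = FALSE, bound_active = NA),
                     class = "speed_tuning_fit"))
  }
  p <- best$par
  tol <- 1e-6
  bound_active <- p[3] <= sigma_bounds[1] + tol || p[3] >= sigma_bounds[2] - tol ||
    p[4] <= zeta_bounds[1] + tol || p[4] >= zeta_bounds[2] - tol
  structure(list(A = p[1] * pk, V = 2^p[2], sigma_v = p[3], zeta = p[4],
                 chi2 = best$ssr, converged = TRUE,
                 bound_active = bound_active),
            class = "speed_tuning_fit")
}

#' Classify a cell as speed responsive
#'
#' A cell is speed responsive when it passed the zF1-rate modulation screen
#' and its tuning fit is good (`chi2 < chi2_max`) at every tested spatial
#' frequency.
#'
#' @param chi2 named or plain numeric vector, one goodness-of-fit value per
#'   tested spatial frequency (no missing values allowed).
#' @param screen_keep logical from [screen_modulated()].
#' @param chi2_max threshold (default 0.05 on the normalized-response SSR).
#' @return logical.
#' @export
classify_speed_responsive <- function(chi2, screen_keep, chi2_max = 0.05) {
  if (any(!is.finite(chi2)) || length(chi2) == 0) {
    stop("incomplete input: a chi2 value is required for every tested ",
         "spatial frequency", call. = FALSE)
  }
  isTRUE(screen_keep) && all(chi2 < chi2_max)
}

#' Normalized tuning-bandwidth change
#'
#' `(sigma_v1 - sigma_v2) / (sigma_v1 + sigma_v2)`, in (-1, 1); positive
#' when the second condition is narrower.
#'
#' @param sigma_v1,sigma_v2 tuning widths (> 0).
#' @return normalized difference.
#' @export
#' @examples
#' delta_sigma(1.76, 0.95)
delta_sigma <- function(sigma_v1, sigma_v2) {
  stopifnot_positive(sigma_v1 = sigma_v1, sigma_v2 = sigma_v2)
  (sigma_v1 - sigma_v2) / (sigma_v1 + sigma_v2)
}

#' Per-condition mean response of one cell
#'
#' Convenience wrapper: mean PSTH rate (the response measure used
#' throughout the tuning analysis) for each row of a condition grid.
#'
#' @param spikes a `spike_data` table.
#' @param cell_id cell to analyse.
#' @param conditions data.frame with `kind, sf0, speed`.
#' @param duration trial length, s.
#' @param bin_width,onset_discard PSTH parameters, s.
#' @return `conditions` with a `response` column (Hz) appended.
#' @export
condition_responses <- function(spikes, cell_id, conditions, duration = 3,
                                bin_width = 0.05, onset_discard = 0.2) {
  resp <- vapply(seq_len(nrow(conditions)), function(i) {
    tr <- spike_times(spikes, cell_id = cell_id, kind = conditions$kind[i],
                      sf0 = conditions$sf0[i], speed = conditions$speed[i],
                      by_trial = TRUE)
    mean(compute_psth(tr, duration, bin_width, onset_discard)$rates)
  }, numeric(1))
  out <- conditions
  out$response <- resp
  out
}

#' Mean-response table for all cells and conditions in one pass
#'
#' Vectorized equivalent of [condition_responses()] over every cell in a
#' spike table: the mean PSTH rate within the analysis window per (cell,
#' condition), computed by a single tabulation.
#'
#' @inheritParams condition_responses
#' @return data.frame with columns `cell_id, kind, sf0, speed, response`.
#' @export
response_table <- function(spikes, conditions, duration = 3,
                           bin_width = 0.05, onset_discard = 0.2) {
  n_trials <- attr(spikes, "n_trials") %||% max(spikes$trial)
  n_bins <- floor((duration - onset_discard) / bin_width)
  window <- n_bins * bin_width
  cells <- sort(unique(spikes$cell_id))
  key_cond <- paste(conditions$kind, conditions$sf0, conditions$speed)
  key_spk <- paste(spikes$kind, spikes$sf0, spikes$speed)
  sel <- spikes$spike_time_s >= onset_discard &
    spikes$spike_time_s < onset_discard + window
  counts <- table(factor(spikes$cell_id[sel], levels = cells),
                  factor(key_spk[sel], levels = key_cond))
  out <- do.call(rbind, lapply(seq_along(cells), function(i) {
    df <- conditions[, c("kind", "sf0", "speed")]
    df$cell_id <- cells[i]
    df$response <- as.numeric(counts[i, ]) / (n_trials * window)
    df
  }))
  rownames(out) <- NULL
  out[, c("cell_id", "kind", "sf0", "speed", "response")]
}
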