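# End-to-end orchestration of the synthetic experiment: stimuli ->
# responses -> screening -> tuning -> sparseness -> decoding.

#' Configuration for a full synthetic speed-tuning analysis
#'
#' All tunable thresholds and problem sizes in one serializable list. The
#' defaults run a scaled-down version of the full protocol grid suitable
#' for interactive use; pass the full six spatial frequencies and 10 trials
#' to mirror the complete protocol.
#'
#' @param n_cells simulated population size.
#' @param on_fraction ON-cell proportion.
#' @param kinds stimulus classes to simulate.
#' @param sf0,speeds condition grid values (cycles/mm, mm/s).
#' @param n_trials repetitions per condition.
#' @param duration trial length, s.
#' @param f1_modulation sinusoidal rate-modulation depth of the tuned
#'   generator.
#' @param sigma_scale per-class tuning-width multipliers of the generator.
#' @param chi2_max,eps_max,alpha analysis thresholds (tuning-fit
#'   goodness, eccentricity discard, modulation-screen level).
#' @param bin_width,onset_discard PSTH parameters, s.
#' @param decode logical; run the reconstruction/decoding stage.
#' @param decode_sf0 spatial frequency used for the decoding stage.
#' @param decode_trials trials per condition in the decoding stage.
#' @param decode_n_cells,decode_size_px,decode_px_per_mm,decode_gain_scale decoding-stage
#'   simulation geometry.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return list of class `speed_analysis_config`.
#' @export
speed_analysis_config <- function(n_cells = 40, on_fraction = 0.2,
                                  kinds = c("grating", "mc_narrow", "mc_broad"),
                                  sf0 = c(0.9, 1.8, 3.6),
                                  speeds = c(0.25, 0.5, 1, 2, 4),
                                  n_trials = 10, duration = 3,
                                  f1_modulation = 0.8,
                                  sigma_scale = c(grating = 1,
                                                  mc_narrow = 0.82,
                                                  mc_broad = 0.54),
                                  chi2_max = 0.05, eps_max = 0.9,
                                  alpha = 0.05, bin_width = 0.05,
                                  onset_discard = 0.2,
                                  decode = FALSE, decode_sf0 = 0.9,
                                  decode_trials = 3, decode_n_cells = 60,
                                  decode_size_px = 128, decode_px_per_mm = 40,
                                  decode_gain_scale = 5, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "speed_analysis_config"
  cfg
}

#' Run the full synthetic speed-tuning analysis
#'
#' Composes the pipeline: ground-truth population with planted tuning,
#' tuned spike trains over the condition grid, PSTH responses, zF1-rate
#' modulation screen (on the grating conditions), skewed log-Gaussian
#' tuning fits per spatial frequency and class, speed-responsive
#' classification, tuning-width comparisons between classes, the
#' sparseness grid, and (optionally) a linear-reconstruction /
#' motion-energy decoding stage on a simulated linear-nonlinear
#' population.
#'
#' @param config a `speed_analysis_config`.
#' @return list of class `speed_analysis_result` with elements
#'   `config, config_checksum, population, conditions, responses, screen,
#'   tuning, sr_cells, delta_sigma, sparseness, decoding (or NULL),
#'   summary`.
#' @export
run_speed_analysis <- function(config = speed_analysis_config()) {
  required <- c("n_cells", "sf0", "speeds", "kinds", "n_trials", "duration",
                "chi2_max", "alpha", "seed")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0) {
    stop("configuration error: missing keys: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  cfg <- config
  pop <- make_ground_truth_population(cfg$n_cells, cfg$on_fraction,
                                      seed = derive_seed(cfg$seed, "population"))
  pop <- attach_speed_tuning(pop, seed = derive_seed(cfg$seed, "tuning"))
  conds <- condition_grid(kinds = cfg$kinds, sf0 = cfg$sf0,
                          speeds = cfg$speeds)
  spikes <- simulate_tuned_spike_trains(
    pop, conds, duration = cfg$duration, n_trials = cfg$n_trials,
    sigma_scale = cfg$sigma_scale, f1_modulation = cfg$f1_modulation,
    seed = derive_seed(cfg$seed, "responses"))

  # per-cell responses and the modulation screen on grating conditions
  responses <- response_table(spikes, conds, cfg$duration, cfg$bin_width,
                              cfg$onset_discard)
  grating_conds <- conds[conds$kind == "grating", ]
  screen <- do.call(rbind, lapply(pop$cell_id, function(cid) {
    zf1 <- vapply(seq_len(nrow(grating_conds)), function(i) {
      tr <- spike_times(spikes, cid, "grating", grating_conds$sf0[i],
                        grating_conds$speed[i], by_trial = TRUE)
      p <- compute_psth(tr, cfg$duration, cfg$bin_width, cfg$onset_discard)
      # empty or single-spike PSTHs have no usable spectrum
      tryCatch(zf1_score(p, grating_conds$tf[i])$zf1,
               error = function(e) NA_real_)
    }, numeric(1))
    rates <- responses$response[responses$cell_id == cid &
                                  responses$kind == "grating"]
    sc <- tryCatch(screen_modulated(zf1[is.finite(zf1)],
                                    rates[is.finite(zf1)], cfg$alpha),
                   error = function(e) list(keep = FALSE, r = NA, p = NA,
                                            n = 0, reason = "error"))
    data.frame(cell_id = cid, keep = sc$keep, r = sc$r, p = sc$p,
               stringsAsFactors = FALSE)
  }))

  # tuning fits per (cell, kind, sf0)
  fit_rows <- list()
  for (cid in pop$cell_id) {
    for (k in cfg$kinds) {
      for (s in cfg$sf0) {
        sel <- responses$cell_id == cid & responses$kind == k &
          abs(responses$sf0 - s) < 1e-9
        y <- responses$response[sel]
        v <- responses$speed[sel]
        ft <- if (max(y) <= 0) NULL else fit_speed_tuning(y, v)
        fit_rows[[length(fit_rows) + 1]] <- data.frame(
          cell_id = cid, kind = k, sf0 = s,
          A = ft$A %||% NA_real_, V = ft$V %||% NA_real_,
          sigma_v = ft$sigma_v %||% NA_real_, zeta = ft$zeta %||% NA_real_,
          chi2 = ft$chi2 %||% Inf, stringsAsFactors = FALSE)
      }
    }
  }
  tuning <- do.call(rbind, fit_rows)

  sr <- vapply(pop$cell_id, function(cid) {
    chi2 <- tuning$chi2[tuning$cell_id == cid & tuning$kind == "grating"]
    keep <- screen$keep[screen$cell_id == cid]
    if (any(!is.finite(chi2))) return(FALSE)
    classify_speed_responsive(chi2, keep, cfg$chi2_max)
  }, logical(1))
  sr_cells <- pop$cell_id[sr]

  # tuning-width change, grating vs each cloud class, per SR cell and sf0
  ds_rows <- list()
  for (k in setdiff(cfg$kinds, "grating")) {
    for (cid in sr_cells) {
      for (s in cfg$sf0) {
        s1 <- tuning$sigma_v[tuning$cell_id == cid &
                               tuning$kind == "grating" & tuning$sf0 == s]
        s2 <- tuning$sigma_v[tuning$cell_id == cid &
                               tuning$kind == k & tuning$sf0 == s]
        if (length(s1) == 1 && length(s2) == 1 &&
            is.finite(s1) && is.finite(s2) && s1 > 0 && s2 > 0) {
          ds_rows[[length(ds_rows) + 1]] <- data.frame(
            cell_id = cid, kind = k, sf0 = s,
            delta_sigma = delta_sigma(s1, s2), stringsAsFactors = FALSE)
        }
      }
    }
  }
  ds <- if (length(ds_rows)) do.call(rbind, ds_rows) else NULL

  sparseness <- sparseness_grid(spikes, conds, cfg$duration,
                                cfg$onset_discard)

  decoding <- NULL
  if (isTRUE(cfg$decode)) {
    decoding <- run_decoding_stage(cfg)
  }

  summary <- list(
    n_cells = cfg$n_cells,
    n_screen_pass = sum(screen$keep),
    n_sr = length(sr_cells),
    median_delta_sigma = if (!is.null(ds))
      stats::aggregate(delta_sigma ~ kind, ds, stats::median) else NULL,
    sparseness_by_kind = stats::aggregate(sparseness_mean ~ kind, sparseness,
                                          mean),
    decoding = if (!is.null(decoding)) decoding$metrics$per_kind else NULL)

  structure(list(config = cfg, config_checksum = config_checksum(cfg),
                 population = pop, conditions = conds, responses = responses,
                 screen = screen, tuning = tuning, sr_cells = sr_cells,
                 delta_sigma = ds, sparseness = sparseness,
                 decoding = decoding, summary = summary),
            class = "speed_analysis_result")
}

# Closed-loop decoding stage: simulate an LN population on drifting
# gratings, reconstruct the space-time stimulus from its spikes with the
# planted kernels, and decode speed with an opponent motion-energy bank.
run_decoding_stage <- function(cfg) {
  seed <- derive_seed(cfg$seed, "decode")
  px_per_mm <- cfg$decode_px_per_mm
  size_px <- cfg$decode_size_px
  field_mm <- size_px / px_per_mm
  pop <- make_ground_truth_population(cfg$decode_n_cells,
                                      on_fraction = cfg$on_fraction,
                                      field_size = field_mm, seed = seed)
  kernels <- lapply(seq_len(nrow(pop)), function(i) {
    collapse_rf(ground_truth_kernel(pop[i, ], size_px, size_px, px_per_mm))
  })
  names(kernels) <- as.character(pop$cell_id)
  bank <- build_motion_energy_bank(cfg$speeds, cfg$decode_sf0, px_per_mm,
                                   frame_rate = 60)
  decisions <- list()
  all_spikes <- list()
  for (v in cfg$speeds) {
    mov <- make_drifting_grating(cfg$decode_sf0, v, duration = cfg$duration,
                                 size_px = size_px, px_per_mm = px_per_mm)
    spk <- simulate_ln_responses(pop, mov, n_trials = cfg$decode_trials,
                                 gain_scale = cfg$decode_gain_scale %||% 5,
                                 seed = derive_seed(seed + round(v * 100), "decode"))
    all_spikes[[length(all_spikes) + 1]] <- spk
    for (tr in seq_len(cfg$decode_trials)) {
      xt <- reconstruct_xt(spk, kernels, cfg$duration, trial = tr)
      dec <- decode_speed(xt, bank)
      decisions[[length(decisions) + 1]] <- data.frame(
        kind = "grating", sf0 = cfg$decode_sf0, speed = v, trial = tr,
        chosen_speed = dec$chosen_speed,
        chosen_direction = dec$chosen_direction, stringsAsFactors = FALSE)
    }
  }
  decisions <- do.call(rbind, decisions)
  spikes <- do.call(rbind, lapply(all_spikes, as.data.frame))
  metrics <- decoding_metrics(decisions, spikes, cfg$decode_n_cells)
  list(decisions = decisions, metrics = metrics)
}

#' @export
print.speed_analysis_result <- function(x, ...) {
  cat("<speed_analysis_result> checksum", x$config_checksum, "\n")
  cat(sprintf("  %d cells; %d pass modulation screen; %d speed responsive\n",
              x$summary$n_cells, x$summary$n_screen_pass, x$summary$n_sr))
  invisible(x)
}

#' Write a human-readable run report
#'
#' Emits the per-stage tables (tab-separated) and a plain-text summary
#' mirroring the analysis grids: tuning-fit table, tuning-width changes,
#' sparseness grid and decoding error rates. Every number in the summary
#' is recomputable from the emitted tables.
#'
#' @param result a `speed_analysis_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "speed_analysis_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) utils::write.table(df, file.path(dir, name), sep = "\t",
                                         row.names = FALSE, quote = FALSE)
  }
  wt(result$responses, "responses.tsv")
  wt(result$screen, "screen.tsv")
  wt(result$tuning, "tuning.tsv")
  wt(result$delta_sigma, "delta_sigma.tsv")
  wt(result$sparseness, "sparseness.tsv")
  if (!is.null(result$decoding)) {
    wt(result$decoding$decisions, "decode_decisions.tsv")
    wt(result$decoding$metrics$per_condition, "decode_error_rates.tsv")
    wt(result$decoding$metrics$per_kind, "decode_summary.tsv")
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("run checksum: %s", result$config_checksum),
    sprintf("cells simulated: %d", result$summary$n_cells),
    sprintf("cells passing modulation screen: %d", result$summary$n_screen_pass),
    sprintf("speed-responsive cells: %d", result$summary$n_sr),
    if (result$summary$n_sr == 0)
      "no speed-responsive cells under this configuration" else NULL,
    "", "sparseness by stimulus class (mean over grid):"), con)
  utils::write.table(result$summary$sparseness_by_kind, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$summary$median_delta_sigma)) {
    writeLines(c("", "median tuning-width change vs grating:"), con)
    utils::write.table(result$summary$median_delta_sigma, con, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$summary$decoding)) {
    writeLines(c("", "decoding summary:"), con)
    utils::write.table(result$summary$decoding, con, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
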