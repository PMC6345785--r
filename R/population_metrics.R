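# Population-level summaries: sparseness, population tuning with paired
# signed-rank comparisons, and flash-based response classification.

#' Population sparseness
#'
#' Treves-Rolls-style sparseness of a population response, corrected for
#' population size: `S_p = [1 - (sum(|A|)/N)^2 / (sum(A^2)/N)] /
#' (1 - 1/N)`. 0 for an exactly uniform response, 1 when a single cell
#' carries all the response; invariant to scaling and to permutation of
#' cells.
#'
#' @param responses per-cell responses `A_i` (Hz); absolute values are used.
#' @return sparseness in `[0, 1]`.
#' @export
#' @examples
#' population_sparseness(c(1, 2, 3))  # 3/14
population_sparseness <- function(responses) {
  n <- length(responses)
  if (n < 2) stop("invalid parameter: need at least 2 cells", call. = FALSE)
  a <- abs(responses)
  if (all(a == 0)) stop("sparseness undefined: all responses are zero",
                        call. = FALSE)
  (1 - (sum(a) / n)^2 / (sum(a^2) / n)) / (1 - 1 / n)
}

# Wilcoxon signed-rank on paired samples; all-zero differences give p = 1.
paired_signed_rank <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(list(statistic = NA_real_, p.value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = length(d) < 25,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Population tuning with class comparisons
#'
#' Averages per-cell responses (mean PSTH rate) over a set of cells for
#' every condition, and compares stimulus classes condition-by-condition
#' with paired two-sided Wilcoxon signed-rank tests over the same cells.
#'
#' @param response_table data.frame with columns `cell_id, kind, sf0,
#'   speed, response`, e.g. stacked [condition_responses()] output
#'   restricted to speed-responsive cells.
#' @param reference_kind stimulus class the others are compared against.
#' @return list: `summary` (per-condition mean, sd, n) and `comparisons`
#'   (per condition and non-reference kind: Wilcoxon `statistic`, `p`).
#' @export
population_tuning <- function(response_table, reference_kind = "grating") {
  req <- c("cell_id", "kind", "sf0", "speed", "response")
  stopifnot(all(req %in% names(response_table)))
  summ <- stats::aggregate(response ~ kind + sf0 + speed, response_table,
                           function(x) c(mean = mean(x), sd = stats::sd(x),
                                         n = length(x)))
  summ <- cbind(summ[c("kind", "sf0", "speed")],
                as.data.frame(summ$response))
  comps <- list()
  kinds <- setdiff(unique(response_table$kind), reference_kind)
  conds <- unique(response_table[c("sf0", "speed")])
  for (k in kinds) {
    for (i in seq_len(nrow(conds))) {
      sel_ref <- response_table$kind == reference_kind &
        response_table$sf0 == conds$sf0[i] & response_table$speed == conds$speed[i]
      sel_k <- response_table$kind == k &
        response_table$sf0 == conds$sf0[i] & response_table$speed == conds$speed[i]
      ref <- response_table[sel_ref, c("cell_id", "response")]
      alt <- response_table[sel_k, c("cell_id", "response")]
      common <- intersect(ref$cell_id, alt$cell_id)
      if (length(common) != nrow(ref) || length(common) != nrow(alt)) {
        stop("pairing error: cell sets differ between stimulus classes",
             call. = FALSE)
      }
      x <- ref$response[match(common, ref$cell_id)]
      y <- alt$response[match(common, alt$cell_id)]
      w <- paired_signed_rank(x, y)
      comps[[length(comps) + 1]] <- data.frame(
        kind = k, sf0 = conds$sf0[i], speed = conds$speed[i],
        statistic = w$statistic, p = w$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = summ,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}

#' Sparseness grid over conditions
#'
#' Per-trial population sparseness of trial spike counts, averaged over
#' trials, for every condition in a spike table.
#'
#' @param spikes a `spike_data` table.
#' @param conditions data.frame with `kind, sf0, speed`.
#' @param duration trial length, s.
#' @param onset_discard s; spikes before it are ignored.
#' @return `conditions` with `sparseness_mean`, `sparseness_sd` appended.
#' @export
sparseness_grid <- function(spikes, conditions, duration = 3,
                            onset_discard = 0.2) {
  n_trials <- attr(spikes, "n_trials") %||% max(spikes$trial)
  cells <- sort(unique(spikes$cell_id))
  out <- conditions
  out$sparseness_mean <- NA_real_
  out$sparseness_sd <- NA_real_
  for (i in seq_len(nrow(conditions))) {
    sel <- spikes$kind == conditions$kind[i] &
      abs(spikes$sf0 - conditions$sf0[i]) < 1e-9 &
      abs(spikes$speed - conditions$speed[i]) < 1e-9 &
      spikes$spike_time_s >= onset_discard
    sub <- spikes[sel, ]
    sp <- vapply(seq_len(n_trials), function(tr) {
      counts <- vapply(cells, function(cid)
        sum(sub$cell_id == cid & sub$trial == tr), numeric(1))
      if (all(counts == 0)) NA_real_ else population_sparseness(counts)
    }, numeric(1))
    out$sparseness_mean[i] <- mean(sp, na.rm = TRUE)
    out$sparseness_sd[i] <- stats::sd(sp, na.rm = TRUE)
  }
  out
}

#' Classify cells by full-field flash response
#'
#' Latency = time from flash onset to the peak rate within the peak-search
#' window; transience index = 1 - (mean rate in the late window / peak
#' rate). Cells are split at the population medians into Fast/Slow and
#' Transient/Sustained. Flat responses are flagged unclassifiable. The
#' index definitions and window lengths are package choices (the
#' classification literature offers several variants) and are exposed as
#' arguments.
#'
#' @param flash_psths list of `psth` objects, one per cell, time measured
#'   from flash onset.
#' @param peak_window s, search window for the peak.
#' @param late_window length-2 numeric, window for the sustained level, s.
#' @return data.frame: `cell_id, latency, transience, speed_class
#'   ("Fast"/"Slow"), persistence_class ("Transient"/"Sustained"),
#'   classifiable`.
#' @export
flash_response_classification <- function(flash_psths,
                                          peak_window = 0.4,
                                          late_window = c(0.4, 0.8)) {
  n <- length(flash_psths)
  latency <- transience <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- flash_psths[[i]]
    in_peak <- p$mids <= peak_window
    if (!any(in_peak) || max(p$rates[in_peak]) <= 0) next
    pk_i <- which.max(p$rates[in_peak])
    pk <- p$rates[in_peak][pk_i]
    latency[i] <- p$mids[in_peak][pk_i]
    late <- p$rates[p$mids >= late_window[1] & p$mids <= late_window[2]]
    transience[i] <- 1 - mean(late) / pk
  }
  classifiable <- is.finite(latency) & is.finite(transience)
  med_l <- stats::median(latency[classifiable])
  med_t <- stats::median(transience[classifiable])
  data.frame(
    cell_id = names(flash_psths) %||% as.character(seq_len(n)),
    latency = latency, transience = transience,
    speed_class = ifelse(classifiable,
                         ifelse(latency <= med_l, "Fast", "Slow"),
                         NA_character_),
    persistence_class = ifelse(classifiable,
                               ifelse(transience > med_t, "Transient",
                                      "Sustained"),
                               NA_character_),
    classifiable = classifiable, stringsAsFactors = FALSE)
}
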