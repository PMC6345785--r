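# Plain-text on-disk dialects for spike tables and stimulus movies.

#' Write / read a spike table
#'
#' One tab-separated table with columns `cell_id, kind, sf0, speed, trial,
#' spike_time_s`, plus a JSON sidecar (`<path>.json`) carrying duration,
#' trial count and generator provenance.
#'
#' @param spikes a `spike_data` data.frame.
#' @param path file path for the TSV table.
#' @param provenance optional list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_data <- function(spikes, path, provenance = NULL) {
  utils::write.table(as.data.frame(spikes), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  header <- list(duration = attr(spikes, "duration"),
                 n_trials = attr(spikes, "n_trials"),
                 seed = attr(spikes, "seed"),
                 provenance = provenance)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  as_spike_data(df, duration = header$duration, n_trials = header$n_trials,
                seed = header$seed)
}

#' Write / read a stimulus movie
#'
#' The luminance grid is stored time-major as a plain-text matrix (one
#' frame per row, pixels in row-major order) and every movie field goes
#' into a JSON sidecar. File stems follow
#' `<kind>_sf<sf0>_v<speed>_b<b_sf>_s<seed>`.
#'
#' @param movie a `stimulus_movie`.
#' @param dir output directory.
#' @param stem optional file stem; derived from the metadata by default.
#' @return path of the data file, invisibly.
#' @export
write_stimulus_movie <- function(movie, dir, stem = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||% sprintf("%s_sf%s_v%s_b%s_s%s", movie$kind,
                            movie$sf0 %||% NA, movie$speed %||% NA,
                            movie$b_sf %||% NA, movie$seed %||% "NA")
  d <- dim(movie$frames)
  mat <- matrix(aperm(movie$frames, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
  data_path <- file.path(dir, paste0(stem, ".txt"))
  utils::write.table(mat, data_path, row.names = FALSE, col.names = FALSE)
  meta <- movie[setdiff(names(movie), "frames")]
  meta$dim <- d
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(data_path)
}

#' @rdname write_stimulus_movie
#' @export
read_stimulus_movie <- function(path) {
  meta_path <- sub("\\.txt$", ".json", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, header = FALSE))
  d <- meta$dim
  frames <- aperm(array(t(mat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  new_stimulus_movie(frames, meta$frame_rate, meta$px_per_mm, meta$kind,
                     meta$sf0 %||% NA_real_, meta$speed %||% NA_real_,
                     meta$b_sf %||% NA_real_, meta$duration,
                     meta$seed, as.list(meta$meta))
}
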