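#' Write / read a recording container
#'
#' On-disk container for a `seeg_recording`: a directory holding
#' `meta.json` (sampling rate, dimensions, seed), `signal.bin` (float64,
#' channel-major, little-endian), `channels.tsv`, and optional `audio.bin` /
#' `state.bin`. The round trip preserves the signal to better than 1e-6
#' relative and all metadata exactly.
#'
#' @param rec A `seeg_recording`.
#' @param path Container directory (created if missing).
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns the `seeg_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               n_channels = n_channels(rec),
               n_samples = n_samples(rec),
               seed = rec$seed,
               has_audio = !is.null(rec$audio),
               has_state = !is.null(rec$state))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  con <- file(file.path(path, "signal.bin"), "wb")
  writeBin(as.vector(rec$signal), con, size = 8, endian = "little")
  close(con)
  utils::write.table(rec$channels, file.path(path, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(rec$audio)) {
    con <- file(file.path(path, "audio.bin"), "wb")
    writeBin(as.numeric(rec$audio), con, size = 8, endian = "little")
    close(con)
  }
  if (!is.null(rec$state)) {
    con <- file(file.path(path, "state.bin"), "wb")
    writeBin(as.integer(rec$state), con, size = 4, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a recording container: missing meta.json in ", path,
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(path, "signal.bin"), "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n)
    stop("signal.bin truncated: expected ", n, " values, got ", length(x),
         call. = FALSE)
  channels <- tibble::as_tibble(
    utils::read.table(file.path(path, "channels.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE))
  audio <- state <- NULL
  if (isTRUE(meta$has_audio)) {
    con <- file(file.path(path, "audio.bin"), "rb")
    audio <- readBin(con, "double", n = meta$n_samples, size = 8,
                     endian = "little")
    close(con)
  }
  if (isTRUE(meta$has_state)) {
    con <- file(file.path(path, "state.bin"), "rb")
    state <- readBin(con, "integer", n = meta$n_samples, size = 4,
                     endian = "little")
    close(con)
  }
  new_recording(matrix(x, nrow = meta$n_channels), meta$sampling_rate,
                channels, audio = audio, state = state,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write / read interval annotations
#'
#' Tab-separated interval representation of a `trial_schedule`: columns
#' `onset_s`, `offset_s`, `label` (phase), `trial_id`, `sentence_id`,
#' `repetition`, `syllable_index`. Reading validates ordering and rejects
#' overlapping intervals within a trial.
#'
#' @param schedule A `trial_schedule`.
#' @param path TSV file path.
#' @return `write_annotation` invisibly returns `path`; `read_annotation`
#'   returns the `trial_schedule`.
#' @export
write_annotation <- function(schedule, path) {
  out <- data.frame(onset_s = schedule$onset, offset_s = schedule$offset,
                    label = schedule$phase, trial_id = schedule$trial_id,
                    sentence_id = schedule$sentence_id,
                    repetition = schedule$repetition,
                    syllable_index = schedule$syllable_index)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "label", "trial_id", "sentence_id",
            "repetition")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("annotation file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$offset_s < df$onset_s))
    stop("annotation has negative-length interval at line ",
         which(df$offset_s < df$onset_s)[1] + 1L, call. = FALSE)
  sched <- tibble::tibble(trial_id = df$trial_id,
                          sentence_id = df$sentence_id,
                          repetition = df$repetition,
                          phase = df$label,
                          syllable_index = if ("syllable_index" %in% names(df))
                            df$syllable_index else NA_integer_,
                          onset = df$onset_s, offset = df$offset_s)
  # overlap validation within each trial
  bad <- sched |>
    dplyr::arrange(.data$trial_id, .data$onset) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(prev_off = dplyr::lag(.data$offset)) |>
    dplyr::filter(!is.na(.data$prev_off) &
                    .data$onset < .data$prev_off - 1e-9)
  if (nrow(bad) > 0)
    stop("annotation has overlapping intervals in trial ",
         bad$trial_id[1], " near t=", signif(bad$onset[1], 6), " s",
         call. = FALSE)
  class(sched) <- c("trial_schedule", class(sched))
  sched
}

#' Write a channel-selection report
#'
#' @param result A `channel_selection` tibble.
#' @param path TSV file path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
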