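# Plain-text I/O: session signal files (header row of channel labels, one row
# per sample, comma-separated), companion JSON metadata, ground-truth masks
# and trigger files in the same columnar format.

#' Write a session to disk
#'
#' Produces `<prefix>_signals.csv` (EMG then EEG columns), `<prefix>_meta.json`
#' (sampling rate, labels, subject, run, condition) and, when ground truth is
#' present, `<prefix>_masks.csv` plus `<prefix>_truth.json` (per-leg stride
#' onsets and curve-step flags).
#'
#' @param rec A `wo_session`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(rec, prefix) {
  stopifnot(inherits(rec, "wo_session"))
  if (is.null(rec$emg)) stop("session has no rendered signals", call. = FALSE)
  files <- character(0)
  sig <- if (is.null(rec$eeg)) rec$emg else cbind(rec$emg, rec$eeg)
  f <- paste0(prefix, "_signals.csv")
  write.csv(as.data.frame(sig), f, row.names = FALSE)
  files <- c(files, f)
  meta <- list(fs_hz = rec$fs_hz, emg_channels = rec$channel_labels$emg,
               eeg_channels = rec$channel_labels$eeg,
               subject_id = rec$subject_id, run_id = rec$run_id,
               condition = rec$condition, snr_db = rec$snr_db,
               n_strides = rec$n_strides, seed = rec$seed)
  f <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (!is.null(rec$truth)) {
    f <- paste0(prefix, "_masks.csv")
    write.csv(as.data.frame(rec$truth$masks), f, row.names = FALSE)
    files <- c(files, f)
    st <- rec$truth$strides
    truth <- list(
      stride_onsets = lapply(split(st$onset_samp, st$leg), as.integer),
      stride_samples = lapply(split(st$stride_samp, st$leg), as.integer),
      curve_steps = lapply(split(st$curve_step, st$leg), as.logical))
    f <- paste0(prefix, "_truth.json")
    jsonlite::write_json(truth, f, auto_unbox = FALSE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a session written by [write_session()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `wo_session` (without the full generator truth; masks and stride
#'   onsets are restored when present).
#' @export
read_session <- function(prefix) {
  sig <- as.matrix(read.csv(paste0(prefix, "_signals.csv"), check.names = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  emg <- sig[, meta$emg_channels, drop = FALSE]
  storage.mode(emg) <- "integer"
  eeg <- if (!is.null(meta$eeg_channels) && length(meta$eeg_channels)) {
    sig[, meta$eeg_channels, drop = FALSE]
  }
  truth <- NULL
  mask_file <- paste0(prefix, "_masks.csv")
  if (file.exists(mask_file)) {
    masks <- as.matrix(read.csv(mask_file, check.names = FALSE))
    storage.mode(masks) <- "integer"
    tj <- jsonlite::read_json(paste0(prefix, "_truth.json"), simplifyVector = TRUE)
    legs <- intersect(c("R", "L"), names(tj$stride_onsets))
    st <- do.call(rbind, lapply(legs, function(leg) {
      data.frame(leg = leg,
                 stride_idx = seq_along(tj$stride_onsets[[leg]]),
                 onset_samp = tj$stride_onsets[[leg]],
                 stride_samp = tj$stride_samples[[leg]],
                 curve_step = tj$curve_steps[[leg]],
                 stringsAsFactors = FALSE)
    }))
    truth <- list(strides = st, masks = masks, cortical = NULL)
  }
  structure(list(emg = emg, eeg = eeg, fs_hz = meta$fs_hz,
                 channel_labels = list(emg = meta$emg_channels,
                                       eeg = meta$eeg_channels),
                 subject_id = meta$subject_id, run_id = meta$run_id,
                 condition = meta$condition, snr_db = meta$snr_db,
                 n_strides = meta$n_strides, seed = meta$seed, truth = truth),
            class = "wo_session")
}

#' Write trigger trains as a columnar 0/1 file
#'
#' @param triggers Named list of [trigger_train()]s.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_triggers <- function(triggers, path) {
  m <- do.call(cbind, lapply(triggers, unclass))
  colnames(m) <- names(triggers)
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triggers
#' @export
read_triggers <- function(path) {
  m <- read.csv(path, check.names = FALSE)
  lapply(setNames(names(m), names(m)), function(ch)
    trigger_train(m[[ch]], muscle_label = ch))
}
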