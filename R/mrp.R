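# Movement-related-potential band features from the pre-movement EEG window.

MRP_WINDOW <- 256L  # last ~512 ms of EEG at 500 Hz

#' Extract movement-related-potential band features from one EEG window
#'
#' Computes, per channel, the maximum short-time-Fourier magnitude in the
#' Bereitschaftspotential (2-5 Hz), mu (9-11 Hz) and beta (12-30 Hz) bands of
#' the 256-sample (about 512 ms) window preceding a foot-strike event, and
#' expresses it in dB relative to 1 microvolt:
#' `20 * log10(max |MRP| / 1 uV)`.
#'
#' Magnitudes are coherent-gain corrected, so an in-bin sinusoid of amplitude
#' A yields peak magnitude A regardless of the analysis window. Band edges
#' are inclusive; when a band contains no bin centre at the configured frame
#' length, the bin nearest the band midpoint is used. Zero or negligible
#' in-band content is floored at -120 dBu.
#'
#' @param eeg_window Numeric matrix, 256 samples x 7 channels
#'   (`T3, C3, Cz, C4, T4, P3, P4`), in volts.
#' @param frame,hop STFT frame length and hop in samples (defaults 128/64,
#'   Hann window). `frame = 256` with `hop = 256` gives the single-frame
#'   rectangular mode used for oracle testing.
#' @param window `"hann"` or `"rect"`; defaults to Hann except in
#'   single-frame mode.
#' @param fs_hz Sampling rate (must be 500).
#' @return Named numeric vector of 21 features (`bp_t3_dbu`, `mu_t3_dbu`,
#'   `beta_t3_dbu`, ..., in channel-major order).
#' @examples
#' w <- matrix(0, 256, 7)
#' w[, 3] <- 1e-6 * sin(2 * pi * 9.765625 * (0:255) / 500)
#' extract_mrp(w, frame = 256, hop = 256)[["mu_cz_dbu"]]  # ~0 dBu
#' @export
extract_mrp <- function(eeg_window, frame = 128L, hop = 64L, window = NULL,
                        fs_hz = 500) {
  if (is.vector(eeg_window)) eeg_window <- matrix(eeg_window, ncol = 1L)
  if (nrow(eeg_window) != MRP_WINDOW) {
    stop(sprintf("EEG window must have exactly %d samples per channel", MRP_WINDOW),
         call. = FALSE)
  }
  if (fs_hz != 500) stop("extract_mrp expects fs = 500 Hz", call. = FALSE)
  frame <- as.integer(frame); hop <- as.integer(hop)
  stopifnot(frame >= 2L, frame <= MRP_WINDOW, hop >= 1L)
  window <- window %||% (if (frame == MRP_WINDOW) "rect" else "hann")
  w <- switch(match.arg(window, c("hann", "rect")),
              hann = 0.5 - 0.5 * cos(2 * pi * seq(0, frame - 1) / (frame - 1)),
              rect = rep(1, frame))
  gain <- 2 / sum(w)  # coherent-gain correction: in-bin amplitude A -> magnitude A

  starts <- seq.int(1L, MRP_WINDOW - frame + 1L, by = hop)
  freqs <- (seq_len(frame %/% 2L + 1L) - 1L) * fs_hz / frame
  bins <- lapply(MRP_BANDS, function(b) {
    sel <- which(freqs >= b[1] & freqs <= b[2])
    if (!length(sel)) sel <- which.min(abs(freqs - mean(b)))
    sel
  })

  n_ch <- ncol(eeg_window)
  labels <- colnames(eeg_window) %||% EEG_CHANNELS[seq_len(n_ch)]
  out <- numeric(0)
  for (ch in seq_len(n_ch)) {
    frames <- vapply(starts, function(s) eeg_window[s:(s + frame - 1L), ch] * w,
                     numeric(frame))
    mag <- abs(stats::mvfft(frames)) * gain
    mag <- mag[seq_len(frame %/% 2L + 1L), , drop = FALSE]
    for (b in names(MRP_BANDS)) {
      peak <- max(mag[bins[[b]], ])
      val <- if (peak <= 0) -120 else max(20 * log10(peak / 1e-6), -120)
      out[paste0(b, "_", tolower(labels[ch]), "_dbu")] <- val
    }
  }
  out
}

#' FIFO buffer of the most recent EEG samples
#'
#' The EEG branch idles as a first-in-first-out buffer holding the last 256
#' samples per channel; when an LG contraction onset fires, the current
#' snapshot is handed to [extract_mrp()].
#'
#' @param n_channels Number of channels (default 7).
#' @param size Buffer depth in samples (default 256).
#' @return A `wo_fifo` object.
#' @export
mrp_fifo <- function(n_channels = 7L, size = MRP_WINDOW) {
  structure(list(buf = matrix(NA_real_, nrow = size, ncol = n_channels),
                 size = size, filled = 0L),
            class = "wo_fifo")
}

#' @rdname mrp_fifo
#' @param fifo A `wo_fifo`.
#' @param x New samples: numeric vector (one multichannel sample) or matrix
#'   with one row per sample.
#' @export
fifo_push <- function(fifo, x) {
  stopifnot(inherits(fifo, "wo_fifo"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == ncol(fifo$buf))
  k <- nrow(x)
  if (k >= fifo$size) {
    fifo$buf <- x[(k - fifo$size + 1L):k, , drop = FALSE]
  } else {
    fifo$buf <- rbind(fifo$buf[-seq_len(k), , drop = FALSE], x)
  }
  fifo$filled <- min(fifo$filled + k, fifo$size)
  fifo
}

#' @rdname mrp_fifo
#' @export
fifo_snapshot <- function(fifo) {
  stopifnot(inherits(fifo, "wo_fifo"))
  if (fifo$filled < fifo$size) {
    stop(sprintf("FIFO underfilled: %d of %d samples", fifo$filled, fifo$size),
         call. = FALSE)
  }
  out <- fifo$buf
  colnames(out) <- colnames(out) %||% EEG_CHANNELS[seq_len(ncol(out))]
  out
}

#' Cortical features for every stride of a session
#'
#' At each stride onset (LG contraction), takes the 256-sample EEG window
#' ending at the onset sample and extracts the 21 movement-related-potential
#' features. Strides whose onset precedes sample 256 are returned as `NA`
#' (underfilled buffer).
#'
#' @param eeg Numeric sample matrix (samples x 7 channels, volts).
#' @param onsets Integer vector of stride onset sample indices.
#' @param ... Passed to [extract_mrp()].
#' @return Matrix with one row per onset and 21 feature columns.
#' @export
session_mrp_features <- function(eeg, onsets, ...) {
  stopifnot(is.matrix(eeg))
  colnames(eeg) <- colnames(eeg) %||% EEG_CHANNELS[seq_len(ncol(eeg))]
  out <- matrix(NA_real_, nrow = length(onsets), ncol = 3L * ncol(eeg))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    if (is.na(on) || on < MRP_WINDOW || on > nrow(eeg)) next
    f <- extract_mrp(eeg[(on - MRP_WINDOW + 1L):on, , drop = FALSE], ...)
    if (i == 1L || is.null(colnames(out))) colnames(out) <- names(f)
    out[i, ] <- f
  }
  if (is.null(colnames(out))) {
    colnames(out) <- as.vector(t(outer(tolower(colnames(eeg)), names(MRP_BANDS),
                                       function(ch, b) paste0(b, "_", ch, "_dbu"))))
  }
  out
}
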