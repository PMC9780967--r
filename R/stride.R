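# Gait-cycle segmentation and per-stride muscular indexes.

#' Segment gait cycles from the lateral Gastrocnemius trigger
#'
#' A stride (gait cycle) spans two consecutive LG contraction onsets of the
#' same leg (the foot-strike event at initial simple support). Intervals are
#' half-open on the sample grid; incomplete leading/trailing cycles are
#' discarded.
#'
#' @param lg_trigger A debounced [trigger_train()] of the LG channel.
#' @return A data.frame with columns `start`, `end` (half-open, 1-based
#'   sample indices) and `stride_samp = end - start`; zero rows (with a
#'   warning) when fewer than two onsets are present.
#' @export
segment_strides <- function(lg_trigger) {
  e <- trigger_edges(lg_trigger)
  on <- e$onsets
  if (length(on) < 2L) {
    warning("fewer than 2 LG onsets: no complete stride", call. = FALSE)
    return(data.frame(start = integer(0), end = integer(0),
                      stride_samp = integer(0)))
  }
  data.frame(start = on[-length(on)], end = on[-1L],
             stride_samp = diff(on))
}

#' Per-stride muscular indexes from the four muscle triggers of one leg
#'
#' For each stride, counts contracted samples of every muscle within the
#' stride interval: contraction time (2 ms per sample), relaxation time (the
#' complement), duty cycle (contraction / stride time x 100) and the
#' co-contraction times of the two agonist/antagonist pairs (LG-TA, RF-BF;
#' samples where both triggers are 1). Contraction times are totals over all
#' bursts intersecting the stride; a burst straddling a boundary contributes
#' its in-stride samples to each stride, so contraction + relaxation equals
#' the stride duration exactly.
#'
#' @param strides Stride intervals from [segment_strides()].
#' @param triggers Named list of [trigger_train()]s for muscles
#'   `LG`, `TA`, `BF`, `RF`, on a common sample grid.
#' @param fs_hz Sampling rate (must be 500).
#' @return A data.frame with one row per stride: `stride_time_ms`,
#'   co-contractions, duty cycles, per-muscle contraction/relaxation times and
#'   a `valid` flag (strides extending past the trigger length are invalid).
#' @export
compute_indexes <- function(strides, triggers, fs_hz = 500) {
  stopifnot(all(MUSCLES %in% names(triggers)))
  lens <- vapply(triggers[MUSCLES], length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("triggers must share the sample grid (equal lengths)", call. = FALSE)
  }
  n <- lens[[1L]]
  ms <- 1000 / fs_hz
  valid <- strides$end <= n + 1L & strides$start >= 1L
  count_in <- function(v) {
    cs <- c(0, cumsum(as.numeric(v)))
    out <- rep(NA_real_, nrow(strides))
    out[valid] <- cs[strides$end[valid]] - cs[strides$start[valid]]
    out
  }
  contr <- lapply(triggers[MUSCLES], function(tr) count_in(unclass(tr)))
  pair_count <- function(a, b) {
    count_in(unclass(triggers[[a]]) & unclass(triggers[[b]]))
  }
  L <- strides$end - strides$start
  out <- data.frame(
    stride_time_ms = L * ms,
    cocon_lg_ta_ms = pair_count("LG", "TA") * ms,
    cocon_rf_bf_ms = pair_count("RF", "BF") * ms,
    dc_lg_pct = 100 * contr$LG / L,
    dc_ta_pct = 100 * contr$TA / L,
    dc_rf_pct = 100 * contr$RF / L,
    dc_bf_pct = 100 * contr$BF / L,
    valid = valid)
  for (m in MUSCLES) {
    out[[paste0("contraction_", tolower(m), "_ms")]] <- contr[[m]] * ms
    out[[paste0("relaxation_", tolower(m), "_ms")]] <- (L - contr[[m]]) * ms
  }
  out
}

#' Pool per-leg stride tables into one observation table
#'
#' Left- and right-leg stride vectors are concatenated into a single table;
#' the leg is kept as metadata only (co-contraction and the other indexes are
#' analysed jointly over both limbs, disregarding possible unilateral
#' involvement).
#'
#' @param ... Per-leg data.frames (or a single list of them); a `leg` column
#'   is added from the argument names `L`/`R` when absent.
#' @return The row-bound data.frame.
#' @export
pool_legs <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  tabs <- tabs[vapply(tabs, function(t) !is.null(t) && nrow(t) > 0L, logical(1))]
  if (!length(tabs)) return(NULL)
  nm <- names(tabs)
  tabs <- lapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]
    if (is.null(t$leg) && !is.null(nm) && nzchar(nm[i])) t$leg <- nm[i]
    t
  })
  do.call(rbind, tabs)
}

#' Extract the per-stride muscular feature table of a whole session
#'
#' Runs the detection pipeline on a session's eight sEMG channels: binarizes
#' every channel, segments strides per leg from the LG triggers, computes the
#' per-stride indexes and pools both legs.
#'
#' @param rec A `wo_session` (or any list with an `emg` sample matrix whose
#'   columns follow the `R_LG ... L_RF` layout).
#' @param cfg A [trigger_config()].
#' @param drop_curve_steps Drop strides flagged as curve steps in the ground
#'   truth, when present (matching by stride order per leg).
#' @return A pooled feature data.frame with metadata columns
#'   (`subject_id`, `condition`, `leg`) and one row per complete stride, plus
#'   an attribute `"triggers"` holding the eight trigger trains.
#' @export
session_features <- function(rec, cfg = trigger_config(),
                             drop_curve_steps = TRUE) {
  stopifnot(!is.null(rec$emg))
  triggers <- lapply(colnames(rec$emg), function(ch)
    binarize(rec$emg[, ch], cfg = cfg, muscle_label = ch))
  names(triggers) <- colnames(rec$emg)
  per_leg <- list()
  for (leg in c("R", "L")) {
    trg <- setNames(triggers[paste(leg, MUSCLES, sep = "_")], MUSCLES)
    strides <- segment_strides(trg$LG)
    if (nrow(strides) == 0L) next
    tab <- compute_indexes(strides, trg)
    tab$leg <- leg
    tab$stride_idx <- seq_len(nrow(tab))
    tab$onset_samp <- strides$start
    if (drop_curve_steps && !is.null(rec$truth)) {
      flags <- rec$truth$strides[rec$truth$strides$leg == leg, "curve_step"]
      k <- seq_len(min(nrow(tab), length(flags)))
      tab <- tab[!(seq_len(nrow(tab)) %in% k[flags[k]]), , drop = FALSE]
    }
    per_leg[[leg]] <- tab
  }
  out <- pool_legs(per_leg)
  if (is.null(out)) {
    out <- data.frame()
  } else {
    out$subject_id <- rec$subject_id %||% NA_character_
    out$condition <- rec$condition %||% NA_character_
    out <- out[out$valid, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "triggers") <- triggers
  out
}
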