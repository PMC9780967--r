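# Muscle trigger generation: raw sEMG channel -> 1-bit contraction trigger.

#' Configuration of the sEMG binarizer
#'
#' @param k_on,k_off ON/OFF thresholds in baseline SDs above the baseline
#'   envelope mean (double threshold with hysteresis; defaults 3 and 1.5).
#' @param rms_win_ms Trailing moving-RMS envelope window (ms).
#' @param baseline_win_ms Span of the sliding baseline buffer, restricted to
#'   relaxed samples (ms).
#' @param debounce_ms Minimum duration of a contraction or relaxation segment;
#'   shorter excursions are suppressed (ms).
#' @param init_ms Initial period assumed relaxed, used to seed the baseline
#'   statistics (ms); a documented limitation of the causal design.
#' @param refine Apply the model-based edge-timing refinement (see
#'   [binarize()]); `FALSE` returns the raw double-threshold trigger whose
#'   edges lag the true activation boundaries by the envelope dynamics.
#' @param ramp_ms Assumed linear activation rise/fall time used by the
#'   refinement's shape correction (ms).
#' @return A list of class `wo_trigger_config`.
#' @export
trigger_config <- function(k_on = 3, k_off = 1.5, rms_win_ms = 50,
                           baseline_win_ms = 2000, debounce_ms = 30,
                           init_ms = 500, refine = TRUE, ramp_ms = 20) {
  stopifnot(k_on >= k_off, k_off >= 0, rms_win_ms > 0, debounce_ms >= 0)
  structure(list(k_on = k_on, k_off = k_off, rms_win_ms = rms_win_ms,
                 baseline_win_ms = baseline_win_ms, debounce_ms = debounce_ms,
                 init_ms = init_ms, refine = isTRUE(refine), ramp_ms = ramp_ms),
            class = "wo_trigger_config")
}

#' Construct a binary trigger train
#'
#' @param values Vector of 0/1 values, one per input sample.
#' @param muscle_label Channel label (e.g. `"R_LG"`).
#' @param fs_hz Sampling rate (Hz).
#' @return An integer vector of class `wo_trigger` with attributes
#'   `muscle_label` and `fs_hz`.
#' @export
trigger_train <- function(values, muscle_label = "", fs_hz = 500) {
  v <- as.integer(values)
  if (length(v) == 0L) stop("trigger train must be non-empty", call. = FALSE)
  if (anyNA(v) || any(v != 0L & v != 1L)) {
    stop("trigger values must be 0 or 1", call. = FALSE)
  }
  structure(v, muscle_label = muscle_label, fs_hz = fs_hz, class = "wo_trigger")
}

#' @export
print.wo_trigger <- function(x, ...) {
  e <- trigger_edges(x)
  cat(sprintf("<wo_trigger> %s: %d samples @ %d Hz, %d bursts (duty %.1f%%)\n",
              attr(x, "muscle_label"), length(x), attr(x, "fs_hz"),
              length(e$onsets), 100 * mean(unclass(x))))
  invisible(x)
}

#' Convert a raw sEMG channel into a 1-bit muscle trigger
#'
#' Implements dynamic-threshold onset/offset detection: full-wave
#' rectification, a trailing moving-RMS envelope, and a double threshold with
#' hysteresis whose baseline mean/SD are tracked over a sliding window
#' restricted to relaxed samples. Detection is causal; committed state changes
#' are backdated over the debounce run.
#'
#' Because the trailing envelope and the asymmetric hysteresis delay the raw
#' threshold crossings (the relaxation edge by most of the envelope window),
#' a refinement stage then re-times each edge: around every provisional edge
#' it estimates the half-activation time by the area (centroid) of the
#' normalized rectified amplitude between the local baseline and the burst
#' plateau, with an analytic shape correction for the rectified-Gaussian
#' amplitude profile computed from the measured burst-to-baseline ratio. The
#' area estimator is linear in the samples, hence unbiased against additive
#' envelope noise and robust to momentary dips below any fixed threshold.
#'
#' @param channel Numeric vector, one raw sEMG sample per 2 ms tick.
#' @param cfg A [trigger_config()].
#' @param muscle_label Label carried into the result.
#' @param fs_hz Sampling rate; must be 500.
#' @return A [trigger_train()] of the same length as `channel`.
#' @examples
#' x <- c(rnorm(500), 10 * rnorm(250), rnorm(500))
#' trig <- binarize(x, trigger_config(refine = FALSE))
#' mean(unclass(trig))
#' @export
binarize <- function(channel, cfg = trigger_config(), muscle_label = "",
                     fs_hz = 500) {
  if (length(channel) == 0L) stop("empty input channel", call. = FALSE)
  if (!is.numeric(channel) || !all(is.finite(channel))) {
    stop("input channel must be finite numeric (no NA/NaN)", call. = FALSE)
  }
  if (fs_hz != 500) stop("binarize expects fs = 500 Hz", call. = FALSE)
  ms2n <- function(ms) max(1L, as.integer(round(ms * fs_hz / 1000)))
  rms_n <- ms2n(cfg$rms_win_ms)
  deb_n <- ms2n(cfg$debounce_ms)
  env <- sqrt(moving_mean_trailing(channel^2, rms_n))
  trig <- wo_coarse_trigger(env, abs(channel), init_n = ms2n(cfg$init_ms),
                            base_n = ms2n(cfg$baseline_win_ms),
                            k_on = cfg$k_on, k_off = cfg$k_off,
                            debounce_n = deb_n)
  if (cfg$refine) {
    e <- edges_from_binary(trig)
    if (length(e$onsets)) {
      ref <- refine_edges(channel, e$onsets, e$offsets, cfg, fs_hz)
      trig <- edges_to_trigger(ref$onsets, ref$offsets, length(channel),
                               truncated_start = e$truncated_start,
                               truncated_end = e$truncated_end,
                               lead_end = e$lead_end, tail_start = e$tail_start)
      trig <- unclass(trig)
    }
  }
  trig <- debounce_binary(trig, deb_n)
  trigger_train(trig, muscle_label = muscle_label, fs_hz = fs_hz)
}

# close short relaxation gaps, then suppress short contraction segments;
# boundary (possibly truncated) runs are left untouched
debounce_binary <- function(v, min_n) {
  v <- as.integer(v)
  if (min_n <= 1L || length(v) == 0L) return(v)
  for (target in c(0L, 1L)) {
    r <- rle(v)
    k <- length(r$values)
    if (k > 2L) {
      short <- r$values == target & r$lengths < min_n
      short[c(1L, k)] <- FALSE
      r$values[short] <- 1L - target
      v <- inverse.rle(r)
    }
  }
  v
}

# Edge re-timing by the area method. Everything vectorized over bursts via
# cumulative sums of |x|.
refine_edges <- function(x, on, off, cfg, fs_hz) {
  n <- length(x)
  ax <- abs(x)
  cs <- c(0, cumsum(ax))
  seg_mean <- function(a, b) {
    bad <- b < a
    out <- (cs[pmin(b, n) + 1L] - cs[pmax(a, 1L)]) / pmax(b - a + 1L, 1L)
    out[bad] <- NA_real_
    out
  }
  # global baseline |x| mean, excluding a margin around every burst
  lo <- pmax(on - 30L, 1L)
  hi <- pmin(off + 29L, n)
  occ <- cumsum(tabulate(lo, nbins = n) - tabulate(hi + 1L, nbins = n))
  base_idx <- occ == 0L
  m_a <- if (any(base_idx)) mean(ax[base_idx]) else min(seg_mean(on, off)) / 10

  nb <- length(on)
  prev_off <- c(1L, off[-nb])
  next_on <- c(on[-1L], n)
  # plateau amplitude per burst (central region, clear of both edges; the
  # coarse offset overshoots the true one by up to the RMS window)
  rms_n <- max(1L, as.integer(round(cfg$rms_win_ms * fs_hz / 1000)))
  pl_a <- on + 8L
  pl_b <- pmax(off - rms_n - 5L, on + 12L)
  m_b <- seg_mean(pl_a, pmin(pl_b, n))
  usable <- !is.na(m_b) & m_b > 1.5 * m_a & (off - on) > 20L
  rho <- pmax(m_b / m_a, 1.6)

  # shape correction: sum over the ramp of (rectified-Gaussian profile -
  # linear ramp), for a linear amplitude ramp of ramp_n samples
  ramp_n <- max(2L, as.integer(round(cfg$ramp_ms * fs_hz / 1000)))
  g <- (seq_len(ramp_n) - 0.5) / ramp_n
  delta <- vapply(rho, function(r) {
    if (!is.finite(r)) return(0)
    u <- (sqrt(1 + (r^2 - 1) * g^2) - 1) / (r - 1)
    sum(u - g)
  }, numeric(1))

  # onset window: must bracket the (earlier) true edge and stay inside burst
  a1 <- pmax(on - 35L, prev_off + 8L, 1L)
  b1 <- pmin(on + 18L, off - 5L, n)
  S1 <- (cs[b1 + 1L] - cs[a1]) - (b1 - a1 + 1L) * m_a
  S1 <- S1 / (m_b - m_a)
  on_hat <- b1 + 1 - S1 + delta
  # offset window: coarse offset lags the true one; open the window backwards
  a2 <- pmax(off - 2L * rms_n - 10L, on + 8L, 1L)
  b2 <- pmin(off + 10L, next_on - 8L, n)
  S2 <- (cs[b2 + 1L] - cs[a2]) - (b2 - a2 + 1L) * m_a
  S2 <- S2 / (m_b - m_a)
  off_hat <- a2 + S2 - delta

  on_new <- as.integer(round(pmin(pmax(on_hat, a1), b1)))
  off_new <- as.integer(round(pmin(pmax(off_hat, a2), b2)))
  bad <- !usable | !is.finite(on_hat) | !is.finite(off_hat) | off_new <= on_new
  on_new[bad] <- on[bad]
  off_new[bad] <- off[bad]
  # keep bursts ordered and disjoint
  if (nb > 1L) {
    for (i in 2:nb) {
      if (on_new[i] <= off_new[i - 1L]) on_new[i] <- off_new[i - 1L] + 1L
    }
  }
  list(onsets = on_new, offsets = off_new)
}

edges_from_binary <- function(v) {
  v <- as.integer(v)
  n <- length(v)
  d <- diff(c(0L, v, 0L))
  ons <- which(d == 1L)    # first contracted sample of each run
  offs <- which(d == -1L)  # first relaxed sample after each run (may be n + 1)
  truncated_start <- length(ons) > 0L && ons[1L] == 1L
  truncated_end <- length(offs) > 0L && offs[length(offs)] == n + 1L
  keep <- rep(TRUE, length(ons))
  lead_end <- NULL
  tail_start <- NULL
  if (truncated_start) {
    keep[1L] <- FALSE
    lead_end <- offs[1L]
  }
  if (truncated_end) {
    keep[length(keep)] <- FALSE
    tail_start <- ons[length(ons)]
  }
  list(onsets = ons[keep], offsets = offs[keep],
       truncated_start = truncated_start, truncated_end = truncated_end,
       lead_end = lead_end, tail_start = tail_start)
}

#' Onset and offset sample indices of a trigger train
#'
#' Onsets are 0-to-1 transitions (index of the first contracted sample);
#' offsets are 1-to-0 transitions (index of the first relaxed sample after a
#' contraction), so each burst occupies the half-open interval
#' `[onset, offset)`. A train that starts or ends mid-contraction yields a
#' truncation flag instead of a phantom edge; truncated runs are excluded
#' from the onset/offset lists.
#'
#' @param trig A [trigger_train()] (or plain 0/1 vector).
#' @return `list(onsets, offsets, truncated_start, truncated_end)` with
#'   `onsets` and `offsets` of equal length, alternating and increasing.
#' @examples
#' trigger_edges(trigger_train(c(0, 0, 1, 1, 0)))  # onset 3, offset 5
#' @export
trigger_edges <- function(trig) {
  v <- if (inherits(trig, "wo_trigger")) unclass(trig) else as.integer(trig)
  if (anyNA(v) || any(v != 0L & v != 1L)) {
    stop("trigger values must be 0 or 1", call. = FALSE)
  }
  edges_from_binary(v)
}

#' Expand onset/offset edges back into a 0/1 trigger train
#'
#' Inverse of [trigger_edges()]: marks each `[onset, offset)` interval with 1
#' and restores boundary-truncated runs from their recorded extents.
#'
#' @param onsets,offsets Equal-length increasing integer vectors.
#' @param n Total length of the output train.
#' @param truncated_start,truncated_end Truncation flags as returned by
#'   [trigger_edges()].
#' @param lead_end,tail_start Extents of the truncated boundary runs (first
#'   relaxed sample after the leading run; first contracted sample of the
#'   trailing run).
#' @return A [trigger_train()].
#' @export
edges_to_trigger <- function(onsets, offsets, n, truncated_start = FALSE,
                             truncated_end = FALSE, lead_end = NULL,
                             tail_start = NULL) {
  stopifnot(length(onsets) == length(offsets))
  v <- integer(n)
  if (length(onsets)) {
    stopifnot(all(offsets > onsets))
    idx <- sequence(offsets - onsets, from = onsets)
    v[idx] <- 1L
  }
  if (truncated_start) {
    end <- min((lead_end %||% (n + 1L)) - 1L, n)
    if (end >= 1L) v[1:end] <- 1L
  }
  if (truncated_end) {
    start <- max(tail_start %||% n, 1L)
    v[start:n] <- 1L
  }
  trigger_train(v, fs_hz = 500)
}

#' @rdname edges_to_trigger
#' @param edges An edge list as returned by [trigger_edges()].
#' @export
expand_edges <- function(edges, n) {
  edges_to_trigger(edges$onsets, edges$offsets, n,
                   truncated_start = isTRUE(edges$truncated_start),
                   truncated_end = isTRUE(edges$truncated_end),
                   lead_end = edges$lead_end, tail_start = edges$tail_start)
}
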