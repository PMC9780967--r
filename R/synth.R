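# Synthetic walking-session generator.
#
# Stride-level truth is drawn first (stride times, per-muscle activation
# windows, co-contractions), then optionally rendered into raw sEMG/EEG
# signals. All durations live on the 2 ms sample grid (500 Hz).

.wo_cache <- new.env(parent = emptyenv())

FS_HZ <- 500
RAMP_SAMP <- 10L      # 20 ms trapezoid ramp, half before / half after the mask edge
SESSION_PAD <- 300L   # relaxed samples before the first and after the last stride

# The co-contraction draw is capped at min(contraction A, contraction B);
# capping would otherwise bias the realized mean below the configured one
# (noticeably so for RF-BF, whose configured SD exceeds the slack to the BF
# contraction time). Solve for the pre-cap mean such that the capped draw has
# the configured mean in expectation. Monte-Carlo with a fixed internal seed,
# memoised on the numeric inputs.
calibrate_cocon_mean <- function(target_ms, sd_ms, stride_mean, stride_sd,
                                 dcA_mean, dcA_sd, dcB_mean, dcB_sd,
                                 comonotone_with_B, nsim = 100000L) {
  key <- paste(signif(c(target_ms, sd_ms, stride_mean, stride_sd,
                        dcA_mean, dcA_sd, dcB_mean, dcB_sd,
                        as.numeric(comonotone_with_B)), 10), collapse = "|")
  hit <- .wo_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (sd_ms == 0) {
    .wo_cache[[key]] <- target_ms
    return(target_ms)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(999983L)
  L <- rnorm(nsim, stride_mean, stride_sd)
  zA <- rnorm(nsim)
  zB <- rnorm(nsim)
  dA <- (dcA_mean + dcA_sd * zA) / 100 * L
  dB <- (dcB_mean + dcB_sd * zB) / 100 * L
  cap <- pmax(pmin(dA, dB), 0)
  zc <- if (comonotone_with_B) zB else rnorm(nsim)
  f <- function(m) mean(pmin(pmax(m + sd_ms * zc, 0), cap)) - target_ms
  upper <- target_ms + 6 * sd_ms
  if (f(upper) < 0) {
    # target unreachable even with a generous shift; keep the raw mean
    .wo_cache[[key]] <- target_ms
    return(target_ms)
  }
  m <- uniroot(f, lower = target_ms - 6 * sd_ms, upper = upper, tol = 1e-3)$root
  .wo_cache[[key]] <- m
  m
}

apply_subject_shift <- function(params, shift) {
  if (is.null(shift)) return(params)
  f_t <- shift[["stride"]]
  params$stride_time_mean_ms <- params$stride_time_mean_ms * f_t
  # co-contractions are durations: they carry both the subject's temporal
  # scale and the pair's activation-width factor, keeping them consistent
  # with the contraction times that bound them
  params$cocon_lg_ta_mean_ms <- params$cocon_lg_ta_mean_ms * f_t * shift[["pair_lgta"]]
  params$cocon_rf_bf_mean_ms <- params$cocon_rf_bf_mean_ms * f_t * shift[["pair_rfbf"]]
  dc <- params$dc_mean_pct *
    c(LG = shift[["pair_lgta"]], TA = shift[["pair_lgta"]],
      BF = shift[["pair_rfbf"]], RF = shift[["pair_rfbf"]])[MUSCLES]
  params$dc_mean_pct <- pmin(pmax(dc, 0.5), 99.5)
  params
}

#' Draw between-subject random-effect multipliers
#'
#' Three multiplicative factors per subject, shared by the Pre and Post
#' sessions of that subject (the subject's gait idiosyncrasy does not change
#' with the medication cycle): a temporal scale (`stride`, applied to stride
#' time and, jointly with the pair factors, to the co-contraction durations)
#' and one activation-width factor per antagonist pair (`pair_lgta`,
#' `pair_rfbf`, applied to the pair's duty cycles and co-contraction). Tying
#' each co-contraction to its pair's width keeps every subject's
#' co-contraction mean compatible with the contraction times that bound it.
#'
#' @param subject_id Subject identifier (enters the derived seed).
#' @param seed Master seed.
#' @param sd SD of each multiplier around 1 (default 0.03).
#' @return Named numeric vector of multipliers.
#' @export
subject_effects <- function(subject_id, seed, sd = 0.03) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, paste0("subject-", subject_id)))
  f <- pmax(rnorm(3, 1, sd), 0.2)
  names(f) <- c("stride", "pair_lgta", "pair_rfbf")
  f
}

# Stride-level ground truth for one leg. All positions in samples; muscle
# windows are offsets relative to the stride onset, half-open [s, e).
simulate_leg_truth <- function(params, n_strides, seed, leg, onset0) {
  set.seed(derive_seed(seed, paste("truth", params$condition, leg, sep = "-")))
  n <- n_strides
  ms2samp <- function(ms) ms / 2
  L <- pmax(150L, as.integer(round(rnorm(n, ms2samp(params$stride_time_mean_ms),
                                         ms2samp(params$stride_time_sd_ms)))))
  dc <- sapply(MUSCLES, function(m)
    pmin(pmax(rnorm(n, params$dc_mean_pct[[m]], params$dc_sd_pct[[m]]), 0.5), 99.5))
  z_bf <- (dc[, "BF"] - params$dc_mean_pct[["BF"]]) /
    max(params$dc_sd_pct[["BF"]], 1e-9)
  d <- sapply(MUSCLES, function(m) {
    v <- as.integer(round(dc[, m] / 100 * L))
    pmin(pmax(v, 1L), L - 1L)
  })

  c1_mean <- calibrate_cocon_mean(params$cocon_lg_ta_mean_ms, params$cocon_lg_ta_sd_ms,
                                  params$stride_time_mean_ms, params$stride_time_sd_ms,
                                  params$dc_mean_pct[["LG"]], params$dc_sd_pct[["LG"]],
                                  params$dc_mean_pct[["TA"]], params$dc_sd_pct[["TA"]],
                                  comonotone_with_B = FALSE)
  c2_mean <- calibrate_cocon_mean(params$cocon_rf_bf_mean_ms, params$cocon_rf_bf_sd_ms,
                                  params$stride_time_mean_ms, params$stride_time_sd_ms,
                                  params$dc_mean_pct[["RF"]], params$dc_sd_pct[["RF"]],
                                  params$dc_mean_pct[["BF"]], params$dc_sd_pct[["BF"]],
                                  comonotone_with_B = TRUE)
  c1 <- as.integer(round(ms2samp(rnorm(n, c1_mean, params$cocon_lg_ta_sd_ms))))
  c1 <- pmin(pmax(c1, 0L), pmin(d[, "LG"], d[, "TA"]))
  c2 <- as.integer(round(ms2samp(c2_mean + params$cocon_rf_bf_sd_ms * z_bf)))
  c2 <- pmin(pmax(c2, 0L), pmin(d[, "RF"], d[, "BF"]))

  # phase template: LG fires at foot strike; TA spans late stance into swing,
  # overlapping the LG burst tail; RF runs up to the next foot strike; BF sits
  # at the stance transition, its tail overlapping the RF head.
  lg_s <- rep(0L, n); lg_e <- d[, "LG"]
  ta_s <- lg_e - c1; ta_e <- ta_s + d[, "TA"]
  over <- ta_e > L
  ta_s[over] <- L[over] - d[over, "TA"]; ta_e[over] <- L[over]
  rf_s <- L - d[, "RF"]; rf_e <- L
  bf_e <- rf_s + c2; bf_s <- bf_e - d[, "BF"]
  neg <- bf_s < 0L
  bf_s[neg] <- 0L; bf_e[neg] <- d[neg, "BF"]
  over <- bf_e > L
  bf_s[over] <- L[over] - d[over, "BF"]; bf_e[over] <- L[over]

  overlap <- function(a1, a2, b1, b2) pmax(0L, pmin(a2, b2) - pmax(a1, b1))
  onset <- onset0 + cumsum(c(0L, L[-n]))
  data.frame(leg = leg, stride_idx = seq_len(n),
             onset_samp = as.integer(onset), stride_samp = L,
             lg_s = lg_s, lg_e = lg_e, ta_s = as.integer(ta_s), ta_e = as.integer(ta_e),
             bf_s = as.integer(bf_s), bf_e = as.integer(bf_e),
             rf_s = as.integer(rf_s), rf_e = as.integer(rf_e),
             cocon_lgta_samp = overlap(lg_s, lg_e, ta_s, ta_e),
             cocon_rfbf_samp = overlap(rf_s, rf_e, bf_s, bf_e),
             stringsAsFactors = FALSE)
}

# Cortical ground truth: per stride, channel and band, a burst magnitude in
# dB re 1 uV. Drawn from a stream seeded WITHOUT the condition label, so that
# matched seeds give identical Pre/Post cortical populations by construction.
cortical_truth_draws <- function(params, n_strides, seed, leg) {
  set.seed(derive_seed(seed, paste("eeg", leg, sep = "-")))
  base <- as.vector(t(params$eeg_base_dbu))  # ch-major blocks of 3 bands -> 21
  z <- matrix(rnorm(n_strides * 21L), nrow = n_strides)
  phases <- matrix(runif(n_strides * 21L, 0, 2 * pi), nrow = n_strides)
  dbu <- sweep(z * params$eeg_jitter_db, 2L, base, `+`)
  colnames(dbu) <- as.vector(t(outer(tolower(EEG_CHANNELS), names(MRP_BANDS),
                                     function(ch, b) paste0(b, "_", ch, "_dbu"))))
  list(dbu = dbu, phases = phases)
}

band_limited_noise <- function(n, low_hz = 20, high_hz = 200, fs = FS_HZ) {
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  x / max(sd(x), 1e-12)
}

# Trapezoidal activation envelope: ground-truth mask = half-maximum support,
# so each 20 ms ramp extends RAMP_SAMP/2 samples beyond the mask edge and the
# continuous half-crossing sits at (edge - 0.5) samples.
add_burst_envelope <- function(env, on, off, total) {
  half <- RAMP_SAMP %/% 2L
  up <- seq.int(on - half, on + half - 1L)
  keep <- up >= 1L & up <= total
  env[up[keep]] <- pmax(env[up[keep]], (seq_len(RAMP_SAMP)[keep] - 0.5) / RAMP_SAMP)
  dn <- seq.int(off - half, off + half - 1L)
  keep <- dn >= 1L & dn <= total
  env[dn[keep]] <- pmax(env[dn[keep]], (RAMP_SAMP - seq_len(RAMP_SAMP)[keep] + 0.5) / RAMP_SAMP)
  core <- seq.int(on + half, off - half - 1L)
  if (length(core) && core[1] <= core[length(core)]) {
    core <- core[core >= 1L & core <= total]
    env[core] <- 1
  }
  env
}

#' Simulate a synthetic walking session
#'
#' Generates one recording of bilateral lower-limb sEMG (8 channels) and,
#' optionally, EEG (7 channels) at 500 Hz, together with complete ground
#' truth: per-channel activation masks, per-leg stride onsets, realized
#' per-stride indexes and cortical burst magnitudes. Per-stride quantities are
#' drawn from the configured population distributions and the muscle windows
#' are placed by a fixed physiological phase template, calibrated so realized
#' duty cycles and co-contractions match the configured means in expectation.
#'
#' EMG channels are a band-limited (20-200 Hz) stochastic carrier,
#' amplitude-modulated by a trapezoidal activation envelope (20 ms ramps),
#' on top of baseline noise; `snr_db` is the carrier-to-baseline amplitude
#' ratio in dB. EEG is 1/f-like background with band-limited bursts
#' (2-5, 9-11, 12-30 Hz) time-locked to the pre-onset window of each stride;
#' the cortical draw stream does not depend on `condition`, so matched seeds
#' give identical Pre/Post cortical truth.
#'
#' @param params A [condition_params()] object.
#' @param n_strides Strides to generate per leg (>= 1).
#' @param seed Integer seed; same (params, n_strides, seed) gives a
#'   bit-identical session.
#' @param snr_db Burst-to-baseline amplitude ratio in dB (default 20).
#' @param subject_id,run_id Metadata labels.
#' @param subject_shift Optional multipliers from [subject_effects()].
#' @param render If `FALSE`, only ground truth is generated (no signals);
#'   useful for large stride-statistics simulations.
#' @param eeg If `FALSE`, the EEG branch is skipped entirely.
#' @param curve_steps_k Flag the first and last `k` strides of each leg as
#'   curve steps (excluded from analysis downstream).
#' @return A `wo_session` object: integer matrix `emg` (samples x 8), numeric
#'   matrix `eeg` (samples x 7, volts) or `NULL`, `fs_hz`, metadata, and a
#'   `truth` list (stride table, activation masks, cortical table).
#' @examples
#' s <- simulate_session(default_params("pre"), n_strides = 5, seed = 1)
#' realized_statistics(s)
#' @export
simulate_session <- function(params, n_strides, seed, snr_db = 20,
                             subject_id = "S1", run_id = "R1",
                             subject_shift = NULL, render = TRUE, eeg = TRUE,
                             curve_steps_k = 0L) {
  stopifnot(inherits(params, "wo_params"))
  stopifnot_scalar_number(n_strides, "n_strides", lower = 1)
  stopifnot_scalar_number(seed, "seed")
  p <- apply_subject_shift(params, subject_shift)

  truth_r <- simulate_leg_truth(p, n_strides, seed, "R", onset0 = SESSION_PAD + 1L)
  onset0_l <- SESSION_PAD + 1L + truth_r$stride_samp[1] %/% 2L
  truth_l <- simulate_leg_truth(p, n_strides, seed, "L", onset0 = onset0_l)
  strides <- rbind(truth_r, truth_l)
  k <- as.integer(curve_steps_k)
  strides$curve_step <- strides$stride_idx <= k | strides$stride_idx > n_strides - k

  total <- max(strides$onset_samp + strides$stride_samp) + SESSION_PAD

  # activation masks from the window table
  masks <- matrix(0L, nrow = total, ncol = 8L, dimnames = list(NULL, EMG_CHANNELS))
  win_cols <- list(LG = c("lg_s", "lg_e"), TA = c("ta_s", "ta_e"),
                   BF = c("bf_s", "bf_e"), RF = c("rf_s", "rf_e"))
  for (leg in c("R", "L")) {
    tl <- strides[strides$leg == leg, ]
    for (m in MUSCLES) {
      ch <- paste(leg, m, sep = "_")
      s <- tl$onset_samp + tl[[win_cols[[m]][1]]]
      e <- tl$onset_samp + tl[[win_cols[[m]][2]]]
      idx <- sequence(e - s, from = s)
      masks[idx, ch] <- 1L
    }
  }

  cort_r <- cortical_truth_draws(p, n_strides, seed, "R")
  cort_l <- cortical_truth_draws(p, n_strides, seed, "L")
  cortical <- data.frame(leg = strides$leg, stride_idx = strides$stride_idx,
                         onset_samp = strides$onset_samp)
  cortical <- cbind(cortical, rbind(cort_r$dbu, cort_l$dbu))
  # a pre-onset window is usable if the buffer is full and it does not
  # overlap the previous usable window (the legs are generated independently,
  # so their onset sequences can drift close together)
  ord <- order(cortical$onset_samp)
  usable <- logical(nrow(cortical))
  last_end <- -Inf
  for (j in ord) {
    on <- cortical$onset_samp[j]
    if (on >= 256L && (on - 255L) > last_end) {
      usable[j] <- TRUE
      last_end <- on
    }
  }
  cortical$window_usable <- usable
  cortical[!usable, cortical_features()] <- NA_real_

  emg_mat <- NULL
  eeg_mat <- NULL
  if (render) {
    set.seed(derive_seed(seed, paste("render", p$condition, sep = "-")))
    amp <- 10^(snr_db / 20)
    emg_mat <- matrix(0L, nrow = total, ncol = 8L,
                      dimnames = list(NULL, EMG_CHANNELS))
    for (leg in c("R", "L")) {
      tl <- strides[strides$leg == leg, ]
      for (m in MUSCLES) {
        ch <- paste(leg, m, sep = "_")
        env <- numeric(total)
        s <- tl$onset_samp + tl[[win_cols[[m]][1]]]
        e <- tl$onset_samp + tl[[win_cols[[m]][2]]]
        for (j in seq_along(s)) env <- add_burst_envelope(env, s[j], e[j], total)
        x <- amp * env * band_limited_noise(total) + band_limited_noise(total)
        emg_mat[, ch] <- as.integer(round(100 * x))
      }
    }
    if (eeg) {
      eeg_mat <- matrix(0, nrow = total, ncol = 7L,
                        dimnames = list(NULL, EEG_CHANNELS))
      sigma_bg <- 20e-6
      for (ch in seq_len(7L)) {
        bg <- as.numeric(stats::filter(rnorm(total), 0.97, method = "recursive"))
        eeg_mat[, ch] <- bg / sd(bg) * sigma_bg
      }
      eeg_mat <- overwrite_mrp_windows(eeg_mat, strides, list(R = cort_r, L = cort_l),
                                       p, seed, sigma_bg, cortical)
    }
  }

  structure(
    list(emg = emg_mat, eeg = if (eeg) eeg_mat else NULL,
         fs_hz = FS_HZ,
         channel_labels = list(emg = EMG_CHANNELS, eeg = if (eeg) EEG_CHANNELS else NULL),
         subject_id = subject_id, run_id = run_id,
         condition = params$condition, snr_db = snr_db, n_strides = n_strides,
         seed = seed,
         truth = list(strides = strides, masks = masks, cortical = cortical,
                      params = p)),
    class = "wo_session")
}

# Rewrite the 256-sample pre-onset window of each usable stride with content
# drawn from the condition-independent cortical stream: AR(1) background plus
# one Hann-windowed burst per band, centred 250 ms before the onset. Windows
# flagged unusable (underfilled buffer or collision with the other leg's
# window) are left as plain background.
overwrite_mrp_windows <- function(eeg_mat, strides, cort, params, seed,
                                  sigma_bg, cortical) {
  hann150 <- 0.5 - 0.5 * cos(2 * pi * seq(0, 149) / 149)
  f_band <- c(bp = 3.5, mu = 10, beta = 21)
  rows_burst <- 56:205
  tt <- seq(0, 149) / FS_HZ
  for (leg in c("R", "L")) {
    set.seed(derive_seed(seed, paste("eeg-window", leg, sep = "-")))
    tl <- strides[strides$leg == leg, ]
    usable <- cortical$window_usable[cortical$leg == leg]
    dbu <- cort[[leg]]$dbu
    phases <- cort[[leg]]$phases
    for (j in seq_len(nrow(tl))) {
      on <- tl$onset_samp[j]
      # draw in fixed order regardless of usability, to keep streams aligned
      bg <- matrix(rnorm(256L * 7L), nrow = 256L)
      if (!usable[j]) next
      win <- matrix(0, nrow = 256L, ncol = 7L)
      for (ch in seq_len(7L)) {
        b <- as.numeric(stats::filter(bg[, ch], 0.97, method = "recursive"))
        win[, ch] <- b / sd(b) * sigma_bg
        for (bi in seq_along(f_band)) {
          col21 <- (ch - 1L) * 3L + bi
          a <- 1e-6 * 10^(dbu[j, col21] / 20)
          win[rows_burst, ch] <- win[rows_burst, ch] +
            a * hann150 * sin(2 * pi * f_band[bi] * tt + phases[j, col21])
        }
      }
      eeg_mat[(on - 255L):on, ] <- win
    }
  }
  eeg_mat
}

#' @export
print.wo_session <- function(x, ...) {
  n <- if (is.null(x$emg)) max(x$truth$strides$onset_samp + x$truth$strides$stride_samp)
       else nrow(x$emg)
  cat(sprintf("<wo_session> %s / %s, condition %s: %d strides/leg, %s samples @ %d Hz%s\n",
              x$subject_id, x$run_id, x$condition, x$n_strides,
              format(n, big.mark = ","), x$fs_hz,
              if (is.null(x$emg)) " (truth only)" else ""))
  invisible(x)
}

#' Per-stride ground-truth feature table of a synthetic session
#'
#' Computes the seven muscular indexes of every stride directly from the
#' generator's window table (bypassing trigger detection), and appends the 21
#' cortical ground-truth features. One row per stride, both legs pooled.
#'
#' @param rec A `wo_session`.
#' @param drop_curve_steps Drop strides flagged as curve steps (default TRUE).
#' @return A data.frame with metadata columns (`subject_id`, `condition`,
#'   `leg`, `stride_idx`) and the feature columns of [muscular_features()] and
#'   [cortical_features()].
#' @export
truth_feature_table <- function(rec, drop_curve_steps = TRUE) {
  stopifnot(inherits(rec, "wo_session"))
  st <- rec$truth$strides
  if (drop_curve_steps) st <- st[!st$curve_step, ]
  L <- st$stride_samp
  out <- data.frame(
    subject_id = rec$subject_id, condition = rec$condition,
    leg = st$leg, stride_idx = st$stride_idx,
    stride_time_ms = 2 * L,
    cocon_lg_ta_ms = 2 * st$cocon_lgta_samp,
    cocon_rf_bf_ms = 2 * st$cocon_rfbf_samp,
    dc_lg_pct = 100 * (st$lg_e - st$lg_s) / L,
    dc_ta_pct = 100 * (st$ta_e - st$ta_s) / L,
    dc_rf_pct = 100 * (st$rf_e - st$rf_s) / L,
    dc_bf_pct = 100 * (st$bf_e - st$bf_s) / L,
    stringsAsFactors = FALSE)
  cc <- rec$truth$cortical
  key <- paste(st$leg, st$stride_idx)
  out <- cbind(out, cc[match(key, paste(cc$leg, cc$stride_idx)), cortical_features()])
  rownames(out) <- NULL
  out
}

#' Ground-truth summary statistics of a synthetic session
#'
#' Summarises each muscular index (mean/SD over strides) directly from the
#' ground-truth activation masks and stride onsets, bypassing the detection
#' pipeline. Used for generator self-validation.
#'
#' @param rec A `wo_session` carrying ground truth.
#' @param from_masks If `TRUE` (default), recompute stride indexes by counting
#'   mask samples (exercising the same counting arithmetic as the detection
#'   path); if `FALSE`, use the generator's window table.
#' @return A data.frame with columns `feature`, `mean`, `sd`, `n`.
#' @export
realized_statistics <- function(rec, from_masks = TRUE) {
  stopifnot(inherits(rec, "wo_session"))
  if (is.null(rec$truth)) stop("session carries no ground truth", call. = FALSE)
  tab <- if (from_masks) mask_feature_table(rec) else truth_feature_table(rec)
  feats <- muscular_features()
  data.frame(feature = feats,
             mean = vapply(feats, function(f) mean(tab[[f]]), numeric(1)),
             sd = vapply(feats, function(f) sd(tab[[f]]), numeric(1)),
             n = nrow(tab), row.names = NULL, stringsAsFactors = FALSE)
}

# stride indexes recomputed from the truth masks via the same counting code
# as the detection path (segment by truth onsets, count mask samples)
mask_feature_table <- function(rec) {
  st <- rec$truth$strides
  out <- NULL
  for (leg in c("R", "L")) {
    tl <- st[st$leg == leg, ]
    ivals <- data.frame(start = tl$onset_samp,
                        end = tl$onset_samp + tl$stride_samp)
    trig <- lapply(MUSCLES, function(m)
      trigger_train(rec$truth$masks[, paste(leg, m, sep = "_")],
                    muscle_label = paste(leg, m, sep = "_")))
    names(trig) <- MUSCLES
    tab <- compute_indexes(ivals, trig)
    tab$leg <- leg
    tab$stride_idx <- tl$stride_idx
    tab$curve_step <- tl$curve_step
    out <- rbind(out, tab)
  }
  out$subject_id <- rec$subject_id
  out$condition <- rec$condition
  out[!out$curve_step, ]
}

#' Simulate paired Pre/Post feature populations (truth level)
#'
#' Generates matched Pre- and Post-levodopa per-stride feature tables for a
#' set of subjects, at the ground-truth level (no signal rendering): subject
#' random effects are shared across conditions, and the cortical draws use
#' matched (condition-independent) seeds so the Pre and Post cortical
#' populations are identical by construction. Rows are ordered identically in
#' both tables, so the i-th rows form a pair.
#'
#' @param seed Master seed.
#' @param n_steps Total steps (pooled strides, both legs) per condition.
#' @param n_subjects Number of subjects; steps are split evenly.
#' @param params_pre,params_post Condition parameter sets.
#' @return `list(pre = , post = )` of feature data.frames.
#' @export
simulate_condition_pair <- function(seed, n_steps = 3600, n_subjects = 3,
                                    params_pre = default_params("pre"),
                                    params_post = default_params("post")) {
  steps_per_subject <- n_steps / n_subjects
  n_strides <- as.integer(round(steps_per_subject / 2))
  tabs <- list(pre = NULL, post = NULL)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%d", i)
    shift <- subject_effects(sid, seed, sd = params_pre$subject_sd_scale)
    sub_seed <- derive_seed(seed, sid)
    for (cond in c("pre", "post")) {
      par <- if (cond == "pre") params_pre else params_post
      rec <- simulate_session(par, n_strides = n_strides, seed = sub_seed,
                              subject_id = sid, subject_shift = shift,
                              render = FALSE)
      tabs[[cond]] <- rbind(tabs[[cond]], truth_feature_table(rec))
    }
  }
  tabs
}
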