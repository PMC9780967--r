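#' Condition parameters for the synthetic walking-session generator
#'
#' Bundles the per-condition stride-level population parameters that the
#' generator reproduces: stride-time mean/SD, per-muscle duty-cycle mean/SD,
#' the two agonist/antagonist co-contraction means/SDs, and the
#' between-subject random-effect scale.
#'
#' @param condition `"pre"` (before levodopa administration, OFF state) or
#'   `"post"` (after administration, ON state).
#' @param stride_time_mean_ms,stride_time_sd_ms Stride-time distribution (ms).
#' @param dc_mean_pct,dc_sd_pct Named numeric vectors over muscles
#'   `c("LG","TA","BF","RF")`, duty-cycle means/SDs in percent of stride time.
#' @param cocon_lg_ta_mean_ms,cocon_lg_ta_sd_ms LG-TA co-contraction (ms).
#' @param cocon_rf_bf_mean_ms,cocon_rf_bf_sd_ms RF-BF co-contraction (ms).
#' @param subject_sd_scale Between-subject multiplicative random effect on the
#'   population means (SD of the multiplier; default 0.03).
#' @param eeg_base_dbu 7 x 3 matrix (channels x bands bp/mu/beta) of baseline
#'   movement-related-potential magnitudes in dB re 1 uV; condition-independent
#'   by design.
#' @param eeg_jitter_db Per-stride lognormal amplitude jitter of the cortical
#'   bursts, expressed as an SD in dB.
#'
#' @return An object of class `wo_params` (a validated list).
#' @seealso [default_params()] for the built-in Pre/Post parameter sets.
#' @export
condition_params <- function(condition,
                             stride_time_mean_ms, stride_time_sd_ms,
                             dc_mean_pct, dc_sd_pct,
                             cocon_lg_ta_mean_ms, cocon_lg_ta_sd_ms,
                             cocon_rf_bf_mean_ms, cocon_rf_bf_sd_ms,
                             subject_sd_scale = 0.03,
                             eeg_base_dbu = default_eeg_base_dbu(),
                             eeg_jitter_db = 1) {
  condition <- match.arg(condition, c("pre", "post"))
  stopifnot_scalar_number(stride_time_mean_ms, "stride_time_mean_ms", lower = 1e-6)
  stopifnot_scalar_number(stride_time_sd_ms, "stride_time_sd_ms", lower = 0)
  stopifnot_scalar_number(cocon_lg_ta_mean_ms, "cocon_lg_ta_mean_ms", lower = 0)
  stopifnot_scalar_number(cocon_lg_ta_sd_ms, "cocon_lg_ta_sd_ms", lower = 0)
  stopifnot_scalar_number(cocon_rf_bf_mean_ms, "cocon_rf_bf_mean_ms", lower = 0)
  stopifnot_scalar_number(cocon_rf_bf_sd_ms, "cocon_rf_bf_sd_ms", lower = 0)
  stopifnot_scalar_number(subject_sd_scale, "subject_sd_scale", lower = 0)
  stopifnot_scalar_number(eeg_jitter_db, "eeg_jitter_db", lower = 0)
  dc_mean_pct <- dc_mean_pct[MUSCLES]
  dc_sd_pct <- dc_sd_pct[MUSCLES]
  if (anyNA(dc_mean_pct) || anyNA(dc_sd_pct)) {
    stop("dc_mean_pct and dc_sd_pct must be named over muscles LG, TA, BF, RF",
         call. = FALSE)
  }
  if (any(dc_mean_pct <= 0 | dc_mean_pct >= 100)) {
    stop("duty-cycle means must lie strictly inside (0, 100) percent", call. = FALSE)
  }
  if (any(dc_sd_pct < 0)) stop("duty-cycle SDs must be >= 0", call. = FALSE)
  stopifnot(is.matrix(eeg_base_dbu), nrow(eeg_base_dbu) == 7L, ncol(eeg_base_dbu) == 3L)
  structure(
    list(condition = condition,
         stride_time_mean_ms = stride_time_mean_ms,
         stride_time_sd_ms = stride_time_sd_ms,
         dc_mean_pct = dc_mean_pct,
         dc_sd_pct = dc_sd_pct,
         cocon_lg_ta_mean_ms = cocon_lg_ta_mean_ms,
         cocon_lg_ta_sd_ms = cocon_lg_ta_sd_ms,
         cocon_rf_bf_mean_ms = cocon_rf_bf_mean_ms,
         cocon_rf_bf_sd_ms = cocon_rf_bf_sd_ms,
         subject_sd_scale = subject_sd_scale,
         eeg_base_dbu = eeg_base_dbu,
         eeg_jitter_db = eeg_jitter_db),
    class = "wo_params")
}

# Condition-independent cortical burst magnitudes (dB re 1 uV), channels x
# {bp, mu, beta}. Values sit in the 37-63 dBu range typical of the
# movement-related potentials this generator emulates.
default_eeg_base_dbu <- function() {
  m <- rbind(
    T3 = c(60.49, 48.02, 40.00),
    C3 = c(61.51, 48.96, 42.51),
    Cz = c(62.50, 49.52, 37.49),
    C4 = c(59.50, 46.99, 40.97),
    T4 = c(61.97, 47.97, 40.50),
    P3 = c(63.02, 48.47, 43.98),
    P4 = c(63.02, 48.51, 44.03))
  m <- m[EEG_CHANNELS, ]
  colnames(m) <- names(MRP_BANDS)
  m
}

#' Built-in generator parameter sets for the Pre/Post levodopa conditions
#'
#' Returns the default stride-level population parameters for a walking
#' session recorded before (`"pre"`, OFF state) or after (`"post"`, ON state)
#' levodopa administration. The two conditions differ in stride time, both
#' co-contraction times and the LG/BF/RF duty cycles; the TA duty cycle is
#' essentially unchanged across conditions. Post-condition duty-cycle SDs are
#' not separately available and reuse the Pre values.
#'
#' Two published orderings of the TA and RF duty-cycle means exist for the
#' same cohort; `dc_source` selects between them (`"table"`, the default, or
#' `"text"`, which swaps TA and RF).
#'
#' @param condition `"pre"` or `"post"`.
#' @param dc_source `"table"` (default) or `"text"`; see Details.
#' @return A [condition_params()] object.
#' @examples
#' default_params("pre")$stride_time_mean_ms   # 1081.09
#' default_params("post")$cocon_rf_bf_mean_ms  # 228.02
#' @export
default_params <- function(condition = c("pre", "post"), dc_source = c("table", "text")) {
  condition <- match.arg(condition)
  dc_source <- match.arg(dc_source)
  dc_sd <- c(LG = 3.70, TA = 5.44, BF = 2.42, RF = 5.49)
  if (condition == "pre") {
    dc_mean <- c(LG = 24.78, TA = 63.48, BF = 23.31, RF = 56.29)
    p <- list(stride = c(1081.09, 72.01),
              lgta = c(113.74, 32.12),
              rfbf = c(232.51, 50.04))
  } else {
    dc_mean <- c(LG = 24.34, TA = 63.49, BF = 23.54, RF = 57.49)
    p <- list(stride = c(1044.64, 34.49),
              lgta = c(106.16, 29.19),
              rfbf = c(228.02, 17.00))
  }
  if (dc_source == "text") {
    dc_mean[c("TA", "RF")] <- dc_mean[c("RF", "TA")]
    dc_sd[c("TA", "RF")] <- dc_sd[c("RF", "TA")]
  }
  condition_params(condition,
                   stride_time_mean_ms = p$stride[1], stride_time_sd_ms = p$stride[2],
                   dc_mean_pct = dc_mean, dc_sd_pct = dc_sd,
                   cocon_lg_ta_mean_ms = p$lgta[1], cocon_lg_ta_sd_ms = p$lgta[2],
                   cocon_rf_bf_mean_ms = p$rfbf[1], cocon_rf_bf_sd_ms = p$rfbf[2])
}

#' @export
print.wo_params <- function(x, ...) {
  cat(sprintf("<wo_params> condition: %s\n", x$condition))
  cat(sprintf("  stride time: %.2f +/- %.2f ms\n",
              x$stride_time_mean_ms, x$stride_time_sd_ms))
  cat(sprintf("  co-contraction LG-TA: %.2f +/- %.2f ms, RF-BF: %.2f +/- %.2f ms\n",
              x$cocon_lg_ta_mean_ms, x$cocon_lg_ta_sd_ms,
              x$cocon_rf_bf_mean_ms, x$cocon_rf_bf_sd_ms))
  dc <- paste(sprintf("%s %.2f%%", names(x$dc_mean_pct), x$dc_mean_pct), collapse = ", ")
  cat("  duty cycles:", dc, "\n")
  invisible(x)
}
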