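test_that("built-in condition parameters carry the published population values", {
  pre <- default_params("pre")
  post <- default_params("post")
  expect_equal(pre$stride_time_mean_ms, 1081.09)
  expect_equal(post$stride_time_mean_ms, 1044.64)
  expect_equal(post$cocon_rf_bf_mean_ms, 228.02)
  expect_equal(pre$cocon_lg_ta_mean_ms, 113.74)
  # duty cycles are percentages: any pair sums strictly below 200
  expect_true(all(outer(pre$dc_mean_pct, pre$dc_mean_pct, `+`) < 200))
  expect_error(default_params("mid"))
  # the alternative published ordering swaps TA and RF
  alt <- default_params("pre", dc_source = "text")
  expect_equal(unname(alt$dc_mean_pct[["TA"]]), 56.29)
  expect_equal(unname(alt$dc_mean_pct[["RF"]]), 63.48)
})

test_that("same parameters and seed give a bit-identical session", {
  a <- simulate_session(default_params("post"), n_strides = 8, seed = 42)
  b <- simulate_session(default_params("post"), n_strides = 8, seed = 42)
  expect_identical(a$emg, b$emg)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$truth$strides, b$truth$strides)
  c <- simulate_session(default_params("post"), n_strides = 8, seed = 43)
  expect_false(identical(a$emg, c$emg))
})

test_that("all ground-truth durations sit on the 2 ms sample grid", {
  s <- fixture_session()
  tab <- truth_feature_table(s)
  expect_true(all(tab$stride_time_ms %% 2 == 0))
  expect_true(all(tab$cocon_lg_ta_ms %% 2 == 0))
  expect_true(all(tab$cocon_rf_bf_ms %% 2 == 0))
  st <- s$truth$strides
  expect_true(all(st$onset_samp == as.integer(st$onset_samp)))
  expect_true(all(diff(st$onset_samp[st$leg == "R"]) > 0))
})

test_that("zero stride-time SD collapses stride times to the quantized mean", {
  p <- condition_params("pre", stride_time_mean_ms = 1080, stride_time_sd_ms = 0,
                        dc_mean_pct = c(LG = 25, TA = 60, BF = 23, RF = 55),
                        dc_sd_pct = c(LG = 0, TA = 0, BF = 0, RF = 0),
                        cocon_lg_ta_mean_ms = 110, cocon_lg_ta_sd_ms = 0,
                        cocon_rf_bf_mean_ms = 200, cocon_rf_bf_sd_ms = 0)
  s <- simulate_session(p, n_strides = 10, seed = 5, render = FALSE)
  tab <- truth_feature_table(s)
  expect_true(all(tab$stride_time_ms == 1080))
  expect_true(all(tab$cocon_lg_ta_ms == 110 + (110 %% 2)))  # quantized to grid
  expect_equal(unique(round(tab$dc_lg_pct, 1)), 25)
})

test_that("realized ground-truth means calibrate to the configured means", {
  # 4 s / sqrt(n) band per configured mean, pooled over both legs
  s <- simulate_session(default_params("pre"), n_strides = 1500, seed = 202,
                        render = FALSE)
  rs <- realized_statistics(s, from_masks = FALSE)
  cfg <- c(stride_time_ms = 1081.09, cocon_lg_ta_ms = 113.74,
           cocon_rf_bf_ms = 232.51, dc_lg_pct = 24.78, dc_ta_pct = 63.48,
           dc_rf_pct = 56.29, dc_bf_pct = 23.31)
  sds <- c(72.01, 32.12, 50.04, 3.70, 5.44, 5.49, 2.42)
  n <- rs$n[1]
  dev <- abs(rs$mean - cfg[rs$feature])
  expect_true(all(dev <= 4 * sds / sqrt(n)),
              info = paste(rs$feature, round(dev, 3), collapse = "; "))
})

test_that("mask-based and window-table ground-truth summaries agree", {
  s <- fixture_session()
  a <- realized_statistics(s, from_masks = TRUE)
  b <- realized_statistics(s, from_masks = FALSE)
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$sd, b$sd, tolerance = 1e-12)
})

test_that("an always-active muscle saturates its duty cycle at 100%", {
  s <- simulate_session(default_params("pre"), n_strides = 5, seed = 9,
                        render = FALSE)
  s$truth$masks[] <- 1L
  rs <- realized_statistics(s, from_masks = TRUE)
  dc <- rs[grepl("^dc_", rs$feature), "mean"]
  expect_true(all(dc == 100))
  # and duty cycles are always bounded in [0, 100]
  rs2 <- realized_statistics(fixture_session())
  tab <- truth_feature_table(fixture_session())
  expect_true(all(tab[paste0("dc_", c("lg", "ta", "rf", "bf"), "_pct")] >= 0 &
                  tab[paste0("dc_", c("lg", "ta", "rf", "bf"), "_pct")] <= 100))
})

test_that("matched seeds give identical Pre/Post cortical truth", {
  pre <- simulate_session(default_params("pre"), n_strides = 12, seed = 7,
                          render = FALSE)
  post <- simulate_session(default_params("post"), n_strides = 12, seed = 7,
                           render = FALSE)
  expect_identical(pre$truth$cortical[cortical_features()],
                   post$truth$cortical[cortical_features()])
})

test_that("curve-step flags mark the first and last k strides per leg", {
  s <- simulate_session(default_params("pre"), n_strides = 10, seed = 3,
                        render = FALSE, curve_steps_k = 2)
  st <- s$truth$strides
  for (leg in c("R", "L")) {
    fl <- st$curve_step[st$leg == leg]
    expect_identical(which(fl), c(1L, 2L, 9L, 10L))
  }
  expect_equal(nrow(truth_feature_table(s)), 12)  # 6 kept strides x 2 legs
})

test_that("invalid generator inputs are rejected", {
  expect_error(simulate_session(default_params("pre"), n_strides = 0, seed = 1))
  expect_error(condition_params("pre", stride_time_mean_ms = 1000,
                                stride_time_sd_ms = -1,
                                dc_mean_pct = c(LG = 25, TA = 60, BF = 23, RF = 55),
                                dc_sd_pct = c(LG = 1, TA = 1, BF = 1, RF = 1),
                                cocon_lg_ta_mean_ms = 100, cocon_lg_ta_sd_ms = 1,
                                cocon_rf_bf_mean_ms = 200, cocon_rf_bf_sd_ms = 1))
  expect_error(condition_params("pre", stride_time_mean_ms = 1000,
                                stride_time_sd_ms = 10,
                                dc_mean_pct = c(LG = 125, TA = 60, BF = 23, RF = 55),
                                dc_sd_pct = c(LG = 1, TA = 1, BF = 1, RF = 1),
                                cocon_lg_ta_mean_ms = 100, cocon_lg_ta_sd_ms = 1,
                                cocon_rf_bf_mean_ms = 200, cocon_rf_bf_sd_ms = 1),
               "duty-cycle")
})
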