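eeg_window <- function() {
  w <- matrix(0, 256, 7)
  colnames(w) <- c("T3", "C3", "Cz", "C4", "T4", "P3", "P4")
  w
}

test_that("a 1 uV in-bin mu sinusoid scores 0 dBu, and scaling adds 20 dB/decade", {
  w <- eeg_window()
  w[, "Cz"] <- 1e-6 * sin(2 * pi * 9.765625 * (0:255) / 500)  # exact 256-pt bin
  f <- extract_mrp(w, frame = 256, hop = 256)
  expect_equal(f[["mu_cz_dbu"]], 0, tolerance = 1e-9)
  f10 <- extract_mrp(w * 10, frame = 256, hop = 256)
  expect_equal(f10[["mu_cz_dbu"]] - f[["mu_cz_dbu"]], 20, tolerance = 1e-9)
  # silent channels are floored
  expect_equal(f[["bp_t3_dbu"]], -120)
})

test_that("single-frame mode matches a direct DFT oracle per band", {
  oracle_band <- function(x, lo, hi, fs = 500) {
    X <- fft(x)
    n <- length(x)
    fr <- (seq_len(n %/% 2 + 1) - 1) * fs / n
    sel <- which(fr >= lo & fr <= hi)
    20 * log10(max(Mod(X[sel]) * 2 / n) / 1e-6)
  }
  set.seed(8)
  for (i in 1:5) {
    w <- eeg_window()
    w[, 1] <- rnorm(256, sd = 2e-5)
    f <- extract_mrp(w, frame = 256, hop = 256)
    expect_equal(f[["bp_t3_dbu"]], oracle_band(w[, 1], 2, 5), tolerance = 1e-10)
    expect_equal(f[["mu_t3_dbu"]], oracle_band(w[, 1], 9, 11), tolerance = 1e-10)
    expect_equal(f[["beta_t3_dbu"]], oracle_band(w[, 1], 12, 30), tolerance = 1e-10)
  }
})

test_that("amplitude scaling shifts every feature by 20*log10(c)", {
  set.seed(2)
  w <- eeg_window()
  w[] <- rnorm(256 * 7, sd = 1e-5)
  d <- extract_mrp(w * 3) - extract_mrp(w)
  expect_equal(unname(d), rep(20 * log10(3), 21), tolerance = 1e-9)
})

test_that("adding in-band energy never decreases the band feature", {
  set.seed(4)
  w <- eeg_window()
  w[] <- rnorm(256 * 7, sd = 1e-5)
  base <- extract_mrp(w)
  w2 <- w
  w2[, "C3"] <- w2[, "C3"] + 5e-6 * sin(2 * pi * 10 * (0:255) / 500)
  bumped <- extract_mrp(w2)
  expect_gte(bumped[["mu_c3_dbu"]], base[["mu_c3_dbu"]])
})

test_that("window length is enforced", {
  expect_error(extract_mrp(matrix(0, 128, 7)), "256")
})

test_that("the FIFO keeps exactly the most recent 256 samples", {
  ff <- mrp_fifo(n_channels = 1, size = 256)
  expect_error(fifo_snapshot(ff), "underfilled")
  ff <- fifo_push(ff, matrix(1:256, ncol = 1))
  ff <- fifo_push(ff, matrix(257, ncol = 1))
  snap <- fifo_snapshot(ff)
  expect_equal(as.numeric(snap), 2:257)
  # snapshot at event time t equals raw samples (t-255):t
  set.seed(6)
  x <- matrix(rnorm(400 * 7), ncol = 7)
  ff2 <- mrp_fifo()
  for (t in 1:400) ff2 <- fifo_push(ff2, x[t, ])
  expect_equal(unname(fifo_snapshot(ff2)), unname(x[145:400, ]))
})

test_that("per-stride extraction skips underfilled onsets and matches truth alignment", {
  s <- fixture_session()
  st <- s$truth$strides
  on <- st$onset_samp[st$leg == "R"][1:10]
  feats <- session_mrp_features(s$eeg, c(100L, on))
  expect_true(all(is.na(feats[1, ])))  # onset before the buffer fills
  expect_true(all(is.finite(feats[-1, ])))
  expect_equal(ncol(feats), 21)
})

test_that("matched seeds give identical Pre/Post cortical windows at truth onsets", {
  pre <- simulate_session(default_params("pre"), n_strides = 40, seed = 31)
  post <- simulate_session(default_params("post"), n_strides = 40, seed = 31)
  f_of <- function(s) {
    cc <- s$truth$cortical  # both legs, fixed R-then-L row order
    list(f = session_mrp_features(s$eeg, cc$onset_samp),
         usable = cc$window_usable)
  }
  fp <- f_of(pre); fq <- f_of(post)
  ok <- fp$usable & fq$usable
  expect_gt(sum(ok), 5)
  expect_equal(fp$f[ok, ], fq$f[ok, ], tolerance = 1e-12)
  # hence every paired cortical t-test on the truth values is degenerate-null
  tp <- truth_feature_table(pre); tq <- truth_feature_table(post)
  p <- vapply(cortical_features(), function(f)
    paired_ttest(tp[[f]], tq[[f]])$p, numeric(1))
  expect_true(all(p == 1))
})
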