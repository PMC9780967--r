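mk_trig <- function(n, bursts) {
  v <- integer(n)
  for (b in bursts) v[b[1]:(b[2] - 1L)] <- 1L
  trigger_train(v)
}

test_that("strides span consecutive LG onsets on the sample grid", {
  # onsets at samples 11 and 551 -> one stride of 540 samples = 1080 ms
  lg <- mk_trig(600, list(c(11L, 150L), c(551L, 590L)))
  st <- segment_strides(lg)
  expect_equal(nrow(st), 1)
  expect_equal(st$stride_samp * 2, 1080)

  # onsets at 11, 511, 1051 -> strides of 1000 and 1080 ms
  lg3 <- mk_trig(1200, list(c(11L, 150L), c(511L, 650L), c(1051L, 1190L)))
  st3 <- segment_strides(lg3)
  expect_equal(st3$stride_samp * 2, c(1000, 1080))

  expect_warning(st0 <- segment_strides(mk_trig(600, list(c(11L, 150L)))),
                 "fewer than 2")
  expect_equal(nrow(st0), 0)
})

test_that("detected stride count matches the generator's complete cycles", {
  s <- fixture_session()
  trig <- binarize(s$emg[, "R_LG"])
  st <- segment_strides(trig)
  expect_equal(nrow(st), s$n_strides - 1L)  # n onsets -> n-1 complete cycles
})

test_that("per-stride indexes follow the counting definitions exactly", {
  n <- 600L
  strides <- data.frame(start = 11L, end = 551L)
  strides$stride_samp <- strides$end - strides$start
  # LG active over samples [111, 246) = 135 samples -> 270 ms, DC 25%
  triggers <- list(LG = mk_trig(n, list(c(111L, 246L))),
                   TA = mk_trig(n, list(c(161L, 261L))),   # [50,150) rel
                   BF = mk_trig(n, list(c(236L, 311L))),   # [125,200) rel
                   RF = mk_trig(n, list(c(236L, 311L))))
  tab <- compute_indexes(strides, triggers)
  expect_equal(tab$contraction_lg_ms, 270)
  expect_equal(tab$dc_lg_pct, 25)
  expect_equal(tab$stride_time_ms, 1080)
  # A active [50,150), B active [125,200) -> 25 samples = 50 ms overlap
  ab <- compute_indexes(strides, list(LG = triggers$TA, TA = triggers$BF,
                                      BF = triggers$BF, RF = triggers$RF))
  expect_equal(ab$cocon_lg_ta_ms, 50)
})

test_that("conservation and overlap bounds hold on random triggers", {
  set.seed(5)
  for (i in 1:10) {
    n <- 2000L
    triggers <- lapply(setNames(MUSCLES <- c("LG", "TA", "BF", "RF"), MUSCLES),
                       function(m) trigger_train(rbinom(n, 1, runif(1, 0.2, 0.7))))
    starts <- sort(sample(1:(n - 400), 4))
    strides <- data.frame(start = starts, end = starts + sample(200:400, 4, TRUE))
    strides$stride_samp <- strides$end - strides$start
    tab <- compute_indexes(strides, triggers)
    for (m in c("lg", "ta", "bf", "rf")) {
      expect_equal(tab[[paste0("contraction_", m, "_ms")]] +
                   tab[[paste0("relaxation_", m, "_ms")]],
                   tab$stride_time_ms)
    }
    expect_true(all(tab$cocon_lg_ta_ms <=
                    pmin(tab$contraction_lg_ms, tab$contraction_ta_ms)))
    expect_true(all(tab$cocon_lg_ta_ms >=
                    pmax(0, tab$contraction_lg_ms + tab$contraction_ta_ms -
                           tab$stride_time_ms)))
    expect_true(all(tab$cocon_rf_bf_ms <=
                    pmin(tab$contraction_rf_ms, tab$contraction_bf_ms)))
  }
})

test_that("on noiseless triggers the pipeline indexes equal ground truth", {
  s <- fixture_session()
  st <- s$truth$strides[s$truth$strides$leg == "R", ]
  strides <- data.frame(start = st$onset_samp, end = st$onset_samp + st$stride_samp)
  strides$stride_samp <- st$stride_samp
  triggers <- lapply(setNames(c("LG", "TA", "BF", "RF"), c("LG", "TA", "BF", "RF")),
                     function(m) trigger_train(s$truth$masks[, paste0("R_", m)]))
  tab <- compute_indexes(strides, triggers)
  truth <- truth_feature_table(s)
  truth_r <- truth[truth$leg == "R", ]
  expect_equal(tab$stride_time_ms, truth_r$stride_time_ms)
  expect_equal(tab$cocon_lg_ta_ms, truth_r$cocon_lg_ta_ms)
  expect_equal(tab$cocon_rf_bf_ms, truth_r$cocon_rf_bf_ms)
  expect_equal(tab$dc_lg_pct, truth_r$dc_lg_pct)
  expect_equal(tab$dc_bf_pct, truth_r$dc_bf_pct)
})

test_that("pooling concatenates legs and preserves weighted means", {
  left <- data.frame(dc_lg_pct = runif(10, 20, 30))
  right <- data.frame(dc_lg_pct = runif(12, 20, 30))
  pooled <- pool_legs(L = left, R = right)
  expect_equal(nrow(pooled), 22)
  expect_setequal(unique(pooled$leg), c("L", "R"))
  expect_equal(mean(pooled$dc_lg_pct),
               (10 * mean(left$dc_lg_pct) + 12 * mean(right$dc_lg_pct)) / 22)
  only_right <- pool_legs(L = left[0, , drop = FALSE], R = right)
  expect_equal(nrow(only_right), nrow(right))
  expect_equal(only_right$dc_lg_pct, right$dc_lg_pct)
})

test_that("strides running past the trigger length are marked invalid", {
  triggers <- lapply(setNames(c("LG", "TA", "BF", "RF"), c("LG", "TA", "BF", "RF")),
                     function(m) trigger_train(rep(c(0L, 1L), 100)))
  strides <- data.frame(start = c(1L, 150L), end = c(101L, 260L))
  strides$stride_samp <- strides$end - strides$start
  tab <- compute_indexes(strides, triggers)
  expect_true(tab$valid[1])
  expect_false(tab$valid[2])
  expect_true(is.na(tab$dc_lg_pct[2]))
})
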