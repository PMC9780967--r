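# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# a mid-sized rendered Pre-levodopa session reused by trigger/stride tests
fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    .fixtures$session <- simulate_session(default_params("pre"),
                                          n_strides = 60, seed = 101)
  }
  .fixtures$session
}

# truth-level labelled tables for quick classifier tests (both partitions)
fixture_tables <- function() {
  if (is.null(.fixtures$tables)) {
    mk <- function(sids, seed) {
      out <- NULL
      for (sid in sids) {
        for (cond in c("pre", "post")) {
          rec <- simulate_session(default_params(cond), n_strides = 150,
                                  seed = wotrack:::derive_seed(seed, sid),
                                  subject_id = sid,
                                  subject_shift = subject_effects(sid, seed),
                                  render = FALSE)
          out <- rbind(out, truth_feature_table(rec))
        }
      }
      out
    }
    .fixtures$tables <- list(train = mk(c("S1", "S2", "S3"), 77),
                             test = mk(c("S4", "S5"), 77))
  }
  .fixtures$tables
}

# synthetic sEMG trace with known trapezoidal bursts (half-max mask support);
# returns the signal and its ground-truth mask
make_burst_signal <- function(n, onsets, durations, amp = 10, seed = 1) {
  set.seed(seed)
  env <- numeric(n)
  mask <- integer(n)
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- on + durations[i]
    mask[on:(off - 1L)] <- 1L
    env <- wotrack:::add_burst_envelope(env, on, off, n)
  }
  bp <- signal::butter(4, c(20, 200) / 250, type = "pass")
  carrier <- as.numeric(signal::filter(bp, rnorm(n)))
  carrier <- carrier / sd(carrier)
  noise <- as.numeric(signal::filter(bp, rnorm(n)))
  noise <- noise / sd(noise)
  list(x = amp * env * carrier + noise, mask = mask)
}

# random debounced 0/1 train: alternating runs of length >= min_run
make_debounced_train <- function(n_runs, min_run = 15L, start = 0L, seed = 1) {
  set.seed(seed)
  lens <- min_run + sample(0:40, n_runs, replace = TRUE)
  vals <- rep_len(c(start, 1L - start), n_runs)
  inverse.rle(structure(list(lengths = lens, values = vals), class = "rle"))
}
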