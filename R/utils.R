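# Internal helpers shared across modules.

# Round half away from zero (the tables' convention), unlike base round()'s
# round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic fan-out of a master seed into per-stage / per-unit seeds.
# Plain polynomial string hash folded into [0, 2^31 - 2]; doubles keep exact
# integer arithmetic well below 2^53.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483629
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(paste0(label))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Trailing (causal) moving mean; first win-1 values use the expanding mean.
moving_mean_trailing <- function(x, win) {
  n <- length(x)
  if (win <= 1L || n == 0L) return(x)
  cs <- cumsum(x)
  out <- numeric(n)
  head_idx <- seq_len(min(win - 1L, n))
  out[head_idx] <- cs[head_idx] / head_idx
  if (n >= win) {
    idx <- win:n
    out[idx] <- (cs[idx] - c(0, cs)[idx - win + 1L]) / win
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
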