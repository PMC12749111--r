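# Internal helpers shared across modules.

# Sample index (1-based) <-> epoch time convention: sample i corresponds to
# t = (i - 1) / fs_hz * 1000 ms, with t = 0 at the stimulation pulse onset.
epoch_time_ms <- function(n, fs_hz) {
  (seq_len(n) - 1) / fs_hz * 1000
}

# Indices of epoch samples falling inside a closed [lo, hi] ms window.
window_idx <- function(n, fs_hz, window_ms) {
  t <- epoch_time_ms(n, fs_hz)
  which(t >= window_ms[1] & t <= window_ms[2])
}

ms_to_samples <- function(ms, fs_hz) {
  round(ms / 1000 * fs_hz)
}

# abort() wrapper giving every validation error a named class so callers and
# tests can condition on it.
stop_mep <- function(message, class) {
  rlang::abort(message, class = c(class, "mepscore_error"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    stop_mep(sprintf("`%s` must be a single finite number", name),
             "mep_invalid_argument")
  }
  if (positive && x <= 0) {
    stop_mep(sprintf("`%s` must be > 0", name), "mep_invalid_argument")
  }
  invisible(x)
}

# Odd window length >= 3 for Savitzky-Golay style filters.
odd_at_least_3 <- function(n) {
  n <- max(3L, as.integer(round(n)))
  if (n %% 2L == 0L) n <- n + 1L
  n
}
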