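# Shared fixtures: the measured transition probabilities of AD-seeded
# 4R/3R tau filaments and small synthetic configurations.

measured_probs <- function(with_err = FALSE) {
  if (with_err) {
    transition_probs(0.37, 0.56, p43_err = 0.03, p34_err = 0.02)
  } else {
    transition_probs(0.37, 0.56)
  }
}

noiseless_config <- function(...) {
  synthesis_config(snr = Inf, ...)
}

# independent re-implementation of the per-point interpolation (oracle for
# estimator tests): plain percent-scale arithmetic on three curves
oracle_interp <- function(meas, low, high, low_pct, high_pct) {
  (meas - high) / (low - high) * (low_pct - high_pct) + high_pct
}
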