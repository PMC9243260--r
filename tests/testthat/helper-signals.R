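# shared fixture builders; everything is generated in code at test time

tone <- function(freq, n, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) + phase)
}

two_tone_pair <- function(n = 1000, f_fast = 0.05, f_slow = 0.005) {
  x <- tone(f_fast, n) + tone(f_slow, n)
  multivariate_signal(cbind(x, x))
}

reconstruction_error <- function(dec, values) {
  rec <- apply(dec$imfs, c(2, 3), sum) + dec$residual
  max(abs(rec - t(values))) / max(abs(values))
}

# extrema minus zero crossings, counted over the interior 90% of samples
imf_extrema_zc_mismatch <- function(x) {
  idx <- seq.int(floor(length(x) * 0.05) + 1, ceiling(length(x) * 0.95))
  v <- x[idx]
  d <- sign(diff(v))
  nz <- d[d != 0]
  n_ext <- sum(diff(nz) != 0)
  s <- sign(v)
  s <- s[s != 0]
  n_zc <- sum(diff(s) != 0)
  n_ext - n_zc
}
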