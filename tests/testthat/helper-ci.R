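# 99% Wilson interval used when comparing a formula's prediction to a
# Monte-Carlo measurement (level chosen so that a handful of simultaneous
# comparisons keeps a small overall false-alarm rate).
.wilson99 <- function(p_hat, m) {
  z <- stats::qnorm(0.995)
  denom <- 1 + z^2 / m
  centre <- (p_hat + z^2 / (2 * m)) / denom
  half <- z / denom * sqrt(p_hat * (1 - p_hat) / m + z^2 / (4 * m^2))
  c(centre - half, centre + half)
}
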