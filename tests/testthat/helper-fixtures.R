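# Deterministic transition fixtures with exact conditional moments.

# Transitions where at each origin n the increment takes the two values
# eps*n +/- sqrt(Vd*n + Ve*n^2), each exactly half the time, so that the
# conditional mean and variance match the n-space model identically.
exact_moment_transitions <- function(ns, eps, Vd, Ve, pairs_per_n = 30L) {
  n <- rep(ns, each = 2L * pairs_per_n)
  sd_n <- sqrt(Vd * ns + Ve * ns^2)
  # each origin n carries both signs equally often
  dn <- as.vector(vapply(seq_along(ns), function(i) {
    rep(c(eps * ns[i] + sd_n[i], eps * ns[i] - sd_n[i]), pairs_per_n)
  }, numeric(2L * pairs_per_n)))
  data.frame(n = n, dn = dn)
}

# z-space two-point fixture: at each origin n the log-increment takes the
# two values (E0 - Vd/(2n)) +/- spread, each half the time.
exact_z_transitions <- function(ns, E0, Vd, spread = 0.01,
                                pairs_per_n = 30L) {
  n <- rep(ns, each = 2L * pairs_per_n)
  dz <- as.vector(vapply(seq_along(ns), function(i) {
    m <- E0 - Vd / (2 * ns[i])
    rep(c(m + spread, m - spread), pairs_per_n)
  }, numeric(2L * pairs_per_n)))
  data.frame(n = n, dn = n * expm1(dz))
}

# gambler's-ruin kernel of the unbiased +/-1 walk on 0..nmax
ruin_kernel <- function(nmax) {
  W <- matrix(0, nmax + 1L, nmax + 1L)
  W[1L, 1L] <- 1
  W[nmax + 1L, nmax + 1L] <- 1
  for (i in 2:nmax) {
    W[i, i - 1L] <- 0.5
    W[i, i + 1L] <- 0.5
  }
  W
}
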