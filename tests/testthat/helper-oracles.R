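# Independent numerical oracles, kept free of the package's own code paths.

# Finite-difference solve of the backward boundary-value problem
#   E[dn](x) P'(x) + Var[dn](x)/2 P''(x) = 0,  P(0) = 0, P(nf) = 1
# with E[dn] = eps*x and Var[dn] = Vd*x + Ve*x^2, on a uniform grid
# (second-order central differences, Thomas algorithm).
fd_bvp_oracle <- function(nf, eps, Vd, Ve, M = 40000L) {
  h <- nf / M
  x <- h * (1:(M - 1))
  mu <- eps * x
  v <- (Vd * x + Ve * x^2) / 2
  lo <- v / h^2 - mu / (2 * h)
  di <- -2 * v / h^2
  up <- v / h^2 + mu / (2 * h)
  rhs <- numeric(M - 1)
  rhs[M - 1] <- -up[M - 1]
  cp <- numeric(M - 1); dp <- numeric(M - 1)
  cp[1] <- up[1] / di[1]; dp[1] <- rhs[1] / di[1]
  for (i in 2:(M - 1)) {
    m <- di[i] - lo[i] * cp[i - 1]
    cp[i] <- up[i] / m
    dp[i] <- (rhs[i] - lo[i] * dp[i - 1]) / m
  }
  P <- numeric(M - 1)
  P[M - 1] <- dp[M - 1]
  for (i in (M - 2):1) P[i] <- dp[i] - cp[i] * P[i + 1]
  stats::approxfun(c(0, x, nf), c(0, P, 1))
}

# Root-solve of the two-destination WKB characteristic equation
#   1 = 2 alpha sinh(q beta) + exp(-q beta)
# for the nontrivial root (sign opposite to E0).
q_bar_root_oracle <- function(E0, Ve) {
  beta <- sqrt(Ve + E0^2)
  alpha <- 0.5 + E0 / (2 * beta)
  # 2 a sinh(x) + e^-x - 1 written as a e^x + (1-a) e^-x - 1 so the two
  # exponentials never produce Inf - Inf; solve in x = q*beta
  f <- function(x) alpha * exp(x) + (1 - alpha) * exp(-x) - 1
  interval <- if (E0 > 0) c(-60, -1e-14) else c(1e-14, 60)
  stats::uniroot(f, interval, tol = 1e-16)$root / beta
}

# Closed-form conditional one-step moments of the discrete lottery scheme,
# derived directly from its sampling structure (dichotomous environment,
# D ~ Bin(N, td) deaths, Hypergeometric invader share, Binomial refills):
#   E[dn | n, s]   = N td (p - n/N)
#   Var[dn | n, s] = N td p(1-p) + N td(1-td) (n/N)(1-n/N)
#                    + (p - n/N)^2 N td (1-td)
# with p = n e^s / (n e^s + N - n), averaged over the two environments.
lottery_moments_oracle <- function(n, N, s0, sigma, tau) {
  td <- min(tau, 1)
  mus <- vars <- numeric(2)
  i <- 0
  for (eta in c(1, -1)) {
    i <- i + 1
    s <- s0 + sigma * eta
    p <- n * exp(s) / (n * exp(s) + (N - n))
    mus[i] <- N * td * (p - n / N)
    vars[i] <- N * td * p * (1 - p) +
      N * td * (1 - td) * (n / N) * (1 - n / N) +
      (p - n / N)^2 * N * td * (1 - td)
  }
  c(mean = mean(mus), var = mean(vars) + mean((mus - mean(mus))^2))
}

# Plain weighted least squares, independent of the package's fitting code.
wls_oracle <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# Direct one-step sampling of the same lottery scheme, written
# independently of .lottery_step, for conditional z-moment ground truth.
lottery_one_step_sample <- function(n, cfg, draws) {
  N <- cfg$N
  td <- min(cfg$tau, 1)
  eta <- sample(c(-1, 1), draws, replace = TRUE)
  s <- cfg$s0 + cfg$sigma * eta
  p <- n * exp(s) / (n * exp(s) + (N - n))
  D <- rbinom(draws, N, td)
  dead <- rhyper(draws, n, N - n, D)
  rec <- rbinom(draws, D, p)
  n - dead + rec
}
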