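# Individual-based stochastic community simulators with a fluctuating
# environment.  All update rules are isolated in small step functions so a
# variant scheme can be swapped in without touching inference or formulae.

#' Discrete-time lottery model configuration
#'
#' A two-species community of fixed size `N`.  Each step spans one dwell
#' period of duration `tau` generations: the environment is redrawn, a
#' Binomial fraction `min(tau, 1)` of individuals die (their split between
#' the species is Hypergeometric), and every vacated site is refilled by
#' the invader with probability \eqn{p = n e^{s}/(n e^{s} + N - n)}, where
#' \eqn{s = s_0 + \sigma \eta} is the invader's current log-fitness
#' advantage and \eqn{\eta} the environmental state.
#'
#' @param N community size (at least 2).
#' @param s0 mean log-fitness advantage of the invader.
#' @param tau dwell time in generations; must be in `(0, 1]` for the
#'   discrete model (a death fraction cannot exceed 1 — use the Moran
#'   variant for longer dwell times).
#' @param sigma amplitude of the environmental log-fitness fluctuations
#'   (nonnegative).
#' @param env_dist distribution of the environmental state `eta`
#'   (unit-variance): `"dichotomous"` (+/-1), `"uniform"`, or
#'   `"gaussian"`.
#' @return An object of class `"lottery_config"`.
#' @export
#' @examples
#' lottery_config(N = 1e4, s0 = 0, tau = 0.2, sigma = 0.25)
lottery_config <- function(N, s0 = 0, tau = 0.2, sigma = 0,
                           env_dist = c("dichotomous", "uniform",
                                        "gaussian")) {
  env_dist <- match.arg(env_dist)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2,
            is.numeric(s0), is.numeric(tau), is.numeric(sigma))
  if (tau <= 0) stop("'tau' must be positive")
  if (sigma < 0) stop("'sigma' must be nonnegative")
  structure(list(N = as.integer(N), s0 = s0, tau = tau, sigma = sigma,
                 env_dist = env_dist),
            class = "lottery_config")
}

# one draw of eta per element of len
.draw_env <- function(len, env_dist) {
  switch(env_dist,
         dichotomous = sample(c(-1, 1), len, replace = TRUE),
         uniform = stats::runif(len, -sqrt(3), sqrt(3)),
         gaussian = stats::rnorm(len))
}

# Vectorised one-dwell update of invader abundances `n` (may contain 0/N).
.lottery_step <- function(n, config, eta) {
  N <- config$N
  td <- min(config$tau, 1)
  s <- config$s0 + config$sigma * eta
  p <- n * exp(s) / (n * exp(s) + (N - n))
  D <- stats::rbinom(length(n), N, td)
  dead_inv <- stats::rhyper(length(n), m = n, n = N - n, k = D)
  recruits <- stats::rbinom(length(n), D, p)
  n - dead_inv + recruits
}

#' Simulate the discrete-time lottery model
#'
#' @param config a [lottery_config()] with `tau <= 1`.
#' @param n0 initial invader abundance in `0..N`.
#' @param horizon length of the run in generations.
#' @param record_interval record the abundance every this many dwell
#'   periods (integer, default 1 so the series is sampled at the dwell
#'   time, as inference requires).
#' @param seed optional RNG seed for reproducibility.
#' @return An [abundance_series()] with `dt = tau * record_interval`.
#' @export
#' @examples
#' s <- simulate_lottery_discrete(lottery_config(1000, tau = 0.2,
#'                                               sigma = 0.3),
#'                                n0 = 100, horizon = 20, seed = 1)
simulate_lottery_discrete <- function(config, n0, horizon,
                                      record_interval = 1L, seed = NULL) {
  stopifnot(inherits(config, "lottery_config"))
  if (config$tau > 1)
    stop("discrete lottery requires tau <= 1 (death fraction cannot ",
         "exceed 1); use the Moran variant")
  if (n0 < 0 || n0 > config$N) stop("'n0' must be in 0..N")
  if (horizon <= 0) stop("'horizon' must be positive")
  record_interval <- as.integer(record_interval)
  if (record_interval < 1L) stop("'record_interval' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  steps <- max(1L, floor(horizon / config$tau))
  out <- integer(steps %/% record_interval + 1L)
  out[1L] <- n <- as.integer(n0)
  j <- 1L
  for (step in seq_len(steps)) {
    n <- .lottery_step(n, config, .draw_env(1L, config$env_dist))
    if (step %% record_interval == 0L) {
      j <- j + 1L
      out[j] <- n
    }
  }
  abundance_series(out[seq_len(j)], dt = config$tau * record_interval)
}

#' Simulate the Moran (continuous-time) lottery model
#'
#' Elementary events advance time by `1/N` generations: one uniformly
#' chosen individual dies and its site is refilled by the invader with
#' probability \eqn{p = n e^{s}/(n e^{s} + N - n)}.  The environment is
#' redrawn every `ceiling(tau * N)` events, so its dwell time is `tau`
#' generations.
#'
#' @inheritParams simulate_lottery_discrete
#' @param config a [lottery_config()] (any positive `tau`).
#' @param record_interval record spacing in generations (default `tau`).
#' @return An [abundance_series()] with `dt = record_interval`.
#' @export
simulate_lottery_moran <- function(config, n0, horizon,
                                   record_interval = config$tau,
                                   seed = NULL) {
  stopifnot(inherits(config, "lottery_config"))
  if (n0 < 0 || n0 > config$N) stop("'n0' must be in 0..N")
  if (horizon <= 0) stop("'horizon' must be positive")
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  k_env <- max(1L, as.integer(ceiling(config$tau * N)))
  k_rec <- max(1L, as.integer(round(record_interval * N)))
  n_events <- floor(horizon * N)
  out <- integer(n_events %/% k_rec + 1L)
  out[1L] <- n <- as.integer(n0)
  eta <- .draw_env(1L, config$env_dist)
  j <- 1L
  for (ev in seq_len(n_events)) {
    if ((ev - 1L) %% k_env == 0L && ev > 1L)
      eta <- .draw_env(1L, config$env_dist)
    s <- config$s0 + config$sigma * eta
    death_inv <- stats::runif(1L) < n / N
    p <- n * exp(s) / (n * exp(s) + (N - n))
    birth_inv <- stats::runif(1L) < p
    n <- n - death_inv + birth_inv
    if (ev %% k_rec == 0L) {
      j <- j + 1L
      out[j] <- n
    }
  }
  abundance_series(out[seq_len(j)], dt = k_rec / N)
}

#' Leslie-Gower tree/sapling competition model configuration
#'
#' A forest of `N` adult sites shared by two species.  Per year, each
#' adult survives with probability `d`; each species' sapling pool keeps a
#' Binomial fraction `f` of its saplings and gains Poisson recruits with
#' mean `adults x recruitment rate of the year`; vacated adult sites are
#' refilled by a lottery weighted by the sapling abundances.
#'
#' @param N number of adult sites.
#' @param d adult survival probability per year, in (0, 1].
#' @param f sapling survival probability per year, in (0, 1).
#' @param recruitment either a list of two positive numeric vectors (the
#'   yearly recruitment-rate series of invader and resident; recycled if
#'   shorter than the run, with a random phase per replicate), or the
#'   result of [generate_recruitment_series()].
#' @return An object of class `"leslie_gower_config"`.
#' @export
leslie_gower_config <- function(N, d, f, recruitment) {
  stopifnot(is.numeric(N), N >= 2, is.numeric(d), is.numeric(f))
  if (d <= 0 || d > 1) stop("'d' must be in (0, 1]")
  if (f <= 0 || f >= 1) stop("'f' must be in (0, 1)")
  if (is.matrix(recruitment))
    recruitment <- list(recruitment[, 1L], recruitment[, 2L])
  if (!is.list(recruitment) || length(recruitment) != 2L)
    stop("'recruitment' must give two per-species rate series")
  if (any(unlist(recruitment) <= 0))
    stop("recruitment rates must be positive")
  structure(list(N = as.integer(N), d = d, f = f,
                 recruitment = recruitment),
            class = "leslie_gower_config")
}

#' Synthetic lognormal recruitment-rate series
#'
#' Generates per-species yearly recruitment rates as correlated lognormal
#' variables: a stand-in for empirical recruitment series (which are
#' typically short and proprietary) with controlled first two moments.
#' `log r_i ~ N(log(mean_i) - log_var/2, log_var)` with cross-correlation
#' `corr` between the two species' log rates, so the natural-scale means
#' equal `means` exactly in expectation.
#'
#' @param means length-2 positive vector of natural-scale mean rates.
#' @param log_var variance of the log rates (nonnegative).
#' @param corr correlation between the species' log rates, in `[-1, 1]`.
#' @param years series length.
#' @param seed optional RNG seed.
#' @return A `years x 2` matrix of rates.
#' @export
#' @examples
#' r <- generate_recruitment_series(c(2, 2), log_var = 0.25, corr = 0.3,
#'                                  years = 100, seed = 1)
generate_recruitment_series <- function(means, log_var, corr, years,
                                        seed = NULL) {
  stopifnot(length(means) == 2L, is.numeric(means))
  if (any(means <= 0)) stop("'means' must be positive")
  if (log_var < 0) stop("'log_var' must be nonnegative")
  if (abs(corr) > 1) stop("'corr' must be in [-1, 1]")
  if (years < 1) stop("'years' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- log(means) - log_var / 2
  if (log_var == 0) {
    out <- cbind(rep(means[1L], years), rep(means[2L], years))
  } else {
    e1 <- stats::rnorm(years)
    e2 <- corr * e1 + sqrt(1 - corr^2) * stats::rnorm(years)
    out <- cbind(exp(mu[1L] + sqrt(log_var) * e1),
                 exp(mu[2L] + sqrt(log_var) * e2))
  }
  colnames(out) <- c("invader", "resident")
  out
}

# rates for years `yrs` (1-based), cycling the stored series from `phase`
.lg_rates <- function(config, yrs, phase = 0L) {
  r1 <- config$recruitment[[1L]]
  r2 <- config$recruitment[[2L]]
  i1 <- ((yrs - 1L + phase) %% length(r1)) + 1L
  i2 <- ((yrs - 1L + phase) %% length(r2)) + 1L
  cbind(r1[i1], r2[i2])
}

# One-year update, vectorised over replicates.
# state: list of vectors A1, S1, S2 (A2 = N - A1); rates: len x 2
.lg_step <- function(A1, S1, S2, config, r1, r2) {
  N <- config$N
  A2 <- N - A1
  surv1 <- stats::rbinom(length(A1), A1, config$d)
  surv2 <- stats::rbinom(length(A1), A2, config$d)
  vac <- N - surv1 - surv2
  S1 <- stats::rbinom(length(S1), S1, config$f) +
    stats::rpois(length(A1), A1 * r1)
  S2 <- stats::rbinom(length(S2), S2, config$f) +
    stats::rpois(length(A1), A2 * r2)
  tot <- S1 + S2
  # weight of the invader in the vacancy lottery; when no saplings exist,
  # fall back to the surviving adults (and to 1/2 if none survive)
  w <- ifelse(tot > 0, S1 / pmax(tot, 1),
              ifelse(surv1 + surv2 > 0, surv1 / pmax(surv1 + surv2, 1), 0.5))
  new1 <- stats::rbinom(length(A1), vac, w)
  list(A1 = surv1 + new1, S1 = S1, S2 = S2)
}

#' Simulate the Leslie-Gower tree/sapling model
#'
#' @param config a [leslie_gower_config()].
#' @param n0 initial invader adult count in `0..N`.
#' @param horizon run length in years.
#' @param record_interval record every this many years (integer).
#' @param seed optional RNG seed.
#' @param s0_saplings optional initial sapling pools (length-2); default
#'   seeds each pool at `adults x mean recruitment rate`.
#' @return An [abundance_series()] of invader adult counts with
#'   `dt = record_interval` years.
#' @export
simulate_leslie_gower <- function(config, n0, horizon, record_interval = 1L,
                                  seed = NULL, s0_saplings = NULL) {
  stopifnot(inherits(config, "leslie_gower_config"))
  if (n0 < 0 || n0 > config$N) stop("'n0' must be in 0..N")
  if (horizon <= 0) stop("'horizon' must be positive")
  record_interval <- as.integer(record_interval)
  if (record_interval < 1L) stop("'record_interval' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  A1 <- as.integer(n0)
  if (is.null(s0_saplings))
    s0_saplings <- c(round(A1 * mean(config$recruitment[[1L]])),
                     round((N - A1) * mean(config$recruitment[[2L]])))
  S1 <- as.integer(s0_saplings[1L]); S2 <- as.integer(s0_saplings[2L])
  years <- as.integer(floor(horizon))
  out <- integer(years %/% record_interval + 1L)
  out[1L] <- A1
  j <- 1L
  for (yr in seq_len(years)) {
    r <- .lg_rates(config, yr)
    st <- .lg_step(A1, S1, S2, config, r[, 1L], r[, 2L])
    A1 <- st$A1; S1 <- st$S1; S2 <- st$S2
    if (yr %% record_interval == 0L) {
      j <- j + 1L
      out[j] <- A1
    }
  }
  abundance_series(out[seq_len(j)], dt = as.numeric(record_interval))
}
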