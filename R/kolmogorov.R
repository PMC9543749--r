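# Exact small-instance solver for the backward recursion Pi = W Pi.

#' Exact invasion probabilities from a one-step transition kernel
#'
#' Solves the backward recursion \eqn{\Pi_n = \sum_{n'} W_{n \to n'}
#' \Pi_{n'}} exactly as a linear system, with boundary conditions
#' \eqn{\Pi_0 = 0} and \eqn{\Pi_n = 1} for all \eqn{n \ge n_f} (all states
#' at or above the target are treated as one absorbing success state).
#' Intended as a numerically exact oracle on small state spaces, e.g. to
#' validate the closed-form formulae and the Monte-Carlo estimator.
#'
#' @param W square row-stochastic matrix over the states `0..nmax`
#'   (`W[i, j]` is the probability of moving from abundance `i-1` to
#'   abundance `j-1` in one dwell period).  State 0 must be absorbing.
#' @param nf target abundance, an integer in `1..nmax`.
#' @return Named numeric vector `Pi` of length `nf + 1` giving the
#'   invasion probability from each starting abundance `0..nf`.
#' @seealso [lottery_transition_matrix()] for an exact lottery kernel.
#' @export
#' @examples
#' # unbiased +/-1 random walk: gambler's ruin, Pi_n = n/10
#' nmax <- 10
#' W <- matrix(0, nmax + 1, nmax + 1)
#' W[1, 1] <- 1; W[nmax + 1, nmax + 1] <- 1
#' for (i in 2:nmax) { W[i, i - 1] <- 0.5; W[i, i + 1] <- 0.5 }
#' solve_kolmogorov_exact(W, nf = 10)
solve_kolmogorov_exact <- function(W, nf) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), is.numeric(W))
  nmax <- nrow(W) - 1L
  nf <- as.integer(nf)
  if (nf < 1L || nf > nmax) stop("'nf' must be an integer in 1..nmax")
  if (any(abs(rowSums(W) - 1) > 1e-8))
    stop("rows of 'W' must sum to 1")
  if (any(W < -1e-12)) stop("'W' must be nonnegative")
  if (abs(W[1L, 1L] - 1) > 1e-12)
    stop("state 0 must be absorbing (W[1, 1] == 1)")
  if (nf == 1L) {
    out <- c(0, 1); names(out) <- 0:1
    return(out)
  }
  interior <- 2:nf                       # abundances 1..nf-1
  diag_int <- diag(W)[interior]
  if (any(diag_int >= 1 - 1e-12))
    stop("absorbing interior state at n = ",
         paste(which(diag_int >= 1 - 1e-12), collapse = ", "))
  A <- W[interior, interior, drop = FALSE]
  b <- rowSums(W[interior, (nf + 1L):(nmax + 1L), drop = FALSE])
  M <- diag(length(interior)) - A
  x <- tryCatch(solve(M, b), error = function(e)
    stop("singular backward system: no path from some interior state to ",
         "either boundary (", conditionMessage(e), ")"))
  out <- c(0, x, 1)
  names(out) <- 0:nf
  out
}

#' Exact one-step transition kernel of the discrete-time lottery model
#'
#' Builds, by direct summation, the one-step (one dwell period) transition
#' matrix of the same individual-based discrete lottery scheme that
#' [simulate_lottery_discrete()] samples from: the environment is redrawn
#' each step from the dichotomous distribution (log-fitness
#' \eqn{s = s_0 \pm \sigma} with probability 1/2 each), a Binomial
#' \eqn{D \sim Bin(N, \min(\tau, 1))} number of individuals die, the
#' invader's share of deaths is Hypergeometric, and each vacated site is
#' refilled by the invader independently with probability
#' \eqn{p = n e^s / (n e^s + N - n)}.
#'
#' All destination states at or above `nf` are lumped into the absorbing
#' success state `nf`, so the returned `(nf + 1) x (nf + 1)` matrix feeds
#' directly into [solve_kolmogorov_exact()].
#'
#' @param config a [lottery_config()]; the environment distribution must be
#'   dichotomous.
#' @param nf target abundance at which states are lumped (success).
#' @param prune probability mass below which Binomial death counts are
#'   skipped (their total mass is folded back by row renormalisation).
#' @return Row-stochastic matrix over the states `0..nf`.
#' @export
lottery_transition_matrix <- function(config, nf, prune = 1e-15) {
  stopifnot(inherits(config, "lottery_config"))
  if (config$env_dist != "dichotomous")
    stop("exact kernel is implemented for the dichotomous environment only")
  N <- config$N
  td <- min(config$tau, 1)
  nf <- as.integer(nf)
  if (nf < 1L || nf >= N) stop("'nf' must be in 1..N-1")
  W <- matrix(0, nf + 1L, nf + 1L)
  W[1L, 1L] <- 1
  W[nf + 1L, nf + 1L] <- 1
  dD_all <- stats::dbinom(0:N, N, td)
  Dsup <- which(dD_all > prune) - 1L
  s_states <- config$s0 + config$sigma * c(1, -1)
  for (n in seq_len(nf - 1L)) {
    row <- numeric(nf + 1L)
    for (s in s_states) {
      p <- n * exp(s) / (n * exp(s) + (N - n))
      for (D in Dsup) {
        wD <- 0.5 * dD_all[D + 1L]
        lo <- max(0L, D - (N - n))
        hi <- min(n, D)
        pdn <- stats::dhyper(lo:hi, n, N - n, D)
        pr <- stats::dbinom(0:D, D, p)
        for (k in seq_along(pdn)) {
          dn <- lo + k - 1L
          base <- n - dn                     # destination for r = 0
          # r values that keep the destination strictly below nf
          r_hi <- min(D, nf - 1L - base)
          if (r_hi >= 0L)
            row[(base:(base + r_hi)) + 1L] <-
              row[(base:(base + r_hi)) + 1L] + wD * pdn[k] * pr[1:(r_hi + 1L)]
          if (r_hi < D)
            row[nf + 1L] <- row[nf + 1L] +
              wD * pdn[k] * sum(pr[(r_hi + 2L):(D + 1L)])
        }
      }
    }
    W[n + 1L, ] <- row / sum(row)
  }
  W
}
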