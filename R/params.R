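#' Per-dwell-time moment parameters on the abundance (n) scale
#'
#' Container for the three constants that describe how the mean and variance
#' of the per-dwell-time abundance increment scale with abundance:
#' \deqn{E[\Delta n] = \epsilon n, \qquad Var[\Delta n] = V_d n + V_e n^2.}
#' The linear variance term is demographic stochasticity (birth/death noise
#' of discrete individuals, present even in a fixed environment); the
#' quadratic term is environmental stochasticity (community-wide fitness
#' fluctuations).  All three constants are per dwell time of the
#' environment, i.e. they refer to increments measured over one dwell
#' period.
#'
#' @param eps dimensionless per-dwell-time mean relative growth.
#' @param Vd demographic variance coefficient (per dwell time, per
#'   individual); must be nonnegative.
#' @param Ve environmental variance coefficient (per dwell time, per squared
#'   abundance); must be nonnegative.
#' @return An object of class `"nspace_params"`.
#' @seealso [zspace_params()] for the log-abundance analogue,
#'   [pi_diffusion()] which consumes these parameters.
#' @export
#' @examples
#' nspace_params(eps = 0.02, Vd = 1, Ve = 0.1)
nspace_params <- function(eps, Vd, Ve) {
  stopifnot(is.numeric(eps), length(eps) == 1L, is.finite(eps),
            is.numeric(Vd), length(Vd) == 1L, is.finite(Vd),
            is.numeric(Ve), length(Ve) == 1L, is.finite(Ve))
  if (Vd < 0) stop("'Vd' must be nonnegative")
  if (Ve < 0) stop("'Ve' must be nonnegative")
  structure(list(eps = eps, Vd = Vd, Ve = Ve), class = "nspace_params")
}

#' Per-dwell-time moment parameters on the log-abundance (z) scale
#'
#' Container for the constants describing the per-dwell-time increment of
#' \eqn{z = \ln n} in the regime where the invader is rare (no density
#' dependence):
#' \deqn{E[\Delta z] = E_0 - V_d/(2n), \qquad Var[\Delta z] = V_e + V_d/n.}
#' `E0` and `Ve` are the large-n (outer-regime) mean and environmental
#' variance of \eqn{\Delta z}; `Vd` is the demographic coefficient whose
#' \eqn{1/n} contribution dominates at small abundance.  The dwell time
#' `tau` is carried along only for the conversion to the invasion growth
#' rate, \eqn{E_r = E_0/\tau} (see [invasion_growth_rate()]).
#'
#' @param E0 per-dwell-time mean log-abundance change at large n.
#' @param Vd demographic variance coefficient in z-space (nonnegative).
#' @param Ve environmental variance of \eqn{\Delta z} at large n
#'   (nonnegative).
#' @param tau dwell time of the environment, in generations (positive).
#' @return An object of class `"zspace_params"`.
#' @seealso [pi_wkb()], [wkb_outer()], [invasion_growth_rate()].
#' @export
#' @examples
#' zspace_params(E0 = 0.1, Vd = 1, Ve = 0.09, tau = 0.2)
zspace_params <- function(E0, Vd, Ve, tau = 1) {
  stopifnot(is.numeric(E0), length(E0) == 1L, is.finite(E0),
            is.numeric(Vd), length(Vd) == 1L, is.finite(Vd),
            is.numeric(Ve), length(Ve) == 1L, is.finite(Ve),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (Vd < 0) stop("'Vd' must be nonnegative")
  if (Ve < 0) stop("'Ve' must be nonnegative")
  if (tau <= 0) stop("'tau' must be positive")
  structure(list(E0 = E0, Vd = Vd, Ve = Ve, tau = tau),
            class = "zspace_params")
}

#' @export
print.nspace_params <- function(x, ...) {
  cat("Per-dwell-time moment parameters (n-space)\n")
  cat(sprintf("  eps (mean relative growth) : %g\n", x$eps))
  cat(sprintf("  Vd  (demographic variance) : %g\n", x$Vd))
  cat(sprintf("  Ve  (environmental var.)   : %g\n", x$Ve))
  invisible(x)
}

#' @export
print.zspace_params <- function(x, ...) {
  cat("Per-dwell-time moment parameters (z = ln n space)\n")
  cat(sprintf("  E0  (mean log growth, large n) : %g\n", x$E0))
  cat(sprintf("  Vd  (demographic variance)     : %g\n", x$Vd))
  cat(sprintf("  Ve  (environmental variance)   : %g\n", x$Ve))
  cat(sprintf("  tau (dwell time, generations)  : %g\n", x$tau))
  cat(sprintf("  => invasion growth rate Er = E0/tau = %g\n", x$E0 / x$tau))
  invisible(x)
}

#' @export
print.wkb_intermediates <- function(x, ...) {
  cat("Two-destination WKB intermediates\n")
  cat(sprintf("  beta  (jump size in z)         : %g\n", x$beta))
  cat(sprintf("  alpha (forward jump prob.)     : %g\n", x$alpha))
  cat(sprintf("  q_bar (outer WKB exponent)     : %g\n", x$q_bar))
  cat(sprintf("  R     (interpolation scale)    : %g\n", x$R))
  if (isTRUE(x$env_degenerate))
    cat("  (environmental variance is zero: fixed-environment limit)\n")
  invisible(x)
}

.check_query <- function(n, nf) {
  stopifnot(is.numeric(n), is.numeric(nf), length(nf) == 1L)
  if (!all(is.finite(n)) || !is.finite(nf))
    stop("'n' and 'nf' must be finite")
  if (nf <= 0) stop("'nf' must be positive")
  if (any(n < 0)) stop("'n' must be nonnegative")
  if (any(n > nf)) stop("'n' must not exceed the target abundance 'nf'")
  invisible(TRUE)
}
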