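# Closed-form invasion probabilities and their limiting branches.
#
# Both formulae have the structure
#     Pi(n -> nf) = (1 - (1 + n*r)^q) / (1 - (1 + nf*r)^q)
# for a scale r and exponent q, and are evaluated throughout as
#     expm1(q * log1p(n*r)) / expm1(q * log1p(nf*r)),
# which is free of cancellation for q -> 0 and safe in log space for large
# |q|.  Only q == 0 exactly takes the analytic logarithmic limit.

# (1 - e^a)/(1 - e^b) = expm1(a)/expm1(b), guarded against overflow.
.expm1_ratio <- function(a, b) {
  big <- 700
  if (a < big && b < big) return(expm1(a) / expm1(b))
  if (a >= big && b >= big) return(exp(a - b))
  if (b >= big) return(expm1(a) * exp(-b))
  exp(a - log(abs(expm1(b)))) * sign(expm1(b))
}

# Absorb floating-point dust only; larger violations indicate misuse.
.clip01 <- function(x, tol = 1e-12) {
  if (any(x < -tol | x > 1 + tol, na.rm = TRUE))
    stop("computed probability falls outside [0, 1] beyond rounding noise; ",
         "check the parameter values")
  pmin(pmax(x, 0), 1)
}

.pi_fixed1 <- function(n, nf, growth, Vd) {
  if (growth == 0) return(n / nf)
  .expm1_ratio(-2 * growth * n / Vd, -2 * growth * nf / Vd)
}

#' Invasion probability in a fixed environment
#'
#' Classical establishment probability of a lineage with constant
#' per-dwell-time mean growth and purely demographic noise,
#' \deqn{\Pi(n \to n_f) = \frac{1 - e^{-2\,growth\, n/V_d}}
#'                             {1 - e^{-2\,growth\, n_f/V_d}},}
#' with the neutral limit \eqn{n/n_f} when `growth = 0`.  This is the limit
#' of both [pi_diffusion()] and [pi_wkb()] as the environmental variance
#' vanishes.
#'
#' @param n initial abundance (nonnegative real, vectorised).
#' @param nf target abundance (positive real, `n <= nf`).
#' @param growth per-dwell-time mean growth (selection) coefficient.
#' @param Vd demographic variance coefficient, strictly positive.
#' @return Probability (vector along `n`) in `[0, 1]`.
#' @export
#' @examples
#' pi_fixed_env(1, 200, growth = 0.05, Vd = 1)  # (1-e^-0.1)/(1-e^-20)
#' pi_fixed_env(5, 50, growth = 0)              # neutral: n/nf = 0.1
pi_fixed_env <- function(n, nf, growth, Vd = 1) {
  .check_query(n, nf)
  stopifnot(is.numeric(growth), length(growth) == 1L, is.finite(growth),
            is.numeric(Vd), length(Vd) == 1L)
  if (Vd <= 0) stop("'Vd' must be strictly positive")
  .clip01(vapply(n, .pi_fixed1, numeric(1), nf = nf,
                 growth = growth, Vd = Vd))
}

#' Quenched-regime invasion probability
#'
#' When the environmental dwell time exceeds the typical invasion time, the
#' environment is effectively frozen during each invasion attempt, and the
#' overall invasibility is the weighted average of fixed-environment
#' probabilities over the environmental states.
#'
#' @param n,nf initial and target abundance as in [pi_fixed_env()].
#' @param growth numeric vector of per-dwell-time growth coefficients, one
#'   per environmental state.
#' @param weights nonnegative state weights summing to 1 (default uniform).
#' @param Vd demographic variance coefficient, strictly positive.
#' @return Probability (vector along `n`).
#' @export
#' @examples
#' # two equally likely environments of opposite selection
#' pi_quenched(1, 200, growth = c(0.05, -0.05), Vd = 1)
pi_quenched <- function(n, nf, growth, weights = NULL, Vd = 1) {
  stopifnot(is.numeric(growth))
  if (length(growth) == 0L) stop("'growth' must name at least one state")
  if (is.null(weights)) weights <- rep(1 / length(growth), length(growth))
  stopifnot(length(weights) == length(growth))
  if (any(weights < 0)) stop("'weights' must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-6) stop("'weights' must sum to 1")
  out <- 0
  for (i in seq_along(growth))
    out <- out + weights[i] * pi_fixed_env(n, nf, growth[i], Vd)
  .clip01(out)
}

.pi_da1 <- function(n, nf, eps, Vd, Ve) {
  if (n == 0) return(0)
  if (n == nf) return(1)
  if (Vd == 0) {
    # pure environmental noise: analytic Vd -> 0 limit of the formula
    Q <- 1 - 2 * eps / Ve
    return(if (Q > 0) (n / nf)^Q else 1)
  }
  if (.ve_negligible(eps, Ve) || Ve == 0)
    return(.pi_fixed1(n, nf, eps, Vd))
  if (eps == 0) return(n / nf)   # Q = 1: exact neutral collapse
  R <- Ve / Vd
  Q <- 1 - 2 * eps / Ve
  if (Q == 0) return(log1p(n * R) / log1p(nf * R))
  .expm1_ratio(Q * log1p(n * R), Q * log1p(nf * R))
}

#' Invasion probability under the diffusion approximation
#'
#' Closed-form solution of the continuum backward equation
#' \eqn{E[\Delta n]\Pi' + \tfrac12 Var[\Delta n]\Pi'' = 0} with
#' \eqn{E[\Delta n] = \epsilon n} and
#' \eqn{Var[\Delta n] = V_d n + V_e n^2}:
#' \deqn{\Pi(n \to n_f) = \frac{1 - (1 + n\mathcal{R})^{Q}}
#'                             {1 - (1 + n_f\mathcal{R})^{Q}}, \qquad
#'       \mathcal{R} = V_e/V_d,\; Q = 1 - 2\epsilon/V_e.}
#' Limiting branches are taken analytically: `eps = 0` returns exactly
#' `n/nf`; numerically negligible `Ve` (zero, `< 1e-8 * eps^2`, or
#' `< 1e-9`) returns the fixed-environment formula; `Q = 0` returns the
#' logarithmic limit; `Vd = 0` (pure environmental noise, only allowed
#' for `n >= 1`) returns the \eqn{V_d \to 0} limit.
#'
#' Valid for weak selection and weak fluctuations; for strong noise prefer
#' [pi_wkb()].  `n` and `nf` are continuous positive reals: the formula is
#' a continuum object even though the underlying populations are discrete.
#'
#' @param n initial abundance (vectorised).
#' @param nf target abundance.
#' @param params an [nspace_params()] object.
#' @return Probability (vector along `n`) in `[0, 1]`.
#' @export
#' @examples
#' p <- nspace_params(eps = 0.02, Vd = 1, Ve = 0.1)
#' pi_diffusion(1, 200, p)
pi_diffusion <- function(n, nf, params) {
  stopifnot(inherits(params, "nspace_params"))
  .check_query(n, nf)
  if (params$Vd == 0) {
    if (params$Ve == 0)
      stop("'Vd' and 'Ve' cannot both be zero")
    if (any(n < 1 & n > 0))
      stop("with no demographic noise (Vd = 0) there is no absorption at ",
           "zero; initial abundances below 1 are not meaningful")
  }
  .clip01(vapply(n, .pi_da1, numeric(1), nf = nf,
                 eps = params$eps, Vd = params$Vd, Ve = params$Ve))
}

#' Outer-regime two-destination WKB intermediates
#'
#' Reduces the per-dwell-time jump distribution of \eqn{\Delta z} in the
#' outer (large-n) regime to a two-destination walk with jump size
#' \eqn{\beta = \sqrt{E[\Delta z^2]} = \sqrt{V_e + E_0^2}} and forward
#' probability \eqn{\alpha = 1/2 + E_0/(2\beta)}, which preserves the first
#' two moments exactly.  The nontrivial WKB exponent is
#' \eqn{\bar q = \ln[(1-\alpha)/\alpha]/\beta} and the abundance scale of
#' the inner/outer interpolation is \eqn{R = -2E_0/(\bar q V_d)}.
#'
#' `1 - alpha` is computed as \eqn{V_e/(2\beta(\beta+E_0))} (and
#' symmetrically for negative `E0`), so \eqn{\bar q} stays accurate even
#' when \eqn{V_e \ll E_0^2}.  For `E0 = 0` the analytic limits
#' \eqn{\bar q = 0}, \eqn{R = V_e/V_d} are returned; for `Ve = 0` a
#' degenerate fixed-environment result is flagged (`env_degenerate`),
#' consumed by [pi_wkb()].
#'
#' @param params a [zspace_params()] object; `Vd` must be positive.
#' @return An object of class `"wkb_intermediates"`: list with elements
#'   `beta`, `alpha`, `q_bar`, `R`, `env_degenerate`.
#' @export
#' @examples
#' wkb_outer(zspace_params(E0 = 0.1, Vd = 1, Ve = 0.09))
wkb_outer <- function(params) {
  stopifnot(inherits(params, "zspace_params"))
  E0 <- params$E0; Vd <- params$Vd; Ve <- params$Ve
  if (Vd <= 0)
    stop("'Vd' must be strictly positive (R is undefined otherwise)")
  if (E0 == 0 && Ve == 0)
    stop("'E0' and 'Ve' cannot both be zero")
  if (Ve == 0) {
    return(structure(list(beta = abs(E0),
                          alpha = if (E0 > 0) 1 else 0,
                          q_bar = -sign(E0) * Inf,
                          R = 0,
                          env_degenerate = TRUE),
                     class = "wkb_intermediates"))
  }
  beta <- sqrt(Ve + E0^2)
  if (E0 >= 0) {
    bp <- beta + E0           # beta + E0, no cancellation
    bm <- Ve / bp             # beta - E0 = Ve/(beta + E0)
  } else {
    bm <- beta - E0
    bp <- Ve / bm
  }
  alpha <- bp / (2 * beta)
  if (E0 == 0) {
    q_bar <- 0
    R <- Ve / Vd              # analytic q_bar -> 0 limit of -2*E0/(q_bar*Vd)
  } else {
    q_bar <- (log(bm) - log(bp)) / beta
    R <- -2 * E0 / (q_bar * Vd)
  }
  structure(list(beta = beta, alpha = alpha, q_bar = q_bar, R = R,
                 env_degenerate = FALSE),
            class = "wkb_intermediates")
}

#' Interpolated WKB exponent profile
#'
#' The local exponent \eqn{q(n)} interpolating between the inner
#' (demographic, \eqn{q_{in}(n) = -2E_0 n/V_d}) and outer (environmental,
#' \eqn{\bar q}) regimes:
#' \deqn{q(n) = \frac{-2E_0 n}{V_d - 2E_0 n/\bar q}.}
#'
#' @param n abundance (vectorised).
#' @param params a [zspace_params()] object.
#' @return Numeric vector of exponent values.
#' @export
wkb_q_interp <- function(n, params) {
  w <- wkb_outer(params)
  if (w$env_degenerate) return(-2 * params$E0 * n / params$Vd)
  if (params$E0 == 0) return(rep(0, length(n)))
  -2 * params$E0 * n / (params$Vd - 2 * params$E0 * n / w$q_bar)
}

# Environmental variance numerically negligible: whenever Ve (hence R) is
# tiny either relative to E0^2 or absolutely, the interpolated formula and
# the fixed-environment formula agree to within q_bar*n^2*R^2/2 in the
# exponent, while direct evaluation converges to that limit only
# logarithmically in Ve; branch to the limit explicitly.
.ve_negligible <- function(E0, Ve) {
  E0 != 0 && (Ve == 0 || Ve < 1e-8 * E0^2 || Ve < 1e-9)
}

.pi_wkb1 <- function(n, nf, E0, Vd, Ve) {
  if (n == 0) return(0)
  if (n == nf) return(1)
  if (.ve_negligible(E0, Ve)) return(.pi_fixed1(n, nf, E0, Vd))
  if (E0 == 0) {
    # q_bar -> 0: Pi = ln(1 + n Ve/Vd)/ln(1 + nf Ve/Vd)
    return(log1p(n * Ve / Vd) / log1p(nf * Ve / Vd))
  }
  w <- wkb_outer(zspace_params(E0 = E0, Vd = Vd, Ve = Ve))
  .expm1_ratio(w$q_bar * log1p(n * w$R), w$q_bar * log1p(nf * w$R))
}

#' Invasion probability from the WKB (large-deviations) formula
#'
#' The two-destination WKB invasion formula
#' \deqn{\Pi(n \to n_f) = \frac{1 - (1 + nR)^{\bar q}}
#'                             {1 - (1 + n_f R)^{\bar q}},}
#' with \eqn{\bar q} and \eqn{R} from [wkb_outer()].  Unlike the diffusion
#' approximation it remains accurate under strong selection and strong
#' environmental fluctuations, and it converges to [pi_fixed_env()] as the
#' environmental variance vanishes.  Analytic branches: `E0 = 0` uses the
#' logarithmic \eqn{\bar q \to 0} limit; numerically negligible `Ve`
#' (zero, `< 1e-8 * E0^2`, or `< 1e-9`) uses the fixed-environment formula.
#'
#' @param n initial abundance (vectorised).
#' @param nf target abundance.
#' @param params a [zspace_params()] object; `Vd` must be positive.
#' @return Probability (vector along `n`) in `[0, 1]`, nondecreasing in `n`.
#' @export
#' @examples
#' p <- zspace_params(E0 = 0.1, Vd = 1, Ve = 0.09)
#' pi_wkb(1, 200, p)
pi_wkb <- function(n, nf, params) {
  stopifnot(inherits(params, "zspace_params"))
  .check_query(n, nf)
  if (params$Vd <= 0)
    stop("'Vd' must be strictly positive")
  if (params$E0 == 0 && params$Ve == 0)
    stop("'E0' and 'Ve' cannot both be zero")
  .clip01(vapply(n, .pi_wkb1, numeric(1), nf = nf,
                 E0 = params$E0, Vd = params$Vd, Ve = params$Ve))
}

#' Extinction threshold of an infinite-population model
#'
#' The abundance \eqn{n_{th} = V_d/V_e} at which demographic and
#' environmental variance contributions are equal.  Infinite-population
#' (environmental-noise-only) models reproduce the finite-population
#' invasion probability when an absorbing boundary is placed at this
#' threshold.
#'
#' @param params an [nspace_params()] object with `Ve > 0`.
#' @return The threshold abundance; `Inf` with a warning when `Ve = 0`
#'   (no finite threshold exists).
#' @export
#' @examples
#' extinction_threshold(nspace_params(0, Vd = 1, Ve = 0.04))  # 25
extinction_threshold <- function(params) {
  stopifnot(inherits(params, "nspace_params"))
  if (params$Ve == 0) {
    warning("environmental variance is zero: no finite extinction threshold")
    return(Inf)
  }
  params$Vd / params$Ve
}

#' Natural target abundance for establishment
#'
#' For a positively growing invader (\eqn{E_0 > 0}, hence \eqn{\bar q < 0})
#' a natural, parameter-free definition of the establishment target is the
#' abundance above which extinction becomes unlikely,
#' \eqn{n_f \sim e^{1/|\bar q|}/R}.
#'
#' @param w a `"wkb_intermediates"` object (from [wkb_outer()]) or a
#'   [zspace_params()] object, which is passed through [wkb_outer()].
#' @return The suggested target abundance.
#' @export
#' @examples
#' natural_target_abundance(wkb_outer(zspace_params(0.1, 1, 0.09)))
natural_target_abundance <- function(w) {
  if (inherits(w, "zspace_params")) w <- wkb_outer(w)
  stopifnot(inherits(w, "wkb_intermediates"))
  if (w$q_bar >= 0)
    stop("only defined for positive mean growth (q_bar < 0)")
  if (w$R <= 0) stop("'R' must be positive")
  exp(1 / abs(w$q_bar)) / w$R
}
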