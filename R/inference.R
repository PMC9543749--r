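# Moment-regression inference of the per-dwell-time parameters from
# abundance time series sampled at the dwell time tau.
#
# n-space:  E[dn | n] = eps * n,      Var[dn | n] = Vd * n + Ve * n^2
# z-space:  E[dz | n] = E0 - Vd/(2n), Var[dz | n] = Ve + Vd/n
#
# Transitions are pooled into logarithmic abundance bins; per-bin moments
# are fitted by weighted least squares with bin-count weights.  Abundance
# visits are roughly geometric over n, which is why the bins are
# logarithmic.

.bin_index <- function(n, bins_per_decade) {
  as.integer(floor(bins_per_decade * log10(n) + 1e-9))
}

# Per-bin summaries used by both fits.
.bin_summaries <- function(n, y, bins_per_decade, min_per_bin) {
  idx <- .bin_index(n, bins_per_decade)
  f <- factor(idx)
  cnt <- as.integer(table(f))
  keep <- cnt >= min_per_bin
  if (sum(keep) < 2L)
    stop("insufficient abundance range: fewer than 2 bins with at least ",
         min_per_bin, " transitions")
  data.frame(
    bin      = as.integer(levels(f))[keep],
    count    = cnt[keep],
    mean_n   = as.numeric(tapply(n, f, mean))[keep],
    mean_n2  = as.numeric(tapply(n^2, f, mean))[keep],
    mean_inv = as.numeric(tapply(1 / n, f, mean))[keep],
    mean_y   = as.numeric(tapply(y, f, mean))[keep],
    var_y    = as.numeric(tapply(y, f, function(v) mean((v - mean(v))^2)))[keep]
  )
}

.wls <- function(x, y, w) {
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  cf <- unname(fit$coefficients)
  list(intercept = cf[1L], slope = cf[2L],
       resid_rms = sqrt(stats::weighted.mean(fit$residuals^2, w)))
}

.as_transitions <- function(x, ...) {
  if (is.data.frame(x) && all(c("n", "dn") %in% names(x))) return(x)
  transitions(x)
}

#' Infer n-space parameters from an abundance time series
#'
#' Reconstructs `(eps, Vd, Ve)` of [nspace_params()] from adjacent-sample
#' transitions.  `eps` is the slope of a zero-intercept weighted regression
#' of the per-bin mean increment on the per-bin mean abundance.  The
#' variance coefficients come from the per-bin second moment of the
#' residuals `dn - eps*n`: dividing by the mean abundance turns
#' `Vd*n + Ve*n^2` into a straight line whose intercept is `Vd` and slope
#' is `Ve` (the regressor is `E[n^2]/E[n]` per bin, exact for within-bin
#' abundance spread).  Negative fitted variance coefficients are truncated
#' at zero and flagged.
#'
#' Demographically induced jumps are symmetric on the abundance scale, so
#' `eps` is estimated without demographic bias even at small abundances —
#' the practical advantage of the n-space route when data are scarce at
#' large abundance.
#'
#' @param x an [abundance_series()], a list of them, or a transitions data
#'   frame from [transitions()].
#' @param bins_per_decade logarithmic binning density (default 12).
#' @param min_per_bin minimum transitions per usable bin (default 50).
#' @return An object of class `"inference_report"` with elements `params`
#'   (an [nspace_params()]), `bins`, `flags`, and fit diagnostics.
#' @export
infer_nspace <- function(x, bins_per_decade = 12, min_per_bin = 50) {
  tr <- .as_transitions(x)
  flags <- character()
  b <- .bin_summaries(tr$n, tr$dn, bins_per_decade, min_per_bin)
  # eps: zero-intercept WLS of per-bin E[dn] on per-bin E[n]
  eps <- sum(b$count * b$mean_y * b$mean_n) / sum(b$count * b$mean_n^2)
  # residual second moments about the fitted mean, per bin
  idx <- .bin_index(tr$n, bins_per_decade)
  f <- factor(idx)
  res2 <- tapply((tr$dn - eps * tr$n)^2, f, mean)
  res2 <- as.numeric(res2)[as.integer(levels(f)) %in% b$bin]
  yv <- res2 / b$mean_n
  xv <- b$mean_n2 / b$mean_n
  fit <- .wls(xv, yv, b$count)
  Vd <- fit$intercept; Ve <- fit$slope
  if (Vd < 0) { flags <- c(flags, "Vd_truncated_at_zero"); Vd <- 0 }
  if (Ve < 0) { flags <- c(flags, "Ve_truncated_at_zero"); Ve <- 0 }
  structure(list(
    space = "n",
    params = nspace_params(eps = eps, Vd = Vd, Ve = Ve),
    bins = b,
    n_transitions = nrow(tr),
    mean_fit = list(eps = eps),
    var_fit = list(intercept = fit$intercept, slope = fit$slope,
                   resid_rms = fit$resid_rms),
    flags = flags
  ), class = "inference_report")
}

#' Infer z-space parameters from an abundance time series
#'
#' Reconstructs `(E0, Vd, Ve)` of [zspace_params()] from the log-abundance
#' increments `dz = ln(n + dn) - ln(n)`.  Transitions whose destination is
#' zero abundance are removed before taking logarithms (their count is
#' reported): this zero-transition filter induces an artificial positive
#' bias in the mean increment at very small abundance, so bins below a
#' cutoff `n_min` are excluded from the mean fit.
#'
#' Regressions against the per-bin mean of `1/n` are performed: the mean
#' fit (`E[dz]` on `1/n`; intercept `E0`, slope `-Vd/2`) and the variance
#' fit (`Var[dz]` on `1/n`; intercept `Ve`, slope `Vd`).  The variance-fit
#' `Vd` is reported as primary — it uses no small-n mean data and is
#' unaffected by the zero-filter bias.  A diagnostic mean-fit `Vd`
#' (`Vd_mean_fit`) is also reported, from a mean fit over all bins whose
#' zero-filter loss is negligible (`zero_frac <= 1e-3`): the `1/n` term
#' only has leverage at small abundance, so this diagnostic keeps the
#' small-n bins that the `E0` fit excludes.
#'
#' `n_min = "auto"` takes five times the demographic/selection crossover
#' `Vd/(2|E0|)` estimated from an initial fit over all bins, refined once
#' (restrict, refit, recompute the cutoff, fit again), and is lowered
#' (with a flag) if fewer than two bins would survive.
#'
#' @inheritParams infer_nspace
#' @param tau dwell time carried into the returned [zspace_params()]
#'   (default 1; when `x` is an [abundance_series()] its `dt` is used).
#' @param n_min abundance cutoff for the mean fit, or `"auto"`.
#' @param zero_frac_max bins losing a larger fraction of their transitions
#'   to the zero filter are excluded from every z-space fit (conditioning
#'   on survival distorts both moments there).
#' @return An object of class `"inference_report"` with elements `params`
#'   (a [zspace_params()]), `bins`, `n_zero_filtered`, `flags`, and both
#'   fits' diagnostics.
#' @export
infer_zspace <- function(x, bins_per_decade = 12, min_per_bin = 50,
                         tau = NULL, n_min = "auto",
                         zero_frac_max = 1e-3) {
  if (is.null(tau))
    tau <- if (inherits(x, "abundance_series")) attr(x, "dt")
           else if (is.list(x) && !is.data.frame(x) &&
                    inherits(x[[1L]], "abundance_series")) attr(x[[1L]], "dt")
           else 1
  tr <- .as_transitions(x)
  flags <- character()
  dest <- tr$n + tr$dn
  n_zero <- sum(dest == 0)
  zero_origins <- tr$n[dest == 0]
  tr <- tr[dest > 0, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no transitions remain after zero filtering")
  dz <- log1p(tr$dn / tr$n)
  b <- .bin_summaries(tr$n, dz, bins_per_decade, min_per_bin)
  # fraction of transitions removed by the zero filter, per bin: where it
  # is non-negligible the bin's mean dz carries the artificial positive
  # bias of conditioning on survival
  zc <- table(factor(.bin_index(zero_origins, bins_per_decade),
                     levels = b$bin))
  b$zero_frac <- as.numeric(zc) / (b$count + as.numeric(zc))
  # All z-space fits are restricted to bins whose zero-filter loss is
  # negligible: conditioning on survival both inflates the mean and
  # deflates the variance of dz where transitions to zero are common.
  usable <- b$zero_frac <= zero_frac_max
  if (sum(usable) < 2L)
    stop("insufficient abundance range: zero-filter losses contaminate ",
         "all but ", sum(usable), " bins")
  if (!all(usable)) flags <- c(flags, "zero_biased_bins_excluded")
  b_all <- b
  b <- b[usable, , drop = FALSE]
  # variance fit: Var[dz] = Ve + Vd/n  (primary source of Vd and Ve)
  vfit <- .wls(b$mean_inv, b$var_y, b$count)
  Ve <- vfit$intercept; Vd <- vfit$slope
  if (Ve < 0) { flags <- c(flags, "Ve_truncated_at_zero"); Ve <- 0 }
  if (Vd < 0) { flags <- c(flags, "Vd_truncated_at_zero"); Vd <- 0 }
  # mean fit: E[dz] = E0 - Vd/(2n), restricted to n >= n_min.  The
  # zero-transition filter biases the small-n bin means upward, which in
  # turn biases the all-bins intercept, so the auto cutoff is refined once:
  # fit over all bins for a first E0 guess, restrict, refit, recompute the
  # cutoff from the refined E0, and fit a final time.
  fit_mean <- function(bb) .wls(bb$mean_inv, bb$mean_y, bb$count)
  restrict <- function(n_min_val) {
    keep <- b$mean_n >= n_min_val
    if (sum(keep) < 2L) {
      # keep the two largest-abundance bins so the fit stays identified
      keep <- rank(-b$mean_n) <= 2
      flags <<- unique(c(flags, "n_min_lowered_to_keep_two_bins"))
      n_min_val <- min(b$mean_n[keep])
    }
    list(keep = keep, n_min = n_min_val)
  }
  auto_cut <- function(E0_guess)
    if (E0_guess != 0 && Vd > 0) 5 * Vd / (2 * abs(E0_guess)) else 0
  if (identical(n_min, "auto")) {
    E0_guess <- fit_mean(b)$intercept
    r1 <- restrict(auto_cut(E0_guess))
    E0_guess <- fit_mean(b[r1$keep, , drop = FALSE])$intercept
    rs <- restrict(auto_cut(E0_guess))
  } else {
    rs <- restrict(as.numeric(n_min))
  }
  keep <- rs$keep
  n_min_val <- rs$n_min
  mfit <- fit_mean(b[keep, , drop = FALSE])
  E0 <- mfit$intercept
  # diagnostic mean-fit Vd: uses all usable bins — the 1/n term only has
  # leverage at small abundance, which the E0 fit excludes
  mdiag <- fit_mean(b)
  Vd_mean <- -2 * mdiag$slope
  structure(list(
    space = "z",
    params = zspace_params(E0 = E0, Vd = Vd, Ve = Ve, tau = tau),
    bins = b,
    bins_all = b_all,
    n_transitions = nrow(tr),
    n_zero_filtered = n_zero,
    n_min = n_min_val,
    bins_in_mean_fit = sum(keep),
    mean_fit = list(E0 = E0, slope = mfit$slope, Vd_mean_fit = Vd_mean,
                    resid_rms = mfit$resid_rms),
    var_fit = list(intercept = vfit$intercept, slope = vfit$slope,
                   resid_rms = vfit$resid_rms),
    flags = flags
  ), class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat(sprintf("Inference report (%s-space), %d transitions in %d bins\n",
              x$space, x$n_transitions, nrow(x$bins)))
  print(x$params)
  if (!is.null(x$n_zero_filtered))
    cat(sprintf("  transitions to zero filtered out: %d\n",
                x$n_zero_filtered))
  if (!is.null(x$mean_fit$Vd_mean_fit))
    cat(sprintf("  diagnostic Vd from mean fit: %g (n_min = %g)\n",
                x$mean_fit$Vd_mean_fit, x$n_min))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Dwell time from the integrated autocorrelation of a signal
#'
#' The environment stays in each state for a dwell period and then takes an
#' uncorrelated new value, so its autocorrelation time is half the dwell
#' time: the dwell time equals twice the integrated autocorrelation time of
#' the signal.  The integrated time is estimated as
#' \eqn{(1/2 + \sum_k \rho_k)\, dt}, summing the empirical autocorrelation
#' from lag 1 up to (excluding) its first non-positive value — the standard
#' initial-positive-sequence truncation.
#'
#' The signal may be the environmental state itself or, when that is not
#' observed, the large-abundance log-abundance increments, whose
#' correlation is inherited from the environment.
#'
#' @param signal numeric time series, sampled every `dt`.
#' @param dt sampling interval of the signal (generations).
#' @param lag_max maximum lag examined (default `min(length - 1, 1000)`).
#' @return The dwell time tau (numeric), with attribute
#'   `"t_autocorrelation"`; when the lag-1 autocorrelation is already
#'   non-positive the sampling is too coarse to resolve persistence and
#'   `tau = dt` is returned with a warning.
#' @export
#' @examples
#' set.seed(1)
#' env <- rep(sample(c(-1, 1), 300, TRUE), each = 5)  # redrawn every 5 samples
#' estimate_dwell_time(env, dt = 0.1)                 # ~ 0.5
estimate_dwell_time <- function(signal, dt = 1,
                                lag_max = min(length(signal) - 1L, 1000L)) {
  stopifnot(is.numeric(signal), length(signal) >= 10L, dt > 0)
  if (stats::sd(signal) == 0)
    stop("constant signal: autocorrelation is undefined")
  rho <- as.numeric(stats::acf(signal, lag.max = lag_max,
                               plot = FALSE)$acf)[-1L]
  if (rho[1L] <= 0) {
    warning("autocorrelation indistinguishable from zero at lag 1: ",
            "sampling too coarse, reporting tau = dt")
    tact <- dt / 2
  } else {
    stop_at <- which(rho <= 0)
    upto <- if (length(stop_at)) stop_at[1L] - 1L else length(rho)
    tact <- (0.5 + sum(rho[seq_len(upto)])) * dt
  }
  tau <- 2 * tact
  attr(tau, "t_autocorrelation") <- tact
  tau
}

#' Invasion growth rate from z-space parameters
#'
#' The classical mean growth rate of a rare species, per unit time:
#' \eqn{E_r = E_0/\tau}.  It is the binary invasion criterion of modern
#' coexistence theory; the invasion formulae of this package supersede it
#' as a quantitative metric.
#'
#' @param params a [zspace_params()] object.
#' @return Numeric `Er`.
#' @export
#' @examples
#' invasion_growth_rate(zspace_params(E0 = 0.02, Vd = 1, Ve = 0.01, tau = 0.2))
invasion_growth_rate <- function(params) {
  stopifnot(inherits(params, "zspace_params"))
  params$E0 / params$tau
}
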