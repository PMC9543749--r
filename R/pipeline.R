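# Orchestration of the validation pipeline: generate a calibration series,
# infer parameters, evaluate both formulae, measure the true invasion
# probability by Monte Carlo, and tabulate the comparison.

#' Calibration transitions from a reflecting-band run
#'
#' Generates per-dwell-time transitions for parameter inference by running
#' `reps` replicate trajectories and re-seeding any trajectory that leaves
#' the abundance band `[1, band_hi]` back at `n_init` (absorption at zero
#' or escape above the band).  All genuine model transitions are recorded
#' — including those into zero abundance, which the z-space analysis
#' filters itself — while the artificial re-seeding jumps are excluded, so
#' every abundance bin stays populated without biasing the statistics.
#'
#' @param config a [lottery_config()].
#' @param n_transitions approximate total number of transitions wanted.
#' @param model `"lottery"` (discrete-time steps) or `"moran"` (dwell-long
#'   blocks of elementary events).
#' @param reps number of parallel replicate trajectories (default 100).
#' @param band_hi top of the abundance band; default
#'   `max(2 * nf_hint, min(5 * nf_hint, 0.05 * N))` keeps the band inside
#'   the density-independent regime.
#' @param n_init re-seeding abundance (default `band_hi / 2`).
#' @param nf_hint target abundance the band should cover (default 200).
#' @param seed optional RNG seed.
#' @return A transitions data frame (columns `n`, `dn`) ready for
#'   [infer_nspace()] / [infer_zspace()].
#' @export
calibration_transitions <- function(config, n_transitions,
                                    model = c("lottery", "moran"),
                                    reps = 100L, band_hi = NULL,
                                    n_init = NULL, nf_hint = 200,
                                    seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(config, "lottery_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  if (is.null(band_hi))
    band_hi <- max(2 * nf_hint, min(5 * nf_hint, floor(0.05 * N)))
  band_hi <- min(band_hi, N - 1L)
  if (is.null(n_init)) n_init <- max(1L, floor(band_hi / 2))
  reps <- as.integer(reps)
  steps <- as.integer(ceiling(n_transitions / reps))
  n <- rep(as.integer(n_init), reps)
  k_env <- max(1L, as.integer(ceiling(config$tau * N)))
  orig <- matrix(0L, steps, reps)
  dest <- matrix(0L, steps, reps)
  for (step in seq_len(steps)) {
    orig[step, ] <- n
    if (model == "lottery") {
      n2 <- .lottery_step(n, config, .draw_env(reps, config$env_dist))
    } else {
      # one dwell period = k_env elementary Moran events
      eta <- .draw_env(reps, config$env_dist)
      s <- config$s0 + config$sigma * eta
      n2 <- n
      for (ev in seq_len(k_env)) {
        death_inv <- stats::runif(reps) < n2 / N
        p <- n2 * exp(s) / (n2 * exp(s) + (N - n2))
        birth_inv <- stats::runif(reps) < p
        n2 <- n2 - death_inv + birth_inv
      }
    }
    dest[step, ] <- n2
    # re-seed trajectories that left the band (after recording the
    # genuine transition that took them out)
    n <- ifelse(n2 < 1L | n2 > band_hi, as.integer(n_init), as.integer(n2))
  }
  data.frame(n = as.numeric(orig), dn = as.numeric(dest - orig))
}

#' Specification of a validation experiment
#'
#' @param model `"lottery"` or `"moran"`.
#' @param grid data frame of grid points; recognised columns are `tau`,
#'   `sigma`, `s0` (missing columns fall back to `base` values).
#' @param N community size.
#' @param n0,nf initial and target abundance of the invasion queries.
#' @param mc_replicates Monte-Carlo replicates per grid point.
#' @param calib_transitions calibration transitions per grid point.
#' @param base named list of default parameter values (`tau`, `sigma`,
#'   `s0`).
#' @param seed base seed; grid point `i` uses `seed + i`.
#' @return An object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(model = c("lottery", "moran"), grid, N,
                            n0 = 1, nf = 200, mc_replicates = 1e4,
                            calib_transitions = 2e5,
                            base = list(tau = 0.2, sigma = 0, s0 = 0),
                            seed = 1) {
  model <- match.arg(model)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  structure(list(model = model, grid = grid, N = N, n0 = n0, nf = nf,
                 mc_replicates = mc_replicates,
                 calib_transitions = calib_transitions,
                 base = base, seed = seed),
            class = "experiment_spec")
}

.grid_value <- function(grid, i, name, base) {
  if (name %in% names(grid)) grid[[name]][i] else base[[name]]
}

#' Run a simulate / infer / predict / compare experiment
#'
#' For every grid point: (1) generate a reflecting-band calibration run,
#' (2) infer the n-space and z-space parameters, (3) evaluate the
#' diffusion-approximation and WKB formulae for the invasion query
#' `(n0, nf)`, (4) measure the true invasion probability by Monte Carlo,
#' and (5) emit one comparison row.  Each grid point is independently
#' seeded (`seed + i`) so the whole table is reproducible and any single
#' point can be recomputed in isolation.  An inference failure at a grid
#' point yields a row of `NA` predictions carrying the error message; the
#' run continues.
#'
#' @param spec an [experiment_spec()].
#' @return A data frame with one row per grid point: the grid parameters,
#'   measured probability with its CI, `pi_da`, `pi_wkb`, `Er`, the
#'   inferred parameters, and diagnostics.
#' @export
run_comparison <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- vector("list", nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    tau <- .grid_value(spec$grid, i, "tau", spec$base)
    sigma <- .grid_value(spec$grid, i, "sigma", spec$base)
    s0 <- .grid_value(spec$grid, i, "s0", spec$base)
    cfg <- lottery_config(N = spec$N, s0 = s0, tau = tau, sigma = sigma)
    seed_i <- spec$seed + i
    row <- data.frame(point = i, tau = tau, sigma = sigma, s0 = s0,
                      n0 = spec$n0, nf = spec$nf, seed = seed_i,
                      measured = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, pi_da = NA_real_,
                      pi_wkb = NA_real_, Er = NA_real_,
                      eps = NA_real_, Vd_n = NA_real_, Ve_n = NA_real_,
                      E0 = NA_real_, Vd_z = NA_real_, Ve_z = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      tr <- calibration_transitions(cfg, spec$calib_transitions,
                                    model = spec$model,
                                    nf_hint = spec$nf, seed = seed_i)
      rn <- infer_nspace(tr)
      rz <- infer_zspace(tr, tau = tau)
      runner <- if (spec$model == "lottery") lottery_mc_runner(cfg)
                else moran_mc_runner(cfg)
      est <- estimate_invasion_mc(runner, spec$n0, spec$nf,
                                  spec$mc_replicates, seed = seed_i + 1L)
      row$measured <- est$probability
      row$ci_lo <- est$ci[1L]; row$ci_hi <- est$ci[2L]
      row$pi_da <- pi_diffusion(spec$n0, spec$nf, rn$params)
      row$pi_wkb <- pi_wkb(spec$n0, spec$nf, rz$params)
      row$Er <- invasion_growth_rate(rz$params)
      row$eps <- rn$params$eps; row$Vd_n <- rn$params$Vd
      row$Ve_n <- rn$params$Ve
      row$E0 <- rz$params$E0; row$Vd_z <- rz$params$Vd
      row$Ve_z <- rz$params$Ve
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}
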