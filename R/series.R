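# Abundance time series sampled at the environmental dwell time.

#' Abundance time series
#'
#' An equally spaced series of nonnegative integer abundances.  For
#' parameter inference the sampling interval `dt` must equal the dwell time
#' of the environment, so that each adjacent pair of samples spans exactly
#' one environmental state.
#'
#' @param counts nonnegative integer abundances.
#' @param dt sampling interval in generations (positive).
#' @param t0 time of the first sample (default 0).
#' @param resets optional integer indices `i` such that the step from
#'   sample `i` to `i + 1` is an artificial re-seeding event (used by
#'   reflecting-band calibration runs) and must be excluded from
#'   transition statistics.
#' @return A data frame with columns `t` and `n`, of class
#'   `"abundance_series"`, carrying `dt` and `resets` attributes.
#' @export
#' @examples
#' abundance_series(c(5, 7, 6, 9), dt = 0.2)
abundance_series <- function(counts, dt, t0 = 0, resets = integer()) {
  stopifnot(is.numeric(counts), is.numeric(dt), length(dt) == 1L)
  if (dt <= 0) stop("'dt' must be positive")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("'counts' must be integer abundances")
  out <- data.frame(t = t0 + dt * (seq_along(counts) - 1L),
                    n = as.numeric(round(counts)))
  attr(out, "dt") <- dt
  attr(out, "resets") <- as.integer(resets)
  class(out) <- c("abundance_series", "data.frame")
  out
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf("Abundance series: %d samples, dt = %g generations\n",
              nrow(x), attr(x, "dt")))
  nr <- length(attr(x, "resets"))
  if (nr > 0) cat(sprintf("  (%d re-seeding events excluded from transitions)\n", nr))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Adjacent-sample transitions of an abundance series
#'
#' Each pair of adjacent samples yields one transition
#' \eqn{(n_t, \Delta n = n_{t+\tau} - n_t)}.  Transitions originating at
#' zero abundance are dropped (no growth rate can be inferred from the
#' extinction state), as are transitions spanning a re-seeding event of a
#' reflecting-band calibration run.
#'
#' @param x an [abundance_series()], or a list of them (transitions are
#'   pooled).
#' @return A data frame with columns `n` (origin abundance) and `dn`
#'   (increment over one sampling interval).
#' @export
#' @examples
#' transitions(abundance_series(c(2, 3, 1), dt = 1))
transitions <- function(x) {
  if (is.list(x) && !inherits(x, "abundance_series")) {
    out <- do.call(rbind, lapply(x, transitions))
    if (nrow(out) == 0L) stop("no usable transitions in input series")
    return(out)
  }
  stopifnot(inherits(x, "abundance_series"))
  if (nrow(x) < 2L) stop("series must contain at least two samples")
  n0 <- x$n[-nrow(x)]
  n1 <- x$n[-1L]
  keep <- n0 > 0
  resets <- attr(x, "resets")
  if (length(resets)) keep[resets[resets <= length(keep)]] <- FALSE
  out <- data.frame(n = n0[keep], dn = (n1 - n0)[keep])
  if (nrow(out) == 0L) stop("no usable transitions (series is all zero)")
  out
}

#' Thin a series to a coarser sampling interval
#'
#' Inference assumes the sampling interval equals the dwell time; a series
#' sampled more finely must be thinned first.
#'
#' @param x an [abundance_series()].
#' @param k keep every `k`-th sample (positive integer).
#' @return A thinned [abundance_series()] with `dt` multiplied by `k`.
#' @export
thin_series <- function(x, k) {
  stopifnot(inherits(x, "abundance_series"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be a positive integer")
  if (k == 1L) return(x)
  idx <- seq(1L, nrow(x), by = k)
  abundance_series(x$n[idx], dt = attr(x, "dt") * k, t0 = x$t[1L])
}

#' Read an abundance series from CSV
#'
#' Expects a header `t,n` with equally spaced times and nonnegative integer
#' counts; malformed rows are reported with their line numbers.
#'
#' @param path path to a CSV file.
#' @return An [abundance_series()].
#' @export
read_series <- function(path) {
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(raw) == 0L) stop("'", path, "' contains no data rows")
  if (!identical(names(raw)[1:2], c("t", "n")))
    stop("'", path, "' must have header 't,n'")
  if (nrow(raw) < 2L) stop("'", path, "' must contain at least two samples")
  bad <- which(!is.finite(raw$t) | !is.finite(raw$n) | raw$n < 0 |
                 abs(raw$n - round(raw$n)) > 1e-8)
  if (length(bad))
    stop("malformed rows in '", path, "' at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (counts must be nonnegative integers)")
  dts <- diff(raw$t)
  dt <- dts[1L]
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    stop("non-constant time spacing in '", path, "' first at line ",
         which(abs(dts - dt) > 1e-6 * max(dt, 1))[1L] + 2L)
  abundance_series(raw$n, dt = dt, t0 = raw$t[1L])
}

#' Write an abundance series to CSV
#'
#' Writes columns `t,n`; [read_series()] of the result reproduces the
#' series exactly.
#'
#' @param x an [abundance_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "abundance_series"))
  utils::write.csv(data.frame(t = x$t, n = x$n), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
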