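#' Multichannel time-series container
#'
#' Thin container for an evenly sampled multichannel signal: a numeric
#' matrix with time points in rows and channels in columns, plus the
#' sampling interval \code{dt}. Frequencies reported downstream are in
#' cycles per time unit, so with annual data and \code{dt = 1} a frequency
#' of 0.04 means one cycle every 25 years.
#'
#' @param values numeric matrix, \code{n_time x n_channels}; all values
#'   finite, at least 8 rows.
#' @param dt sampling interval (> 0), default 1.
#' @param channel_names optional column labels.
#' @return object of class \code{mv_signal}.
#' @examples
#' s <- multivariate_signal(cbind(rnorm(64), rnorm(64)))
#' s
#' @export
multivariate_signal <- function(values, dt = 1, channel_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 8L) {
    stop(errorCondition(sprintf("signal too short: %d time points (need >= 8)", nrow(values)),
                        class = c("nacd_too_short", "nacd_data_error", "nacd_error", "error", "condition")))
  }
  if (!all(is.finite(values))) {
    stop(errorCondition("signal contains non-finite values",
                        class = c("nacd_data_error", "nacd_error", "error", "condition")))
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop(errorCondition("dt must be a single positive number",
                        class = c("nacd_data_error", "nacd_error", "error", "condition")))
  }
  if (!is.null(channel_names)) colnames(values) <- channel_names
  structure(list(values = values, dt = dt), class = "mv_signal")
}

as_mv_signal <- function(x, dt = 1) {
  if (inherits(x, "mv_signal")) return(x)
  multivariate_signal(as.matrix(x), dt = dt)
}

#' @export
print.mv_signal <- function(x, ...) {
  cat(sprintf("multivariate signal: %d samples x %d channels, dt = %g\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Number of time points / channels of a multichannel signal
#' @param x an \code{mv_signal}.
#' @return integer.
#' @export
n_time <- function(x) nrow(x$values)

#' @rdname n_time
#' @export
n_channels <- function(x) ncol(x$values)

# interior window used for all phase/frequency averages: drops `frac`/2 of
# the samples at each end (Hilbert and spline end effects)
interior_idx <- function(n, frac = 0.90) {
  drop <- floor(n * (1 - frac) / 2)
  seq.int(drop + 1L, n - drop)
}

# draw reproducible child seeds without disturbing the caller's RNG stream
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
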