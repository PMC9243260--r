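#' Low-discrepancy projection directions on the unit sphere
#'
#' Multivariate EMD estimates the local mean of a multichannel signal from
#' envelopes of its projections onto a set of direction vectors spread over
#' the unit \code{(n_channels - 1)}-sphere. Directions are taken from a
#' Hammersley point set mapped to the sphere, so the set is deterministic
#' and quasi-uniform. The set is closed under swapping of the first two
#' coordinates: the first half of the points is generated, the second half
#' is the coordinate-swapped copy. This makes every downstream decomposition
#' exactly equivariant under exchange of channels 1 and 2, which the causal
#' pipeline relies on.
#'
#' @param n_channels number of signal dimensions (>= 2).
#' @param n_directions number of direction vectors (>= 2 * n_channels,
#'   rounded up to an even number).
#' @return An object of class \code{direction_set}: list with \code{vectors}
#'   (\code{n_directions x n_channels} matrix of unit rows) and \code{count}.
#' @examples
#' d <- generate_directions(2, 64)
#' range(sqrt(rowSums(d$vectors^2)))
#' @export
generate_directions <- function(n_channels, n_directions = NULL) {
  if (n_channels < 2) {
    stop(errorCondition("MEMD projections are undefined for a single channel (n_channels must be >= 2)",
                        class = c("nacd_invalid_dimension", "nacd_error", "error", "condition")))
  }
  if (is.null(n_directions)) {
    n_directions <- if (n_channels <= 8) 64L else 8L * n_channels
  }
  n_directions <- as.integer(n_directions)
  if (n_directions < 2L * n_channels) {
    stop(errorCondition("n_directions must be at least 2 * n_channels",
                        class = c("nacd_invalid_dimension", "nacd_error", "error", "condition")))
  }
  if (n_directions %% 2L == 1L) n_directions <- n_directions + 1L
  half <- n_directions %/% 2L

  if (n_channels == 2L) {
    # uniform angles on the half grid; swapped copies fill the other half
    theta <- 2 * pi * (seq_len(half) - 0.5) / half
    base <- cbind(cos(theta), sin(theta))
  } else {
    # Hammersley set in [0,1]^d -> Gaussian quantiles -> normalise to sphere
    u <- matrix(0, half, n_channels)
    u[, 1] <- (seq_len(half) - 0.5) / half
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
    for (j in 2:n_channels) {
      u[, j] <- vapply(seq_len(half), van_der_corput, numeric(1),
                       base = primes[j - 1])
    }
    g <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
    base <- g / sqrt(rowSums(g^2))
  }
  swapped <- base
  swapped[, c(1L, 2L)] <- base[, c(2L, 1L)]
  vectors <- rbind(base, swapped)
  structure(list(vectors = vectors, count = nrow(vectors)),
            class = "direction_set")
}

# radical-inverse sequence used by the Hammersley construction
van_der_corput <- function(i, base) {
  v <- 0
  f <- 1 / base
  while (i > 0) {
    v <- v + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  v
}

# Local extrema of a numeric vector with plateau midpoints.
# A maximum is a +/- sign change of the first difference, possibly across a
# run of zeros; the plateau contributes its midpoint index.
find_extrema <- function(p) {
  d <- diff(p)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  sv <- s[nz]
  left <- sv[-length(sv)]
  right <- sv[-1L]
  jmax <- which(left > 0 & right < 0)
  jmin <- which(left < 0 & right > 0)
  maxima <- as.integer(floor((nz[jmax] + 1L + nz[jmax + 1L]) / 2))
  minima <- as.integer(floor((nz[jmin] + 1L + nz[jmin + 1L]) / 2))
  list(maxima = maxima, minima = minima)
}

# Cubic-spline envelope of the multichannel samples at extrema positions
# `idx`, mirror-extending two extrema past each end to damp end swings.
# Returns an n x C matrix, or NULL when fewer than two usable knots remain.
interp_envelope <- function(idx, values) {
  n <- nrow(values)
  m <- length(idx)
  if (m < 2L) return(NULL)
  lk <- min(2L, m)
  t_left <- 2 - rev(idx[seq_len(lk)])        # mirror about sample 1
  t_right <- 2 * n - rev(idx[seq.int(m - lk + 1L, m)])  # mirror about sample n
  knots <- c(t_left, idx, rev(t_right))
  rows <- c(rev(seq_len(lk)), seq_len(m), seq.int(m - lk + 1L, m))
  ord <- order(knots)
  knots <- knots[ord]
  rows <- rows[ord]
  keep <- !duplicated(knots)
  knots <- knots[keep]
  rows <- rows[keep]
  if (length(knots) < 2L) return(NULL)
  vals <- values[idx[rows], , drop = FALSE]
  out <- matrix(0, n, ncol(values))
  xout <- seq_len(n)
  for (ch in seq_len(ncol(values))) {
    out[, ch] <- stats::spline(knots, vals[, ch], xout = xout,
                               method = "natural")$y
  }
  out
}

#' Mean envelope of a multichannel signal over projection directions
#'
#' For every direction the signal is projected onto the direction vector,
#' maxima and minima of the projection are located, the multichannel samples
#' at those locations are interpolated with natural cubic splines
#' (mirror-extended at the ends), and the upper/lower envelopes are averaged.
#' The result is averaged over all usable directions. Directions whose
#' projection carries fewer than four extrema are skipped; if no direction is
#' usable the signal is flagged as monotone.
#'
#' @param signal a \code{\link{multivariate_signal}} or a numeric matrix
#'   (time in rows, channels in columns).
#' @param directions a \code{\link{generate_directions}} result.
#' @return list with \code{mean} (n_time x n_channels local-mean estimate),
#'   \code{amplitude} (per-sample mean envelope amplitude over directions)
#'   and \code{n_used} (number of usable directions), or an error of class
#'   \code{nacd_monotone_signal} when no projection has enough extrema.
#' @export
envelope_mean <- function(signal, directions) {
  values <- if (inherits(signal, "mv_signal")) signal$values else signal
  em <- envelope_mean_impl(values, directions$vectors)
  if (is.null(em)) {
    stop(errorCondition("signal is monotone in every projection direction (fewer than 4 extrema); sifting must stop",
                        class = c("nacd_monotone_signal", "nacd_error", "error", "condition")))
  }
  em
}

# returns NULL on the monotone condition instead of signalling, for use in
# the sifting loop; dispatches to the compiled core
envelope_mean_impl <- function(values, dirvecs) {
  em <- envelope_mean_cpp(values, dirvecs)
  if (em$n_used == 0L) return(NULL)
  em
}

# pure-R reference implementation of the envelope mean, kept as an
# independent cross-check of the compiled core
envelope_mean_r <- function(values, dirvecs) {
  n <- nrow(values)
  acc_mean <- matrix(0, n, ncol(values))
  acc_amp <- numeric(n)
  n_used <- 0L
  proj_all <- values %*% t(dirvecs)
  for (k in seq_len(nrow(dirvecs))) {
    ext <- find_extrema(proj_all[, k])
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L ||
        length(ext$maxima) + length(ext$minima) < 4L) next
    env_max <- interp_envelope(ext$maxima, values)
    env_min <- interp_envelope(ext$minima, values)
    if (is.null(env_max) || is.null(env_min)) next
    acc_mean <- acc_mean + (env_max + env_min)
    diffm <- env_max - env_min
    acc_amp <- acc_amp + sqrt(rowSums(diffm * diffm))
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(NULL)
  list(mean = acc_mean / (2 * n_used),
       amplitude = acc_amp / (2 * n_used),
       n_used = n_used)
}

#' Multivariate empirical mode decomposition
#'
#' Iterated sifting: the local-mean estimate from \code{\link{envelope_mean}}
#' is subtracted from the current prototype until a Rilling-style stopping
#' criterion is met, producing one intrinsic mode function (IMF) jointly
#' across channels; the IMF is subtracted from the residual and extraction
#' repeats until the residual is monotone in every projection. IMFs are
#' ordered fastest first. The decomposition is fully deterministic given its
#' arguments.
#'
#' @param signal a \code{\link{multivariate_signal}} (or numeric matrix,
#'   time x channels).
#' @param n_directions number of projection directions (default 64 for up to
#'   8 channels, otherwise 8 per channel).
#' @param stop_params numeric triple \code{(theta1, theta2, alpha)} of the
#'   Rilling envelope-amplitude criterion: sifting stops once the ratio
#'   |local mean| / envelope amplitude is below \code{theta1} on at least a
#'   fraction \code{1 - alpha} of samples and below \code{theta2} everywhere.
#' @param max_sift hard cap on sifting iterations per IMF.
#' @param max_imfs safety cap on the number of extracted IMFs.
#' @return An \code{imf_decomposition}: list with \code{imfs} (array
#'   \code{n_imfs x n_channels x n_time}), \code{residual}
#'   (\code{n_channels x n_time}), \code{n_imfs} and \code{dt}.
#' @examples
#' t <- 0:499
#' x <- sin(2 * pi * 0.05 * t) + sin(2 * pi * 0.005 * t)
#' dec <- memd(multivariate_signal(cbind(x, x)))
#' dec$n_imfs
#' @export
memd <- function(signal, n_directions = NULL,
                 stop_params = c(0.05, 0.5, 0.05),
                 max_sift = 15L, max_imfs = 30L) {
  sig <- as_mv_signal(signal)
  values <- sig$values
  n <- nrow(values)
  nc <- ncol(values)
  stopifnot(length(stop_params) == 3L)
  th1 <- stop_params[1]; th2 <- stop_params[2]; alpha <- stop_params[3]
  dirs <- generate_directions(nc, n_directions)
  dirvecs <- dirs$vectors

  r <- values
  imf_list <- list()
  repeat {
    if (length(imf_list) >= max_imfs) break
    h <- r
    em <- envelope_mean_impl(h, dirvecs)
    if (is.null(em)) break          # residual monotone: extraction finished
    iter <- 0L
    repeat {
      sx <- sqrt(rowSums(em$mean^2)) / pmax(em$amplitude, .Machine$double.xmin)
      if ((mean(sx > th1) <= alpha && all(sx < th2)) || iter >= max_sift) break
      h <- h - em$mean
      iter <- iter + 1L
      em <- envelope_mean_impl(h, dirvecs)
      if (is.null(em)) break        # over-sifted to monotone; accept h
    }
    imf_list[[length(imf_list) + 1L]] <- h
    r <- r - h
  }

  k <- length(imf_list)
  imfs <- array(0, dim = c(k, nc, n))
  for (j in seq_len(k)) imfs[j, , ] <- t(imf_list[[j]])
  structure(list(imfs = imfs, residual = t(r), n_imfs = k, dt = sig$dt),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("MEMD decomposition: %d IMFs x %d channels x %d samples (dt = %g)\n",
              x$n_imfs, dim(x$imfs)[2], dim(x$imfs)[3], x$dt))
  invisible(x)
}
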