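#' Noise-assisted ensemble configuration
#'
#' Parameters of the noise-assisted ensemble wrapper around MEMD:
#' \code{level_noise} scales the standard deviation of the auxiliary
#' Gaussian white-noise channels relative to the mean sample standard
#' deviation of the input channels; \code{noise_channel_num} auxiliary
#' channels are appended; the decomposition is repeated \code{en_num} times
#' with fresh noise and the signal-channel IMFs are averaged. \code{seed}
#' fixes every noise draw, so runs are exactly reproducible. The defaults
#' (0.001, 3, 5) are the configuration used for the robustness analysis of
#' the wolf-moose demo series; a smaller \code{noise_channel_num} of 2 is a
#' commonly recommended alternative.
#'
#' @param level_noise nonnegative noise intensity scale.
#' @param noise_channel_num integer >= 0, number of appended noise channels.
#' @param en_num integer >= 1, ensemble repetitions.
#' @param seed integer PRNG seed.
#' @return object of class \code{noise_config}.
#' @export
noise_config <- function(level_noise = 0.001, noise_channel_num = 3L,
                         en_num = 5L, seed = 1L) {
  bad <- function(msg) stop(errorCondition(msg,
    class = c("nacd_config_error", "nacd_error", "error", "condition")))
  if (!is.numeric(level_noise) || level_noise < 0) bad("level_noise must be >= 0")
  if (noise_channel_num < 0) bad("noise_channel_num must be >= 0")
  if (en_num < 1) bad("en_num must be >= 1")
  if (noise_channel_num > 0 && level_noise <= 0) {
    bad("level_noise must be > 0 when noise channels are appended")
  }
  structure(list(level_noise = as.numeric(level_noise),
                 noise_channel_num = as.integer(noise_channel_num),
                 en_num = as.integer(en_num),
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Append auxiliary white-noise channels to a signal
#'
#' Draws \code{noise_channel_num} i.i.d. Gaussian channels with mean 0 and
#' standard deviation \code{level_noise} times the mean of the input
#' channels' sample standard deviations, and binds them after the original
#' channels, which are left untouched.
#'
#' @param signal a \code{\link{multivariate_signal}}.
#' @param config a \code{\link{noise_config}}.
#' @param stream_seed integer seed for this draw (one ensemble repetition).
#' @return a \code{multivariate_signal} with
#'   \code{n_channels + noise_channel_num} channels.
#' @export
append_noise_channels <- function(signal, config, stream_seed = config$seed) {
  sig <- as_mv_signal(signal)
  m <- config$noise_channel_num
  if (m == 0L) return(sig)
  n <- nrow(sig$values)
  sd_scale <- config$level_noise * mean(apply(sig$values, 2, stats::sd))
  noise <- with_seed(stream_seed,
                     matrix(stats::rnorm(n * m, sd = sd_scale), n, m))
  multivariate_signal(cbind(sig$values, noise), dt = sig$dt)
}

#' Common IMF count across ensemble repetitions
#'
#' Repetitions of a noisy decomposition can disagree on how many IMFs they
#' extract. The ensemble keeps the minimum count: IMFs beyond it are folded
#' into the repetition's residual, and residuals are excluded from the
#' ensemble average.
#'
#' @param decompositions non-empty list of \code{\link{memd}} results.
#' @return integer, the common (minimum) IMF count.
#' @export
align_imf_counts <- function(decompositions) {
  if (length(decompositions) == 0L) {
    stop(errorCondition("empty decomposition list",
                        class = c("nacd_data_error", "nacd_error", "error", "condition")))
  }
  counts <- vapply(decompositions, function(d) as.integer(d$n_imfs),
                   integer(1))
  zero <- which(counts == 0L)
  if (length(zero) > 0L) {
    stop(errorCondition(
      sprintf("degenerate decomposition with 0 IMFs in repetition(s) %s",
              paste(zero, collapse = ", ")),
      class = c("nacd_degenerate_decomposition", "nacd_error", "error", "condition")))
  }
  min(counts)
}

#' Noise-assisted multivariate EMD
#'
#' For each of \code{en_num} repetitions, fresh Gaussian noise channels are
#' appended (an independent substream per repetition, derived from
#' \code{config$seed}), the augmented matrix is decomposed with
#' \code{\link{memd}}, and the noise-channel IMFs are discarded. IMF counts
#' are harmonized to the minimum over repetitions and the signal-channel IMF
#' stacks are averaged elementwise. The result is bit-reproducible for a
#' fixed \code{(signal, config)}.
#'
#' @param signal a \code{\link{multivariate_signal}} (typically bivariate).
#' @param config a \code{\link{noise_config}}.
#' @param n_directions,stop_params,max_sift passed to \code{\link{memd}}.
#' @return object of class \code{ensemble_imfs}: list with \code{imfs}
#'   (array \code{n_kept_imfs x n_signal_channels x n_time}),
#'   \code{n_kept_imfs}, \code{rep_imf_counts}, \code{config}, \code{dt}.
#'   Use \code{\link{channel_imfs}} to pull one channel's stack.
#' @examples
#' s <- gen_white_noise_pair(128, seed = 1)
#' e <- na_memd(s, noise_config(0.001, 2, 2, seed = 1))
#' e$n_kept_imfs
#' @export
na_memd <- function(signal, config = noise_config(),
                    n_directions = NULL, stop_params = c(0.05, 0.5, 0.05),
                    max_sift = 15L) {
  sig <- as_mv_signal(signal)
  nc_sig <- ncol(sig$values)
  rep_seeds <- derive_seeds(config$seed, config$en_num)
  decs <- vector("list", config$en_num)
  for (i in seq_len(config$en_num)) {
    aug <- append_noise_channels(sig, config, rep_seeds[i])
    decs[[i]] <- tryCatch(
      memd(aug, n_directions = n_directions, stop_params = stop_params,
           max_sift = max_sift),
      nacd_error = function(e) {
        stop(errorCondition(
          sprintf("repetition %d: %s", i, conditionMessage(e)),
          class = class(e)))
      })
  }
  k <- align_imf_counts(decs)
  n <- nrow(sig$values)
  avg <- array(0, dim = c(k, nc_sig, n))
  for (i in seq_len(config$en_num)) {
    avg <- avg + decs[[i]]$imfs[seq_len(k), seq_len(nc_sig), , drop = FALSE]
  }
  avg <- avg / config$en_num
  structure(list(imfs = avg, n_kept_imfs = k,
                 rep_imf_counts = vapply(decs, function(d) d$n_imfs, integer(1)),
                 config = config, dt = sig$dt),
            class = "ensemble_imfs")
}

#' Extract one channel's IMF stack from an ensemble decomposition
#' @param ensemble an \code{\link{na_memd}} result.
#' @param channel channel index.
#' @return matrix \code{n_kept_imfs x n_time}.
#' @export
channel_imfs <- function(ensemble, channel) {
  k <- ensemble$n_kept_imfs
  n <- dim(ensemble$imfs)[3]
  matrix(ensemble$imfs[, channel, ], nrow = k, ncol = n)
}

#' @export
print.ensemble_imfs <- function(x, ...) {
  cat(sprintf("noise-assisted ensemble decomposition: %d IMFs kept x %d channels x %d samples\n",
              x$n_kept_imfs, dim(x$imfs)[2], dim(x$imfs)[3]))
  cat(sprintf("  per-repetition IMF counts: %s (level_noise = %g, %d noise channels, en_num = %d)\n",
              paste(x$rep_imf_counts, collapse = ", "),
              x$config$level_noise, x$config$noise_channel_num, x$config$en_num))
  invisible(x)
}
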