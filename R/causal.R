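#' Select the intrinsic causal components from a phase summary
#'
#' IMF pairs qualify as intrinsic causal components (ICCs) when the two
#' channels share a frequency scale and keep a small phase difference: the
#' ratio of their average frequencies must not exceed \code{freq_ratio_max}
#' and the mean phase difference, wrapped to its principal value in
#' (-pi, pi], must not exceed \code{phase_diff_max} in absolute value (the
#' unwrapped difference accumulates arbitrary multiples of 2*pi that carry
#' no lag information). The main ICC is the member with the minimal wrapped
#' absolute phase difference; ties go to the lowest (fastest) IMF index.
#'
#' @param summary a \code{\link{pl_series}} result.
#' @param freq_ratio_max maximal allowed ratio max/min of the two average
#'   frequencies (default 2: same dyadic scale).
#' @param phase_diff_max maximal allowed |phase difference| in radians
#'   (default pi/2).
#' @return object of class \code{icc_selection}: list with
#'   \code{icc_indices}, \code{main_index}, \code{selection_mode}.
#' @export
select_iccs <- function(summary, freq_ratio_max = 2, phase_diff_max = pi / 2) {
  if (nrow(summary) == 0L) {
    stop(errorCondition("empty phase summary",
                        class = c("nacd_data_error", "nacd_error", "error", "condition")))
  }
  f1 <- summary$av_fre1
  f2 <- summary$av_fre2
  ratio <- pmax(f1, f2) / pmin(f1, f2)        # Inf when one side is 0
  # phase offsets are circular: screen on the principal value in (-pi, pi],
  # since the mean unwrapped difference accumulates arbitrary 2*pi multiples
  # (and slow drift) that carry no lag information
  wdiff <- abs(wrap_to_pi(summary$difference))
  ok <- is.finite(ratio) & ratio <= freq_ratio_max & wdiff <= phase_diff_max
  if (!any(ok)) {
    stop(errorCondition(
      "no IMF pair qualifies as an ICC; relax freq_ratio_max / phase_diff_max or supply an explicit override",
      class = c("nacd_no_icc", "nacd_error", "error", "condition")))
  }
  icc <- summary$imf_index[ok]
  main <- icc[which.min(wdiff[ok])]            # which.min: first = lowest index
  icc_selection(icc, main, "automatic")
}

# principal value of a phase difference, in (-pi, pi]
wrap_to_pi <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- pi
  w
}

#' Construct an ICC selection by hand
#'
#' Explicit, scriptable replacement for interactive ICC picking: supply the
#' accepted IMF indices and the main ICC directly (e.g. after inspecting the
#' \code{\link{pl_series}} report).
#'
#' @param icc_indices integer vector of accepted IMF indices (non-empty).
#' @param main_index the main ICC; must be one of \code{icc_indices}
#'   (default: the first).
#' @param selection_mode \code{"automatic"} or \code{"override"}.
#' @return an \code{icc_selection}.
#' @export
icc_selection <- function(icc_indices, main_index = icc_indices[1],
                          selection_mode = "override") {
  icc_indices <- sort(unique(as.integer(icc_indices)))
  main_index <- as.integer(main_index)
  if (length(icc_indices) == 0L || !(main_index %in% icc_indices)) {
    stop(errorCondition("main_index must belong to a non-empty ICC set",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  structure(list(icc_indices = icc_indices, main_index = main_index,
                 selection_mode = selection_mode),
            class = "icc_selection")
}

#' @export
print.icc_selection <- function(x, ...) {
  cat(sprintf("ICC selection (%s): indices {%s}, main ICC = %d\n",
              x$selection_mode, paste(x$icc_indices, collapse = ", "),
              x$main_index))
  invisible(x)
}

#' Remove the main ICC from a channel signal
#'
#' Subtracts the main ICC (one row of the channel's ensemble IMF stack) from
#' the raw channel; adding it back reproduces the original exactly.
#'
#' @param channel_signal numeric vector, the raw channel.
#' @param channel_imfs matrix \code{n_imfs x n_time} for that channel.
#' @param main_index row to remove.
#' @return numeric vector of the same length.
#' @export
remove_main_icc <- function(channel_signal, channel_imfs, main_index) {
  channel_imfs <- as.matrix(channel_imfs)
  if (main_index < 1L || main_index > nrow(channel_imfs)) {
    stop(errorCondition(sprintf("main_index %d out of range 1..%d",
                                main_index, nrow(channel_imfs)),
                        class = c("nacd_index_error", "nacd_error", "error", "condition")))
  }
  if (length(channel_signal) != ncol(channel_imfs)) {
    stop(errorCondition("signal and IMF stack lengths differ",
                        class = c("nacd_shape_error", "nacd_error", "error", "condition")))
  }
  as.numeric(channel_signal) - channel_imfs[main_index, ]
}

#' Variance weights over the ICC set
#'
#' Weight of ICC \code{j} is the summed sample variance of the two channels'
#' IMF \code{j}, normalized over the ICC set, so the weights sum to one.
#' These weights define the variance-weighted Euclidean distance behind the
#' absolute causal strengths.
#'
#' @param imfs1,imfs2 matrices \code{n_imfs x n_time}, the two channels'
#'   stacks.
#' @param icc an \code{\link{icc_selection}}.
#' @return nonnegative numeric vector over \code{icc$icc_indices}, summing
#'   to 1.
#' @export
icc_variance_weights <- function(imfs1, imfs2, icc) {
  idx <- icc$icc_indices
  v <- apply(as.matrix(imfs1)[idx, , drop = FALSE], 1, stats::var) +
    apply(as.matrix(imfs2)[idx, , drop = FALSE], 1, stats::var)
  tot <- sum(v)
  if (tot <= 0 || !is.finite(tot)) {
    stop(errorCondition("total ICC variance is zero; weights undefined",
                        class = c("nacd_degenerate_variance", "nacd_error", "error", "condition")))
  }
  v / tot
}

#' Variance-weighted Euclidean distance between coherence profiles
#'
#' \code{sqrt(sum(w * (original - redecomposed)^2))} over the ICC set.
#'
#' @param original_coherences,redecomposed_coherences equal-length numeric
#'   vectors of per-ICC phase coherences.
#' @param weights nonnegative weights summing to 1.
#' @return nonnegative scalar.
#' @export
coherence_distance <- function(original_coherences, redecomposed_coherences,
                               weights) {
  if (length(original_coherences) != length(redecomposed_coherences) ||
      length(original_coherences) != length(weights)) {
    stop(errorCondition("coherence vectors and weights must share a length",
                        class = c("nacd_shape_error", "nacd_error", "error", "condition")))
  }
  sqrt(sum(weights * (original_coherences - redecomposed_coherences)^2))
}

#' Absolute and relative causal strengths from coherence distances
#'
#' The absolute causal strength (ACS) of a channel is the coherence
#' disruption observed when the main ICC is removed from that channel. The
#' relative causal strengths (RCS) normalize the two ACS values to sum to
#' one; when the summed ACS does not exceed the negligibility threshold
#' (0.05 by convention) both RCS values are set to 0.5, the
#' reciprocal-or-unrelated regime.
#'
#' @param d_x,d_y nonnegative coherence distances for removal from channel 1
#'   (X) and channel 2 (Y).
#' @param negligibility threshold on \code{d_x + d_y} below which the RCS
#'   pair collapses to (0.5, 0.5).
#' @param diagnostics optional list carried through to the result.
#' @return object of class \code{causal_strengths} with fields
#'   \code{rcs_xy}, \code{rcs_yx}, \code{acs_xy}, \code{acs_yx},
#'   \code{diagnostics}.
#' @examples
#' causal_strengths(0.3, 0.1)
#' @export
causal_strengths <- function(d_x, d_y, negligibility = 0.05,
                             diagnostics = NULL) {
  if (d_x < 0 || d_y < 0) {
    stop(errorCondition("coherence distances must be nonnegative",
                        class = c("nacd_domain_error", "nacd_error", "error", "condition")))
  }
  tot <- d_x + d_y
  if (tot > negligibility) {
    rcs_xy <- d_x / tot
    rcs_yx <- d_y / tot
  } else {
    rcs_xy <- 0.5
    rcs_yx <- 0.5
  }
  structure(list(rcs_xy = rcs_xy, rcs_yx = rcs_yx,
                 acs_xy = d_x, acs_yx = d_y,
                 negligibility = negligibility,
                 diagnostics = diagnostics),
            class = "causal_strengths")
}

#' @export
print.causal_strengths <- function(x, ...) {
  cat("causal strengths (channel 1 = X, channel 2 = Y)\n")
  cat(sprintf("  RCS  X->Y: %.4f   Y->X: %.4f\n", x$rcs_xy, x$rcs_yx))
  cat(sprintf("  ACS  X->Y: %.4f   Y->X: %.4f\n", x$acs_xy, x$acs_yx))
  if (x$rcs_xy == 0.5 && x$acs_xy + x$acs_yx <= x$negligibility) {
    cat(sprintf("  (summed ACS below negligibility threshold %g: reciprocal or unrelated)\n",
                x$negligibility))
  }
  invisible(x)
}

# match every original ICC to the re-decomposed IMF with the nearest
# average frequency (log scale); returns NA where nothing lies within
# freq_ratio_max
match_iccs_by_frequency <- function(target_freqs, candidate_freqs,
                                    freq_ratio_max = 2) {
  eps <- 1e-12
  vapply(target_freqs, function(f) {
    dist <- abs(log((candidate_freqs + eps) / (f + eps)))
    j <- which.min(dist)
    if (length(j) == 0L || dist[j] > log(freq_ratio_max)) NA_integer_ else j
  }, integer(1))
}

#' Full causal decomposition of a bivariate time series
#'
#' End-to-end pipeline: ensemble decomposition of the pair
#' (\code{\link{na_memd}}), per-IMF phase summary (\code{\link{pl_series}}),
#' ICC selection (automatic or explicit override), removal of the main ICC
#' from each channel in turn, joint re-decomposition of \code{(x - ICC, y)}
#' and \code{(x, y - ICC)}, per-ICC phase coherences before and after, the
#' two variance-weighted coherence distances, and the causal strengths.
#'
#' Re-decomposed IMFs are matched to the original ICCs by nearest average
#' frequency (IMF counts can shift once a component is removed); ICCs with
#' no match within the frequency-ratio threshold in either re-decomposition
#' are dropped from the distance with a warning and the weights are
#' renormalized. Both re-decompositions share one noise substream derived
#' from \code{config$seed}, so exchanging the input channels exactly swaps
#' the reported strengths.
#'
#' @param input bivariate \code{\link{multivariate_signal}} (2 channels).
#' @param config a \code{\link{noise_config}}.
#' @param freq_ratio_max,phase_diff_max ICC screening thresholds, see
#'   \code{\link{select_iccs}}.
#' @param negligibility see \code{\link{causal_strengths}}.
#' @param icc_override optional \code{\link{icc_selection}} replacing the
#'   automatic screening.
#' @param n_directions,stop_params,max_sift passed to \code{\link{memd}}.
#' @return a \code{\link{causal_strengths}} object whose
#'   \code{diagnostics} list holds the phase summary, the selection, the
#'   per-ICC original and re-decomposed coherences (\code{p_original},
#'   \code{ps12}, \code{ps21}), the variance weights, the matched indices
#'   and the ensemble decomposition.
#' @examples
#' \donttest{
#' s <- gen_coupled_oscillators(300, coupling = 0.8, seed = 2)
#' run_causal_decomposition(s, noise_config(0.001, 2, 2, seed = 2))
#' }
#' @export
run_causal_decomposition <- function(input, config = noise_config(),
                                     freq_ratio_max = 2,
                                     phase_diff_max = pi / 2,
                                     negligibility = 0.05,
                                     icc_override = NULL,
                                     n_directions = NULL,
                                     stop_params = c(0.05, 0.5, 0.05),
                                     max_sift = 15L) {
  sig <- as_mv_signal(input)
  if (ncol(sig$values) != 2L) {
    stop(errorCondition("causal decomposition is defined for a bivariate input (2 channels)",
                        class = c("nacd_data_error", "nacd_error", "error", "condition")))
  }
  seeds <- derive_seeds(config$seed, 2L)
  cfg_orig <- config; cfg_orig$seed <- seeds[1]
  cfg_redec <- config; cfg_redec$seed <- seeds[2]

  ens <- na_memd(sig, cfg_orig, n_directions = n_directions,
                 stop_params = stop_params, max_sift = max_sift)
  imfs1 <- channel_imfs(ens, 1L)
  imfs2 <- channel_imfs(ens, 2L)
  summary <- pl_series(imfs1, imfs2, dt = sig$dt)

  sel <- if (is.null(icc_override)) {
    select_iccs(summary, freq_ratio_max, phase_diff_max)
  } else {
    if (any(icc_override$icc_indices > ens$n_kept_imfs)) {
      stop(errorCondition("icc_override indices exceed the number of kept IMFs",
                          class = c("nacd_index_error", "nacd_error", "error", "condition")))
    }
    icc_override
  }

  s1 <- sig$values[, 1L]
  s2 <- sig$values[, 2L]
  s1r <- remove_main_icc(s1, imfs1, sel$main_index)
  s2r <- remove_main_icc(s2, imfs2, sel$main_index)

  ens_x <- na_memd(multivariate_signal(cbind(s1r, s2), dt = sig$dt),
                   cfg_redec, n_directions = n_directions,
                   stop_params = stop_params, max_sift = max_sift)
  ens_y <- na_memd(multivariate_signal(cbind(s1, s2r), dt = sig$dt),
                   cfg_redec, n_directions = n_directions,
                   stop_params = stop_params, max_sift = max_sift)

  idx <- sel$icc_indices
  p_orig <- vapply(idx, function(j)
    phase_coherence(imfs1[j, ], imfs2[j, ], sig$dt), numeric(1))

  # frequency key of each ICC pair in the original decomposition
  target_freq <- (summary$av_fre1[idx] + summary$av_fre2[idx]) / 2
  coh_after <- function(ens_r) {
    a1 <- channel_imfs(ens_r, 1L)
    a2 <- channel_imfs(ens_r, 2L)
    sm <- pl_series(a1, a2, dt = sig$dt)
    cand_freq <- (sm$av_fre1 + sm$av_fre2) / 2
    m <- match_iccs_by_frequency(target_freq, cand_freq, freq_ratio_max)
    coh <- rep(NA_real_, length(idx))
    for (j in seq_along(idx)) {
      if (!is.na(m[j])) coh[j] <- phase_coherence(a1[m[j], ], a2[m[j], ], sig$dt)
    }
    list(coherence = coh, matched = m)
  }
  after_x <- coh_after(ens_x)
  after_y <- coh_after(ens_y)

  usable <- !is.na(after_x$coherence) & !is.na(after_y$coherence)
  if (!all(usable)) {
    warning(sprintf("ICC(s) %s had no frequency-matchable IMF after re-decomposition; truncating to the matchable subset",
                    paste(idx[!usable], collapse = ", ")))
    if (!any(usable)) {
      stop(errorCondition("no ICC could be matched after re-decomposition",
                          class = c("nacd_no_icc", "nacd_error", "error", "condition")))
    }
  }
  sel_use <- icc_selection(idx[usable],
                           main_index = if (sel$main_index %in% idx[usable])
                             sel$main_index else idx[usable][1],
                           selection_mode = sel$selection_mode)
  w <- icc_variance_weights(imfs1, imfs2, sel_use)

  d_x <- coherence_distance(p_orig[usable], after_x$coherence[usable], w)
  d_y <- coherence_distance(p_orig[usable], after_y$coherence[usable], w)

  causal_strengths(d_x, d_y, negligibility = negligibility,
                   diagnostics = list(
                     phase_summary = summary,
                     selection = sel,
                     selection_used = sel_use,
                     p_original = p_orig,
                     ps12 = after_x$coherence,
                     ps21 = after_y$coherence,
                     matched_x = after_x$matched,
                     matched_y = after_y$matched,
                     weights = w,
                     ensemble = ens))
}
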