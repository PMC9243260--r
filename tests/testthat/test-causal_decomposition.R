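make_summary <- function(f1, f2, diff) {
  structure(data.frame(imf_index = seq_along(f1), av_fre1 = f1,
                       av_fre2 = f2, difference = diff),
            class = c("phase_summary", "data.frame"))
}

test_that("ICC selection keeps same-scale, phase-locked rows and picks the main ICC", {
  sm <- make_summary(f1 = c(0.4, 0.2, 0.1, 0.05, 0.01),
                     f2 = c(0.4, 0.02, 0.1, 0.05, 0.01),
                     diff = c(2.0, 0.2, 0.1, 0.5, 0.9))
  sel <- select_iccs(sm, freq_ratio_max = 2, phase_diff_max = pi / 2)
  # row 1 fails the phase screen, row 2 fails the frequency-ratio screen
  expect_equal(sel$icc_indices, c(3L, 4L, 5L))
  expect_equal(sel$main_index, 3L)        # minimal |difference|
  expect_identical(sel$selection_mode, "automatic")

  # a 10x frequency mismatch is excluded at any sane ratio threshold
  sm2 <- make_summary(c(0.5, 0.1), c(0.05, 0.1), c(0.0, 0.3))
  expect_equal(select_iccs(sm2)$icc_indices, 2L)

  sm3 <- make_summary(c(0.5, 0.3), c(0.05, 0.02), c(3.0, 2.8))
  expect_error(select_iccs(sm3), class = "nacd_no_icc")

  # phase screening is circular: a difference of 2*pi is a zero-lag lock
  sm4 <- make_summary(c(0.1, 0.05), c(0.1, 0.05), c(2 * pi + 0.1, 3.0))
  expect_equal(select_iccs(sm4)$icc_indices, 1L)
})

test_that("manual ICC override validates its indices", {
  sel <- icc_selection(c(4, 2), main_index = 4)
  expect_equal(sel$icc_indices, c(2L, 4L))
  expect_equal(sel$main_index, 4L)
  expect_error(icc_selection(integer(0)), class = "nacd_config_error")
  expect_error(icc_selection(c(1, 2), main_index = 3),
               class = "nacd_config_error")
})

test_that("removing the main ICC is an exact additive inverse", {
  n <- 256
  a <- tone(0.1, n, amp = 2)
  b <- tone(0.01, n)
  stack <- rbind(a, b)
  sig <- a + b

  removed <- remove_main_icc(sig, stack, 1L)
  expect_lt(max(abs(removed + stack[1, ] - sig)), 1e-10)
  # tone A carries > 50% of power, so its removal shrinks the variance
  expect_lt(var(removed), var(sig))

  zero_stack <- rbind(rep(0, n), b)
  expect_equal(remove_main_icc(sig, zero_stack, 1L), sig)

  expect_error(remove_main_icc(sig, stack, 3L), class = "nacd_index_error")
})

test_that("ICC variance weights normalize channel-summed variances", {
  n <- 200
  s1 <- icc_selection(1L)
  one <- rbind(tone(0.1, n))
  expect_equal(icc_variance_weights(one, one, s1), 1.0)

  both <- icc_selection(c(1L, 2L), main_index = 1L)
  eq <- rbind(tone(0.1, n), tone(0.05, n))
  expect_equal(unname(icc_variance_weights(eq, eq, both)), c(0.5, 0.5),
               tolerance = 1e-6)

  # variances (3, 1) on both channels -> weights (0.75, 0.25)
  v1 <- rbind(sqrt(3) * scale(rnorm(n))[, 1], scale(rnorm(n))[, 1])
  expect_equal(unname(icc_variance_weights(v1, v1, both)), c(0.75, 0.25),
               tolerance = 1e-9)

  zero <- rbind(rep(0, n))
  expect_error(icc_variance_weights(zero, zero, s1),
               class = "nacd_degenerate_variance")
})

test_that("coherence distance and strengths match brute-force arithmetic", {
  expect_equal(coherence_distance(c(0.4, 0.7), c(0.4, 0.7), c(0.5, 0.5)), 0)
  expect_equal(coherence_distance(1, 0, 1), 1)
  expect_equal(coherence_distance(c(0.9, 0.5), c(0.1, 0.5), c(0.75, 0.25)),
               sqrt(0.75 * 0.64), tolerance = 1e-12)
  expect_error(coherence_distance(c(1, 0), 1, 1), class = "nacd_shape_error")

  cs <- causal_strengths(0.3, 0.1, negligibility = 0.05)
  expect_equal(cs$rcs_xy, 0.75)
  expect_equal(cs$rcs_yx, 0.25)

  null_cs <- causal_strengths(0, 0)
  expect_equal(c(null_cs$rcs_xy, null_cs$rcs_yx, null_cs$acs_xy,
                 null_cs$acs_yx), c(0.5, 0.5, 0, 0))
  expect_error(causal_strengths(-0.1, 0.2), class = "nacd_domain_error")

  # independent brute-force oracle on random small instances
  set.seed(51)
  for (i in 1:1000) {
    k <- sample(1:5, 1)
    orig <- runif(k)
    redec <- runif(k)
    w <- runif(k)
    w <- w / sum(w)
    acc <- 0
    for (j in seq_len(k)) acc <- acc + w[j] * (orig[j] - redec[j])^2
    expect_equal(coherence_distance(orig, redec, w), sqrt(acc),
                 tolerance = 1e-12)

    dx <- runif(1, 0, 0.5); dy <- runif(1, 0, 0.5)
    cs <- causal_strengths(dx, dy, negligibility = 0.05)
    if (dx + dy > 0.05) {
      expect_equal(cs$rcs_xy, dx / (dx + dy), tolerance = 1e-12)
    } else {
      expect_equal(cs$rcs_xy, 0.5)
    }
    expect_equal(cs$rcs_xy + cs$rcs_yx, 1, tolerance = 1e-12)
  }
})

test_that("exchanging the input channels exactly swaps the causal strengths", {
  sig <- gen_coupled_oscillators(300, coupling = 0.7, seed = 61)
  cfg <- noise_config(0.01, 2, 2, seed = 61)
  fwd <- run_causal_decomposition(sig, cfg)
  rev <- run_causal_decomposition(
    multivariate_signal(sig$values[, c(2, 1)]), cfg)
  expect_identical(fwd$rcs_xy, rev$rcs_yx)
  expect_identical(fwd$rcs_yx, rev$rcs_xy)
  expect_identical(fwd$acs_xy, rev$acs_yx)
  expect_identical(fwd$acs_yx, rev$acs_xy)
})

test_that("identical channels plus symmetric noise read as reciprocal", {
  set.seed(62)
  x <- tone(0.06, 300) + rnorm(300, sd = 0.2)
  res <- run_causal_decomposition(multivariate_signal(cbind(x, x)),
                                  noise_config(0.01, 2, 2, seed = 62))
  # exchange symmetry of identical channels forces exact 0.5/0.5
  expect_equal(res$rcs_xy, 0.5)
  expect_equal(res$rcs_yx, 0.5)
})

test_that("the pipeline rejects non-bivariate input and respects overrides", {
  set.seed(63)
  expect_error(run_causal_decomposition(
    multivariate_signal(matrix(rnorm(300), 100, 3)), noise_config()),
    class = "nacd_data_error")

  sig <- gen_coupled_oscillators(256, coupling = 0.8, seed = 63)
  cfg <- noise_config(0.01, 2, 2, seed = 63)
  auto <- run_causal_decomposition(sig, cfg)
  ov <- icc_selection(auto$diagnostics$selection$icc_indices,
                      auto$diagnostics$selection$main_index)
  manual <- run_causal_decomposition(sig, cfg, icc_override = ov)
  expect_equal(manual$rcs_xy, auto$rcs_xy)
  expect_error(run_causal_decomposition(sig, cfg,
                                        icc_override = icc_selection(50L)),
               class = "nacd_index_error")
})
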