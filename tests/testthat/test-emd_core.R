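test_that("direction sets are unit-norm, balanced, and closed under channel swap", {
  d <- generate_directions(2, 64)
  expect_equal(d$count, 64L)
  expect_equal(nrow(d$vectors), 64L)
  expect_true(all(abs(sqrt(rowSums(d$vectors^2)) - 1) < 1e-12))
  # quasi-uniform coverage: the vector mean nearly cancels
  expect_lt(sqrt(sum(colMeans(d$vectors)^2)), 0.05)

  d3 <- generate_directions(3, 8)
  expect_equal(nrow(d3$vectors), 8L)
  expect_true(all(abs(sqrt(rowSums(d3$vectors^2)) - 1) < 1e-12))

  # swapping coordinates 1 and 2 permutes the set onto itself
  for (dd in list(d, d3)) {
    swapped <- dd$vectors
    swapped[, c(1, 2)] <- dd$vectors[, c(2, 1)]
    key <- function(m) sort(apply(round(m, 10), 1, paste, collapse = ","))
    expect_identical(key(swapped), key(dd$vectors))
  }

  expect_error(generate_directions(1, 64), class = "nacd_invalid_dimension")
  expect_error(generate_directions(3, 4), class = "nacd_invalid_dimension")
})

test_that("envelope mean flags monotone signals and cancels for symmetric tones", {
  dirs <- generate_directions(2, 64)
  const2 <- matrix(1, 64, 2)
  expect_error(envelope_mean(const2, dirs), class = "nacd_monotone_signal")

  n <- 1024
  x <- tone(0.02, n)
  em <- envelope_mean(cbind(x, x), dirs)
  interior <- 100:(n - 100)
  expect_lt(max(abs(em$mean[interior, ])), 0.1)

  # odd symmetry: negating the input negates the envelope mean
  set.seed(5)
  v <- matrix(rnorm(400), 200, 2)
  em1 <- envelope_mean(v, dirs)
  em2 <- envelope_mean(-v, dirs)
  expect_lt(max(abs(em1$mean + em2$mean)), 1e-10)
})

test_that("compiled envelope core matches the pure-R reference", {
  dirs <- generate_directions(2, 16)
  set.seed(11)
  v <- matrix(rnorm(600), 300, 2)
  a <- nacd:::envelope_mean_cpp(v, dirs$vectors)
  b <- nacd:::envelope_mean_r(v, dirs$vectors)
  expect_equal(a$n_used, b$n_used)
  expect_lt(max(abs(a$mean - b$mean)), 1e-12)
  expect_lt(max(abs(a$amplitude - b$amplitude)), 1e-12)

  dirs5 <- generate_directions(5, 64)
  set.seed(12)
  v5 <- matrix(rnorm(1500), 300, 5)
  a <- nacd:::envelope_mean_cpp(v5, dirs5$vectors)
  b <- nacd:::envelope_mean_r(v5, dirs5$vectors)
  expect_lt(max(abs(a$mean - b$mean)), 1e-12)
})

test_that("memd on a monotone ramp yields no IMFs and an exact residual", {
  v <- cbind(seq_len(64), seq_len(64) * 2)
  dec <- memd(multivariate_signal(v))
  expect_equal(dec$n_imfs, 0L)
  expect_equal(dec$residual, t(v))
})

test_that("memd separates a fast tone from a slow tone", {
  sig <- two_tone_pair(1000)
  dec <- memd(sig)
  expect_gte(dec$n_imfs, 2L)
  interior <- 101:900
  fast <- tone(0.05, 1000)
  for (ch in 1:2) {
    expect_gt(cor(dec$imfs[1, ch, interior], fast[interior]), 0.95)
  }
  expect_lt(reconstruction_error(dec, sig$values), 1e-8)
})

test_that("memd is complete, mode-aligned, and deterministic", {
  set.seed(21)
  v <- matrix(rnorm(512 * 2), 512, 2)
  sig <- multivariate_signal(v)
  dec1 <- memd(sig)
  dec2 <- memd(sig)
  expect_identical(dec1, dec2)
  expect_lt(reconstruction_error(dec1, v), 1e-8)

  # identical channels decompose identically
  set.seed(22)
  x <- rnorm(400)
  dec <- memd(multivariate_signal(cbind(x, x)))
  for (j in seq_len(dec$n_imfs)) {
    expect_lt(max(abs(dec$imfs[j, 1, ] - dec$imfs[j, 2, ])), 1e-6)
  }

  expect_error(memd(multivariate_signal(matrix(1:6, 3, 2))),
               class = "nacd_too_short")
})

test_that("IMFs satisfy the extrema/zero-crossing condition on interior samples", {
  # identical channels make the joint sifting univariate-equivalent, where
  # the IMF condition holds strictly
  set.seed(23)
  x <- rnorm(512)
  dec <- memd(multivariate_signal(cbind(x, x)))
  for (j in seq_len(dec$n_imfs)) {
    expect_lte(abs(imf_extrema_zc_mismatch(dec$imfs[j, 1, ])), 1L)
  }

  # genuinely multivariate input: the sifting criterion constrains the joint
  # envelope, so per channel the condition holds only up to a small fraction
  # of the extrema count
  set.seed(24)
  sig <- multivariate_signal(matrix(rnorm(1024), 512, 2))
  dec <- memd(sig)
  for (j in seq_len(dec$n_imfs)) {
    for (ch in 1:2) {
      v <- dec$imfs[j, ch, ]
      n_ext <- length(nacd:::find_extrema(v)$maxima) +
        length(nacd:::find_extrema(v)$minima)
      expect_lte(abs(imf_extrema_zc_mismatch(v)), max(1L, ceiling(0.05 * n_ext)))
    }
  }
})

test_that("white-noise decomposition has strictly decreasing IMF frequencies", {
  set.seed(24)
  sig <- multivariate_signal(matrix(rnorm(2 * 2048), 2048, 2))
  dec <- memd(sig)
  for (ch in 1:2) {
    freqs <- vapply(seq_len(dec$n_imfs), function(j)
      average_frequency(instantaneous_phase(dec$imfs[j, ch, ])), numeric(1))
    expect_true(all(diff(freqs) < 0))
  }
})
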