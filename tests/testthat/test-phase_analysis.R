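test_that("instantaneous phase of a pure tone advances at the tone frequency", {
  n <- 1000
  tr <- instantaneous_phase(cos(2 * pi * 0.01 * (0:(n - 1))), dt = 1)
  interior <- 101:900
  slope <- mean(diff(tr$phase[interior]))
  expect_lt(abs(slope - 2 * pi * 0.01) / (2 * pi * 0.01), 0.02)
  # no unwrap jump may exceed pi
  expect_lt(max(abs(diff(tr$phase) -
                    2 * pi * round(diff(tr$phase) / (2 * pi)))), pi + 1e-12)
  expect_equal(length(tr$phase), n)
  expect_equal(length(tr$frequency), n)
})

test_that("sin and cos at one frequency are in quadrature", {
  n <- 1000
  t1 <- instantaneous_phase(tone(0.02, n))
  t2 <- instantaneous_phase(cos(2 * pi * 0.02 * (0:(n - 1))))
  interior <- 101:900
  dphi <- (t2$phase - t1$phase)[interior]
  expect_true(all(abs(dphi - pi / 2) < 0.05))
})

test_that("degenerate inputs are rejected", {
  expect_error(instantaneous_phase(numeric(4)), class = "nacd_data_error")
  expect_error(instantaneous_phase(rep(0, 100)), class = "nacd_degenerate_phase")
  expect_error(phase_coherence(rep(0, 100), tone(0.1, 100)),
               class = "nacd_degenerate_phase")
  expect_error(phase_coherence(tone(0.1, 100), tone(0.1, 50)),
               class = "nacd_shape_error")
})

test_that("average frequency recovers tones and chirps, independent of amplitude", {
  n <- 1000
  f_tone <- average_frequency(instantaneous_phase(tone(0.02, n)))
  expect_lt(abs(f_tone - 0.02), 0.001)

  # linear chirp 0.01 -> 0.03 cycles/sample: time-averaged frequency 0.02
  tt <- 0:(n - 1)
  finst <- 0.01 + (0.03 - 0.01) * tt / (n - 1)
  chirp <- sin(2 * pi * cumsum(finst))
  f_chirp <- average_frequency(instantaneous_phase(chirp))
  expect_lt(abs(f_chirp - 0.02) / 0.02, 0.10)

  f_scaled <- average_frequency(instantaneous_phase(5 * tone(0.02, n)))
  expect_lt(abs(f_scaled - f_tone), 1e-9)
})

test_that("pl_series assembles the peak matrix with antisymmetric differences", {
  n <- 512
  stack1 <- rbind(tone(0.1, n), tone(0.02, n, phase = 0.4))
  stack2 <- rbind(tone(0.1, n, phase = 0.3), tone(0.02, n))
  ps <- pl_series(stack1, stack2)
  expect_equal(dim(ps), c(2L, 4L))
  expect_identical(names(ps), c("imf_index", "av_fre1", "av_fre2", "difference"))
  expect_lt(abs(ps$av_fre1[1] - 0.1), 0.005)
  expect_lt(abs(ps$av_fre2[1] - 0.1), 0.005)
  expect_true(all(ps$av_fre1 >= 0) && all(ps$av_fre2 >= 0))

  # identical stacks: zero differences
  same <- pl_series(stack1, stack1)
  expect_lt(max(abs(same$difference)), 1e-10)

  # exchanging channels negates the difference column
  sw <- pl_series(stack2, stack1)
  expect_equal(sw$difference, -ps$difference, tolerance = 1e-12)

  expect_error(pl_series(stack1, stack2[, 1:100]), class = "nacd_shape_error")
})

test_that("phase coherence is a phase-locking value in [0, 1]", {
  n <- 1000
  x <- tone(0.05, n)
  expect_equal(phase_coherence(x, x), 1.0, tolerance = 1e-12)
  expect_gt(phase_coherence(tone(0.05, n),
                            cos(2 * pi * 0.05 * (0:(n - 1)))), 0.99)

  # independent white noise: PLV near its small-sample null level
  plvs <- vapply(1:50, function(s) {
    set.seed(s)
    phase_coherence(rnorm(2000), rnorm(2000))
  }, numeric(1))
  expect_lt(mean(plvs), 0.1)
})

test_that("phase coherence is symmetric and offset-invariant", {
  set.seed(31)
  for (i in 1:5) {
    a <- as.vector(stats::filter(rnorm(600), rep(1, 5), sides = 1))[-(1:10)]
    b <- as.vector(stats::filter(rnorm(600), rep(1, 5), sides = 1))[-(1:10)]
    p_ab <- phase_coherence(a, b)
    expect_true(p_ab >= 0 && p_ab <= 1)
    expect_lt(abs(p_ab - phase_coherence(b, a)), 1e-12)
  }
  # constant phase offset on an exact-bin tone leaves the PLV unchanged
  n <- 1000
  set.seed(32)
  b <- as.vector(stats::filter(rnorm(n + 10), rep(1, 5), sides = 1))[-(1:10)]
  p0 <- phase_coherence(tone(0.05, n), b)
  p1 <- phase_coherence(tone(0.05, n, phase = 0.7), b)
  expect_lt(abs(p0 - p1), 1e-9)
})
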