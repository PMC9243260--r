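#' Independent Gaussian white-noise pair
#'
#' Two independent standard-normal channels: the null fixture for causal
#' inference (no coupling in either direction) and the input used for
#' runtime scaling experiments.
#'
#' @param n_time number of samples (>= 32).
#' @param seed PRNG seed; the output is a pure function of the arguments.
#' @param dt sampling interval.
#' @return a bivariate \code{\link{multivariate_signal}}.
#' @export
gen_white_noise_pair <- function(n_time, seed = 1L, dt = 1) {
  if (n_time < 32L) {
    stop(errorCondition("white-noise pair needs n_time >= 32",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  vals <- with_seed(seed, matrix(stats::rnorm(2L * n_time), n_time, 2L))
  multivariate_signal(vals, dt = dt, channel_names = c("x", "y"))
}

#' Unidirectionally coupled stochastic phase oscillators
#'
#' The driver is a stochastic-phase oscillator: its phase advances by
#' \code{2 * pi * base_freq} per sample plus Gaussian phase noise. The
#' driven channel has the same mean rate but its phase increment is pulled
#' toward the driver's current phase with gain \code{coupling}
#' (Kuramoto-style \code{coupling * sin(phase_x - phase_y)} term), so for
#' \code{coupling = 0} the two phases drift apart as independent random
#' walks, while strong coupling phase-locks them. Observations are the
#' sines of the phases plus independent Gaussian measurement noise.
#'
#' By default the driver is the more phase-coherent of the two
#' (\code{driver_phase_sd < response_phase_sd}): a pacemaker entraining a
#' sloppier follower. This mirrors how driven systems look in practice —
#' the autonomous rhythm is spectrally concentrated while the entrained
#' response carries the inherited phase spread across a broader band — and
#' that spectral asymmetry is precisely what phase-dependency causal
#' analysis keys on; with identical phase-noise levels on both channels the
#' pair is statistically exchange-symmetric up to lag and carries no
#' recoverable direction information.
#'
#' @param n_time number of samples (>= 32).
#' @param base_freq oscillation frequency, cycles per sample (default 0.05).
#' @param coupling pulling gain in \[0, 1\].
#' @param direction \code{"x_to_y"}, \code{"y_to_x"} or \code{"none"};
#'   channel 1 is always called X in the output.
#' @param noise_sd observation noise standard deviation (default 0.1).
#' @param driver_phase_sd per-step phase noise of the autonomous driver,
#'   radians (default 0.05).
#' @param response_phase_sd per-step intrinsic phase noise of the driven
#'   oscillator, radians (default 0.3).
#' @param seed PRNG seed.
#' @param dt sampling interval.
#' @return a bivariate \code{\link{multivariate_signal}}.
#' @export
gen_coupled_oscillators <- function(n_time, base_freq = 0.05, coupling = 0,
                                    direction = "x_to_y", noise_sd = 0.1,
                                    driver_phase_sd = 0.05,
                                    response_phase_sd = 0.3,
                                    seed = 1L, dt = 1) {
  if (n_time < 32L) {
    stop(errorCondition("coupled oscillators need n_time >= 32",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  if (coupling < 0 || coupling > 1) {
    stop(errorCondition("coupling must lie in [0, 1]",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  if (!direction %in% c("x_to_y", "y_to_x", "none")) {
    stop(errorCondition("direction must be one of 'x_to_y', 'y_to_x', 'none'",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  vals <- with_seed(seed, {
    w <- 2 * pi * base_freq
    eps_d <- stats::rnorm(n_time, sd = driver_phase_sd)
    eps_r <- stats::rnorm(n_time, sd = response_phase_sd)
    ph_d <- ph_r <- numeric(n_time)
    ph_d[1] <- stats::runif(1, 0, 2 * pi)
    ph_r[1] <- stats::runif(1, 0, 2 * pi)
    k <- if (direction == "none") 0 else coupling
    for (t in seq_len(n_time - 1L)) {
      ph_d[t + 1L] <- ph_d[t] + w + eps_d[t]
      ph_r[t + 1L] <- ph_r[t] + w + k * sin(ph_d[t] - ph_r[t]) + eps_r[t]
    }
    obs_d <- sin(ph_d) + stats::rnorm(n_time, sd = noise_sd)
    obs_r <- sin(ph_r) + stats::rnorm(n_time, sd = noise_sd)
    if (direction == "y_to_x") cbind(obs_r, obs_d) else cbind(obs_d, obs_r)
  })
  multivariate_signal(vals, dt = dt, channel_names = c("x", "y"))
}

#' Noisy Lotka-Volterra predator-prey series
#'
#' Integrates the classic two-species Lotka-Volterra system
#' \code{dN/dt = a N - b N P}, \code{dP/dt = -c P + d N P}, samples it
#' annually, and applies multiplicative lognormal observation noise (counts
#' are positive). With the defaults the equilibrium sits at 1000 prey and
#' 25 predators and small cycles have period \code{2 * pi / sqrt(a * c)},
#' about 26 years — an emulator of annual predator-prey count series such
#' as the 61-year Isle Royale wolf-moose record, so no download is needed
#' for tests or demos.
#'
#' @param n_years number of annual samples (>= 16).
#' @param growth prey intrinsic growth rate \code{a} (1/year).
#' @param predation predation rate \code{b}.
#' @param mortality predator mortality \code{c} (1/year).
#' @param conversion prey-to-predator conversion \code{d}.
#' @param init named vector \code{c(prey =, predator =)} initial state.
#' @param obs_noise_cv coefficient of variation of the lognormal
#'   observation noise (0 disables it).
#' @param seed PRNG seed (observation noise only; the ODE is
#'   deterministic).
#' @return a bivariate \code{\link{multivariate_signal}} with channels
#'   (prey, predator), \code{dt = 1} year.
#' @examples
#' lv <- gen_lotka_volterra(61, seed = 1)
#' matplot(lv$values, type = "l")
#' @export
gen_lotka_volterra <- function(n_years = 61L, growth = 0.3,
                               predation = 0.012, mortality = 0.2,
                               conversion = 2e-4,
                               init = c(prey = 1300, predator = 20),
                               obs_noise_cv = 0.1, seed = 1L) {
  if (n_years < 16L) {
    stop(errorCondition("Lotka-Volterra emulator needs n_years >= 16",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  if (any(c(growth, predation, mortality, conversion) <= 0)) {
    stop(errorCondition("all rate parameters must be > 0",
                        class = c("nacd_config_error", "nacd_error", "error", "condition")))
  }
  rhs <- function(t, state, p) {
    with(as.list(c(state, p)), {
      list(c(prey = a * prey - b * prey * predator,
             predator = -cc * predator + dd * prey * predator))
    })
  }
  times <- seq(0, n_years - 1L)
  sol <- deSolve::ode(y = c(prey = unname(init["prey"]),
                            predator = unname(init["predator"])),
                      times = times, func = rhs,
                      parms = list(a = growth, b = predation,
                                   cc = mortality, dd = conversion))
  traj <- sol[, c("prey", "predator")]
  if (any(!is.finite(traj)) || any(traj < 1e-6)) {
    stop(errorCondition("parameter set drives a population to (near) extinction",
                        class = c("nacd_degenerate_trajectory", "nacd_error", "error", "condition")))
  }
  if (obs_noise_cv > 0) {
    sdlog <- sqrt(log(1 + obs_noise_cv^2))
    noise <- with_seed(seed,
                       matrix(stats::rlnorm(2L * n_years, meanlog = -sdlog^2 / 2,
                                            sdlog = sdlog), n_years, 2L))
    traj <- traj * noise
  }
  multivariate_signal(traj, dt = 1, channel_names = c("prey", "predator"))
}
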