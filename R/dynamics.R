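#' Draw source states from the prior
#'
#' Samples (direction, angular velocity) pairs from the bivariate Gaussian
#' prior of a configuration. Directions are wrapped to \code{[-180, 180)}.
#'
#' @param config a [sim_config()].
#' @param count number of draws.
#' @param seed optional integer seed.
#' @return A data frame with columns \code{theta} (deg) and \code{omega}
#'   (deg/s), one row per draw.
#' @examples
#' s <- sample_prior(sim_config(), 1000, seed = 1)
#' sd(s$theta)   # close to the prior sd of 23.3 deg
#' @export
sample_prior <- function(config, count, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("'count' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  s <- config$prior_sd
  r <- config$prior_corr
  # lower-triangular factor of the prior covariance; valid for zero sds too
  z1 <- stats::rnorm(count)
  z2 <- stats::rnorm(count)
  theta <- config$prior_mean[1] + s[1] * z1
  omega <- config$prior_mean[2] + s[2] * (r * z1 + sqrt(1 - r^2) * z2)
  data.frame(theta = wrap_deg(theta), omega = omega)
}

#' Advance a source state by one time step
#'
#' Applies the state dynamics
#' \deqn{\theta_k = \theta_{k-1} + \Delta t\, \omega_{k-1} + \eta_k, \quad
#'       \omega_k = \omega_{k-1} + \nu_k}
#' where \eqn{\eta_k} is circular (wrapped) Gaussian direction noise and
#' \eqn{\nu_k} is Gaussian velocity noise.
#'
#' @param state numeric vector \code{c(theta, omega)} in (deg, deg/s).
#' @param config a [sim_config()].
#' @param noisy if \code{FALSE}, the noise terms are zero.
#' @return The next state \code{c(theta, omega)} with \code{theta} wrapped.
#' @export
step_dynamics <- function(state, config, noisy = TRUE) {
  stopifnot(length(state) == 2L, all(is.finite(state)))
  sd <- step_noise_sd(config)
  eta <- if (noisy && sd["theta"] > 0) stats::rnorm(1, 0, sd["theta"]) else 0
  nu  <- if (noisy && sd["omega"] > 0) stats::rnorm(1, 0, sd["omega"]) else 0
  c(theta = wrap_deg(state[[1]] + config$dt * state[[2]] + eta),
    omega = state[[2]] + nu)
}

new_trajectory <- function(k, t, theta_unwrapped, omega, dt) {
  structure(
    data.frame(k = k,
               t_seconds = t,
               theta_deg = wrap_deg(theta_unwrapped),
               omega_deg_s = omega,
               theta_unwrapped = theta_unwrapped),
    dt = dt, class = c("source_trajectory", "data.frame"))
}

#' Simulate a stochastic source trajectory
#'
#' Runs the generative dynamics forward from an initial state (drawn from
#' the prior unless given), with fresh noise at every step.
#'
#' @param config a [sim_config()].
#' @param n_steps number of steps (trajectory length).
#' @param init optional initial state \code{c(theta, omega)}; drawn from the
#'   prior when \code{NULL}.
#' @param seed optional integer seed.
#' @return A \code{source_trajectory} data frame with columns \code{k},
#'   \code{t_seconds}, \code{theta_deg} (wrapped), \code{omega_deg_s} and
#'   \code{theta_unwrapped}.
#' @export
simulate_trajectory <- function(config, n_steps, init = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  else if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(init)) {
    p <- sample_prior(config, 1L)
    init <- c(p$theta, p$omega)
  }
  sd <- step_noise_sd(config)
  theta <- numeric(n_steps)
  omega <- numeric(n_steps)
  theta[1] <- init[[1]]
  omega[1] <- init[[2]]
  if (n_steps > 1L) {
    eta <- stats::rnorm(n_steps - 1L, 0, sd["theta"])
    nu  <- stats::rnorm(n_steps - 1L, 0, sd["omega"])
    for (k in 2:n_steps) {
      theta[k] <- theta[k - 1L] + config$dt * omega[k - 1L] + eta[k - 1L]
      omega[k] <- omega[k - 1L] + nu[k - 1L]
    }
  }
  new_trajectory(seq_len(n_steps), (seq_len(n_steps) - 1) * config$dt,
                 theta, omega, config$dt)
}

#' Convert an ITD-rate velocity to angular velocity
#'
#' Stimulus velocities are often stated as ITD change per second; the
#' frontal linear map (default slope 2.67 microseconds per degree) converts
#' them to deg/s.
#'
#' @param v_itd_us_s velocity in microseconds of ITD per second.
#' @param slope linear ITD slope in microseconds per degree.
#' @return Angular velocity in deg/s.
#' @examples
#' itd_velocity_to_deg(40)  # about 14.98 deg/s
#' @export
itd_velocity_to_deg <- function(v_itd_us_s, slope = 2.67) {
  v_itd_us_s / slope
}

#' Deterministic constant-velocity stimulus sweep
#'
#' The stimulus protocol used throughout the receptive-field and decoding
#' analyses: a source moving at constant angular velocity, no dynamics
#' noise. The trajectory includes both endpoints, so it has
#' \code{round(duration_s / dt) + 1} steps and ends exactly at
#' \code{start_deg + velocity * duration_s} (wrapped).
#'
#' @param start_deg starting direction, degrees.
#' @param velocity source velocity; units per \code{velocity_units}.
#' @param duration_s sweep duration in seconds (>= \code{dt}).
#' @param config a [sim_config()] (supplies \code{dt}).
#' @param velocity_units \code{"deg_s"} (default) or \code{"itd_us_s"}, the
#'   latter converted through \code{itd_slope}.
#' @param itd_slope linear ITD slope (microseconds/deg) for the conversion.
#' @return A \code{source_trajectory} data frame.
#' @examples
#' sw <- constant_velocity_sweep(20, -100, 1, sim_config())
#' tail(sw$theta_deg, 1)  # -80
#' @export
constant_velocity_sweep <- function(start_deg, velocity, duration_s, config,
                                    velocity_units = c("deg_s", "itd_us_s"),
                                    itd_slope = 2.67) {
  stopifnot(inherits(config, "sim_config"))
  velocity_units <- match.arg(velocity_units)
  if (duration_s < config$dt) stop("'duration_s' must be at least one time step")
  v <- if (velocity_units == "itd_us_s") itd_velocity_to_deg(velocity, itd_slope)
       else velocity
  n <- round(duration_s / config$dt) + 1L
  t <- (seq_len(n) - 1) * config$dt
  new_trajectory(seq_len(n), t, start_deg + v * t, rep(v, n), config$dt)
}

#' @export
print.source_trajectory <- function(x, ...) {
  cat(sprintf("Source trajectory: %d steps, dt = %g s, duration %.3f s\n",
              nrow(x), attr(x, "dt"), max(x$t_seconds)))
  cat(sprintf("  direction %g -> %g deg; velocity %g -> %g deg/s\n",
              round(x$theta_deg[1], 2), round(x$theta_deg[nrow(x)], 2),
              round(x$omega_deg_s[1], 2), round(x$omega_deg_s[nrow(x)], 2)))
  invisible(x)
}

#' @export
plot.source_trajectory <- function(x, ...) {
  graphics::plot(x$t_seconds, x$theta_deg, type = "l",
                 xlab = "time (s)", ylab = "direction (deg)", ...)
  invisible(x)
}
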