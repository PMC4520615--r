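#' Simulation configuration for the source-dynamics model
#'
#' Bundles every parameter of the generative model of source motion: the
#' time step, the prediction lookahead, the per-step dynamics noise, and the
#' Gaussian prior over initial direction and angular velocity.
#'
#' The defaults encode the study conditions: 10-ms observation frames
#' (about the integration window over which the auditory system forms an
#' ITD estimate) with a 10-step lookahead, giving the 100-ms prediction
#' horizon that matches the owl's sensorimotor delay; velocity noise of
#' 0.125 deg/s per step (smooth escape trajectories); a zero-mean prior
#' with standard deviations 23.3 deg for direction and 50 deg/s for
#' velocity; and a weak negative direction-velocity correlation of -0.05
#' favouring sources moving into the centre of gaze. The time step and the
#' direction-noise standard deviation are free parameters of the model;
#' their defaults are set jointly so that, with the 12.5-microsecond ITD
#' noise, the prior washes out over roughly a hundred milliseconds (the
#' delayed receptive-field-shift regime) and the 100-ms predictive
#' uncertainty (about 2 deg, 6 microseconds of ITD) sits at the scale of
#' owl midbrain receptive fields. See the methods vignette.
#'
#' @param dt time step in seconds (> 0).
#' @param horizon_steps integer prediction lookahead \eqn{n}; the prediction
#'   horizon is \code{horizon_steps * dt} seconds.
#' @param sigma_theta_noise standard deviation of the per-step circular
#'   Gaussian direction noise, degrees.
#' @param sigma_omega_noise standard deviation of the per-step velocity
#'   noise, deg/s.
#' @param prior_mean length-2 numeric, prior mean of (direction deg,
#'   velocity deg/s).
#' @param prior_sd length-2 numeric, prior standard deviations (deg, deg/s);
#'   zero is allowed and gives a degenerate (point-mass) prior component.
#' @param prior_corr correlation between direction and velocity in the
#'   prior, strictly inside (-1, 1).
#' @param noise_scaling \code{"per_step"} (default) treats the noise
#'   standard deviations as per-step values at any \code{dt};
#'   \code{"per_sqrt_second"} scales them by \code{sqrt(dt)} so that noise
#'   accumulates at a rate independent of the step size.
#' @param rng_seed optional integer seed recorded with the configuration and
#'   used by simulators when no explicit seed is given.
#' @return An object of class \code{"sim_config"}.
#' @seealso [simulate_trajectory()], [sample_prior()], [itd_track()]
#' @examples
#' cfg <- sim_config()
#' cfg
#' prior_cov(cfg)
#' @export
sim_config <- function(dt = 0.01,
                       horizon_steps = 10L,
                       sigma_theta_noise = 0.5,
                       sigma_omega_noise = 0.125,
                       prior_mean = c(0, 0),
                       prior_sd = c(23.3, 50),
                       prior_corr = -0.05,
                       noise_scaling = c("per_step", "per_sqrt_second"),
                       rng_seed = NULL) {
  noise_scaling <- match.arg(noise_scaling)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  horizon_steps <- as.integer(horizon_steps)
  if (is.na(horizon_steps) || horizon_steps < 0L)
    stop("'horizon_steps' must be a nonnegative integer")
  if (sigma_theta_noise < 0 || sigma_omega_noise < 0)
    stop("noise standard deviations must be nonnegative")
  if (length(prior_mean) != 2L || length(prior_sd) != 2L)
    stop("'prior_mean' and 'prior_sd' must have length 2")
  if (any(prior_sd < 0))
    stop("prior standard deviations must be nonnegative")
  if (!is.finite(prior_corr) || abs(prior_corr) >= 1)
    stop("prior covariance is not positive definite: |prior_corr| must be < 1")
  structure(
    list(dt = dt,
         horizon_steps = horizon_steps,
         sigma_theta_noise = sigma_theta_noise,
         sigma_omega_noise = sigma_omega_noise,
         prior_mean = as.numeric(prior_mean),
         prior_sd = as.numeric(prior_sd),
         prior_corr = prior_corr,
         noise_scaling = noise_scaling,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Source dynamics configuration\n")
  cat(sprintf("  dt: %g s, prediction horizon: %d steps (%.3f s)\n",
              x$dt, x$horizon_steps, x$horizon_steps * x$dt))
  cat(sprintf("  dynamics noise sd: theta %g deg, omega %g deg/s (%s)\n",
              x$sigma_theta_noise, x$sigma_omega_noise,
              gsub("_", " ", x$noise_scaling)))
  cat(sprintf("  prior: mean (%g deg, %g deg/s), sd (%g, %g), corr %g\n",
              x$prior_mean[1], x$prior_mean[2],
              x$prior_sd[1], x$prior_sd[2], x$prior_corr))
  invisible(x)
}

#' Prior covariance matrix of (direction, velocity)
#'
#' @param config a [sim_config()].
#' @return The 2x2 prior covariance matrix (deg^2 on the direction entry,
#'   deg^2/s^2 on the velocity entry).
#' @export
prior_cov <- function(config) {
  s <- config$prior_sd
  r <- config$prior_corr
  matrix(c(s[1]^2, r * s[1] * s[2],
           r * s[1] * s[2], s[2]^2), 2, 2)
}

# per-step noise sds after applying the scaling convention
step_noise_sd <- function(config) {
  f <- if (config$noise_scaling == "per_sqrt_second") sqrt(config$dt) else 1
  c(theta = config$sigma_theta_noise * f,
    omega = config$sigma_omega_noise * f)
}
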