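#' Weighted particle ensemble over (direction, velocity)
#'
#' @param theta particle directions, degrees.
#' @param omega particle angular velocities, deg/s.
#' @param weights nonnegative weights; normalised to sum to one.
#' @param step step index the ensemble refers to.
#' @return An object of class \code{"particle_ensemble"}.
#' @export
particle_ensemble <- function(theta, omega, weights = NULL, step = 0L) {
  m <- length(theta)
  stopifnot(m >= 1L, length(omega) == m)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0))
    stop("weights must be nonnegative and match the particle count")
  tot <- sum(weights)
  if (!is.finite(tot) || tot <= 0) stop("weights must have a positive sum")
  structure(list(theta = as.numeric(theta), omega = as.numeric(omega),
                 weights = weights / tot, step = as.integer(step)),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("Particle ensemble: m = %d, step %d, ESS = %.1f\n",
              length(x$theta), x$step, pf_ess(x)))
  cat(sprintf("  circular mean direction %.2f deg, mean velocity %.2f deg/s\n",
              pf_estimate(x), sum(x$weights * x$omega)))
  invisible(x)
}

#' Initialise particles from the prior
#'
#' @param config a [sim_config()].
#' @param m number of particles (default 10,000).
#' @param seed optional integer seed.
#' @return A uniform-weight [particle_ensemble()] drawn i.i.d. from the
#'   prior.
#' @export
pf_init <- function(config, m = 10000L, seed = NULL) {
  s <- sample_prior(config, m, seed = seed)
  particle_ensemble(s$theta, s$omega, step = 0L)
}

#' Reweight particles by the ITD likelihood
#'
#' Multiplies each particle's weight by the Gaussian likelihood of the
#' observed ITD given the particle's direction (through the observation
#' model's direction-to-ITD map), then renormalises. Computed on the log
#' scale for numerical stability.
#'
#' @param ensemble a [particle_ensemble()].
#' @param itd observed ITD, microseconds.
#' @param model an [itd_model()] (sinusoid or linear form).
#' @return The reweighted [particle_ensemble()].
#' @export
pf_weight <- function(ensemble, itd, model) {
  stopifnot(inherits(ensemble, "particle_ensemble"), inherits(model, "itd_model"))
  if (model$noise_sd <= 0) stop("pf_weight requires a positive observation noise sd")
  innov <- itd - itd_of_direction(ensemble$theta, model)
  logw <- log(ensemble$weights) - innov^2 / (2 * model$noise_sd^2)
  mx <- max(logw)
  if (!is.finite(mx))
    stop(sprintf(
      "degenerate likelihood: all particle weights underflowed (min |innovation| = %.1f us)",
      min(abs(innov))))
  w <- exp(logw - mx)
  particle_ensemble(ensemble$theta, ensemble$omega, w, step = ensemble$step)
}

#' Multinomial (or systematic) resampling
#'
#' Draws a new equal-weight sample of the same size with replacement, with
#' selection probabilities equal to the current weights.
#'
#' @param ensemble a [particle_ensemble()].
#' @param seed optional integer seed.
#' @param scheme \code{"multinomial"} (default, as in sequential importance
#'   resampling) or \code{"systematic"} (lower resampling variance).
#' @return An equal-weight [particle_ensemble()] of the same size.
#' @export
pf_resample <- function(ensemble, seed = NULL,
                        scheme = c("multinomial", "systematic")) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  m <- length(ensemble$theta)
  idx <- if (scheme == "multinomial") {
    sample.int(m, m, replace = TRUE, prob = ensemble$weights)
  } else {
    u <- (stats::runif(1) + seq_len(m) - 1) / m
    findInterval(u, cumsum(ensemble$weights)) + 1L
  }
  particle_ensemble(ensemble$theta[idx], ensemble$omega[idx],
                    step = ensemble$step)
}

#' Effective sample size of an ensemble
#'
#' @param ensemble a [particle_ensemble()].
#' @return \eqn{1 / \sum_j w_j^2}; equals m for uniform weights.
#' @export
pf_ess <- function(ensemble) {
  1 / sum(ensemble$weights^2)
}

#' Propagate particles n steps through the source dynamics
#'
#' Advances every particle n noisy dynamics steps, producing the sampled
#' predictive posterior at step k+n. The tracking ensemble is not modified;
#' the noise draws are independent of the tracking stream. By default the n
#' accumulated Gaussian increments are drawn as a single exact joint sample
#' per particle (their sum is Gaussian with covariance equal to the n-step
#' accumulated process noise); \code{exact = FALSE} iterates the n per-step
#' draws explicitly, which is distributionally identical.
#'
#' @param ensemble a [particle_ensemble()] (normally post-resampling).
#' @param config a [sim_config()].
#' @param n number of dynamics steps (>= 0); \code{n = 0} returns the input.
#' @param seed optional integer seed.
#' @param exact use the single-draw form (default \code{TRUE}).
#' @return The propagated [particle_ensemble()] at step k+n.
#' @export
pf_predict_n <- function(ensemble, config, n, seed = NULL, exact = TRUE) {
  stopifnot(inherits(ensemble, "particle_ensemble"), inherits(config, "sim_config"))
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be nonnegative")
  if (n == 0L) return(ensemble)
  if (!is.null(seed)) set.seed(seed)
  m <- length(ensemble$theta)
  dt <- config$dt
  sd <- step_noise_sd(config)
  th <- ensemble$theta
  om <- ensemble$omega
  if (exact) {
    W <- kf_wn(n, dt, sd[["theta"]]^2, sd[["omega"]]^2)
    # lower-triangular factor of W (2x2), valid for zero noise
    l11 <- sqrt(W[1, 1])
    l21 <- if (l11 > 0) W[1, 2] / l11 else 0
    l22 <- sqrt(max(W[2, 2] - l21^2, 0))
    z1 <- stats::rnorm(m)
    z2 <- stats::rnorm(m)
    th <- th + n * dt * om + l11 * z1
    om <- om + l21 * z1 + l22 * z2
  } else {
    for (i in seq_len(n)) {
      th <- th + dt * om + stats::rnorm(m, 0, sd[["theta"]])
      om <- om + stats::rnorm(m, 0, sd[["omega"]])
    }
  }
  particle_ensemble(wrap_deg(th), om, ensemble$weights,
                    step = ensemble$step + n)
}

#' Circular-mean direction estimate from an ensemble
#'
#' The direction of the weighted resultant vector of the particle
#' directions: the sampled form of the Bayesian prediction vector.
#'
#' @param ensemble a [particle_ensemble()].
#' @return Estimated direction, degrees in \code{[-180, 180)}.
#' @export
pf_estimate <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  circ_mean_deg(ensemble$theta, ensemble$weights)
}

# Full sequential importance resampling run over an ITD sequence.
# At each step: weight by the likelihood, resample, estimate tracking
# direction, propagate n steps (fresh noise) for the predictive estimate at
# the steps listed in predict_at, and advance the tracking ensemble one
# dynamics step. Returns per-step summaries; used by itd_track().
run_particle <- function(itds, config, observation, m, n,
                         predict_at = NULL, seed = NULL,
                         resample_scheme = "multinomial") {
  K <- length(itds)
  if (is.null(predict_at)) predict_at <- seq_len(K)
  if (!is.null(seed)) set.seed(seed)
  ens <- pf_init(config, m)
  dt <- config$dt
  sd <- step_noise_sd(config)

  filt <- matrix(NA_real_, K, 3,
                 dimnames = list(NULL, c("mean_theta", "mean_omega", "ess")))
  pred <- matrix(NA_real_, K, 5,
                 dimnames = list(NULL,
                                 c("mean_theta", "mean_omega", "s11", "s12", "s22")))
  for (k in seq_len(K)) {
    ens$step <- k
    w <- pf_weight(ens, itds[k], observation)
    ens <- pf_resample(w, scheme = resample_scheme)
    filt[k, ] <- c(pf_estimate(ens), mean(ens$omega), pf_ess(w))
    if (k %in% predict_at) {
      pe <- pf_predict_n(ens, config, n)
      # moments of the predictive ensemble; direction by circular mean
      dth <- ang_diff_deg(pe$theta, pf_estimate(pe))
      pred[k, ] <- c(pf_estimate(pe), mean(pe$omega),
                     stats::var(dth), stats::cov(dth, pe$omega),
                     stats::var(pe$omega))
    }
    # one-step propagation feeds the next iteration's tracking ensemble
    mm <- length(ens$theta)
    ens <- particle_ensemble(
      wrap_deg(ens$theta + dt * ens$omega + stats::rnorm(mm, 0, sd[["theta"]])),
      ens$omega + stats::rnorm(mm, 0, sd[["omega"]]),
      step = k)
  }
  list(filtered = filt, predicted = pred)
}
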