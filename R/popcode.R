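#' Build a non-uniform population of direction-tuned neurons
#'
#' Draws the preferred stimuli of \code{N} neurons i.i.d. from a proposal
#' density q. The default proposal is the prior -- the experimentally
#' supported special case in which the distribution of preferred
#' directions itself encodes the prior. Firing rates are later assigned as
#' a scaled ratio of the predictive posterior to q (see [compute_rates()]),
#' so the proposal must be strictly positive at every preferred stimulus.
#'
#' With the default \code{tuning = "direction"} the neurons are tuned to
#' direction only: preferred directions are drawn from the direction prior
#' (mean zero, sd 23.3 deg) and rates use the direction marginal of the
#' posterior. \code{tuning = "joint"} additionally assigns each neuron a
#' preferred velocity, drawing (direction, velocity) pairs from the full
#' bivariate prior (including its -0.05 correlation) and using the joint
#' posterior density. Both satisfy the convergence conditions of the
#' population-vector readout; direction tuning concentrates the population
#' where the decoded quantity lives and is the configuration used by the
#' decoding analyses.
#'
#' @param config a [sim_config()]; supplies the prior.
#' @param N number of neurons (default 5000).
#' @param proposal \code{"prior"}, \code{"uniform"} (directions uniform on
#'   \code{theta_range}), or \code{"custom"}.
#' @param tuning \code{"direction"} (default) or \code{"joint"}; see
#'   Details.
#' @param theta_range direction support for the uniform proposal, degrees.
#' @param proposal_sample,proposal_density for \code{proposal = "custom"}:
#'   a sampler \code{n -> data.frame(theta, omega)} and a vectorised
#'   density -- \code{f(theta)} under direction tuning,
#'   \code{f(theta, omega)} under joint tuning.
#' @param peak_rate target peak firing rate in spikes/s used when rates
#'   are calibrated (default 10, the approximate peak of owl midbrain
#'   auditory responses).
#' @param spike_bin decoding bin in seconds for Poisson spike generation
#'   and population-vector readout (default 0.01).
#' @param seed optional integer seed.
#' @return An object of class \code{"itd_population"}.
#' @examples
#' pop <- build_population(sim_config(), N = 1000, seed = 1)
#' sd(pop$preferred$theta)  # near the prior sd of 23.3 deg
#' @export
build_population <- function(config, N = 5000L,
                             proposal = c("prior", "uniform", "custom"),
                             tuning = c("direction", "joint"),
                             theta_range = c(-90, 90),
                             proposal_sample = NULL,
                             proposal_density = NULL,
                             peak_rate = 10,
                             spike_bin = 0.01,
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  proposal <- match.arg(proposal)
  tuning <- match.arg(tuning)
  N <- as.integer(N)
  if (N < 1L) stop("'N' must be >= 1")
  if (peak_rate <= 0) stop("'peak_rate' must be positive")
  if (!is.null(seed)) set.seed(seed)

  if (proposal == "prior") {
    pref <- sample_prior(config, N)
    mu <- config$prior_mean
    S <- prior_cov(config)
    q_fun <- if (tuning == "direction") {
      function(theta) stats::dnorm(theta, mu[1], config$prior_sd[1])
    } else {
      function(theta, omega) dbvnorm(theta, omega, mu, S)
    }
  } else if (proposal == "uniform") {
    width <- diff(theta_range)
    if (width <= 0) stop("'theta_range' must be increasing")
    pref <- data.frame(
      theta = stats::runif(N, theta_range[1], theta_range[2]),
      omega = stats::rnorm(N, config$prior_mean[2], config$prior_sd[2]))
    q_fun <- if (tuning == "direction") {
      function(theta) {
        ifelse(theta >= theta_range[1] & theta <= theta_range[2], 1 / width, 0)
      }
    } else {
      function(theta, omega) {
        inside <- theta >= theta_range[1] & theta <= theta_range[2]
        ifelse(inside, 1 / width, 0) *
          stats::dnorm(omega, config$prior_mean[2], config$prior_sd[2])
      }
    }
  } else {
    if (!is.function(proposal_sample) || !is.function(proposal_density))
      stop("custom proposal needs 'proposal_sample' and 'proposal_density'")
    pref <- proposal_sample(N)
    stopifnot(is.data.frame(pref), all(c("theta", "omega") %in% names(pref)))
    q_fun <- proposal_density
  }
  q_pref <- if (tuning == "direction") q_fun(pref$theta)
            else q_fun(pref$theta, pref$omega)
  if (any(!is.finite(q_pref)) || any(q_pref <= 0))
    stop("encoding error: proposal density must be strictly positive at every preferred stimulus")
  structure(list(preferred = pref[, c("theta", "omega")],
                 proposal = proposal,
                 tuning = tuning,
                 q = q_fun,
                 q_pref = q_pref,
                 N = N,
                 peak_rate = peak_rate,
                 spike_bin = spike_bin,
                 seed = seed),
            class = "itd_population")
}

#' @export
print.itd_population <- function(x, ...) {
  cat(sprintf("Neural population: N = %d, %s tuning, proposal = %s\n",
              x$N, x$tuning, x$proposal))
  cat(sprintf("  preferred direction sd %.1f deg; peak rate %g sp/s; spike bin %g s\n",
              stats::sd(x$preferred$theta), x$peak_rate, x$spike_bin))
  invisible(x)
}

# bivariate normal density at (x, y), 2x2 covariance S
dbvnorm <- function(x, y, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (det <= 0) stop("degenerate covariance in density evaluation")
  dx <- x - mu[1]
  dy <- y - mu[2]
  qf <- (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / det
  exp(-qf / 2) / (2 * pi * sqrt(det))
}

# alias of each preferred direction nearest the belief mean, so the code
# respects the circularity of direction
alias_theta <- function(theta, mu1) {
  theta + 360 * round((mu1 - theta) / 360)
}

# posterior/proposal ratio at the preferred stimuli for a Gaussian belief
# given as mean (unwrapped) and covariance entries
ratio_gaussian <- function(pop, mu, S) {
  th <- alias_theta(pop$preferred$theta, mu[1])
  p <- if (pop$tuning == "direction") {
    stats::dnorm(th, mu[1], sqrt(S[1, 1]))
  } else {
    dbvnorm(th, pop$preferred$omega, mu, S)
  }
  p / pop$q_pref
}

# product-kernel Gaussian KDE for a particle belief, Silverman bandwidths;
# direction tuning uses the 1D direction kernel only
kde_density_at <- function(pop, ensemble, bandwidth = NULL) {
  m <- length(ensemble$theta)
  ctr <- circ_mean_deg(ensemble$theta, ensemble$weights)
  dth <- ang_diff_deg(ensemble$theta, ctr)
  one_d <- pop$tuning == "direction"
  if (is.null(bandwidth)) {
    bw_exp <- if (one_d) -1 / 5 else -1 / 6
    bandwidth <- c(stats::sd(dth), stats::sd(ensemble$omega)) * m^bw_exp
    bandwidth[!is.finite(bandwidth) | bandwidth <= 0] <- 1e-3
  }
  th_eval <- ang_diff_deg(pop$preferred$theta, ctr)
  w <- ensemble$weights
  vapply(seq_len(pop$N), function(i) {
    kth <- stats::dnorm(th_eval[i], dth, bandwidth[1])
    if (one_d) sum(w * kth)
    else sum(w * kth * stats::dnorm(pop$preferred$omega[i],
                                    ensemble$omega, bandwidth[2]))
  }, numeric(1))
}

#' Firing rates as a scaled posterior/proposal ratio
#'
#' Computes each neuron's deterministic firing rate for a predictive
#' belief: \eqn{a_j = \alpha\, p_{k+n}(\cdot^{(j)}) / q(\cdot^{(j)})}
#' evaluated at the neuron's preferred stimulus (the direction marginal
#' under direction tuning, the joint density under joint tuning; the
#' direction is taken at the alias nearest the belief mean). Particle
#' beliefs are evaluated through a Gaussian kernel density estimate with
#' Silverman bandwidths.
#'
#' When \code{alpha} is \code{NULL} the gain is calibrated so the
#' population's peak rate equals \code{pop$peak_rate} for this belief
#' (per-time-step calibration); pass a fixed \code{alpha} to pin the gain
#' across a whole run instead.
#'
#' @param pop a [build_population()] population.
#' @param belief a [gaussian_belief()] or [particle_ensemble()] holding
#'   the predictive posterior at k+n.
#' @param alpha fixed gain (spikes/s per unit density ratio) or
#'   \code{NULL} to calibrate to the peak rate.
#' @param bandwidth optional KDE bandwidth(s) for particle beliefs
#'   (deg, deg/s).
#' @return Numeric vector of rates (spikes/s), one per neuron, with
#'   attribute \code{"alpha"} holding the gain used.
#' @export
compute_rates <- function(pop, belief, alpha = NULL, bandwidth = NULL) {
  stopifnot(inherits(pop, "itd_population"))
  ratio <- if (inherits(belief, "gaussian_belief")) {
    ratio_gaussian(pop, belief$mean, belief$cov)
  } else if (inherits(belief, "particle_ensemble")) {
    kde_density_at(pop, belief, bandwidth) / pop$q_pref
  } else stop("'belief' must be a gaussian_belief or particle_ensemble")
  if (is.null(alpha)) {
    mx <- max(ratio)
    # normalise before scaling so a denormal peak cannot overflow the gain
    rates <- if (mx > 0) (ratio / mx) * pop$peak_rate else ratio * 0
    attr(rates, "alpha") <- if (mx > 0) pop$peak_rate / mx else 0
    return(rates)
  }
  rates <- alpha * ratio
  attr(rates, "alpha") <- alpha
  rates
}

#' Poisson spike counts from rates
#'
#' @param rates firing rates (spikes/s), e.g. from [compute_rates()].
#' @param spike_bin bin duration in seconds.
#' @param seed optional integer seed.
#' @return Integer spike counts, independently
#'   Poisson(\code{rate * spike_bin}) per neuron.
#' @export
poissonify <- function(rates, spike_bin, seed = NULL) {
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and nonnegative")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(rates), rates * spike_bin)
}

#' Population-vector direction estimate
#'
#' The direction of the activity-weighted resultant of the preferred
#' direction unit vectors,
#' \eqn{PV = \frac{1}{N}\sum_j a_j u(\theta^{(j)})}. Use deterministic
#' rates or Poisson counts as the activity.
#'
#' @param pop a [build_population()] population.
#' @param activity numeric vector of rates or spike counts, one per
#'   neuron.
#' @param on_zero behaviour when the resultant is zero (e.g. no spikes):
#'   \code{"error"} (default) or \code{"na"}.
#' @return Decoded direction in degrees.
#' @export
population_vector <- function(pop, activity, on_zero = c("error", "na")) {
  stopifnot(inherits(pop, "itd_population"))
  if (length(activity) != pop$N)
    stop("activity length must equal the number of neurons")
  circ_mean_deg(pop$preferred$theta, activity, on_zero = match.arg(on_zero))
}

#' Bayesian prediction vector direction of a belief
#'
#' The direction of \eqn{BV = \int u(\theta)\, p(\theta)\, d\theta} for
#' the direction marginal of a belief. For a Gaussian (wrapped-normal)
#' belief the circular mean equals the distribution mean, so the BV
#' direction is the wrapped mean; for a particle belief it is the
#' weighted circular mean of the particles.
#'
#' @param belief a [gaussian_belief()] or [particle_ensemble()].
#' @return Direction in degrees, wrapped to \code{[-180, 180)}.
#' @export
bv_direction <- function(belief) {
  if (inherits(belief, "gaussian_belief")) wrap_deg(belief$mean[1])
  else if (inherits(belief, "particle_ensemble")) pf_estimate(belief)
  else stop("'belief' must be a gaussian_belief or particle_ensemble")
}

#' Population-vector decoding of a fitted track
#'
#' Decodes the predicted source direction from the population over a run:
#' the track's predictive beliefs are sampled at the centre of consecutive
#' bins of \code{pop$spike_bin} seconds, rates are computed for each bin's
#' belief, and the PV is read out from the deterministic rates and
#' (optionally) from Poisson spike counts accumulated over the bin. Bins
#' whose spike resultant is zero inherit the previous estimate (initially
#' the centre of gaze, 0 deg), mimicking a motor readout that holds its
#' state without input.
#'
#' @param track an [itd_track()] fit (Kalman method).
#' @param pop a [build_population()] population.
#' @param mode \code{"both"} (default), \code{"deterministic"} or
#'   \code{"poisson"}.
#' @param alpha_mode \code{"bin"} (default) calibrates the gain so each
#'   bin's peak rate is \code{pop$peak_rate}; \code{"run"} uses one gain
#'   for the whole run, set by the bin with the sharpest posterior.
#' @param seed optional integer seed for the Poisson draws.
#' @return A data frame with one row per decode bin: \code{bin}, \code{k}
#'   (centre step), \code{t_seconds} (prediction target time),
#'   \code{bayes} (Bayesian prediction direction), \code{pv_det},
#'   \code{pv_poisson}, \code{spikes}.
#' @export
pv_decode <- function(track, pop,
                      mode = c("both", "deterministic", "poisson"),
                      alpha_mode = c("bin", "run"),
                      seed = NULL) {
  stopifnot(inherits(track, "itd_track"), inherits(pop, "itd_population"))
  mode <- match.arg(mode)
  alpha_mode <- match.arg(alpha_mode)
  if (!is.null(seed)) set.seed(seed)
  dt <- track$config$dt
  bin_steps <- max(1L, round(pop$spike_bin / dt))
  K <- nrow(track$predicted)
  starts <- seq(1L, K - bin_steps + 1L, by = bin_steps)
  centres <- starts + bin_steps %/% 2L
  p <- track$predicted

  ratio <- matrix(NA_real_, length(centres), pop$N)
  for (i in seq_along(centres)) {
    k <- centres[i]
    ratio[i, ] <- ratio_gaussian(
      pop, c(p$mean_theta_unwrapped[k], p$mean_omega[k]),
      matrix(c(p$s11[k], p$s12[k], p$s12[k], p$s22[k]), 2, 2))
  }
  peak <- apply(ratio, 1, max)
  # divide by the peak first: a denormal peak must not overflow the gain
  rates <- if (alpha_mode == "bin") {
    pop$peak_rate * sweep(ratio, 1, ifelse(peak > 0, peak, 1), `/`)
  } else {
    pop$peak_rate * (ratio / max(peak))
  }
  rates[!is.finite(rates)] <- 0

  pv_det <- rep(NA_real_, length(centres))
  pv_poi <- rep(NA_real_, length(centres))
  spikes <- rep(NA_integer_, length(centres))
  for (i in seq_along(centres)) {
    if (mode != "poisson")
      pv_det[i] <- population_vector(pop, rates[i, ], on_zero = "na")
    if (mode != "deterministic") {
      counts <- stats::rpois(pop$N, rates[i, ] * pop$spike_bin)
      spikes[i] <- sum(counts)
      pv_poi[i] <- if (spikes[i] > 0)
        population_vector(pop, counts, on_zero = "na") else NA_real_
    }
  }
  hold_last <- function(x) {
    last <- 0
    for (i in seq_along(x)) {
      if (is.na(x[i])) x[i] <- last else last <- x[i]
    }
    x
  }
  if (mode != "poisson") pv_det <- hold_last(pv_det)
  if (mode != "deterministic") pv_poi <- hold_last(pv_poi)
  data.frame(bin = seq_along(centres),
             k = centres,
             t_seconds = p$t_seconds[centres],
             bayes = p$mean_theta[centres],
             pv_det = pv_det,
             pv_poisson = pv_poi,
             spikes = spikes)
}
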