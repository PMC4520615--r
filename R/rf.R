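# deterministic rate of one direction-tuned neuron over a run's predictive
# beliefs: posterior direction-marginal density at the preferred direction
# (alias nearest the belief mean). The proposal-density divisor is a
# constant for one neuron and cancels in best-ITD/width extraction.
neuron_rate_series <- function(pred, theta_n, omega_n) {
  mu1 <- pred$mean_theta_unwrapped
  th <- theta_n + 360 * round((mu1 - theta_n) / 360)
  stats::dnorm(th, mu1, sqrt(pred$s11))
}

# Covariance of the Kalman predictive *mean* over observation-noise
# realisations. The filtered mean is linear in the observations, so its
# deviation from the noise-free run obeys e_k = (I - L_k C) A e_{k-1} +
# L_k xi_k, giving a deterministic covariance recursion (gains are
# observation-independent). Returns the predictive-mean direction variance
# per step; adding it to the posterior variance yields the exact
# trial-averaged rate map.
kf_estimator_noise_var <- function(model, prior, K, n) {
  dt <- model$dt
  c_obs <- model$C[1, 1]
  R <- model$R
  q1 <- model$Q[1, 1]
  q2 <- model$Q[2, 2]
  a <- n * dt
  s11 <- prior$cov[1, 1]; s12 <- prior$cov[1, 2]; s22 <- prior$cov[2, 2]
  p11 <- p12 <- p22 <- 0
  out <- numeric(K)
  for (k in seq_len(K)) {
    s11 <- s11 + 2 * dt * s12 + dt^2 * s22 + q1
    s12 <- s12 + dt * s22
    s22 <- s22 + q2
    S <- c_obs^2 * s11 + R
    L1 <- s11 * c_obs / S
    L2 <- s12 * c_obs / S
    f <- 1 - L1 * c_obs
    # error transition M = (I - L C) A
    m11 <- f;          m12 <- f * dt
    m21 <- -L2 * c_obs; m22 <- 1 - L2 * c_obs * dt
    u11 <- m11 * p11 + m12 * p12
    u12 <- m11 * p12 + m12 * p22
    u21 <- m21 * p11 + m22 * p12
    u22 <- m21 * p12 + m22 * p22
    p11n <- u11 * m11 + u12 * m12 + R * L1 * L1
    p12n <- u11 * m21 + u12 * m22 + R * L1 * L2
    p22n <- u21 * m21 + u22 * m22 + R * L2 * L2
    p11 <- p11n; p12 <- p12n; p22 <- p22n
    s22 <- s22 - L2 * c_obs * s12
    s11 <- f * s11
    s12 <- f * s12
    out[k] <- p11 + 2 * a * p12 + a^2 * p22
  }
  out
}

rf_uniform_config <- function(config) {
  sim_config(dt = config$dt, horizon_steps = config$horizon_steps,
             sigma_theta_noise = config$sigma_theta_noise,
             sigma_omega_noise = config$sigma_omega_noise,
             prior_mean = config$prior_mean,
             prior_sd = c(1e4, config$prior_sd[2]),
             prior_corr = 0,
             noise_scaling = config$noise_scaling)
}

#' Model receptive field of one neuron for a moving stimulus
#'
#' Maps a neuron's deterministic firing rate against elapsed time and the
#' stimulus's instantaneous ITD, the convention used when measuring
#' receptive-field shifts for moving sources. A family of constant-velocity
#' sweeps whose starting directions tile a band around the neuron is
#' played; for each sweep the Bayes filter runs on the ITD observations
#' and the neuron's rate at each step is the predictive posterior density
#' at its preferred stimulus. Rates are averaged into (time bin, ITD bin)
#' cells; the per-time best ITD (peak over the ITD axis, ties broken
#' toward the static preferred ITD, with parabolic sub-bin refinement on a
#' lightly smoothed profile) and full width at half maximum are extracted.
#'
#' Two estimators of the trial-averaged map are available.
#' \code{method = "expected"} (default) computes it exactly: the filtered
#' mean is linear in the observations, so the average over
#' observation-noise realisations is the noise-free run with the
#' posterior variance inflated by the analytic variance of the predictive
#' mean; no Monte Carlo noise enters. \code{method = "sampled"} follows
#' the empirical protocol instead, averaging \code{trials} runs with
#' fresh ITD noise over a jittered starting grid, and converges to the
#' expected map as trials grow.
#'
#' The receptive-field shift is reported as positive toward the
#' approaching source (the anticipatory direction), so that its magnitude
#' grows with source speed irrespective of the motion sense.
#'
#' @param neuron length-2 numeric: preferred (direction deg, velocity
#'   deg/s); preferred velocity 0 measures a standard spatial RF.
#' @param velocity source velocity; sign gives the motion sense
#'   (counterclockwise positive).
#' @param config a [sim_config()].
#' @param observation an [itd_model()] (linear form; Kalman reference).
#' @param prior \code{"gaussian"} (the configured prior) or
#'   \code{"uniform"} (a diffuse, uncorrelated direction prior).
#' @param velocity_units \code{"deg_s"} or \code{"itd_us_s"}.
#' @param method \code{"expected"} (exact trial average) or
#'   \code{"sampled"} (Monte Carlo protocol); see Details.
#' @param trials noisy-ITD repetitions per sweep for
#'   \code{method = "sampled"} (default 20).
#' @param starts sweep starting directions, degrees. The default tiles a
#'   90-deg band either side of the neuron's preferred direction (the
#'   frontal hemisphere for a midline neuron), so stimulus coverage
#'   around the receptive field is balanced for both motion senses at any
#'   eccentricity; 1-deg steps for the expected map, 5-deg steps
#'   (jittered per trial) for the sampled protocol.
#' @param duration_s sweep duration, seconds.
#' @param time_bin_s,itd_bin_us bin sizes for the rate map.
#' @param seed optional integer seed for the observation noise.
#' @return An object of class \code{"receptive_field"}: the rate map
#'   (time x ITD), bin centres, static preferred ITD, and per-time-bin
#'   \code{best_itd}, \code{width} and \code{shift} (microseconds).
#' @export
receptive_field <- function(neuron, velocity,
                            config = sim_config(),
                            observation = itd_model("linear"),
                            prior = c("gaussian", "uniform"),
                            velocity_units = c("deg_s", "itd_us_s"),
                            method = c("expected", "sampled"),
                            trials = 20L,
                            starts = NULL,
                            duration_s = 1,
                            time_bin_s = 0.02,
                            itd_bin_us = 2,
                            seed = NULL) {
  prior <- match.arg(prior)
  velocity_units <- match.arg(velocity_units)
  method <- match.arg(method)
  stopifnot(length(neuron) == 2L, is.finite(velocity), trials >= 1L)
  if (!is.null(seed)) set.seed(seed)
  v <- if (velocity_units == "itd_us_s")
    itd_velocity_to_deg(velocity, observation$slope) else velocity
  cfg <- if (prior == "uniform") rf_uniform_config(config) else config
  if (is.null(starts))
    starts <- neuron[1] + seq(-90, 90, by = if (method == "expected") 1 else 5)
  static_itd <- itd_of_direction(neuron[1], observation)

  n_tbin <- floor(duration_s / time_bin_s)
  t_edges <- seq(0, n_tbin * time_bin_s, by = time_bin_s)
  t_centres <- t_edges[-1] - time_bin_s / 2

  spacing <- if (length(starts) > 1L) min(diff(sort(starts))) else 0
  margin <- max(abs(starts)) + spacing + abs(v) * duration_s
  i_edges <- seq(-(ceiling(abs(itd_of_direction(-margin, observation)) /
                             itd_bin_us) + 1) * itd_bin_us,
                 (ceiling(abs(itd_of_direction(margin, observation)) /
                            itd_bin_us) + 1) * itd_bin_us,
                 by = itd_bin_us)
  i_centres <- i_edges[-1] - itd_bin_us / 2

  acc <- matrix(0, n_tbin, length(i_centres))
  cnt <- matrix(0, n_tbin, length(i_centres))
  lm <- linear_model(cfg, observation)
  add_run <- function(sw, r) {
    tb <- pmin(pmax(floor(sw$t_seconds / time_bin_s) + 1L, 1L), n_tbin)
    ib <- findInterval(itd_of_direction(sw$theta_deg, observation),
                       i_edges, rightmost.closed = TRUE)
    for (k in seq_along(r)) {
      acc[tb[k], ib[k]] <<- acc[tb[k], ib[k]] + r[k]
      cnt[tb[k], ib[k]] <<- cnt[tb[k], ib[k]] + 1
    }
  }
  if (method == "expected") {
    # The filter output is linear in the observations, hence in the sweep
    # start: two noise-free runs (starts 0 and 1) give the predictive mean
    # of the sweep through any (time, ITD) lattice point exactly, so the
    # map is evaluated continuously instead of being accumulated from a
    # finite sweep family.
    K <- round(duration_s / cfg$dt) + 1L
    n <- cfg$horizon_steps
    mean_var <- kf_estimator_noise_var(lm, prior_belief(cfg), K, n)
    base <- constant_velocity_sweep(0, v, duration_s, cfg)
    runA <- run_kalman(itd_of_direction(base$theta_unwrapped, observation),
                       lm, prior_belief(cfg), n)
    runB <- run_kalman(itd_of_direction(base$theta_unwrapped + 1, observation),
                       lm, prior_belief(cfg), n)
    muA <- runA$predicted[, "mean_theta"]
    gain <- runB$predicted[, "mean_theta"] - muA
    sdp <- sqrt(runA$predicted[, "s11"] + mean_var)
    t_steps <- base$t_seconds
    tb_of_k <- pmin(pmax(floor(t_steps / time_bin_s) + 1L, 1L), n_tbin)
    for (k in seq_len(K)) {
      # sweep reaching stimulus ITD x at step k starts at x/slope - v t
      s0 <- i_centres / observation$slope - v * t_steps[k]
      mu <- muA[k] + s0 * gain[k]
      r <- stats::dnorm(alias_theta(neuron[1], mu), mu, sdp[k])
      keep <- s0 >= min(starts) & s0 <= max(starts)
      tb <- tb_of_k[k]
      acc[tb, keep] <- acc[tb, keep] + r[keep]
      cnt[tb, keep] <- cnt[tb, keep] + 1
    }
  } else {
    for (tr in seq_len(trials)) {
      # jitter the grid each trial so stimulus ITDs sample the axis
      # continuously rather than on the grid's comb
      off <- if (spacing > 0) stats::runif(1, 0, spacing) else 0
      for (s0 in starts) {
        sw <- constant_velocity_sweep(s0 + off, v, duration_s, cfg)
        itd <- observe(sw, observation)
        fit <- itd_track(itd, cfg, observation, method = "kalman")
        add_run(sw, neuron_rate_series(fit$predicted, neuron[1], neuron[2]))
      }
    }
  }
  rate <- acc / ifelse(cnt > 0, cnt, NA)
  # meaningful density values are O(0.01-1) per degree; a map whose peak
  # sits 30+ posterior widths away is empty for any practical purpose
  if (!any(is.finite(rate)) || max(rate, na.rm = TRUE) < 1e-30)
    warning("empty receptive field: the neuron's rate is zero over the protocol")

  best <- width <- rep(NA_real_, n_tbin)
  # light Gaussian smoothing (sd = one ITD bin) before peak extraction
  # suppresses trial-sampling jitter in the argmax; the stored rate map
  # stays raw
  kern <- stats::dnorm(-3:3)
  kern <- kern / sum(kern)
  for (ti in seq_len(n_tbin)) {
    r0 <- rate[ti, ]
    if (all(!is.finite(r0))) next
    r <- ifelse(is.finite(r0), r0, 0)
    r <- as.numeric(stats::filter(r, kern, sides = 2))
    r[is.na(r)] <- 0
    mx <- max(r)
    if (mx <= 0) next
    at_max <- which(r >= mx * (1 - 1e-12))
    j <- at_max[which.min(abs(i_centres[at_max] - static_itd))]
    b <- i_centres[j]
    # parabolic sub-bin refinement around the peak
    if (j > 1L && j < length(r)) {
      den <- r[j - 1L] - 2 * r[j] + r[j + 1L]
      if (den < 0) b <- b + 0.5 * itd_bin_us * (r[j - 1L] - r[j + 1L]) / den
    }
    best[ti] <- b
    # full width at half maximum by linear interpolation on the smoothed
    # profile
    above <- r >= mx / 2
    lo <- min(which(above))
    hi <- max(which(above))
    left <- if (lo > 1L)
      i_centres[lo] - itd_bin_us * (r[lo] - mx / 2) / (r[lo] - r[lo - 1L])
      else i_centres[lo] - itd_bin_us / 2
    right <- if (hi < length(r))
      i_centres[hi] + itd_bin_us * (r[hi] - mx / 2) / (r[hi] - r[hi + 1L])
      else i_centres[hi] + itd_bin_us / 2
    width[ti] <- right - left
  }
  raw_shift <- best - static_itd
  shift <- if (v == 0) raw_shift else -sign(v) * raw_shift
  structure(list(rate = rate,
                 time_centres = t_centres,
                 itd_centres = i_centres,
                 static_itd = static_itd,
                 best_itd = best,
                 width = width,
                 shift = shift,
                 raw_shift = raw_shift,
                 neuron = neuron,
                 velocity_deg_s = v,
                 prior = prior,
                 method = method,
                 trials = if (method == "sampled") trials else NA_integer_,
                 time_bin_s = time_bin_s,
                 itd_bin_us = itd_bin_us),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("Receptive field: neuron (%g deg, %g deg/s), source %.2f deg/s, %s prior\n",
              x$neuron[1], x$neuron[2], x$velocity_deg_s, x$prior))
  cat(sprintf("  static preferred ITD %.1f us; terminal shift %.1f us; width %.0f -> %.0f us\n",
              x$static_itd, utils::tail(stats::na.omit(x$shift), 1),
              utils::head(stats::na.omit(x$width), 1),
              utils::tail(stats::na.omit(x$width), 1)))
  invisible(x)
}

#' @export
plot.receptive_field <- function(x, ...) {
  graphics::image(x$time_centres, x$itd_centres, x$rate,
                  xlab = "time (s)", ylab = "stimulus ITD (us)",
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE), ...)
  graphics::abline(h = x$static_itd, lwd = 1)
  graphics::points(x$time_centres, x$best_itd, pch = 8)
  invisible(x)
}

#' Receptive-field shift versus source velocity
#'
#' Computes the best-ITD shift curve of one neuron for each velocity in a
#' list (stated as ITD change per second by convention; converted through
#' the linear slope).
#'
#' @param neuron length-2 numeric preferred (direction, velocity).
#' @param velocities source velocities in microseconds of ITD per second.
#' @param ... passed to [receptive_field()].
#' @return A data frame with columns \code{velocity_itd_us_s},
#'   \code{time_s}, \code{shift_us} (positive toward the approaching
#'   source) and \code{width_us}.
#' @export
shift_vs_velocity <- function(neuron, velocities = c(5, 20, 40, 80), ...) {
  if (length(velocities) == 0L) stop("'velocities' must be nonempty")
  do.call(rbind, lapply(velocities, function(v) {
    rf <- receptive_field(neuron, v, velocity_units = "itd_us_s", ...)
    data.frame(velocity_itd_us_s = v, time_s = rf$time_centres,
               shift_us = rf$shift, width_us = rf$width)
  }))
}

#' Clockwise/counterclockwise shift asymmetry across eccentricities
#'
#' For each preferred direction, computes the raw best-ITD shift curves
#' for counterclockwise and clockwise motion and the asymmetry index: the
#' maximum absolute deviation of the CCW curve from the sign-flipped CW
#' curve (zero for mirror-image shifts). A prior emphasising the centre of
#' gaze makes the shifts asymmetric for eccentric neurons; a uniform prior
#' restores the symmetry.
#'
#' @param preferred_thetas preferred directions to probe, degrees.
#' @param velocity source speed, deg/s (applied as +v and -v).
#' @param ... passed to [receptive_field()].
#' @return A list with \code{curves} (per neuron and motion sense, raw
#'   signed shift in microseconds over time) and \code{index} (one
#'   asymmetry index per preferred direction, microseconds).
#' @export
asymmetry_profile <- function(preferred_thetas, velocity = 15, ...) {
  if (length(preferred_thetas) == 0L) stop("'preferred_thetas' must be nonempty")
  curves <- list()
  idx <- numeric(length(preferred_thetas))
  for (i in seq_along(preferred_thetas)) {
    th <- preferred_thetas[i]
    ccw <- receptive_field(c(th, 0), velocity, ...)
    cw <- receptive_field(c(th, 0), -velocity, ...)
    curves[[i]] <- data.frame(
      preferred_theta = th,
      sense = rep(c("ccw", "cw"), each = length(ccw$time_centres)),
      time_s = c(ccw$time_centres, cw$time_centres),
      shift_raw_us = c(ccw$raw_shift, cw$raw_shift))
    idx[i] <- max(abs(ccw$raw_shift + cw$raw_shift), na.rm = TRUE)
  }
  list(curves = do.call(rbind, curves),
       index = data.frame(preferred_theta = preferred_thetas,
                          asymmetry_index_us = idx))
}

#' Robustness of the shift to individual parameter changes
#'
#' Recomputes the shift and width curves with one model parameter scaled
#' by each factor (parameters changed individually; all others at their
#' configured values).
#'
#' @param neuron length-2 numeric preferred (direction, velocity).
#' @param parameter one of \code{"itd_noise_sd"}, \code{"theta_noise_sd"},
#'   \code{"omega_noise_sd"}, \code{"prior_theta_sd"},
#'   \code{"prior_omega_sd"}.
#' @param factors multiplicative factors (default 0.5, 1, 2).
#' @param velocity source velocity, deg/s.
#' @param config a [sim_config()] holding the baseline parameters.
#' @param observation an [itd_model()] holding the baseline ITD noise.
#' @param ... passed to [receptive_field()].
#' @return A data frame with columns \code{parameter}, \code{factor},
#'   \code{time_s}, \code{shift_us}, \code{width_us}.
#' @export
parameter_sweep <- function(neuron, parameter = c("itd_noise_sd",
                                                  "theta_noise_sd",
                                                  "omega_noise_sd",
                                                  "prior_theta_sd",
                                                  "prior_omega_sd"),
                            factors = c(0.5, 1, 2),
                            velocity = 15,
                            config = sim_config(),
                            observation = itd_model("linear"),
                            ...) {
  parameter <- match.arg(parameter)
  stopifnot(length(neuron) == 2L)
  do.call(rbind, lapply(factors, function(f) {
    cfg <- config
    obs <- observation
    if (parameter == "itd_noise_sd") {
      obs <- itd_model(observation$form, slope = observation$slope,
                       amplitude = observation$amplitude,
                       frequency = observation$frequency,
                       noise_sd = observation$noise_sd * f)
    } else {
      sd_th <- config$sigma_theta_noise
      sd_om <- config$sigma_omega_noise
      p_sd <- config$prior_sd
      if (parameter == "theta_noise_sd") sd_th <- sd_th * f
      if (parameter == "omega_noise_sd") sd_om <- sd_om * f
      if (parameter == "prior_theta_sd") p_sd[1] <- p_sd[1] * f
      if (parameter == "prior_omega_sd") p_sd[2] <- p_sd[2] * f
      cfg <- sim_config(dt = config$dt, horizon_steps = config$horizon_steps,
                        sigma_theta_noise = sd_th, sigma_omega_noise = sd_om,
                        prior_mean = config$prior_mean, prior_sd = p_sd,
                        prior_corr = config$prior_corr,
                        noise_scaling = config$noise_scaling)
    }
    rf <- receptive_field(neuron, velocity, config = cfg, observation = obs, ...)
    data.frame(parameter = parameter, factor = f, time_s = rf$time_centres,
               shift_us = rf$shift, width_us = rf$width)
  }))
}
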