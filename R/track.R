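#' Bayesian tracking and n-step-ahead prediction from an ITD sequence
#'
#' Fits the Bayes filter for a moving sound source to an observed ITD
#' sequence and extrapolates the posterior \code{horizon_steps} steps ahead
#' at every step, yielding both the tracking belief (k | k) and the
#' predictive belief (k+n | k). With \code{method = "kalman"} the
#' linear-Gaussian model is solved exactly by the Kalman filter (linear
#' observation form only; the state is kept unwrapped during the run and
#' wrapped for reporting). With \code{method = "particle"} a sequential
#' importance resampling filter handles the sinusoidal (or linear)
#' observation form with \code{m} particles.
#'
#' @param itd an \code{itd_sequence} from [observe()], or a numeric vector
#'   of ITDs (microseconds).
#' @param config a [sim_config()]; supplies the prior, dynamics noise and
#'   prediction horizon.
#' @param observation an [itd_model()].
#' @param method \code{"kalman"} or \code{"particle"}.
#' @param m particle count (particle method only; default 10,000).
#' @param predict_at steps at which to evaluate the predictive belief
#'   (particle method; default every step). The Kalman predictive belief is
#'   cheap and always evaluated everywhere.
#' @param resample_scheme resampling scheme for the particle method.
#' @param seed optional integer seed (particle method and any downstream
#'   stochastic use).
#' @return An object of class \code{"itd_track"} with components
#'   \code{filtered} and \code{predicted} (data frames with columns
#'   \code{k}, \code{t_seconds}, \code{mean_theta} (wrapped),
#'   \code{mean_theta_unwrapped}, \code{mean_omega}, \code{s11}, \code{s12},
#'   \code{s22}, \code{kind}), the horizon, the models, and (Kalman) the
#'   innovation sequence.
#' @examples
#' cfg <- sim_config()
#' sw <- constant_velocity_sweep(20, -50, 0.5, cfg)
#' itd <- observe(sw, itd_model("linear"), seed = 1)
#' fit <- itd_track(itd, cfg)
#' fit
#' head(predict(fit))
#' @export
itd_track <- function(itd,
                      config = sim_config(),
                      observation = itd_model("linear"),
                      method = c("kalman", "particle"),
                      m = 10000L,
                      predict_at = NULL,
                      resample_scheme = c("multinomial", "systematic"),
                      seed = NULL) {
  method <- match.arg(method)
  resample_scheme <- match.arg(resample_scheme)
  stopifnot(inherits(config, "sim_config"), inherits(observation, "itd_model"))
  itds <- as.numeric(itd)
  K <- length(itds)
  if (K < 1L) stop("empty ITD sequence")
  dt <- if (!is.null(attr(itd, "dt"))) attr(itd, "dt") else config$dt
  if (abs(dt - config$dt) > 1e-12)
    stop("ITD sequence dt does not match the configuration dt")
  n <- config$horizon_steps
  t <- (seq_len(K) - 1) * dt

  if (method == "kalman") {
    lm <- linear_model(config, observation)
    run <- run_kalman(itds, lm, prior_belief(config), n)
    filtered <- as.data.frame(run$filtered)
    predicted <- as.data.frame(run$predicted)
    innovations <- run$innovations
  } else {
    run <- run_particle(itds, config, observation, m = m, n = n,
                        predict_at = predict_at, seed = seed,
                        resample_scheme = resample_scheme)
    filtered <- as.data.frame(run$filtered)
    filtered$s11 <- filtered$s12 <- filtered$s22 <- NA_real_
    filtered$ess <- NULL
    predicted <- as.data.frame(run$predicted)
    innovations <- NULL
  }
  shape <- function(df, kind, tt) {
    data.frame(k = seq_len(K), t_seconds = tt,
               mean_theta = wrap_deg(df$mean_theta),
               mean_theta_unwrapped = df$mean_theta,
               mean_omega = df$mean_omega,
               s11 = df$s11, s12 = df$s12, s22 = df$s22,
               kind = kind)
  }
  structure(list(
    call = match.call(),
    method = method,
    config = config,
    observation = observation,
    horizon_steps = n,
    horizon_seconds = n * dt,
    itd = itds,
    filtered = shape(filtered, "tracking", t),
    predicted = shape(predicted,
                      if (method == "kalman") "predictive" else "pf_predictive",
                      t + n * dt),
    innovations = innovations,
    m = if (method == "particle") as.integer(m) else NULL,
    seed = seed), class = "itd_track")
}

#' @export
print.itd_track <- function(x, ...) {
  cat(sprintf("ITD track (%s filter): %d steps, dt = %g s, lead %.3f s (%d steps)\n",
              x$method, nrow(x$filtered), x$config$dt,
              x$horizon_seconds, x$horizon_steps))
  if (x$method == "particle")
    cat(sprintf("  particles: m = %d\n", x$m))
  last <- nrow(x$filtered)
  cat(sprintf("  final state: theta %.2f deg, omega %.2f deg/s; predicted (+%d): %.2f deg\n",
              x$filtered$mean_theta[last], x$filtered$mean_omega[last],
              x$horizon_steps, x$predicted$mean_theta[last]))
  invisible(x)
}

#' @export
summary.itd_track <- function(object, ...) {
  f <- object$filtered
  p <- object$predicted
  out <- list(
    method = object$method,
    steps = nrow(f),
    dt = object$config$dt,
    horizon_seconds = object$horizon_seconds,
    final_state = c(theta = f$mean_theta[nrow(f)], omega = f$mean_omega[nrow(f)]),
    innovation_rms = if (!is.null(object$innovations))
      sqrt(mean(object$innovations^2)) else NA_real_,
    mean_tracking_sd = mean(sqrt(f$s11)),
    mean_predictive_sd = mean(sqrt(p$s11), na.rm = TRUE))
  class(out) <- "summary.itd_track"
  out
}

#' @export
print.summary.itd_track <- function(x, ...) {
  cat(sprintf("ITD track summary (%s): %d steps of %g s, prediction lead %.3f s\n",
              x$method, x$steps, x$dt, x$horizon_seconds))
  cat(sprintf("  final state: theta %.2f deg, omega %.2f deg/s\n",
              x$final_state["theta"], x$final_state["omega"]))
  if (is.finite(x$innovation_rms))
    cat(sprintf("  ITD innovation RMS: %.2f us\n", x$innovation_rms))
  cat(sprintf("  mean posterior sd: tracking %.2f deg, predictive %.2f deg\n",
              x$mean_tracking_sd, x$mean_predictive_sd))
  invisible(x)
}

#' Tracking direction estimates
#'
#' @param object an [itd_track()] fit.
#' @param ... unused.
#' @return The per-step filtered direction means (wrapped), degrees.
#' @export
fitted.itd_track <- function(object, ...) {
  object$filtered$mean_theta
}

#' Final filtered state estimate
#'
#' @param object an [itd_track()] fit.
#' @param ... unused.
#' @return Named vector \code{c(theta, omega)} at the last step.
#' @export
coef.itd_track <- function(object, ...) {
  f <- object$filtered
  c(theta = f$mean_theta[nrow(f)], omega = f$mean_omega[nrow(f)])
}

#' One-step ITD innovations
#'
#' @param object an [itd_track()] fit.
#' @param ... unused.
#' @return For the Kalman method, the innovation sequence
#'   \eqn{ITD_k - C \hat x_{k|k-1}} (microseconds). For the particle
#'   method, the residual of the observed ITD against the tracked
#'   direction mapped through the observation model.
#' @export
residuals.itd_track <- function(object, ...) {
  if (!is.null(object$innovations)) return(object$innovations)
  object$itd - itd_of_direction(object$filtered$mean_theta, object$observation)
}

#' Predictive beliefs of a fitted track
#'
#' Returns the stored n-step-ahead predictive beliefs, or (Kalman method)
#' re-extrapolates the filtered beliefs to a different lookahead.
#'
#' @param object an [itd_track()] fit.
#' @param n optional new lookahead in steps; \code{NULL} returns the stored
#'   horizon. Only the Kalman method supports re-extrapolation.
#' @param ... unused.
#' @return A data frame in the same shape as \code{object$predicted}.
#' @export
predict.itd_track <- function(object, n = NULL, ...) {
  if (is.null(n) || n == object$horizon_steps) return(object$predicted)
  if (object$method != "kalman")
    stop("re-extrapolation to a new horizon requires the Kalman method")
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be nonnegative")
  lm <- linear_model(object$config, object$observation)
  dt <- lm$dt
  a <- n * dt
  W <- kf_wn(n, dt, lm$Q[1, 1], lm$Q[2, 2])
  f <- object$filtered
  th <- f$mean_theta_unwrapped + a * f$mean_omega
  data.frame(k = f$k, t_seconds = f$t_seconds + a,
             mean_theta = wrap_deg(th),
             mean_theta_unwrapped = th,
             mean_omega = f$mean_omega,
             s11 = f$s11 + 2 * a * f$s12 + a^2 * f$s22 + W[1, 1],
             s12 = f$s12 + a * f$s22 + W[1, 2],
             s22 = f$s22 + W[2, 2],
             kind = "predictive")
}

#' Plot a fitted track
#'
#' Shows the tracked direction and the n-step-ahead prediction against
#' time, optionally overlaid on the true source trajectory.
#'
#' @param x an [itd_track()] fit.
#' @param trajectory optional \code{source_trajectory} to overlay.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.itd_track <- function(x, trajectory = NULL, ...) {
  f <- x$filtered
  p <- x$predicted
  yl <- range(f$mean_theta_unwrapped, p$mean_theta_unwrapped,
              if (!is.null(trajectory)) trajectory$theta_unwrapped, na.rm = TRUE)
  graphics::plot(f$t_seconds, f$mean_theta_unwrapped, type = "l",
                 xlab = "time (s)", ylab = "direction (deg)", ylim = yl, ...)
  graphics::lines(p$t_seconds, p$mean_theta_unwrapped, col = "tomato", lty = 2)
  if (!is.null(trajectory))
    graphics::lines(trajectory$t_seconds, trajectory$theta_unwrapped,
                    col = "grey50")
  graphics::legend("topleft", bty = "n",
                   legend = c("tracking", "prediction",
                              if (!is.null(trajectory)) "source"),
                   col = c("black", "tomato",
                           if (!is.null(trajectory)) "grey50"),
                   lty = c(1, 2, if (!is.null(trajectory)) 1))
  invisible(x)
}
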