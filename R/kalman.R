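#' Gaussian belief over (direction, velocity)
#'
#' The mean and covariance of the posterior over the source state at step
#' \code{step} given observations up to step \code{last_obs}; the pair
#' records the conditioning (i | j) of the belief.
#'
#' @param mean length-2 numeric, (direction deg, velocity deg/s). The
#'   direction is kept unwrapped inside a filter run (the linear map is a
#'   frontal approximation) and wrapped only at reporting.
#' @param cov 2x2 symmetric positive-semidefinite covariance.
#' @param step step index i the belief refers to.
#' @param last_obs last observation step j the belief conditions on.
#' @return An object of class \code{"gaussian_belief"}.
#' @export
gaussian_belief <- function(mean, cov, step = 0L, last_obs = 0L) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 2L, all(dim(cov) == c(2L, 2L)))
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev)))
    stop("covariance must be positive semidefinite")
  structure(list(mean = mean, cov = cov,
                 step = as.integer(step), last_obs = as.integer(last_obs)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("Gaussian belief (%d | %d): theta %.3f deg (sd %.3f), omega %.3f deg/s (sd %.3f)\n",
              x$step, x$last_obs, wrap_deg(x$mean[1]), sqrt(x$cov[1, 1]),
              x$mean[2], sqrt(x$cov[2, 2])))
  invisible(x)
}

#' Prior belief from a configuration
#'
#' @param config a [sim_config()].
#' @return A [gaussian_belief()] at step 0 holding the configured prior mean
#'   and covariance, including the direction-velocity correlation.
#' @export
prior_belief <- function(config) {
  gaussian_belief(config$prior_mean, prior_cov(config), step = 0L, last_obs = 0L)
}

#' Linear-Gaussian state-space model for Kalman prediction
#'
#' Assembles the matrices of the tracking model: state transition
#' \eqn{A = [1, \Delta t; 0, 1]}, observation row \eqn{C = [s, 0]} with the
#' linear ITD slope s, process noise covariance Q (diagonal, from the
#' per-step dynamics noise), and observation noise variance R (squared ITD
#' noise sd). All unit conversions live here: Q in deg^2 and deg^2/s^2, R in
#' microseconds^2, C in microseconds/deg.
#'
#' @param config a [sim_config()].
#' @param observation an [itd_model()]; must be the linear form.
#' @return An object of class \code{"linear_model"} with elements \code{A},
#'   \code{C}, \code{Q}, \code{R}, \code{dt}.
#' @export
linear_model <- function(config, observation = itd_model("linear")) {
  stopifnot(inherits(config, "sim_config"), inherits(observation, "itd_model"))
  if (observation$form != "linear")
    stop("Kalman tracking requires the linear observation form")
  sd <- step_noise_sd(config)
  structure(list(
    A = matrix(c(1, 0, config$dt, 1), 2, 2),
    C = matrix(c(observation$slope, 0), 1, 2),
    Q = diag(c(sd[["theta"]]^2, sd[["omega"]]^2)),
    R = observation$noise_sd^2,
    dt = config$dt), class = "linear_model")
}

#' One-step Kalman prediction
#'
#' Advances a filtered belief (k-1 | k-1) to the one-step-ahead belief
#' (k | k-1): mean \eqn{A \hat x}, covariance \eqn{A \Sigma A^T + Q}.
#'
#' @param belief a [gaussian_belief()] conditioned as (k-1 | k-1).
#' @param model a [linear_model()].
#' @return The predicted [gaussian_belief()] at (k | k-1).
#' @export
kf_predict_one <- function(belief, model) {
  stopifnot(inherits(belief, "gaussian_belief"), inherits(model, "linear_model"))
  gaussian_belief(drop(model$A %*% belief$mean),
                  model$A %*% belief$cov %*% t(model$A) + model$Q,
                  step = belief$step + 1L, last_obs = belief$last_obs)
}

#' Kalman measurement update
#'
#' Folds one ITD observation into a predicted belief (k | k-1) using the
#' Kalman gain \eqn{L_k = \Sigma C^T (C \Sigma C^T + R)^{-1}}, giving the
#' filtered belief (k | k).
#'
#' @param belief a [gaussian_belief()] conditioned as (k | k-1).
#' @param itd observed ITD at step k, microseconds.
#' @param model a [linear_model()].
#' @return The updated [gaussian_belief()] at (k | k).
#' @export
kf_update <- function(belief, itd, model) {
  stopifnot(inherits(belief, "gaussian_belief"), inherits(model, "linear_model"))
  S <- drop(model$C %*% belief$cov %*% t(model$C)) + model$R
  if (S <= 0) stop("degenerate update: innovation variance is zero")
  L <- belief$cov %*% t(model$C) / S
  mean <- belief$mean + drop(L) * drop(itd - model$C %*% belief$mean)
  cov <- (diag(2) - L %*% model$C) %*% belief$cov
  gaussian_belief(mean, (cov + t(cov)) / 2,
                  step = belief$step, last_obs = belief$step)
}

# Accumulated process noise over n steps:
# W_n = sum_{m=1}^{n} A^(m-1) Q (A^(m-1))^T, in closed form for the shear A.
kf_wn <- function(n, dt, q1, q2) {
  if (n == 0L) return(matrix(0, 2, 2))
  s1 <- n * (n - 1) / 2
  s2 <- (n - 1) * n * (2 * n - 1) / 6
  matrix(c(n * q1 + dt^2 * q2 * s2, dt * q2 * s1,
           dt * q2 * s1, n * q2), 2, 2)
}

#' n-step-ahead Kalman extrapolation
#'
#' From a filtered belief (k | k), computes the predictive belief
#' (k+n | k): mean \eqn{A^n \hat x_{k|k}} and covariance
#' \deqn{\Sigma_{k+n|k} = \sum_{m=1}^{n} A^{m-1} Q (A^{m-1})^T
#'   + A^n \Sigma_{k|k} (A^n)^T.}
#' The noise sum is evaluated in closed form by default; \code{method =
#' "loop"} evaluates it by explicit accumulation (the two agree to machine
#' precision and the loop serves as a cross-check).
#'
#' @param belief a [gaussian_belief()] conditioned as (k | k).
#' @param model a [linear_model()].
#' @param n number of steps ahead (>= 0); \code{n = 0} returns the input.
#' @param method \code{"closed_form"} (default) or \code{"loop"}.
#' @return The predictive [gaussian_belief()] at (k+n | k).
#' @export
kf_predict_n <- function(belief, model, n, method = c("closed_form", "loop")) {
  stopifnot(inherits(belief, "gaussian_belief"), inherits(model, "linear_model"))
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be nonnegative")
  if (n == 0L) return(belief)
  dt <- model$dt
  An <- matrix(c(1, 0, n * dt, 1), 2, 2)
  W <- if (method == "closed_form") {
    kf_wn(n, dt, model$Q[1, 1], model$Q[2, 2])
  } else {
    acc <- matrix(0, 2, 2)
    for (m in seq_len(n)) {
      Am <- matrix(c(1, 0, (m - 1) * dt, 1), 2, 2)
      acc <- acc + Am %*% model$Q %*% t(Am)
    }
    acc
  }
  gaussian_belief(drop(An %*% belief$mean),
                  An %*% belief$cov %*% t(An) + W,
                  step = belief$step + n, last_obs = belief$last_obs)
}

# Fast scalar Kalman filtering + n-step prediction over a whole ITD
# sequence. Returns matrices of filtered and predictive means/covariances;
# used by itd_track() and the evaluation grid.
run_kalman <- function(itds, model, prior, n) {
  K <- length(itds)
  c_obs <- model$C[1, 1]
  R <- model$R
  dt <- model$dt
  q1 <- model$Q[1, 1]
  q2 <- model$Q[2, 2]
  W <- kf_wn(n, dt, q1, q2)
  a <- n * dt

  m1 <- prior$mean[1]; m2 <- prior$mean[2]
  s11 <- prior$cov[1, 1]; s12 <- prior$cov[1, 2]; s22 <- prior$cov[2, 2]

  filt <- matrix(NA_real_, K, 5)
  pred <- matrix(NA_real_, K, 5)
  innov <- numeric(K)

  for (k in seq_len(K)) {
    # time update (k-1|k-1) -> (k|k-1)
    m1 <- m1 + dt * m2
    s11 <- s11 + 2 * dt * s12 + dt^2 * s22 + q1
    s12 <- s12 + dt * s22
    s22 <- s22 + q2
    # measurement update
    S <- c_obs^2 * s11 + R
    v <- itds[k] - c_obs * m1
    innov[k] <- v
    L1 <- s11 * c_obs / S
    L2 <- s12 * c_obs / S
    m1 <- m1 + L1 * v
    m2 <- m2 + L2 * v
    f <- 1 - L1 * c_obs
    s22 <- s22 - L2 * c_obs * s12
    s11 <- f * s11
    s12 <- f * s12
    filt[k, ] <- c(m1, m2, s11, s12, s22)
    # n-step-ahead extrapolation (k+n|k)
    pred[k, ] <- c(m1 + a * m2, m2,
                   s11 + 2 * a * s12 + a^2 * s22 + W[1, 1],
                   s12 + a * s22 + W[1, 2],
                   s22 + W[2, 2])
  }
  colnames(filt) <- colnames(pred) <-
    c("mean_theta", "mean_omega", "s11", "s12", "s22")
  list(filtered = filt, predicted = pred, innovations = innov)
}
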