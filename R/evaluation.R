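#' Wrap-aware RMS angular error between two direction series
#'
#' Discrete form of \eqn{\sqrt{\frac{1}{T}\int_0^T (\theta_a(t) -
#' \theta_b(t))^2 dt}} with each difference wrapped to the circle, so
#' series straddling +/-180 deg are compared correctly.
#'
#' @param a,b direction series in degrees, equal length.
#' @return RMS error in degrees.
#' @examples
#' rms_angular(c(179, 179), c(-179, -179))  # 2, not 358
#' @export
rms_angular <- function(a, b) {
  if (length(a) != length(b)) stop("direction series must have equal lengths")
  if (length(a) == 0L) stop("empty direction series")
  sqrt(mean(ang_diff_deg(a, b)^2))
}

#' Fraction of time a direction series is frontal
#'
#' @param predicted direction series in degrees.
#' @return Fraction of steps with \code{|theta| <= 90} (the boundary counts
#'   as frontal); the behind-head fraction is one minus this.
#' @export
frontal_fraction <- function(predicted) {
  if (length(predicted) == 0L) stop("empty direction series")
  mean(abs(wrap_deg(predicted)) <= 90)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (via
#' \code{stats::cor(method = "spearman")}).
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @return Correlation in \code{[-1, 1]}.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal lengths")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Stimulus condition grid for the decoding evaluation
#'
#' The standard test battery: counterclockwise 1-s constant-velocity
#' sweeps with initial directions covering -180 to 180 deg in 10-deg steps
#' and angular velocities from 0 to 150 deg/s in 25-deg/s steps.
#'
#' @param init_dirs initial directions, degrees.
#' @param velocities angular velocities, deg/s (counterclockwise positive).
#' @param duration_s sweep duration, seconds.
#' @return A data frame of conditions with columns \code{init_dir} and
#'   \code{velocity}, plus attribute \code{duration_s}.
#' @export
condition_grid <- function(init_dirs = seq(-180, 180, by = 10),
                           velocities = seq(0, 150, by = 25),
                           duration_s = 1) {
  g <- expand.grid(init_dir = init_dirs, velocity = velocities,
                   KEEP.OUT.ATTRS = FALSE)
  attr(g, "duration_s") <- duration_s
  g
}

#' Population-vector fidelity over a grid of stimulus conditions
#'
#' For every condition: simulates the sweep, observes its ITD sequence,
#' runs Kalman prediction at the configured lookahead, decodes the
#' population vector from deterministic rates and from Poisson spike
#' counts, and records the wrap-aware RMS error of each readout against
#' the Bayesian prediction together with the frontal-time fraction of the
#' predicted trajectory.
#'
#' @param pop a [build_population()] population.
#' @param config a [sim_config()].
#' @param grid a [condition_grid()].
#' @param observation an [itd_model()] (linear form; the Bayes reference is
#'   the Kalman predictive mean).
#' @param seed integer seed fixing observation noise and Poisson spiking
#'   for the whole grid (bit-reproducible for a fixed seed).
#' @return A data frame of class \code{"pv_eval"} with one row per
#'   condition: \code{init_dir}, \code{velocity}, \code{rms_det},
#'   \code{rms_poisson}, \code{ratio} (det/Poisson), \code{frontal_frac},
#'   \code{behind_frac}, \code{stays_frontal}.
#' @seealso [summary.pv_eval()] for the headline statistics.
#' @export
run_grid <- function(pop, config = sim_config(), grid = condition_grid(),
                     observation = itd_model("linear"), seed = NULL) {
  stopifnot(inherits(pop, "itd_population"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  dur <- attr(grid, "duration_s")
  if (is.null(dur)) dur <- 1
  nC <- nrow(grid)
  out <- data.frame(grid,
                    rms_det = NA_real_, rms_poisson = NA_real_,
                    ratio = NA_real_,
                    frontal_frac = NA_real_, behind_frac = NA_real_,
                    stays_frontal = NA)
  for (i in seq_len(nC)) {
    traj <- constant_velocity_sweep(grid$init_dir[i], grid$velocity[i],
                                    dur, config)
    itd <- observe(traj, observation)
    fit <- itd_track(itd, config, observation, method = "kalman")
    dec <- pv_decode(fit, pop, mode = "both")
    out$rms_det[i] <- rms_angular(dec$pv_det, dec$bayes)
    out$rms_poisson[i] <- rms_angular(dec$pv_poisson, dec$bayes)
    out$ratio[i] <- if (out$rms_poisson[i] > 0)
      out$rms_det[i] / out$rms_poisson[i] else NA_real_
    out$frontal_frac[i] <- frontal_fraction(dec$bayes)
    out$behind_frac[i] <- 1 - out$frontal_frac[i]
    out$stays_frontal[i] <- all(abs(dec$bayes) <= 90)
  }
  structure(out, class = c("pv_eval", "data.frame"),
            seed = seed, N = pop$N, duration_s = dur)
}

#' Headline statistics of a decoding evaluation
#'
#' @param object a \code{pv_eval} table from [run_grid()].
#' @param max_velocity velocity bound (deg/s) for the fidelity statistic.
#' @param ... unused.
#' @return A list of class \code{"summary.pv_eval"}: the worst Poisson-mode
#'   RMS over qualifying conditions (velocity within bound, predicted
#'   trajectory entirely frontal), the Spearman rank correlation between
#'   per-condition RMS and behind-head time fraction, and the mean and sd
#'   of the deterministic/Poisson RMS ratio.
#' @export
summary.pv_eval <- function(object, max_velocity = 125, ...) {
  qual <- object$stays_frontal & object$velocity <= max_velocity
  rho <- spearman_rank(object$rms_poisson, object$behind_frac)
  out <- list(
    n_conditions = nrow(object),
    n_qualifying = sum(qual),
    max_velocity = max_velocity,
    max_rms_frontal = if (any(qual)) max(object$rms_poisson[qual]) else NA_real_,
    spearman_rms_behind = rho,
    ratio_mean = mean(object$ratio, na.rm = TRUE),
    ratio_sd = stats::sd(object$ratio, na.rm = TRUE))
  class(out) <- "summary.pv_eval"
  out
}

#' @export
print.summary.pv_eval <- function(x, ...) {
  cat(sprintf("PV-vs-Bayes decoding evaluation: %d conditions\n", x$n_conditions))
  cat(sprintf("  max RMS over %d frontal conditions (v <= %g deg/s): %.2f deg\n",
              x$n_qualifying, x$max_velocity, x$max_rms_frontal))
  cat(sprintf("  spearman(RMS, behind-head fraction): %.3f\n",
              x$spearman_rms_behind))
  cat(sprintf("  deterministic/Poisson RMS ratio: %.2f +/- %.2f\n",
              x$ratio_mean, x$ratio_sd))
  invisible(x)
}

#' @export
print.pv_eval <- function(x, ...) {
  cat(sprintf("PV decoding grid: %d conditions (seed %s)\n",
              nrow(x), format(attr(x, "seed"))))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE, ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Image of RMS error over the condition grid
#'
#' @param x a \code{pv_eval} table.
#' @param what column to display, default \code{"rms_poisson"}.
#' @param ... passed to [graphics::image()].
#' @export
plot.pv_eval <- function(x, what = "rms_poisson", ...) {
  dirs <- sort(unique(x$init_dir))
  vels <- sort(unique(x$velocity))
  z <- matrix(NA_real_, length(dirs), length(vels))
  for (i in seq_len(nrow(x))) {
    z[match(x$init_dir[i], dirs), match(x$velocity[i], vels)] <- x[[what]][i]
  }
  graphics::image(dirs, vels, z, xlab = "initial direction (deg)",
                  ylab = "velocity (deg/s)",
                  main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
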