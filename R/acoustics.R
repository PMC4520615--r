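#' Direction-to-ITD observation model
#'
#' The interaural time difference (ITD) carried by a source at direction
#' \eqn{\theta} is modelled either as a sinusoid,
#' \eqn{ITD = A \sin(2\pi f \theta)}, or as its frontal linear
#' approximation \eqn{ITD = s\,\theta} with slope \eqn{s = 2.67}
#' microseconds/deg. Observations add zero-mean Gaussian noise with
#' standard deviation \code{noise_sd} (default 12.5 microseconds).
#'
#' The sinusoid's amplitude and period are not uniquely constrained by the
#' frontal slope alone; the defaults place the ITD extrema at +/-90 deg
#' (\code{frequency = 1/360} cycles/deg) and match the linear slope at zero,
#' \eqn{A = s \cdot 180/\pi \approx 152.95} microseconds, so both forms have
#' the same derivative at the midline.
#'
#' @param form \code{"linear"} or \code{"sinusoid"}.
#' @param slope linear slope, microseconds per degree (> 0).
#' @param amplitude sinusoid amplitude A, microseconds; default matches the
#'   linear slope at \eqn{\theta = 0}.
#' @param frequency sinusoid frequency f, cycles per degree.
#' @param noise_sd observation noise standard deviation, microseconds.
#' @return An object of class \code{"itd_model"}.
#' @examples
#' m <- itd_model("linear")
#' itd_of_direction(10, m)  # 26.7
#' @export
itd_model <- function(form = c("linear", "sinusoid"),
                      slope = 2.67,
                      amplitude = slope * 180 / pi,
                      frequency = 1 / 360,
                      noise_sd = 12.5) {
  form <- match.arg(form)
  if (slope <= 0) stop("'slope' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (form == "sinusoid" && (amplitude <= 0 || frequency <= 0))
    stop("sinusoid form requires positive amplitude and frequency")
  structure(list(form = form, slope = slope, amplitude = amplitude,
                 frequency = frequency, noise_sd = noise_sd),
            class = "itd_model")
}

#' @export
print.itd_model <- function(x, ...) {
  if (x$form == "linear")
    cat(sprintf("ITD model: linear, %g us/deg, noise sd %g us\n",
                x$slope, x$noise_sd))
  else
    cat(sprintf("ITD model: sinusoid, A = %.2f us, f = %g cyc/deg, noise sd %g us\n",
                x$amplitude, x$frequency, x$noise_sd))
  invisible(x)
}

#' Noise-free ITD of a direction
#'
#' @param theta direction(s) in degrees.
#' @param model an [itd_model()].
#' @return ITD in microseconds; odd in \code{theta} for both forms.
#' @export
itd_of_direction <- function(theta, model) {
  stopifnot(inherits(model, "itd_model"))
  if (model$form == "linear") model$slope * theta
  else model$amplitude * sin(2 * pi * model$frequency * theta)
}

#' Observe a trajectory through the ITD model
#'
#' Produces the per-step ITD sequence for a trajectory, adding independent
#' Gaussian observation noise. The sinusoidal form is 360-periodic and uses
#' the wrapped direction; the linear form uses the unwrapped direction so
#' that the linear-Gaussian world remains self-consistent for trajectories
#' that leave the frontal hemisphere.
#'
#' @param trajectory a \code{source_trajectory}.
#' @param model an [itd_model()].
#' @param seed optional integer seed for the observation noise.
#' @return An object of class \code{"itd_sequence"}: a numeric vector of
#'   ITDs (microseconds) with attributes \code{dt} and \code{t_seconds}.
#' @export
observe <- function(trajectory, model, seed = NULL) {
  stopifnot(inherits(trajectory, "source_trajectory"),
            inherits(model, "itd_model"))
  if (!is.null(seed)) set.seed(seed)
  theta <- if (model$form == "linear") trajectory$theta_unwrapped
           else trajectory$theta_deg
  itd <- itd_of_direction(theta, model)
  if (model$noise_sd > 0)
    itd <- itd + stats::rnorm(length(itd), 0, model$noise_sd)
  structure(itd, dt = attr(trajectory, "dt"),
            t_seconds = trajectory$t_seconds,
            class = "itd_sequence")
}

#' @export
print.itd_sequence <- function(x, ...) {
  cat(sprintf("ITD sequence: %d steps, dt = %g s, range [%.1f, %.1f] us\n",
              length(x), attr(x, "dt"), min(x), max(x)))
  invisible(x)
}
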