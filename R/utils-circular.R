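#' Wrap angles to [-180, 180)
#'
#' @param theta numeric vector of angles in degrees.
#' @return Angles mapped to the half-open interval \code{[-180, 180)}.
#' @examples
#' wrap_deg(c(0, 180, -180, 359, 540))
#' @export
wrap_deg <- function(theta) {
  ((theta + 180) %% 360) - 180
}

#' Signed angular difference a - b on the circle
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return Wrapped differences in \code{[-180, 180)}.
#' @export
ang_diff_deg <- function(a, b) {
  wrap_deg(a - b)
}

#' Weighted circular mean of directions
#'
#' Direction of the weighted resultant vector \eqn{\sum_j w_j u(\theta_j)},
#' where \eqn{u(\theta)} is the unit vector pointing in direction
#' \eqn{\theta}. This is the sampled form of the Bayesian prediction vector
#' for a circular variable.
#'
#' @param theta directions in degrees.
#' @param w nonnegative weights (default equal).
#' @param on_zero what to do when the resultant length is numerically zero:
#'   \code{"error"} (default) or \code{"na"}.
#' @return The circular mean direction in degrees, in \code{[-180, 180)}.
#' @export
circ_mean_deg <- function(theta, w = NULL, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  if (length(theta) == 0L) stop("empty direction vector")
  if (is.null(w)) w <- rep(1, length(theta))
  rad <- theta * pi / 180
  x <- sum(w * cos(rad))
  y <- sum(w * sin(rad))
  if (sqrt(x^2 + y^2) < .Machine$double.eps * max(1, sum(abs(w)))) {
    if (on_zero == "na") return(NA_real_)
    stop("circular mean undefined: resultant vector has zero length")
  }
  wrap_deg(atan2(y, x) * 180 / pi)
}

#' Resultant length of a set of directions
#'
#' @inheritParams circ_mean_deg
#' @return Mean resultant length in \code{[0, 1]}.
#' @export
circ_resultant <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  w <- w / sum(w)
  rad <- theta * pi / 180
  sqrt(sum(w * cos(rad))^2 + sum(w * sin(rad))^2)
}
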