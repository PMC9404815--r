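## Pen kinematics: velocity and acceleration magnitudes from first and
## second finite differences of the sampled position.
##
## v(t)  = sqrt(vx^2 + vy^2),  vx(t) = (x(t+1) - x(t)) / dt(t)
## a(t)  = sqrt(ax^2 + ay^2),  ax(t) = (vx(t+1) - vx(t)) / dt(t)
##
## The derivative value is assigned to the earlier sample index and the
## trailing value(s) are replicated so the series has one value per
## sample, which keeps pointwise rendering trivially aligned.  Signed
## component velocities (not the magnitude) feed the acceleration.
## Kinematics run over the full sequence including in-air samples: the
## digitizer captures the in-air trajectory and its velocity is part of
## the rendered gesture.

signedComponentVelocities <- function(stream) {
  s <- penSamples(stream)
  dt <- diff(s$t)
  list(vx = diff(s$x) / dt, vy = diff(s$y) / dt, dt = dt)
}

#' Pen velocity magnitude
#'
#' @param stream a [PenStream-class] with at least 2 samples.
#' @return A [KinematicSeries-class] of per-sample speed magnitudes
#'   (tablet units per second), same length as the stream.
#' @examples
#' s <- data.frame(t = 0:2, x = c(0, 3, 6), y = c(0, 4, 8), p = 1,
#'                 az = 0, alt = 45, penDown = TRUE)
#' seriesValues(computeVelocity(PenStream(s)))  # 5 5 5
#' @export
computeVelocity <- function(stream) {
  s <- penSamples(stream)
  if (nrow(s) < 2) stop("degenerate input: velocity needs at least 2 samples")
  cv <- signedComponentVelocities(stream)
  v <- sqrt(cv$vx^2 + cv$vy^2)
  new("KinematicSeries", parameter = "velocity",
      values = c(v, v[length(v)]))
}

#' Pen acceleration magnitude
#'
#' @param stream a [PenStream-class] with at least 3 samples.
#' @return A [KinematicSeries-class] of per-sample acceleration
#'   magnitudes (tablet units per second squared), same length as the
#'   stream.
#' @export
computeAcceleration <- function(stream) {
  s <- penSamples(stream)
  if (nrow(s) < 3)
    stop("degenerate input: acceleration needs at least 3 samples")
  cv <- signedComponentVelocities(stream)
  n1 <- length(cv$vx)
  dt <- cv$dt[seq_len(n1 - 1)]
  ax <- diff(cv$vx) / dt
  ay <- diff(cv$vy) / dt
  a <- sqrt(ax^2 + ay^2)
  new("KinematicSeries", parameter = "acceleration",
      values = c(a, rep(a[length(a)], 2L)))
}
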