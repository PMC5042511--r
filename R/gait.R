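#' Gait cycle container
#'
#' One stride of walking sampled on a uniform time grid: ankle plantarflexion
#' torque (N.m, >= 0; dorsiflexor phases carry zero tendon load) and ankle
#' angle (rad, plantarflexion positive).
#'
#' @param time Time samples (s), uniform grid, length >= 2.
#' @param torque Ankle plantarflexion torque (N.m), >= 0.
#' @param angle Ankle angle (rad).
#' @return An object of class `gait_cycle`.
#' @export
gait_cycle <- function(time, torque, angle) {
  stopifnot(length(time) >= 2, length(torque) == length(time),
            length(angle) == length(time), all(torque >= 0),
            all(diff(time) > 0))
  structure(list(time = time, torque = torque, angle = angle),
            class = "gait_cycle")
}

#' Synthesize a walking gait cycle
#'
#' Surrogate for lab-measured walking data. The plantarflexion torque is a
#' smooth single bump over the stance phase, zero at heel strike and toe-off
#' and zero throughout swing, peaking at `peak_torque` near 45% of the
#' stride. The ankle angle follows the phasing of normal walking: the ankle
#' dorsiflexes progressively while the torque rises (the loaded tendon is
#' stretched and stores energy), reverses at peak torque into a rapid
#' push-off plantarflexion that peaks at toe-off, and returns through swing.
#' The waveform is a periodic spline through normative anchors, scaled so
#' the peak plantarflexion equals `angle_amplitude`. Deterministic.
#'
#' @param peak_torque Peak plantarflexion torque (N.m), > 0. Default 165.
#' @param stride_duration Stride period (s). Default 1.1.
#' @param n_samples Number of time samples, >= 50. Default 101.
#' @param angle_amplitude Peak plantarflexion angle (rad). Default 0.35.
#' @param stance_fraction Fraction of the stride in stance, in (0, 1).
#'   Default 0.6.
#' @return A [gait_cycle()].
#' @examples
#' g <- make_walking_cycle()
#' max(g$torque)  # 165 exactly
#' @export
make_walking_cycle <- function(peak_torque = 165, stride_duration = 1.1,
                               n_samples = 101, angle_amplitude = 0.35,
                               stance_fraction = 0.6) {
  stopifnot(peak_torque > 0, stance_fraction > 0, stance_fraction < 1,
            n_samples >= 50)
  time <- seq(0, stride_duration, length.out = n_samples)
  s <- time / (stance_fraction * stride_duration)  # stance-phase coordinate
  # exponent places the bump peak at 75% of stance (45% of the default stride)
  q <- log(0.5) / log(0.75)
  torque <- ifelse(s <= 1, sin(pi * pmin(s, 1)^q), 0)
  torque[torque < 0] <- 0
  torque <- peak_torque * torque / max(torque)
  # normative ankle waveform (fractions of stance / of swing), plantarflexion
  # positive, normalized to peak plantarflexion 1 at toe-off
  anchor_t <- c(0, 0.15, 0.45, 0.75, 1, 1.25, 1.6, 5 / 3) * stance_fraction
  anchor_a <- c(0, -0.2, -0.45, -0.55, 1, -0.25, -0.1, 0)
  sp <- stats::spline(anchor_t * stride_duration, anchor_a,
                      xout = time, method = "periodic")
  angle <- angle_amplitude * sp$y / max(sp$y)
  gait_cycle(time, torque, angle)
}

#' Write / read a gait cycle as CSV
#'
#' Three columns: `time_s`, `torque_Nm`, `angle_rad`.
#'
#' @param gait A [gait_cycle()].
#' @param path File path.
#' @return `read_gait_cycle` returns a [gait_cycle()]; `write_gait_cycle`
#'   returns `path` invisibly.
#' @export
write_gait_cycle <- function(gait, path) {
  utils::write.csv(data.frame(time_s = gait$time, torque_Nm = gait$torque,
                              angle_rad = gait$angle),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gait_cycle
#' @export
read_gait_cycle <- function(path) {
  d <- utils::read.csv(path)
  gait_cycle(d$time_s, d$torque_Nm, d$angle_rad)
}
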