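# Two-axis input-device control law for the virtual viewpoint.
#
# A raw input q in [-1, 1]^2 is mapped to a rotation increment
#   dtheta = Omega %*% (q - q_neutral)
# where the default Omega couples the two input axes to rotations about x
# and y through a direction angle gamma:
#   Omega = [ cos g  sin g ;  sin g  cos g ;  0  0 ]
# The accumulated viewpoint angle is then advanced per axis with a
# sign-preserving power law,
#   theta_i <- clamp(theta_i + alpha_i * sign(d_i) * |d_i|^r, +-theta_limit),
# so r > 1 gives fine motion near neutral and fast motion at full deflection;
# r = 1 is exactly linear.  All user-facing angles are degrees.

#' Control-law configuration
#'
#' @param gamma Direction angle between input-device axes and rotation axes,
#'   degrees. Used to build the default \code{omega}.
#' @param omega Optional 3 x 2 mapping matrix overriding the default built
#'   from \code{gamma}. The default is symmetric (both off-diagonal entries
#'   \code{sin(gamma)}) and its third row is zero, so the roll axis is never
#'   driven by the stick.
#' @param alpha Per-axis gains, degrees per update at unit mapped input.
#'   The default drives only the x axis at the gain produced by
#'   \code{rate_to_gain(28.2, 16)}: full deflection sweeps the viewpoint at
#'   28.2 degrees per second when updating at 16 Hz.
#' @param r Power coefficient of the update law, >= 1. Default 2.
#' @param q_neutral Neutral (resting) input position, set by
#'   \code{\link{calibrate_neutral}}.
#' @param theta_limit Per-axis bound on the accumulated angle, degrees.
#' @param n_neutral_frames Number of initial frames averaged by
#'   \code{\link{calibrate_neutral}}. Default 10.
#' @return An object of class \code{"control_config"}.
#' @export
control_config <- function(gamma = 0,
                           omega = NULL,
                           alpha = c(rate_to_gain(28.2, 16), 0, 0),
                           r = 2,
                           q_neutral = c(0, 0),
                           theta_limit = 90,
                           n_neutral_frames = 10L) {
  check_scalar(gamma, "gamma")
  check_scalar(r, "r")
  if (r < 1) stopf("'r' must be >= 1")
  check_scalar(theta_limit, "theta_limit", positive = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 3L || any(!is.finite(alpha)))
    stopf("'alpha' must be 3 finite gains")
  if (!is.numeric(q_neutral) || length(q_neutral) != 2L ||
      any(!is.finite(q_neutral)))
    stopf("'q_neutral' must be a finite 2-vector")
  if (is.null(omega)) {
    g <- deg2rad(gamma)
    omega <- matrix(c(cos(g), sin(g), 0,
                      sin(g), cos(g), 0), nrow = 3L, ncol = 2L)
  }
  if (!is.matrix(omega) || any(dim(omega) != c(3L, 2L)) ||
      any(!is.finite(omega)))
    stopf("'omega' must be a finite 3 x 2 matrix")
  n_neutral_frames <- as.integer(n_neutral_frames)
  if (n_neutral_frames < 1L) stopf("'n_neutral_frames' must be >= 1")
  structure(
    list(gamma = gamma, omega = omega, alpha = as.numeric(alpha), r = r,
         q_neutral = as.numeric(q_neutral), theta_limit = theta_limit,
         n_neutral_frames = n_neutral_frames),
    class = "control_config"
  )
}

#' Viewpoint state
#'
#' The accumulated viewpoint rotation (degrees, per axis) together with the
#' pivot about which the virtual viewpoint rotates.
#'
#' @param theta Length-3 vector \code{(theta_x, theta_y, theta_z)}, degrees.
#' @param pivot A \code{\link{pivot_pose}}.
#' @export
viewpoint_state <- function(theta = c(0, 0, 0), pivot = pivot_pose()) {
  if (!is.numeric(theta) || length(theta) != 3L || any(!is.finite(theta)))
    stopf("'theta' must be a finite 3-vector (degrees)")
  stopifnot(inherits(pivot, "pivot_pose"))
  structure(list(theta = as.numeric(theta), pivot = pivot),
            class = "viewpoint_state")
}

#' Calibrate the neutral input position
#'
#' Sets \code{q_neutral} to the per-component mean of the first
#' \code{cfg$n_neutral_frames} input samples, mirroring the automatic
#' neutral-position calibration performed when the controller starts up.
#'
#' @param q_samples n x 2 matrix/data frame of raw input samples.
#' @param cfg A \code{\link{control_config}}.
#' @return The configuration with \code{q_neutral} replaced.
#' @export
calibrate_neutral <- function(q_samples, cfg) {
  stopifnot(inherits(cfg, "control_config"))
  q <- as_point_matrix(q_samples, 2L, "q_samples")
  n <- cfg$n_neutral_frames
  if (nrow(q) < n)
    pv_error("bad_input",
             "neutral calibration needs %d samples, got %d", n, nrow(q))
  cfg$q_neutral <- colMeans(q[seq_len(n), , drop = FALSE])
  cfg
}

#' Map a raw input sample to a rotation increment
#'
#' Clamps the raw input to \code{[-1, 1]} per axis, subtracts the calibrated
#' neutral position and applies the 3 x 2 mapping matrix.  With the default
#' matrix the z (roll) increment is always zero.
#'
#' @param q Length-2 raw input sample.
#' @param cfg A \code{\link{control_config}}.
#' @return Length-3 rotation increment, degrees.
#' @export
map_input <- function(q, cfg) {
  stopifnot(inherits(cfg, "control_config"))
  if (!is.numeric(q) || length(q) != 2L || any(!is.finite(q)))
    stopf("'q' must be a finite 2-vector")
  q <- pmin(pmax(q, -1), 1)
  as.numeric(cfg$omega %*% (q - cfg$q_neutral))
}

#' Advance the viewpoint by one control update
#'
#' Applies the sign-preserving power law
#' \code{theta_i <- theta_i + alpha_i * sign(d_i) * |d_i|^r} and clamps each
#' axis to \code{+-theta_limit}.  With \code{r = 1} the update is exactly
#' linear in the increment.
#'
#' @param state A \code{\link{viewpoint_state}}.
#' @param dtheta Length-3 rotation increment from \code{\link{map_input}}.
#' @param cfg A \code{\link{control_config}}.
#' @return The updated \code{viewpoint_state}.
#' @export
update_viewpoint <- function(state, dtheta, cfg) {
  stopifnot(inherits(state, "viewpoint_state"),
            inherits(cfg, "control_config"))
  if (!is.numeric(dtheta) || length(dtheta) != 3L || any(!is.finite(dtheta)))
    stopf("'dtheta' must be a finite 3-vector")
  step <- cfg$alpha * sign(dtheta) * abs(dtheta)^cfg$r
  state$theta <- pmin(pmax(state$theta + step, -cfg$theta_limit),
                      cfg$theta_limit)
  state
}

#' Reset the viewpoint to the true camera view
#'
#' Zeroes the accumulated angles (the action bound to the controller's push
#' switch); the pivot is unchanged.
#'
#' @param state A \code{\link{viewpoint_state}}.
#' @export
reset_viewpoint <- function(state) {
  stopifnot(inherits(state, "viewpoint_state"))
  state$theta <- c(0, 0, 0)
  state
}

#' Convert a maximum rotation rate to a per-update gain
#'
#' Returns the gain \code{alpha} at which a sustained full-deflection input
#' (\code{|dtheta| = 1}, so \code{|dtheta|^r = 1} for any \code{r}) advances
#' the viewpoint by \code{max_rate} degrees per second when the control loop
#' runs at \code{update_rate} updates per second.
#'
#' @param max_rate Desired full-deflection rotation rate, degrees/s.
#' @param update_rate Control-loop rate, updates/s.
#' @param r Power coefficient (does not affect the result at unit input;
#'   kept for signature symmetry with \code{\link{control_config}}).
#' @return Gain in degrees per update.
#' @examples
#' rate_to_gain(28.2, 16)  # 1.7625 deg/update
#' @export
rate_to_gain <- function(max_rate, update_rate, r = 2) {
  check_scalar(max_rate, "max_rate", positive = TRUE)
  check_scalar(update_rate, "update_rate", positive = TRUE)
  max_rate / update_rate
}

#' Replay a recorded input trace through the control law
#'
#' Calibrates the neutral position from the first
#' \code{cfg$n_neutral_frames} samples (during which the viewpoint is held
#' still), then feeds every subsequent sample through
#' \code{\link{map_input}} and \code{\link{update_viewpoint}}.
#'
#' @param trace Data frame with columns \code{q1}, \code{q2} and optionally
#'   \code{t} (seconds).
#' @param cfg A \code{\link{control_config}}.
#' @param state Initial \code{\link{viewpoint_state}} (default: zero angles).
#' @return Data frame with columns \code{t}, \code{theta_x}, \code{theta_y},
#'   \code{theta_z} — the viewpoint trajectory, one row per input sample.
#' @export
replay_trace <- function(trace, cfg, state = viewpoint_state()) {
  stopifnot(inherits(cfg, "control_config"))
  if (!all(c("q1", "q2") %in% names(trace)))
    pv_error("bad_format", "trace must have columns q1, q2")
  n <- nrow(trace)
  cfg <- calibrate_neutral(as.matrix(trace[, c("q1", "q2")]), cfg)
  th <- matrix(NA_real_, n, 3L)
  ncal <- cfg$n_neutral_frames
  for (i in seq_len(n)) {
    if (i > ncal) {
      d <- map_input(c(trace$q1[i], trace$q2[i]), cfg)
      state <- update_viewpoint(state, d, cfg)
    }
    th[i, ] <- state$theta
  }
  data.frame(t = if ("t" %in% names(trace)) trace$t else seq_len(n) - 1,
             theta_x = th[, 1L], theta_y = th[, 2L], theta_z = th[, 3L])
}
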