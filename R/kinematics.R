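# Kinematic analysis of guided circle drawing.
#
# A trial is a time-stamped planar finger trajectory traced against a displayed
# guide circle of known center, radius and angular velocity. Performance is
# summarized by four root-mean-square metrics computed in polar coordinates:
# radius variability (SDR), radius error against the guide radius (RE),
# angular-velocity variability (SDAV) and angular-velocity error against the
# guide angular velocity (AVE). All four use the population (divisor-n) form.

#' Construct a circle-drawing trajectory trace
#'
#' Bundles one trial of planar positions with the parameters of the guide
#' circle the subject was tracking.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param x,y Numeric vectors of planar positions (tablet units).
#' @param hand `"left"` or `"right"`.
#' @param condition Condition code (e.g. `"RHCW"`).
#' @param center Length-2 numeric, center of the guide circle.
#' @param guide_radius Radius of the guide circle (same units as `x`, `y`); > 0.
#' @param guide_angular_velocity Guide angular velocity in rad/s; nonzero, the
#'   sign encodes direction (positive = counterclockwise).
#' @param trial Optional trial index.
#'
#' @return An object of class `trajectory_trace`.
#' @export
trajectory_trace <- function(t, x, y, hand = "right", condition = "RHCW",
                             center = c(0, 0), guide_radius = 1,
                             guide_angular_velocity = pi / 2, trial = 1L) {
  if (length(t) < 8L) stop("a trial needs at least 8 samples", call. = FALSE)
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("`t`, `x` and `y` must have equal length", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  check_positive_scalar(guide_radius, "guide_radius")
  if (guide_angular_velocity == 0) {
    stop("`guide_angular_velocity` must be nonzero", call. = FALSE)
  }
  hand <- match.arg(hand, c("left", "right"))
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         hand = hand, condition = condition, center = as.numeric(center),
         guide_radius = guide_radius,
         guide_angular_velocity = guide_angular_velocity,
         trial = as.integer(trial)),
    class = "trajectory_trace")
}

#' @export
print.trajectory_trace <- function(x, ...) {
  cat(sprintf(
    "<trajectory_trace> %d samples, %.1f s, hand=%s, condition=%s, r_o=%.3g, w_o=%.3g rad/s\n",
    length(x$t), diff(range(x$t)), x$hand, x$condition,
    x$guide_radius, x$guide_angular_velocity))
  invisible(x)
}

#' Trim mode-switching transients from a trial
#'
#' Acquisition software emits redundant samples while the display switches
#' between movement modes; these are removed by dropping a fixed window at the
#' start and end of the trial.
#'
#' @param trace A [trajectory_trace()].
#' @param window Seconds to drop at each end (default 0.5).
#' @return The trimmed `trajectory_trace`.
#' @export
trim_trace <- function(trace, window = 0.5) {
  stopifnot(inherits(trace, "trajectory_trace"))
  if (window < 0) stop("`window` must be >= 0", call. = FALSE)
  keep <- trace$t >= (trace$t[1] + window) & trace$t <= (trace$t[length(trace$t)] - window)
  if (sum(keep) < 8L) stop("trimming leaves fewer than 8 samples", call. = FALSE)
  trace$t <- trace$t[keep]; trace$x <- trace$x[keep]; trace$y <- trace$y[keep]
  trace
}

# Algebraic (Kasa) least-squares circle fit; exploratory alternative to the
# known guide center.
#' @noRd
fit_circle_lsq <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(cx = sol[1], cy = sol[2],
    r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Convert a trajectory to polar coordinates
#'
#' Radius is the Euclidean distance to the guide center; the angle is the
#' four-quadrant arctangent, unwrapped to a continuous series; angular
#' velocity is its finite-difference derivative (central differences, one-sided
#' at the endpoints, so it is defined at every sample).
#'
#' @param trace A [trajectory_trace()].
#' @param center `"guide"` (default) uses the known guide-circle center;
#'   `"fit"` estimates the center by least-squares circle fit (exploratory).
#' @return An object of class `polar_trace` with fields `t`, `r`, `theta`,
#'   `w`, `r_bar`, `w_bar`, and the guide parameters carried over.
#' @export
to_polar <- function(trace, center = c("guide", "fit")) {
  stopifnot(inherits(trace, "trajectory_trace"))
  center <- match.arg(center)
  if (length(trace$t) < 2L) stop("need at least 2 samples", call. = FALSE)
  ctr <- if (center == "fit") {
    f <- fit_circle_lsq(trace$x, trace$y)
    c(f[["cx"]], f[["cy"]])
  } else {
    trace$center
  }
  dx <- trace$x - ctr[1]
  dy <- trace$y - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- unwrap_phase(atan2(dy, dx))
  w <- grad_fd(theta, trace$t)
  structure(
    list(t = trace$t, r = r, theta = theta, w = w,
         r_bar = mean(r), w_bar = mean(w),
         guide_radius = trace$guide_radius,
         guide_angular_velocity = trace$guide_angular_velocity,
         hand = trace$hand, condition = trace$condition, trial = trace$trial),
    class = "polar_trace")
}

# Unwrap a wrapped phase series by removing 2*pi jumps.
#' @noRd
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# Finite-difference derivative: central in the interior, one-sided at ends.
#' @noRd
grad_fd <- function(y, x) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples for a derivative", call. = FALSE)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  g
}

# Shared population-RMS deviation.
#' @noRd
rms_dev <- function(v, ref) sqrt(mean((v - ref)^2))

#' Radius standard deviation (SDR)
#'
#' Root-mean-square deviation of the per-sample radius from its trial mean,
#' with divisor n (population form). Measures trajectory variability.
#'
#' @param p A [to_polar()] result.
#' @return SDR in input length units.
#' @export
radius_sd <- function(p) {
  stopifnot(inherits(p, "polar_trace"))
  if (length(p$r) < 2L) stop("need at least 2 samples", call. = FALSE)
  rms_dev(p$r, mean(p$r))
}

#' Radius error (RE)
#'
#' Root-mean-square deviation of the per-sample radius from the guide radius
#' `r_o`, divisor n. Measures tracking accuracy against the displayed circle.
#'
#' @param p A [to_polar()] result.
#' @param r_o Guide radius; defaults to the one carried in `p`.
#' @return RE in input length units.
#' @export
radius_error <- function(p, r_o = p$guide_radius) {
  stopifnot(inherits(p, "polar_trace"))
  check_positive_scalar(r_o, "r_o")
  rms_dev(p$r, r_o)
}

#' Angular-velocity standard deviation (SDAV)
#'
#' Root-mean-square deviation of per-sample angular velocity from its trial
#' mean, divisor n. Measures movement smoothness.
#'
#' @param p A [to_polar()] result.
#' @return SDAV in rad/s.
#' @export
angvel_sd <- function(p) {
  stopifnot(inherits(p, "polar_trace"))
  if (length(p$w) < 2L) stop("need at least 2 samples", call. = FALSE)
  rms_dev(p$w, mean(p$w))
}

#' Angular-velocity error (AVE)
#'
#' Root-mean-square deviation of per-sample angular velocity from the signed
#' guide angular velocity `w_o`, divisor n. Direction must match in sign.
#'
#' @param p A [to_polar()] result.
#' @param w_o Guide angular velocity in rad/s; defaults to the one in `p`.
#' @return AVE in rad/s.
#' @export
angvel_error <- function(p, w_o = p$guide_angular_velocity) {
  stopifnot(inherits(p, "polar_trace"))
  if (!is.numeric(w_o) || length(w_o) != 1L || w_o == 0) {
    stop("`w_o` must be a single nonzero number", call. = FALSE)
  }
  rms_dev(p$w, w_o)
}

#' All four kinematic metrics for one trial
#'
#' @param trace A [trajectory_trace()] (or an already-converted `polar_trace`).
#' @param trim Seconds trimmed at each end before conversion (0 disables).
#' @return A one-row data frame: `hand`, `condition`, `trial`, `sdr`, `re`,
#'   `sdav`, `ave`, `n`.
#' @export
kinematic_metrics <- function(trace, trim = 0) {
  p <- if (inherits(trace, "polar_trace")) {
    trace
  } else {
    if (trim > 0) trace <- trim_trace(trace, trim)
    to_polar(trace)
  }
  data.frame(
    hand = p$hand, condition = p$condition, trial = p$trial,
    sdr = radius_sd(p), re = radius_error(p),
    sdav = angvel_sd(p), ave = angvel_error(p),
    n = length(p$r), stringsAsFactors = FALSE)
}
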