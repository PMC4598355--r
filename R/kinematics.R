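# Kinematic series derived from a trajectory: speed u_t, signed turning
# speed omega_t and heading phi_t. All downstream calibration operates on
# these series, never on raw positions.

#' Instantaneous speed
#'
#' Speed is the norm of the planar velocity vector,
#' `u[k] = sqrt(vx[k]^2 + vy[k]^2)`.
#'
#' @param traj an `fw_trajectory`.
#' @return Non-negative numeric vector (cm/s), one value per sample.
#' @export
compute_speed <- function(traj) {
  stopifnot(inherits(traj, "fw_trajectory"))
  sqrt(traj$vx^2 + traj$vy^2)
}

#' Signed turning speed
#'
#' The turning speed at sample `k` is the signed angle from `v[k]` to
#' `v[k+1]` divided by the sampling step: positive for anticlockwise (left)
#' turns, negative for clockwise (right) turns. Its magnitude is bounded by
#' `pi/dt`, the largest rotation detectable between consecutive samples.
#'
#' The forward difference leaves the final sample undefined; it is padded
#' with 0 and flagged in the mask. Samples where either velocity involved is
#' exactly zero get `omega = 0` and a flag rather than an error, because
#' tracked fish do stop. When consecutive velocities are exactly antiparallel
#' the rotation direction is genuinely ambiguous; the sign is taken from the
#' most recent nonzero turning speed (or `+` if there is none) so the result
#' is deterministic.
#'
#' @param traj an `fw_trajectory`.
#' @return A list with `omega` (rad/s) and `flagged` (logical mask marking
#'   padded or zero-speed samples).
#' @export
compute_turning_speed <- function(traj) {
  stopifnot(inherits(traj, "fw_trajectory"))
  dt <- attr(traj, "dt")
  n <- nrow(traj)
  vx <- traj$vx; vy <- traj$vy

  v1x <- vx[-n]; v1y <- vy[-n]
  v2x <- vx[-1L]; v2y <- vy[-1L]
  cross <- v1x * v2y - v1y * v2x        # z-component, > 0 anticlockwise
  dot <- v1x * v2x + v1y * v2y
  ang <- atan2(cross, dot)              # signed angle in (-pi, pi]

  zero <- (v1x == 0 & v1y == 0) | (v2x == 0 & v2y == 0)
  ang[zero] <- 0

  omega <- ang / dt
  # antiparallel: atan2(0, dot<0) = +pi; resolve sign deterministically
  anti <- which(!zero & cross == 0 & dot < 0)
  for (i in anti) {
    prev <- omega[seq_len(i - 1L)]
    prev <- prev[prev != 0]
    s <- if (length(prev)) sign(prev[length(prev)]) else 1
    omega[i] <- s * pi / dt
  }

  flagged <- c(zero, TRUE)              # last sample padded
  list(omega = c(omega, 0), flagged = flagged)
}

#' Heading reconstructed from velocity
#'
#' The heading is the orientation of the velocity vector, wrapped into the
#' half-open interval `[-pi, pi)` (so an exactly backward velocity maps to
#' `-pi`). At stationary samples (zero speed) the orientation is undefined
#' and the last moving heading is carried forward; a stationary run at the
#' start of the series takes the heading of the first moving sample.
#'
#' @param traj an `fw_trajectory`.
#' @return Numeric vector of headings in radians, in `[-pi, pi)`.
#' @export
reconstruct_heading <- function(traj) {
  stopifnot(inherits(traj, "fw_trajectory"))
  moving <- !(traj$vx == 0 & traj$vy == 0)
  if (!any(moving)) stop("heading undefined: all velocities are zero")
  phi <- wrap_angle(atan2(traj$vy, traj$vx))
  # hold last moving heading across stationary samples; a stationary run at
  # the start borrows the first moving heading
  idx <- cumsum(moving)
  idx[idx == 0L] <- 1L
  phi[moving][idx]
}

#' Derive the full kinematic series of a trajectory
#'
#' Convenience wrapper bundling [compute_speed()], [compute_turning_speed()]
#' and [reconstruct_heading()].
#'
#' @param traj an `fw_trajectory`.
#' @return A list of class `"fw_kinematics"` with elements `u` (cm/s),
#'   `omega` (rad/s), `phi` (rad), `flagged` (logical) and `dt` (s).
#' @export
kinematics <- function(traj) {
  om <- compute_turning_speed(traj)
  structure(list(u = compute_speed(traj),
                 omega = om$omega,
                 phi = reconstruct_heading(traj),
                 flagged = om$flagged,
                 dt = attr(traj, "dt")),
            class = "fw_kinematics")
}

# wrap angles into [-pi, pi); the shift-mod-shift maps +pi to -pi
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}
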