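# Bounded square arena with rounded corners, and the projected-collision
# geometry (d_W, t_W, phi_W) that drives wall avoidance. Corners are
# quarter-circles of radius R_c: a sharp corner would let two perpendicular
# walls compete and produce singular turning for a point-like walker.

#' Rounded-corner square arena
#'
#' @param side side length L in cm (default 120, the experimental tank).
#' @param corner_radius quarter-circle radius R_c in cm (default 10).
#' @return A list of class `"fw_arena"` with fields `side` and
#'   `corner_radius`; the arena is centred at the origin.
#' @export
arena <- function(side = 120, corner_radius = 10) {
  stopifnot(side > 0, corner_radius >= 0, corner_radius <= side / 2)
  structure(list(side = side, corner_radius = corner_radius),
            class = "fw_arena")
}

#' Point-in-arena test
#'
#' A point is inside the rounded square iff it is inside the square of side
#' `L` and, when it falls in a corner square, within the quarter-circle arc.
#' Vectorised over points.
#'
#' @param a an `fw_arena`.
#' @param x,y coordinates (cm), centre of arena at the origin.
#' @return Logical vector.
#' @export
arena_contains <- function(a, x, y) {
  h <- a$side / 2
  rc <- a$corner_radius
  cx <- h - rc
  inside_sq <- abs(x) <= h & abs(y) <= h
  in_corner <- abs(x) > cx & abs(y) > cx
  ok_corner <- (abs(x) - cx)^2 + (abs(y) - cx)^2 <= rc^2
  inside_sq & (!in_corner | ok_corner)
}

#' Projected wall collision
#'
#' Casts a ray from the current position along the heading and intersects it
#' with the boundary (four flat wall segments plus four corner arcs, all
#' treated as exact line/circle intersections). Returns the distance `d_W`
#' and time `t_W = d_W / u` to the projected collision, the hit point, and
#' the signed collision angle `phi_W`.
#'
#' `phi_W` is the signed angle from the outward direction at the hit point
#' (the reversed inward normal) to the ray, wrapped to `[-pi, pi)`. With
#' this convention `phi_W > 0` exactly when the inward normal lies
#' anticlockwise of the ray, i.e. when a positive (left) turn steers away
#' from the wall; a head-on approach gives `phi_W = 0`.
#'
#' @param x,y current position (cm), must be inside the arena.
#' @param phi heading (rad).
#' @param u current speed (cm/s); `t_W` is `Inf` when `u = 0`.
#' @param a an `fw_arena`.
#' @return A list with `d_w` (cm), `t_w` (s), `phi_w` (rad) and `hit`
#'   (length-2 numeric, cm).
#' @export
project_collision <- function(x, y, phi, u = 0, a = arena()) {
  if (!arena_contains(a, x, y)) stop("position outside arena")
  h <- a$side / 2
  rc <- a$corner_radius
  cx <- h - rc
  dx <- cos(phi); dy <- sin(phi)

  best_s <- Inf
  best_n <- c(NA_real_, NA_real_)   # inward normal at hit point

  # flat walls: x = +/-h (valid while |y| <= h - rc), y = +/-h likewise
  walls <- list(list(p = h, d = dx, o = dy, n = c(-1, 0), ax = TRUE),
                list(p = -h, d = dx, o = dy, n = c(1, 0), ax = TRUE),
                list(p = h, d = dy, o = dx, n = c(0, -1), ax = FALSE),
                list(p = -h, d = dy, o = dx, n = c(0, 1), ax = FALSE))
  for (w in walls) {
    if (w$d == 0) next
    s <- if (w$ax) (w$p - x) / dx else (w$p - y) / dy
    if (s <= 1e-12 || s >= best_s) next
    other <- if (w$ax) y + s * dy else x + s * dx
    if (abs(other) <= cx + 1e-12) {
      best_s <- s
      best_n <- w$n
    }
  }

  # corner arcs: circles of radius rc centred at (+/-cx, +/-cx)
  if (rc > 0) for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    ccx <- sx * cx; ccy <- sy * cx
    mx <- x - ccx; my <- y - ccy
    b <- mx * dx + my * dy
    cc <- mx^2 + my^2 - rc^2
    disc <- b^2 - cc
    if (disc < 0) next
    for (s in c(-b - sqrt(disc), -b + sqrt(disc))) {
      if (s <= 1e-12 || s >= best_s) next
      px <- x + s * dx; py <- y + s * dy
      # only the quadrant of the arc facing outward from the corner centre
      if ((px - ccx) * sx >= -1e-12 && (py - ccy) * sy >= -1e-12) {
        best_s <- s
        best_n <- c(ccx - px, ccy - py) / rc
      }
    }
  }

  if (!is.finite(best_s)) stop("ray does not hit the boundary")
  hit <- c(x + best_s * dx, y + best_s * dy)
  # angle from the outward direction (-n) to the ray, anticlockwise positive
  phi_w <- wrap_angle(atan2(dy, dx) - atan2(-best_n[2], -best_n[1]))
  list(d_w = best_s,
       t_w = if (u > 0) best_s / u else Inf,
       phi_w = phi_w,
       hit = hit)
}

#' Wall-corrected turning speed
#'
#' Re-signs a turning speed by whether the turn steers away from the
#' projected collision: `+|omega|` when `sign(omega)` matches
#' `sign(phi_W)`, `-|omega|` otherwise. A head-on approach (`phi_W = 0`)
#' takes the negative branch since no turn direction is distinguished.
#' Vectorised.
#'
#' @param omega turning speed(s), rad/s.
#' @param phi_w signed collision angle(s), rad.
#' @return Numeric vector of wall-corrected turning speeds (rad/s).
#' @export
wall_corrected_turning <- function(omega, phi_w) {
  ifelse(sign(omega) == sign(phi_w), abs(omega), -abs(omega))
}
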