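# Independent oracles used across test files. These deliberately avoid the
# implementation paths they check.

# Eq-style lag-1 autocorrelation transcribed as explicit loops.
r1_bruteforce <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  num <- 0
  for (k in 1:(n - 1)) num <- num + (x[k] - m) * (x[k + 1] - m)
  den <- 0
  for (k in 1:n) den <- den + (x[k] - m)^2
  num / den
}

# Centred moving average by direct convolution with shrunken edge windows.
moving_average_bruteforce <- function(u, window) {
  h <- (window - 1) %/% 2
  n <- length(u)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    out[i] <- mean(u[idx])
  }
  out
}

# Distance to the arena boundary along a ray, by coarse marching on the
# point-membership test followed by bisection. Independent of the analytic
# line/circle intersections in project_collision().
ray_march_distance <- function(x, y, phi, a, coarse = 0.05, iters = 60L) {
  dx <- cos(phi); dy <- sin(phi)
  smax <- a$side * sqrt(2) + 1
  s_grid <- seq(0, smax, by = coarse)
  inside <- arena_contains(a, x + s_grid * dx, y + s_grid * dy)
  first_out <- which(!inside)[1]
  lo <- s_grid[first_out - 1L]
  hi <- s_grid[first_out]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (arena_contains(a, x + mid * dx, y + mid * dy)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Draw a uniform point strictly inside the arena.
random_interior_point <- function(a) {
  repeat {
    p <- stats::runif(2, -a$side / 2 + 1e-6, a$side / 2 - 1e-6)
    if (arena_contains(a, p[1], p[2])) return(p)
  }
}

# Build an fw_trajectory directly from a velocity series (positions by
# cumulative sum), for kinematics tests that specify velocities.
traj_from_velocity <- function(vx, vy, dt = 0.2) {
  n <- length(vx)
  t <- seq(0, by = dt, length.out = n)
  x <- cumsum(c(0, vx[-1] * dt))
  y <- cumsum(c(0, vy[-1] * dt))
  trajectory(t, x, y, vx, vy)
}
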