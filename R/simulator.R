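# Euler-Maruyama simulation of the coupled speed / turning-speed SDEs in a
# bounded arena:
#   dU = theta_u (mu_u - U) dt + sigma_u dW
#   dOmega = theta_w (mu_w + f_W - Omega) dt + f_c(U) dZ
# f_W biases the turning equilibrium away from the projected wall collision;
# f_c shrinks the turning noise as speed grows, reproducing the observed
# narrowing of the turning-speed distribution at high speed.

#' Full walker parameterisation
#'
#' @param speed `fw_ou_params` for the speed process (cm/s units).
#' @param turn `fw_ou_params` for the turning-speed process (rad/s units).
#' @param sigma0 saturation noise amplitude (rad s^-1 s^-1/2); must exceed
#'   `turn$sigma` for the coupling to be well defined.
#' @param A wall-avoidance amplitude (rad/s), non-negative.
#' @param B wall-avoidance decay rate (1/cm), non-positive so the repulsion
#'   fades with distance.
#' @return A list of class `"fw_model_params"`.
#' @export
model_params <- function(speed, turn, sigma0, A, B) {
  stopifnot(inherits(speed, "fw_ou_params"), inherits(turn, "fw_ou_params"),
            A >= 0, B <= 0)
  if (sigma0 <= turn$sigma)
    stop("sigma0 must exceed the turning noise amplitude sigma_w")
  structure(list(speed = speed, turn = turn, sigma0 = sigma0, A = A, B = B),
            class = "fw_model_params")
}

#' Simulation configuration
#'
#' @param dt time step (s); default 0.2 s, matching the 5 Hz tracking rate.
#' @param T total simulated time (s).
#' @param seed integer RNG seed; fixing it makes runs bit-reproducible.
#' @param omega_clamp hard limit on |Omega| (rad/s); default 15, the
#'   observed maximum turning speed. Use `Inf` to disable.
#' @param arena an `fw_arena`.
#' @param init `"random"` (position uniform in the arena, heading uniform
#'   on `[-pi, pi)`) or `"fixed"` (origin, heading 0). Either way the
#'   initial speed is `mu_u` and the initial turning speed 0.
#' @param walls if `FALSE`, wall repulsion and the hard boundary are both
#'   disabled (free-space run; useful for checking stationary statistics
#'   against O-U theory).
#' @param coupling if `FALSE`, the turning noise amplitude is the constant
#'   `turn$sigma` instead of the speed-dependent `f_c`.
#' @return A list of class `"fw_sim_config"`.
#' @export
sim_config <- function(dt = 0.2, T = 60, seed = 1L, omega_clamp = 15,
                       arena = finwalk::arena(), init = c("random", "fixed"),
                       walls = TRUE, coupling = TRUE) {
  stopifnot(dt > 0, T >= dt, omega_clamp > 0, inherits(arena, "fw_arena"))
  init <- match.arg(init)
  structure(list(dt = dt, T = T, seed = as.integer(seed),
                 omega_clamp = omega_clamp, arena = arena, init = init,
                 walls = walls, coupling = coupling),
            class = "fw_sim_config")
}

#' Speed-to-turning-noise coupling
#'
#' `f_c(U) = sigma0 * (2 sigma0 / sigma_w)^(-U / mu_u)`: a strictly
#' decreasing exponential in the current speed, equal to the saturation
#' amplitude `sigma0` at `U = 0` and to `sigma_w / 2` at the mean speed
#' `U = mu_u`. Vectorised over `U`.
#'
#' @param U current speed(s) (cm/s), non-negative.
#' @param sigma_w turning noise amplitude, with `0 < sigma_w < sigma0`.
#' @param sigma0 saturation amplitude.
#' @param mu_u mean speed (cm/s), positive.
#' @return Noise amplitude(s), rad s^-1 s^-1/2.
#' @export
coupling_fc <- function(U, sigma_w, sigma0, mu_u) {
  if (!(sigma0 > sigma_w) || sigma_w <= 0 || mu_u <= 0 || any(U < 0))
    stop("require sigma0 > sigma_w > 0, mu_u > 0, U >= 0")
  sigma0 * (2 * sigma0 / sigma_w)^(-U / mu_u)
}

#' Wall-avoidance turning bias
#'
#' `f_W(phi_W, d_W) = sign(phi_W) * A * exp(B * d_W)`: an exponentially
#' decaying bias on the turning equilibrium, signed to steer the walker
#' away from the projected collision. Its magnitude never exceeds `A`, and
#' it vanishes for a head-on approach (`phi_W = 0`). Vectorised.
#'
#' @param phi_w signed collision angle(s) (rad).
#' @param d_w projected collision distance(s) (cm), non-negative.
#' @param A amplitude (rad/s).
#' @param B decay rate (1/cm), non-positive.
#' @return Turning bias(es), rad/s.
#' @export
wall_force_fw <- function(phi_w, d_w, A, B) {
  if (any(d_w < 0)) stop("d_w must be non-negative")
  sign(phi_w) * A * exp(B * d_w)
}

#' One Euler-Maruyama step of the walker
#'
#' Advances a walker state by one time step, in this order: (1) project the
#' wall collision from the current state; (2) update speed
#' (`U + theta_u (mu_u - U) dt + sigma_u sqrt(dt) z1`, floored at 0 since
#' speed is a norm); (3) update turning speed with the wall bias and the
#' coupling evaluated at the *pre-update* speed, then clamp to
#' `±omega_clamp`; (4) update heading with the new turning speed,
#' wrapping to `[-pi, pi)`; (5) advance position with the new heading and
#' new speed; (6) if the new position leaves the arena, treat the event as
#' a fully inelastic collision: position and heading revert to their
#' previous values and the speed is set to zero (the turning speed is not
#' reset).
#'
#' @param state list with `x`, `y`, `phi`, `U`, `Omega`, `t`.
#' @param params an `fw_model_params`.
#' @param cfg an `fw_sim_config`.
#' @param noise length-2 numeric: standard normal draws for the speed and
#'   turning updates, in that order.
#' @return The updated state list.
#' @export
em_step <- function(state, params, cfg, noise) {
  dt <- cfg$dt
  sp <- params$speed; tu <- params$turn
  sqdt <- sqrt(dt)

  fw <- 0
  if (cfg$walls && params$A > 0) {
    pr <- project_collision(state$x, state$y, state$phi, state$U, cfg$arena)
    fw <- wall_force_fw(pr$phi_w, pr$d_w, params$A, params$B)
  }

  U_prev <- state$U
  U <- U_prev + sp$theta * (sp$mu - U_prev) * dt + sp$sigma * sqdt * noise[1]
  if (U < 0) U <- 0

  amp <- if (cfg$coupling)
    coupling_fc(U_prev, tu$sigma, params$sigma0, sp$mu) else tu$sigma
  Om <- state$Omega +
    tu$theta * (tu$mu + fw - state$Omega) * dt + amp * sqdt * noise[2]
  Om <- max(min(Om, cfg$omega_clamp), -cfg$omega_clamp)

  phi <- wrap_angle(state$phi + Om * dt)
  x <- state$x + cos(phi) * U * dt
  y <- state$y + sin(phi) * U * dt

  if (cfg$walls && !arena_contains(cfg$arena, x, y)) {
    x <- state$x; y <- state$y; phi <- state$phi
    U <- 0
  }
  list(x = x, y = y, phi = phi, U = U, Omega = Om, t = state$t + dt)
}

#' Simulate a random-walker trajectory
#'
#' Iterates [em_step()] for `T / dt` steps from the configured initial
#' conditions, drawing two standard normals per step (speed first, then
#' turning) from a generator seeded with `cfg$seed`, so a given seed always
#' reproduces the same trajectory.
#'
#' @param params an `fw_model_params`.
#' @param cfg an `fw_sim_config`.
#' @param subject_id label for the output trajectory.
#' @return A list of class `"fw_simulation"`: `trajectory` (an
#'   `fw_trajectory` whose velocities are backwards differences of the
#'   simulated positions) and `latent` (data frame `t, U, Omega, phi` of
#'   the walker's internal state, including the initial state at `t = 0`).
#' @export
run_simulation <- function(params, cfg, subject_id = "walker") {
  stopifnot(inherits(params, "fw_model_params"),
            inherits(cfg, "fw_sim_config"))
  n <- round(cfg$T / cfg$dt)
  set.seed(cfg$seed)

  if (cfg$init == "random") {
    repeat {
      p0 <- stats::runif(2, -cfg$arena$side / 2, cfg$arena$side / 2)
      if (arena_contains(cfg$arena, p0[1], p0[2])) break
    }
    phi0 <- stats::runif(1, -pi, pi)
  } else {
    p0 <- c(0, 0); phi0 <- 0
  }
  state <- list(x = p0[1], y = p0[2], phi = phi0,
                U = params$speed$mu, Omega = 0, t = 0)

  # two draws per step, speed first then turning
  z <- matrix(stats::rnorm(2L * n), nrow = 2L)

  xs <- numeric(n + 1L); ys <- numeric(n + 1L)
  Us <- numeric(n + 1L); Oms <- numeric(n + 1L); phis <- numeric(n + 1L)
  xs[1] <- state$x; ys[1] <- state$y
  Us[1] <- state$U; Oms[1] <- state$Omega; phis[1] <- state$phi
  for (k in seq_len(n)) {
    state <- em_step(state, params, cfg, z[, k])
    xs[k + 1L] <- state$x; ys[k + 1L] <- state$y
    Us[k + 1L] <- state$U; Oms[k + 1L] <- state$Omega
    phis[k + 1L] <- state$phi
  }

  tt <- seq(0, by = cfg$dt, length.out = n + 1L)
  traj <- trajectory(tt, xs, ys, subject_id = subject_id)
  structure(list(trajectory = traj,
                 latent = data.frame(t = tt, U = Us, Omega = Oms,
                                     phi = phis)),
            class = "fw_simulation")
}
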