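# Synthetic-data generators. gen_ou_exact draws from the *exact*
# transition density of the O-U process, so it serves as an independent
# oracle for both the MLE and the Euler-Maruyama discretisation.

#' Exact Ornstein-Uhlenbeck sampler
#'
#' Draws a regularly sampled path from the exact conditional distribution
#' of the O-U process:
#' `x[k+1] = mu + (x[k] - mu) * a + sigma * sqrt((1 - a^2) / (2 theta)) * z`
#' with `a = exp(-theta dt)` and `z` standard normal. No discretisation
#' error at any step size.
#'
#' @param params an `fw_ou_params`.
#' @param n number of samples.
#' @param dt sampling step (s).
#' @param seed integer seed; fixed seed gives identical output.
#' @param init `"stationary"` (draw `x[1]` from the stationary
#'   `N(mu, sigma^2 / 2 theta)`, so finite-sample statistics match
#'   stationary theory) or `"fixed"` (start at `x0`).
#' @param x0 starting value for `init = "fixed"`.
#' @return Numeric vector of length `n`.
#' @export
gen_ou_exact <- function(params, n, dt, seed = 1L,
                         init = c("stationary", "fixed"), x0 = params$mu) {
  stopifnot(inherits(params, "fw_ou_params"), n >= 1, dt > 0)
  init <- match.arg(init)
  set.seed(seed)
  a <- exp(-params$theta * dt)
  s_cond <- params$sigma * sqrt((1 - a^2) / (2 * params$theta))
  s_stat <- params$sigma / sqrt(2 * params$theta)

  start <- if (init == "stationary") stats::rnorm(1, params$mu, s_stat) else x0
  innov <- s_cond * stats::rnorm(n - 1L)
  # x[k] - mu follows a linear AR(1) recursion; filter() runs it in C
  dev <- stats::filter(c(start - params$mu, innov), a,
                       method = "recursive")
  params$mu + as.numeric(dev)
}

#' Synthetic wall-response scatter
#'
#' Generates `(z, omega_c)` pairs from the exponential wall-response model
#' `omega_c = A * exp(B * z) + e`, `e ~ N(0, noise_sd)`, with abscissae
#' uniform on `range`. Used to exercise [fit_wall_response()].
#'
#' @param A amplitude (rad/s).
#' @param B decay rate (1/cm in distance mode, 1/s in time mode).
#' @param noise_sd Gaussian noise standard deviation (rad/s).
#' @param n number of pairs.
#' @param range abscissa range, e.g. `c(0, 60)` cm.
#' @param seed integer seed.
#' @return A data frame with columns `z` and `omega_c`.
#' @export
gen_wall_response <- function(A, B, noise_sd = 1, n = 2000L,
                              range = c(0, 60), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  z <- stats::runif(n, range[1], range[2])
  data.frame(z = z,
             omega_c = A * exp(B * z) + stats::rnorm(n, 0, noise_sd))
}

#' Write a simulated reference trajectory to disk
#'
#' Runs the walker simulator and writes the resulting trajectory in the
#' CSV dialect of [read_trajectory()], producing a file that emulates the
#' tracked-fish data format with fully known generating parameters.
#'
#' @param params an `fw_model_params`.
#' @param cfg an `fw_sim_config`.
#' @param path output CSV path.
#' @param subject_id trajectory label.
#' @return The `fw_simulation` object, invisibly.
#' @export
gen_reference_trajectory <- function(params, cfg, path,
                                     subject_id = "walker") {
  sim <- run_simulation(params, cfg, subject_id = subject_id)
  write_trajectory(sim$trajectory, path)
  invisible(sim)
}
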