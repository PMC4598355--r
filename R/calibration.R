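# Parameter estimation: exact maximum likelihood for regularly sampled
# Ornstein-Uhlenbeck series, segment-count-weighted parameter averaging,
# two-stage (LOESS + exponential) fitting of the wall-avoidance response,
# and the saturation noise amplitude sigma_0.

#' Ornstein-Uhlenbeck parameter triple
#'
#' @param mu equilibrium value (process units).
#' @param theta mean-reversion rate (1/s), must be positive. The
#'   autocorrelation time of the process is `1/theta`.
#' @param sigma noise amplitude (process units per sqrt(s)), non-negative.
#'   The stationary variance is `sigma^2 / (2 theta)`.
#' @return A list of class `"fw_ou_params"`.
#' @export
ou_params <- function(mu, theta, sigma) {
  stopifnot(is.finite(mu), theta > 0, sigma >= 0)
  structure(list(mu = mu, theta = theta, sigma = sigma),
            class = "fw_ou_params")
}

#' Exact MLE for a regularly sampled Ornstein-Uhlenbeck process
#'
#' Uses the conditional-Gaussian AR(1) representation of the O-U process:
#' given `x[k]`, the next observation is normal with mean
#' `mu + (x[k] - mu) * a` and variance `sigma^2 (1 - a^2) / (2 theta)`,
#' where `a = exp(-theta dt)`. Maximising the likelihood conditional on the
#' first observation reduces to least squares of `x[k+1]` on `x[k]`, giving
#' closed-form estimates that satisfy the score equations exactly.
#'
#' @param x numeric series (length >= 10, nonzero variance).
#' @param dt sampling step (s).
#' @return An `fw_ou_params` with the estimated `mu`, `theta`, `sigma`.
#' @section Errors:
#' A constant series has no information about any parameter
#' (`"degenerate variance"`). A sample whose fitted AR(1) coefficient falls
#' outside (0, 1) is not mean-reverting at this sampling rate
#' (`"non-mean-reverting sample"`); the fitted coefficient is reported to
#' aid diagnosis.
#' @export
fit_ou_mle <- function(x, dt) {
  stopifnot(dt > 0)
  n <- length(x) - 1L
  if (n < 9L) stop("need at least 10 observations")
  if (stats::var(x) == 0) stop("degenerate variance: constant series")

  x0 <- x[-(n + 1L)]
  x1 <- x[-1L]
  mx0 <- mean(x0); mx1 <- mean(x1)
  sxx <- sum((x0 - mx0)^2)
  sxy <- sum((x0 - mx0) * (x1 - mx1))
  if (sxx == 0) stop("degenerate variance: constant predecessors")

  a <- sxy / sxx
  if (a <= 0 || a >= 1)
    stop(sprintf("non-mean-reverting sample: fitted AR(1) coefficient %.4f outside (0, 1)", a))

  mu <- (mx1 - a * mx0) / (1 - a)
  resid <- (x1 - mu) - a * (x0 - mu)
  cvar <- mean(resid^2)                     # conditional variance MLE
  theta <- -log(a) / dt
  sigma <- sqrt(2 * theta * cvar / (1 - a^2))
  ou_params(mu = mu, theta = theta, sigma = sigma)
}

#' Average per-segment parameters into per-fish and global values
#'
#' Each fish's parameter is the unweighted mean over its segments; the
#' global parameter is the mean of the per-fish values weighted by each
#' fish's segment count `n_i`:
#' `mu_tilde = sum(n_i * mu[F_i]) / sum(n_i)`.
#'
#' @param per_segment named list: one entry per fish, each a list of
#'   `fw_ou_params` (one per segment for that fish).
#' @return A list with `per_fish` (data frame of per-fish means and segment
#'   counts) and `global` (an `fw_ou_params` of the weighted means).
#' @export
average_params <- function(per_segment) {
  if (length(per_segment) == 0L) stop("no segments to average")
  rows <- lapply(names(per_segment), function(f) {
    ps <- per_segment[[f]]
    if (length(ps) == 0L) stop("fish ", f, " has no segments")
    data.frame(fish = f,
               n = length(ps),
               mu = mean(vapply(ps, `[[`, 0, "mu")),
               theta = mean(vapply(ps, `[[`, 0, "theta")),
               sigma = mean(vapply(ps, `[[`, 0, "sigma")))
  })
  per_fish <- do.call(rbind, rows)
  w <- per_fish$n
  glob <- ou_params(mu = sum(w * per_fish$mu) / sum(w),
                    theta = sum(w * per_fish$theta) / sum(w),
                    sigma = sum(w * per_fish$sigma) / sum(w))
  list(per_fish = per_fish, global = glob)
}

#' Segment-count-weighted mean
#'
#' The elementary weighted average used for the global parameter table:
#' `sum(n_i v_i) / sum(n_i)`.
#'
#' @param values per-fish parameter values.
#' @param counts per-fish segment counts.
#' @return Scalar weighted mean.
#' @export
weighted_param_mean <- function(values, counts) {
  stopifnot(length(values) == length(counts), all(counts >= 0),
            sum(counts) > 0)
  sum(values * counts) / sum(counts)
}

#' Fit the wall-avoidance response
#'
#' Two-stage estimate of the repulsion amplitude `A` and decay rate `B` in
#' the wall-response model `omega_c = A * exp(B * z)`, where `z` is either
#' the projected collision distance `d_W` (cm) or time `t_W` (s). Stage 1
#' smooths the noisy scatter of wall-corrected turning speeds with a LOESS
#' regression; stage 2 fits the exponential to the LOESS curve evaluated on
#' an even grid, by nonlinear least squares initialised from a log-linear
#' fit to the positive part of the curve.
#'
#' @param z abscissae: projected distance (cm) or time (s), positive.
#' @param omega_c wall-corrected turning speeds (rad/s).
#' @param mode `"distance"` or `"time"`, recorded in the result.
#' @param span LOESS span (fraction of points in each local fit). The
#'   default 0.2 keeps the local bandwidth comparable to the ~9 cm decay
#'   length of the fitted response; much wider spans flatten the curve near
#'   the wall and bias the amplitude downwards.
#' @param degree local polynomial degree. The default 2 is essentially
#'   unbiased on an exponential of this decay length, where local-linear
#'   smoothing attenuates the amplitude by ~10% through its curvature bias.
#' @param grid_n number of grid points the exponential is fitted on.
#' @return A list of class `"fw_wall_fit"` with `A`, `B`, `se_A`, `se_B`,
#'   `mode`, and the LOESS `grid` (data frame `z`, `omega`).
#' @export
fit_wall_response <- function(z, omega_c, mode = c("distance", "time"),
                              span = 0.2, degree = 2, grid_n = 100L) {
  mode <- match.arg(mode)
  stopifnot(length(z) == length(omega_c))
  if (length(z) < 50L) stop("need at least 50 samples")
  if (any(z < 0)) stop("abscissae must be non-negative")

  lo <- stats::loess(omega_c ~ z, span = span, degree = degree,
                     data = data.frame(z = z, omega_c = omega_c))
  zg <- seq(min(z), max(z), length.out = grid_n)
  yg <- stats::predict(lo, newdata = data.frame(z = zg))
  ok <- is.finite(yg)
  zg <- zg[ok]; yg <- yg[ok]
  if (all(yg <= 0)) stop("no repulsive signal: LOESS curve non-positive everywhere")

  pos <- yg > 0
  init <- stats::lm(log(yg[pos]) ~ zg[pos])$coefficients
  fit <- minpack.lm::nlsLM(y ~ A * exp(B * zz),
                           data = data.frame(zz = zg, y = yg),
                           start = list(A = exp(unname(init[1])),
                                        B = unname(init[2])))
  cf <- summary(fit)$coefficients
  structure(list(A = cf["A", "Estimate"], B = cf["B", "Estimate"],
                 se_A = cf["A", "Std. Error"], se_B = cf["B", "Std. Error"],
                 mode = mode,
                 grid = data.frame(z = zg, omega = yg)),
            class = "fw_wall_fit")
}

#' Saturation noise amplitude for the turning-speed process
#'
#' The speed-coupled noise amplitude saturates at `sigma_0` as the walker's
#' speed approaches zero. `sigma_0` is set so that the stationary standard
#' deviation of a turning-speed O-U process running at the saturated
#' amplitude, `sigma_0 / sqrt(2 theta_omega)`, equals half the maximum
#' observed turning speed (a two-sigma band covering the observed range):
#' `sigma_0 = max_omega * sqrt(2 theta_omega) / 2`.
#'
#' @param max_omega maximum turning speed (rad/s), positive.
#' @param theta_omega turning mean-reversion rate (1/s), positive.
#' @return `sigma_0` in rad s^-1 per sqrt(s).
#' @export
estimate_sigma0 <- function(max_omega, theta_omega) {
  if (max_omega <= 0 || theta_omega <= 0)
    stop("max_omega and theta_omega must be positive")
  max_omega * sqrt(2 * theta_omega) / 2
}
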