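# Summary statistics used to compare experimental and simulated
# trajectories: lag-1 autocorrelation and the derived correlation time,
# full ACF with its exponential envelope, joint speed-turn log-densities
# and positional occupancy maps.

#' Lag-1 autocorrelation coefficient
#'
#' `r1 = sum_{k=1}^{N-1} (X_k - Xbar)(X_{k+1} - Xbar) / sum_{k=1}^{N}
#' (X_k - Xbar)^2`, with the overall sample mean in both sums. Note the
#' asymmetric normalisation — the numerator runs over N-1 terms, the
#' denominator over N — so the value can marginally exceed the
#' conventional [-1, 1] bounds for short series.
#'
#' @param x numeric series, length >= 3, nonzero variance.
#' @return Scalar `r1`.
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  m <- mean(x)
  d <- x - m
  den <- sum(d^2)
  if (den == 0) stop("degenerate variance: constant series")
  sum(d[-n] * d[-1L]) / den
}

#' Correlation time and half-life from the lag-1 autocorrelation
#'
#' For a process with an exponential autocorrelation envelope
#' `exp(-t / tau)`, the lag-1 coefficient determines
#' `tau = -dt / log(r1)`; the half-life is `tau * log(2)`.
#'
#' @param r1 lag-1 autocorrelation, strictly between 0 and 1.
#' @param dt sampling step (s).
#' @return List with `tau` and `half_life` (s).
#' @export
correlation_time <- function(r1, dt) {
  if (!is.finite(r1) || r1 <= 0 || r1 >= 1)
    stop("no exponential envelope: r1 must lie in (0, 1)")
  tau <- -dt / log(r1)
  list(tau = tau, half_life = tau * log(2))
}

#' Sample autocorrelation function with exponential envelope
#'
#' Computes the standard biased sample ACF (normalised by N and the overall
#' mean) up to `max_lag`, together with the lag-1 coefficient (its own
#' asymmetric normalisation, see [lag1_autocorr()]), the correlation time
#' derived from it, and the fitted envelope `exp(-lag * dt / tau)`.
#'
#' @param x numeric series.
#' @param dt sampling step (s).
#' @param max_lag largest lag (samples); must be below `length(x) / 2`.
#' @return A list of class `"fw_acf"`: `lag` (s), `acf`, `envelope`, `r1`,
#'   `tau`, `half_life`, `dt`.
#' @export
acf_summary <- function(x, dt, max_lag = 25L) {
  n <- length(x)
  if (max_lag >= n / 2) stop("max_lag must be below length(x) / 2")
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  r1 <- lag1_autocorr(x)
  ct <- correlation_time(r1, dt)
  lags <- seq(0L, max_lag) * dt
  structure(list(lag = lags, acf = rho,
                 envelope = exp(-lags / ct$tau),
                 r1 = r1, tau = ct$tau, half_life = ct$half_life, dt = dt),
            class = "fw_acf")
}

#' Joint speed / turning-speed log-density
#'
#' 2-D histogram of paired speed and turning-speed samples on a regular
#' grid, reported as `log10(count + 1)` so empty bins stay finite. The
#' marginal means are annotated, mirroring how joint densities of the two
#' processes are usually displayed.
#'
#' @param u speed series (cm/s).
#' @param omega turning-speed series (rad/s), same length.
#' @param bins number of bins per axis.
#' @return List with `u_breaks`, `omega_breaks`, `log_density` (matrix,
#'   rows = u bins), `mean_u`, `mean_omega`.
#' @export
joint_log_density <- function(u, omega, bins = 50L) {
  stopifnot(length(u) == length(omega))
  ub <- seq(min(u), max(u), length.out = bins + 1L)
  ob <- seq(min(omega), max(omega), length.out = bins + 1L)
  ui <- findInterval(u, ub, rightmost.closed = TRUE, all.inside = TRUE)
  oi <- findInterval(omega, ob, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ui))
    counts[ui[k], oi[k]] <- counts[ui[k], oi[k]] + 1L
  list(u_breaks = ub, omega_breaks = ob,
       log_density = log10(counts + 1),
       mean_u = mean(u), mean_omega = mean(omega))
}

#' Positional occupancy density map
#'
#' Fraction of time spent in each cell of a regular grid over the arena.
#' Samples outside the grid are counted in the nearest edge bin, with a
#' warning.
#'
#' @param traj an `fw_trajectory`.
#' @param xlim,ylim grid extent (cm).
#' @param bins number of bins per axis; the default 60 gives 2-cm pixels
#'   over the 120-cm tank.
#' @return A list of class `"fw_density_map"`: `x_breaks`, `y_breaks`,
#'   `density` (matrix summing to 1, rows = x bins).
#' @export
occupancy_density <- function(traj, xlim = c(-60, 60), ylim = c(-60, 60),
                              bins = 60L) {
  stopifnot(inherits(traj, "fw_trajectory"))
  out <- traj$x < xlim[1] | traj$x > xlim[2] |
    traj$y < ylim[1] | traj$y > ylim[2]
  if (any(out))
    warning(sum(out), " samples outside the grid counted in edge bins")
  xb <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = bins + 1L)
  xi <- findInterval(traj$x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(traj$y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(xi))
    counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  structure(list(x_breaks = xb, y_breaks = yb,
                 density = counts / sum(counts)),
            class = "fw_density_map")
}
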