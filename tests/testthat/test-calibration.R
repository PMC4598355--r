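test_that("O-U MLE recovers generating parameters from long exact samples", {
  # speed-process values
  x <- gen_ou_exact(ou_params(14.02, 0.59, 4.21), 2e5, 0.2, seed = 101)
  fit <- fit_ou_mle(x, 0.2)
  expect_equal(fit$mu, 14.02, tolerance = 0.02)
  expect_equal(fit$theta, 0.59, tolerance = 0.02)
  expect_equal(fit$sigma, 4.21, tolerance = 0.02)
  # turning-process values
  w <- gen_ou_exact(ou_params(-0.02, 2.74, 2.85), 2e5, 0.2, seed = 102)
  fit <- fit_ou_mle(w, 0.2)
  expect_equal(fit$theta, 2.74, tolerance = 0.02)
  expect_equal(fit$sigma, 2.85, tolerance = 0.02)
  expect_lt(abs(fit$mu - (-0.02)), 0.05)
})

test_that("O-U MLE rejects degenerate and non-mean-reverting input", {
  expect_error(fit_ou_mle(rep(3, 100), 0.2), "degenerate variance")
  expect_error(fit_ou_mle(1:100, 0.2), "non-mean-reverting")
  expect_error(fit_ou_mle(c(1, 2), 0.2), "at least 10")
})

test_that("MLE estimates satisfy the AR(1) score equations", {
  x <- gen_ou_exact(ou_params(2, 1.3, 0.8), 5000, 0.1, seed = 8)
  f <- fit_ou_mle(x, 0.1)
  a <- exp(-f$theta * 0.1)
  r <- (x[-1] - f$mu) - a * (x[-length(x)] - f$mu)
  # d/dmu and d/da of the conditional log-likelihood vanish
  expect_lt(abs(sum(r)), 1e-8 * length(x))
  expect_lt(abs(sum(r * (x[-length(x)] - f$mu))), 1e-6 * length(x))
})

test_that("MLE error shrinks with sample size", {
  true <- ou_params(5, 2, 1.5)
  err <- function(n) {
    e <- matrix(0, 50, 3)
    for (s in 1:50) {
      f <- fit_ou_mle(gen_ou_exact(true, n, 0.2, seed = 1000 + s), 0.2)
      e[s, ] <- c(f$mu - 5, f$theta - 2, f$sigma - 1.5)
    }
    sqrt(colMeans(e^2))
  }
  rmse_small <- err(1e3)
  rmse_big <- err(1e5)
  expect_true(all(rmse_big < rmse_small))
})

test_that("segment-count weighting reproduces the packaged global parameter table", {
  fp <- fish_params()
  expect_equal(weighted_param_mean(fp$mu_u, fp$n), 14.02, tolerance = 5e-4)
  expect_equal(weighted_param_mean(fp$theta_u, fp$n), 0.59, tolerance = 1e-2)
  expect_equal(weighted_param_mean(fp$sigma_u, fp$n), 4.21, tolerance = 5e-3)
  expect_equal(weighted_param_mean(fp$mu_w, fp$n), -0.02, tolerance = 0.05)
  expect_equal(weighted_param_mean(fp$theta_w, fp$n), 2.74, tolerance = 2e-3)
  expect_equal(weighted_param_mean(fp$sigma_w, fp$n), 2.85, tolerance = 5e-3)
})

test_that("average_params nests per-segment means inside count-weighted fish means", {
  per_seg <- list(
    A = list(ou_params(1, 1, 1), ou_params(3, 2, 2)),
    B = list(ou_params(10, 4, 3))
  )
  res <- average_params(per_seg)
  expect_equal(res$per_fish$mu, c(2, 10))
  expect_equal(res$per_fish$n, c(2L, 1L))
  expect_equal(res$global$mu, (2 * 2 + 1 * 10) / 3)
  expect_equal(res$global$theta, (2 * 1.5 + 1 * 4) / 3)
  # single fish: global equals that fish regardless of counts
  solo <- average_params(list(C = list(ou_params(7, 2, 1))))
  expect_equal(solo$global$mu, 7)
  # all-equal per-fish values pass through unchanged
  eq <- average_params(list(A = list(ou_params(4, 2, 1)),
                            B = list(ou_params(4, 2, 1),
                                     ou_params(4, 2, 1))))
  expect_equal(eq$global$mu, 4)
  expect_error(average_params(list()), "no segments")
})

test_that("noiseless wall-response input is recovered almost exactly", {
  d <- gen_wall_response(2.25, -0.11, noise_sd = 0, n = 2000,
                         range = c(0, 60), seed = 1)
  f <- fit_wall_response(d$z, d$omega_c)
  expect_equal(f$A, 2.25, tolerance = 1e-3)
  expect_equal(f$B, -0.11, tolerance = 1e-2)
  expect_equal(f$mode, "distance")
})

test_that("wall-response fit recovers parameters from noisy scatter", {
  d <- gen_wall_response(2.25, -0.11, noise_sd = 1, n = 2000,
                         range = c(0, 60), seed = 2)
  f <- fit_wall_response(d$z, d$omega_c)
  expect_lt(abs(f$A - 2.25), 0.3)
  expect_lt(abs(f$B + 0.11), 0.04)
  expect_true(f$se_A > 0 && f$se_B > 0)
})

test_that("time-mode wall-response fit recovers its parameters", {
  d <- gen_wall_response(2.25, -1.68, noise_sd = 1, n = 2000,
                         range = c(0, 4), seed = 3)
  f <- fit_wall_response(d$z, d$omega_c, mode = "time")
  expect_lt(abs(f$A - 2.25), 0.3)
  expect_lt(abs(f$B + 1.68), 0.53)
  expect_equal(f$mode, "time")
})

test_that("wall-response fit is equivariant under scaling of the response", {
  d <- gen_wall_response(2.25, -0.11, noise_sd = 1, n = 2000,
                         range = c(0, 60), seed = 4)
  f1 <- fit_wall_response(d$z, d$omega_c)
  f2 <- fit_wall_response(d$z, 3 * d$omega_c)
  expect_equal(f2$A, 3 * f1$A, tolerance = 1e-6)
  expect_equal(f2$B, f1$B, tolerance = 1e-6)
})

test_that("pure-noise wall data with no repulsive trend is rejected", {
  set.seed(6)
  z <- runif(500, 0, 60)
  expect_error(fit_wall_response(z, rep(-1, 500) + 0.01 * rnorm(500)),
               "no repulsive signal")
  expect_error(fit_wall_response(z[1:20], rnorm(20)), "at least 50")
})

test_that("sigma0 follows the two-sigma saturation rule", {
  expect_equal(estimate_sigma0(10, 2.81), 11.853, tolerance = 1e-4)
  expect_equal(round(estimate_sigma0(10, 2.81)), 12)
  expect_equal(estimate_sigma0(10, 0.5), 5)
  expect_equal(estimate_sigma0(20, 2.81), 2 * estimate_sigma0(10, 2.81))
  # as a stationary-variance cap: sigma0^2 / (2 theta) = (max/2)^2 exactly
  s0 <- estimate_sigma0(10, 2.81)
  expect_equal(s0^2 / (2 * 2.81), (10 / 2)^2)
  expect_error(estimate_sigma0(-1, 2), "positive")
})
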