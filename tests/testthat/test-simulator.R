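test_that("the speed-turn coupling hits its closed-form anchors", {
  # saturates at sigma0 when stationary, sigma_w/2 at the mean speed
  expect_equal(coupling_fc(0, 2.85, 12, 14.02), 12)
  expect_equal(coupling_fc(14.02, 2.85, 12, 14.02), 2.85 / 2)
  expect_equal(coupling_fc(28.04, 2.85, 12, 14.02), 12 * (24 / 2.85)^-2)
  # strictly decreasing in speed
  u <- seq(0, 40, by = 0.5)
  expect_true(all(diff(coupling_fc(u, 2.85, 12, 14.02)) < 0))
  expect_error(coupling_fc(1, 3, 2, 14), "sigma0 > sigma_w")
})

test_that("the wall bias is antisymmetric, bounded by A and decays from the wall", {
  expect_equal(wall_force_fw(0.4, 0, 6.75, -0.11), 6.75)
  expect_equal(wall_force_fw(-0.4, 7, 6.75, -0.11),
               -wall_force_fw(0.4, 7, 6.75, -0.11))
  expect_equal(wall_force_fw(1, 10, 6.75, -0.11), 6.75 * exp(-1.1),
               tolerance = 1e-9)
  expect_equal(wall_force_fw(0, 5, 6.75, -0.11), 0)
  d <- seq(0, 80, by = 1)
  f <- wall_force_fw(0.2, d, 6.75, -0.11)
  expect_true(all(abs(f) <= 6.75) && all(diff(f) < 0))
})

test_that("a noise-free walker at equilibrium runs straight at constant speed", {
  p <- model_params(speed = ou_params(14.02, 0.59, 0),
                    turn = ou_params(0, 2.74, 0),
                    sigma0 = 1, A = 0, B = 0)
  cfg <- sim_config(dt = 0.2, T = 10, seed = 1, walls = FALSE,
                    coupling = FALSE, init = "fixed")
  st <- list(x = 0, y = 0, phi = 0, U = 14.02, Omega = 0, t = 0)
  st2 <- em_step(st, p, cfg, c(0.7, -1.2))  # noise multiplied by sigma = 0
  expect_equal(st2$x, 14.02 * 0.2)
  expect_equal(st2$y, 0)
  expect_equal(st2$phi, 0)
  expect_equal(st2$U, 14.02)
})

test_that("without noise the turning speed follows the Euler recursion exactly", {
  p <- model_params(speed = ou_params(10, 0.5, 0),
                    turn = ou_params(0.3, 2.74, 0),
                    sigma0 = 1, A = 0, B = 0)
  cfg <- sim_config(dt = 0.2, T = 10, seed = 1, walls = FALSE,
                    coupling = FALSE)
  st <- list(x = 0, y = 0, phi = 0, U = 10, Omega = 2, t = 0)
  for (k in 1:10) {
    st <- em_step(st, p, cfg, c(0, 0))
    expect_equal(st$Omega, 0.3 + (2 - 0.3) * (1 - 2.74 * 0.2)^k,
                 tolerance = 1e-12)
  }
})

test_that("crossing the boundary is a fully inelastic collision", {
  p <- default_params()
  cfg <- sim_config(dt = 0.2, T = 10, seed = 1)
  st <- list(x = 59.9, y = 0, phi = 0, U = 14, Omega = 0, t = 0)
  st2 <- em_step(st, p, cfg, c(0.3, -0.8))
  expect_equal(c(st2$x, st2$y), c(59.9, 0))
  expect_equal(st2$U, 0)
  expect_equal(st2$phi, 0)   # heading reverts with the position
})

test_that("simulation is reproducible and matches stepwise em_step iteration", {
  p <- default_params()
  cfg <- sim_config(T = 30, seed = 77)
  s1 <- run_simulation(p, cfg)
  s2 <- run_simulation(p, cfg)
  expect_identical(s1$trajectory$x, s2$trajectory$x)
  expect_identical(s1$latent$Omega, s2$latent$Omega)

  cfg_f <- sim_config(T = 10, seed = 9, init = "fixed")
  sim <- run_simulation(p, cfg_f)
  set.seed(9L)
  z <- matrix(rnorm(2 * 50), nrow = 2)
  st <- list(x = 0, y = 0, phi = 0, U = p$speed$mu, Omega = 0, t = 0)
  for (k in 1:50) st <- em_step(st, p, cfg_f, z[, k])
  expect_equal(st$x, sim$trajectory$x[51], tolerance = 1e-12)
  expect_equal(st$Omega, sim$latent$Omega[51], tolerance = 1e-12)
})

test_that("free-space uncoupled runs reach the O-U stationary mean and the AR(1) variance", {
  p <- default_params()
  cfg <- sim_config(dt = 0.2, T = 2e4, seed = 13, walls = FALSE,
                    coupling = FALSE, omega_clamp = Inf, init = "fixed")
  sim <- run_simulation(p, cfg)
  U <- sim$latent$U[-(1:200)]
  Om <- sim$latent$Omega[-(1:200)]
  # mean speed -> mu_u within 3 standard errors of the time-average
  se_mean <- p$speed$sigma / p$speed$theta / sqrt(cfg$T)
  expect_lt(abs(mean(U) - p$speed$mu), 3 * se_mean)
  # Euler-discretised stationary variance sigma^2 / (theta (2 - theta dt))
  v_th <- p$turn$sigma^2 / (p$turn$theta * (2 - p$turn$theta * cfg$dt))
  expect_equal(var(Om), v_th, tolerance = 0.05)
})

test_that("walled coupled runs respect heading range, clamp and containment", {
  p <- default_params()
  sim <- run_simulation(p, sim_config(T = 400, seed = 2))
  expect_true(all(sim$latent$phi >= -pi & sim$latent$phi < pi))
  expect_true(all(abs(sim$latent$Omega) <= 15))
  expect_true(all(arena_contains(arena(), sim$trajectory$x,
                                 sim$trajectory$y)))
})

test_that("Euler-Maruyama marginals match the exact O-U sampler at small dt", {
  tp <- ou_params(0, 20, 2)
  p <- model_params(speed = ou_params(10, 0.5, 1), turn = tp,
                    sigma0 = 3, A = 0, B = 0)
  cfg <- sim_config(dt = 1e-3, T = 1000, seed = 31, walls = FALSE,
                    coupling = FALSE, omega_clamp = Inf, init = "fixed")
  sim <- run_simulation(p, cfg)
  em <- sim$latent$Omega[-(1:10000)]
  em_thin <- em[seq(1, length(em), by = 99)]
  exact <- gen_ou_exact(tp, length(em_thin), dt = 0.099, seed = 32)
  ks <- suppressWarnings(stats::ks.test(em_thin, exact))
  expect_gt(ks$p.value, 0.01)
})

test_that("coupling narrows the turning distribution at high speed", {
  p <- default_params()
  sim <- run_simulation(p, sim_config(T = 4000, seed = 4, walls = FALSE))
  U <- sim$latent$U; Om <- sim$latent$Omega
  expect_lt(sd(Om[U > p$speed$mu]), sd(Om[U < p$speed$mu]))
})

test_that("low sigma_w/theta_w walkers hug the walls more than high-ratio walkers", {
  dist_to_wall <- function(sim) {
    mean(60 - pmax(abs(sim$trajectory$x), abs(sim$trajectory$y)))
  }
  ratio <- function(f) { p <- fish_model_params(f); p$turn$sigma / p$turn$theta }
  expect_lt(ratio("F7"), 1)   # thigmotactic
  expect_gt(ratio("F2"), 1)   # ranging
  d_f7 <- dist_to_wall(run_simulation(fish_model_params("F7"),
                                      sim_config(T = 2000, seed = 6)))
  d_f2 <- dist_to_wall(run_simulation(fish_model_params("F2"),
                                      sim_config(T = 2000, seed = 6)))
  expect_lt(d_f7, d_f2)
})
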