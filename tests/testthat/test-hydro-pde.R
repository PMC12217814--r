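test_that("the homogeneous state is an exact fixed point", {
  p <- ps_point_params()
  g <- pde_grid(2, dx = 0.02)
  f <- density_field(rep(0.25, g$N), rep(0.25, g$N), rep(0.1, g$N), g)
  for (scheme in c("upwind", "centered")) {
    d <- pde_rhs(f, p, scheme = scheme)
    expect_equal(max(abs(c(d$dp, d$dm, d$d0))), 0)
  }
  tr <- integrate_pde(f, p, t_end = 0.5, dt_save = 0.25)
  expect_equal(frame_field(tr)$rp, f$rp, tolerance = 1e-14)
})

test_that("fluxes conserve species masses to machine precision", {
  p <- tw_point_params()
  g <- pde_grid(25, dx = 0.25)
  set.seed(2)
  f <- make_initial_condition(p, g, "noise", noise_amplitude = 0.05, seed = 2)
  d <- pde_rhs(f, p)
  expect_lt(abs(sum(d$dp + d$dm)), 1e-12)  # flips conserve rho_a
  expect_lt(abs(sum(d$d0)), 1e-12)
  tr <- integrate_pde(f, p, t_end = 5, dt_save = 5)
  ff <- frame_field(tr)
  expect_lt(abs(mean(ff$rp + ff$rm) - p$phi_a), 1e-10)
  expect_lt(abs(mean(ff$r0) - p$phi_p), 1e-10)
})

test_that("passive relaxation rate at Pe = 0 is q^2", {
  # single passive species: rho D + d_s = 1 makes the collective
  # diffusivity exactly 1, so a sinusoid of wavenumber q decays at q^2
  p <- aplg_params(0, phi_a = 0, phi_p = 0.4)
  g <- pde_grid(2 * pi, N = 400L)
  q <- 1
  amp <- 1e-4
  f <- density_field(rep(0, g$N), rep(0, g$N), 0.4 + amp * cos(q * g$x), g)
  tr <- integrate_pde(f, p, t_end = 0.2, save_times = c(0, 0.1, 0.2),
                      scheme = "centered")
  a1 <- tr$r0[2, ] %*% cos(q * g$x)
  a2 <- tr$r0[3, ] %*% cos(q * g$x)
  rate <- -log(as.numeric(a2 / a1)) / 0.1
  expect_equal(rate, q^2, tolerance = 1e-3)
})

test_that("initial conditions preserve means exactly and honor amplitude", {
  p <- ps_point_params()
  g <- pde_grid(2, dx = 0.01)
  f0 <- make_initial_condition(p, g, "noise", noise_amplitude = 0)
  expect_equal(f0$rp, rep(0.25, g$N))
  f1 <- make_initial_condition(p, g, "noise", seed = 9)
  expect_equal(mean(f1$rp), 0.25, tolerance = 1e-15)
  expect_equal(mean(f1$r0), 0.1, tolerance = 1e-15)
  f2 <- make_initial_condition(p, g, "noise", seed = 9)
  expect_identical(f1$rp, f2$rp)  # seeded reproducibility
  # eigenmode kinds refuse stable points unless forced
  stable <- aplg_params(2, L = 2, phi_a = 0.1, phi_p = 0.5)
  expect_error(make_initial_condition(stable, g, "left"), "stable|unstable")
  f3 <- make_initial_condition(p, g, "pair", seed = 9)
  expect_equal(mean(f3$rp + f3$rm), 0.5, tolerance = 1e-15)
})

test_that("measure_speed recovers the drift of a manufactured wave", {
  g <- pde_grid(10, N = 500L)
  prof <- 0.4 + 0.2 * sin(2 * pi * g$x / 10) + 0.05 * cos(4 * pi * g$x / 10)
  v <- -0.173
  times <- seq(0, 20, by = 0.5)
  roll <- function(f, sh) {
    x0 <- (g$x - sh) %% 10
    stats::approx(c(g$x[1] - 10 + g$x[500], g$x, g$x[1] + 10),
                  c(prof[500], prof, prof[1]), xout = x0)$y
  }
  frames <- t(vapply(times, function(t1) roll(prof, v * t1), numeric(500)))
  tr <- structure(list(times = times, rp = frames / 3, rm = frames / 3,
                       r0 = frames / 3, grid = g,
                       params = aplg_params(1, L = 10, phi_a = 0.2,
                                            phi_p = 0.1)),
                  class = "aplg_trajectory")
  sp <- measure_speed(tr)
  expect_equal(sp$velocity, v, tolerance = 1e-3)
  expect_equal(sp$c, v * 10, tolerance = 1e-2)
})

test_that("noise-seeded run at strong activity phase separates", {
  st <- relaxed_ps_state()
  f <- st$field
  rho <- f$rp + f$rm + f$r0
  expect_gt(max(rho), 0.9)   # dense liquid
  expect_lt(min(rho), 0.35)  # dilute vapor
  # magnetization small in both bulk phases, large at interfaces
  m <- f$rp - f$rm
  expect_lt(abs(m[which.max(rho)]), 0.02)
  expect_lt(abs(m[which.min(rho)]), 0.02)
  expect_gt(max(abs(m)), 0.3)
  expect_gt(distance_from_uniform(f, st$params), 0.05)
})

test_that("density field validation rejects invalid states", {
  g <- pde_grid(1, N = 10L)
  expect_error(density_field(rep(0.5, 10), rep(0.4, 10), rep(0.2, 10), g),
               "total")
  expect_error(density_field(rep(-0.1, 10), rep(0.1, 10), rep(0.1, 10), g),
               "nonnegative")
})
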