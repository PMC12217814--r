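# Shared converged finite-L wave at the traveling-state fixture (cached).
traveling_wave_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    at <- traveling_attractor()
    cache <<- solve_finite_L(at$params, N = 500L, init = at$traj)
    cache
  }
})

test_that("finite-L Newton converges from a time-stepped attractor", {
  w <- traveling_wave_fixture()
  expect_true(w$converged)
  expect_lt(w$residual, 1e-8)
  # mass constraints exact
  expect_lt(abs(mean(w$rho_a) - 0.36), 1e-12)
  expect_lt(abs(mean(w$r0) - 0.3), 1e-12)
  # the orientation-flip balance int m dz = 0 emerges automatically
  expect_lt(abs(mean(w$m)), 1e-10)
  # left-moving branch, O(1) speed
  expect_lt(w$c, -1)
  expect_gt(w$c, -3)
})

test_that("the gauge fixes translation but not the speed", {
  w <- traveling_wave_fixture()
  N <- length(w$rho)
  sh <- 57L
  roll <- function(v) v[((seq_len(N) + sh - 1L) %% N) + 1L]
  w2 <- solve_finite_L(w$params, N = N,
                       init = list(rp = roll(w$rp), rm = roll(w$rm),
                                   r0 = roll(w$r0), c = w$c))
  expect_true(w2$converged)
  expect_equal(w2$c, w$c, tolerance = 1e-8)
})

test_that("mirroring a traveling solution flips its speed", {
  w <- traveling_wave_fixture()
  init <- list(rp = rev(w$rm), rm = rev(w$rp), r0 = rev(w$r0), c = -w$c)
  w2 <- solve_finite_L(w$params, N = length(w$rho), init = init)
  expect_true(w2$converged)
  expect_equal(w2$c, -w$c, tolerance = 1e-7)
})

test_that("a relaxed phase-separated state solves the c = 0 branch", {
  st <- relaxed_ps_state()
  f <- st$field
  w <- solve_finite_L(st$params, N = f$grid$N,
                      init = list(rp = f$rp, rm = f$rm, r0 = f$r0, c = 0))
  expect_true(w$converged)
  expect_lt(abs(w$c), 1e-6)
  # stationary phase separation: two distinct plateaus are allowed
  chk <- no_traveling_ps_check(w)
  expect_true(chk$pass)
  expect_false(chk$applicable)  # theorem silent at c = 0
  expect_gte(chk$n_plateaus, 2)
  expect_gt(max(chk$plateau_densities) - min(chk$plateau_densities), 0.3)
})

test_that("moving solutions never carry two distinct plateaus", {
  w <- traveling_wave_fixture()
  chk <- no_traveling_ps_check(w)
  expect_true(chk$pass)
  if (chk$applicable)
    expect_lt(max(chk$plateau_densities) - min(chk$plateau_densities), 1e-4)
})

test_that("interface insertion finds the steepest front", {
  z <- seq(0, 1, length.out = 257)
  prof <- 0.4 + 0.3 * tanh((z - 0.31) / 0.01)
  sol <- structure(list(z = z, rho = prof, c = 1, nu = 0.3),
                   class = "aplg_wave")
  ii <- insert_interface(sol)
  expect_equal(ii$z_star, 0.31, tolerance = 0.01)
  # symmetric double front: tie broken toward smaller z
  prof2 <- 0.4 + 0.2 * tanh((z - 0.25) / 0.01) - 0.2 * tanh((z - 0.75) / 0.01)
  sol2 <- structure(list(z = z, rho = prof2, c = 1, nu = 0.3),
                    class = "aplg_wave")
  expect_lt(insert_interface(sol2)$z_star, 0.5)
  # flat profile is an error
  sol3 <- structure(list(z = z, rho = rep(0.5, 257), c = 1, nu = 0.3),
                    class = "aplg_wave")
  expect_error(insert_interface(sol3), "flat")
})

test_that("outer solve reproduces the large-size limit of finite-L waves", {
  skip_if_not(file.exists(test_path("..", "..", "inst", "extdata",
                                    "outer_wave_seeds.json")) ||
              nzchar(system.file("extdata", "outer_wave_seeds.json",
                                 package = "aplg")))
  seeds <- jsonlite::read_json(system.file("extdata",
                                           "outer_wave_seeds.json",
                                           package = "aplg"),
                               simplifyVector = TRUE)
  sd <- seeds$a_036_030
  w <- solve_outer(0.36, 0.3, 7.5, N = 256,
                   init = list(ra = sd$ra, r0 = sd$r0, c = sd$c,
                               nu = sd$nu))
  expect_true(w$converged)
  expect_lt(w$residual, 1e-8)
  # interface endpoints sit on the binodal tie line of the converged nu
  bn <- binodal_at_nu(7.5, w$nu)
  expect_equal(w$rho[1], bn$phi_v, tolerance = 1e-8)
  expect_equal(w$rho[length(w$rho)], bn$phi_l, tolerance = 1e-8)
  expect_equal(w$r0[1], w$nu * (1 - w$rho[1]), tolerance = 1e-10)
  # masses
  trap <- function(v) (sum(v) - 0.5 * v[1] - 0.5 * v[length(v)]) / 256
  expect_lt(abs(trap(w$rho_a) - 0.36), 1e-9)
  expect_lt(abs(trap(w$r0) - 0.3), 1e-9)
})

test_that("outer stability matrix flags the oscillatory band", {
  os <- outer_stability(0.44, 0.28, 7.5)
  expect_true(os$unstable)
  expect_true(os$complex_pair)
  os2 <- outer_stability(0.2, 0.2, 7.5)
  expect_false(os2$unstable)
  # low Pe: diffusive, stable everywhere sampled
  for (pa in c(0.2, 0.5, 0.7))
    expect_false(outer_stability(pa, 0.1, 1)$unstable)
})
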