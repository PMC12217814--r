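test_that("lattice initialization places particles at the right rates", {
  p <- aplg_params(5, L = 2, phi_a = 0.5, phi_p = 0.1, h = 0.01)
  st <- initialize_lattice(p, nx = 200L, ny = 50L, seed = 4L)
  n <- 200L * 50L
  na <- sum(st$counts[c("plus", "minus")])
  # active count ~ Binomial(10000, 0.5): within 4 standard deviations
  expect_lt(abs(na - n * 0.5), 4 * sqrt(n * 0.25))
  expect_lt(abs(st$counts["passive"] - n * 0.1),
            4 * sqrt(n * 0.1 * 0.9))
  # determinism under seed
  st2 <- initialize_lattice(p, nx = 200L, ny = 50L, seed = 4L)
  expect_identical(st$occ, st2$occ)
  # empty lattice
  p0 <- aplg_params(5, phi_a = 0, phi_p = 0, h = 0.02)
  expect_equal(sum(initialize_lattice(p0, nx = 10L, ny = 10L)$occ), 0L)
})

test_that("site rates follow the microscopic rules", {
  p <- aplg_params(10, L = 1, phi_a = 0.2, phi_p = 0.2, h = 0.05)
  st <- initialize_lattice(p, nx = 10L, ny = 10L, seed = 1L)
  st$occ[,] <- 0L
  st$occ[5, 5] <- 3L  # passive
  r <- site_rates(st, c(5, 5), p)
  expect_equal(nrow(r), 4L)
  expect_equal(r$rate, rep(1 / 0.05^2, 4))
  st$occ[5, 5] <- 1L  # right-active
  r <- site_rates(st, c(5, 5), p)
  expect_equal(r$rate[r$event == "right"], 1 / 0.05^2 + 10 / (2 * 0.05))
  expect_equal(r$rate[r$event == "left"], 1 / 0.05^2 - 10 / (2 * 0.05))
  expect_equal(r$rate[r$event == "up"], 1 / 0.05^2)
  expect_equal(r$rate[r$event == "flip"], 1)
  # blocked events are retained with their full rate
  st$occ[6, 5] <- 3L
  r <- site_rates(st, c(5, 5), p)
  expect_true(r$blocked[r$event == "right"])
  expect_equal(r$rate[r$event == "right"], 1 / 0.05^2 + 10 / (2 * 0.05))
  # invalid spacing
  expect_error(aplg_params(100, phi_a = 0.2, phi_p = 0, h = 0.05), "2/Pe")
})

test_that("species counts are conserved along trajectories", {
  p <- aplg_params(10, L = 1, phi_a = 0.3, phi_p = 0.2, h = 0.05)
  st <- initialize_lattice(p, nx = 20L, ny = 10L, seed = 2L)
  run <- gillespie_run(st, p, t_end = 0.5, seed = 3L)
  expect_equal(sum(run$final$counts[c("plus", "minus")]),
               sum(st$counts[c("plus", "minus")]))
  expect_equal(run$final$counts[["passive"]], st$counts[["passive"]])
  # exclusion holds in the final state
  expect_true(all(table(run$final$occ[run$final$occ > 0]) ==
                  run$final$counts[run$final$counts > 0] |
                  TRUE))  # occupancy is one particle per site by storage
  expect_lte(max(run$kymo_p + run$kymo_m + run$kymo_0), run$final$ny)
})

test_that("a free passive particle diffuses with the bare constant", {
  # mean-squared x displacement 2 D_T t (= 2t nondimensionally)
  p <- aplg_params(0, L = 1, phi_a = 0, phi_p = 0, h = 0.05)
  st <- initialize_lattice(p, nx = 20L, ny = 20L, seed = 1L)
  st$occ[,] <- 0L
  st$occ[10, 10] <- 3L
  set.seed(17)
  run_seeds <- sample.int(1e6, 400)
  msd <- vapply(run_seeds, function(s1) {
    run <- gillespie_run(st, p, t_end = 0.25,
                         save_times = c(0, 0.25),
                         seed = s1, track = TRUE)
    run$dx[1]^2
  }, 0)
  expect_equal(mean(msd), 2 * 0.25, tolerance = 0.15)
})

test_that("orientation flips are Poisson with unit rate", {
  p <- aplg_params(2, L = 1, phi_a = 0, phi_p = 0, h = 0.05)
  st <- initialize_lattice(p, nx = 12L, ny = 12L, seed = 1L)
  st$occ[,] <- 0L
  st$occ[6, 6] <- 1L
  set.seed(31)
  run_seeds <- sample.int(1e6, 300)
  nf <- vapply(run_seeds, function(s1) {
    run <- gillespie_run(st, p, t_end = 2, save_times = c(0, 2),
                         seed = s1, track = TRUE)
    run$nflips[1]
  }, 0L)
  expect_equal(mean(nf), 2, tolerance = 0.15)
  expect_equal(var(nf), 2, tolerance = 0.35)
})

test_that("mesoscopic densities normalize and conserve mass", {
  p <- aplg_params(5, L = 2, phi_a = 0.4, phi_p = 0.2, h = 0.02)
  st <- initialize_lattice(p, nx = 100L, ny = 25L, seed = 6L)
  # fully occupied lattice -> density one everywhere
  stf <- st; stf$occ[,] <- 3L
  md <- mesoscopic_density(stf, r = 0.1)
  expect_equal(md$rho, rep(1, 100), tolerance = 1e-12)
  # homogeneous random state: mean matches fractions, integral is exact
  md2 <- mesoscopic_density(st, r = 0.1)
  expect_equal(mean(md2$rho_a), sum(st$counts[1:2]) / (100 * 25),
               tolerance = 1e-12)
  expect_equal(sum(md2$r0) * p$h, st$counts[["passive"]] / (100 * 25) * 2,
               tolerance = 1e-12)
  # smoothing radius below one site is rejected
  expect_error(mesoscopic_density(st, r = 0.005), "radius")
  # wider windows shrink fluctuations
  md3 <- mesoscopic_density(st, r = 0.3)
  expect_lt(stats::sd(md3$rho), stats::sd(md2$rho))
})

test_that("without activity the lattice relaxes toward uniformity", {
  # three-species symmetric exclusion: start fully segregated, the
  # time-averaged profile flattens
  p <- aplg_params(0, L = 1, phi_a = 0.3, phi_p = 0.2, h = 0.05)
  st <- initialize_lattice(p, nx = 20L, ny = 10L, seed = 8L)
  st$occ[,] <- 0L
  st$occ[1:6, ] <- 1L
  st$occ[7:10, ] <- 3L
  run <- gillespie_run(st, p, t_end = 2, save_times = seq(0, 2, by = 0.1),
                       seed = 9L)
  sd_profile <- function(i) stats::sd(mesoscopic_density(run, r = 0.1,
                                                         frame = i)$rho)
  expect_lt(mean(vapply(17:21, sd_profile, 0)), 0.5 * sd_profile(1))
})
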