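test_that("effective terms reduce to g0 in the bulk and kappa is positive", {
  et <- effective_terms(7.5, 0.5)
  r <- seq(0.05, 0.95, by = 0.05)
  expect_equal(et$g(r, 0, 0), et$g0(r))
  expect_true(all(et$kappa(seq(0.01, 0.99, by = 0.01)) > 0))
  # analytic g0 derivative agrees with numerical differentiation
  h <- 1e-6
  expect_equal(et$g0p(r), (et$g0(r + h) - et$g0(r - h)) / (2 * h),
               tolerance = 1e-7)
  expect_error(effective_terms(0, 0.5))
})

test_that("g is constant along an independently relaxed stationary profile", {
  # residual oracle for the symbolic elimination: relax the PDE to a
  # phase-separated steady state and evaluate g(rho, rho_x, rho_xx)
  st <- relaxed_ps_state()
  f <- st$field
  g2 <- pde_grid(2, dx = 0.0025)
  itp <- function(v) stats::approx(c(f$grid$x, f$grid$x[1] + 2), c(v, v[1]),
                                   xout = g2$x, rule = 2)$y
  ic <- density_field(itp(f$rp), itp(f$rm), itp(f$r0), g2)
  tr <- integrate_pde(ic, st$params, t_end = f$time + 60, dt_save = 30,
                      scheme = "centered")
  ff <- frame_field(tr)
  rho <- ff$rp + ff$rm + ff$r0
  m <- ff$rp - ff$rm
  N <- g2$N; dx <- g2$dx
  ip <- c(2:N, 1L); im <- c(N, 1:(N - 1L))
  rx <- (rho[ip] - rho[im]) / (2 * dx)
  rxx <- (rho[ip] - 2 * rho + rho[im]) / dx^2
  nu <- 0.1 / (1 - 0.6)
  et <- effective_terms(20, nu)
  gv <- et$g(rho, rx, rxx)
  expect_lt(stats::sd(gv) / abs(mean(gv)), 1e-3)
  # magnetization slaving m = rho_x / (Pe (1 - rho)) (vanishing flux)
  expect_lt(max(abs(m - rx / (20 * (1 - rho)))), 5e-3 * max(abs(m)))
  # passive/vacancy proportionality holds along the entire profile
  expect_lt(max(abs(ff$r0 - nu * (1 - rho))), 1e-6)
})

test_that("critical nu bounds coexistence and gives degenerate results", {
  cn <- critical_nu(7.5)
  expect_gt(cn$nu_star, 0)
  bn <- binodal_at_nu(7.5, cn$nu_star * 1.05)
  expect_true(bn$degenerate)
  expect_equal(bn$phi_v, bn$phi_l)
  bn2 <- binodal_at_nu(7.5, cn$nu_star * 0.98)
  expect_false(bn2$degenerate)
  expect_lt(bn2$phi_l - bn2$phi_v, 0.15)  # closing near the critical point
})

test_that("binodal satisfies both coexistence conditions", {
  for (case in list(c(7.5, 0.5), c(20, 0.25), c(5, 0.1))) {
    bn <- binodal_at_nu(case[1], case[2])
    et <- bn$terms
    expect_lt(abs(et$g0(bn$phi_l) - et$g0(bn$phi_v)), 1e-8)
    # equal-intercept condition: integral of (g0 - gbar) dR vanishes
    tb <- bn$tables
    fint <- function(r) (et$g0(r) - bn$gbar) * exp(tb$lnmu_f(r))
    val <- stats::integrate(fint, bn$phi_v, bn$rho_s[1])$value +
      stats::integrate(fint, bn$rho_s[1], bn$rho_s[2])$value +
      stats::integrate(fint, bn$rho_s[2], bn$phi_l,
                       rel.tol = 1e-10)$value
    scale <- abs(stats::integrate(function(r) abs(fint(r)),
                                  bn$phi_v, bn$phi_l,
                                  rel.tol = 1e-8)$value)
    expect_lt(abs(val) / scale, 1e-6)
    # endpoints satisfy rho_0 = nu (1 - rho) exactly by construction
    expect_equal(bn$endpoints$phi_p, case[2] * (1 - bn$endpoints$rho))
  }
})

test_that("long-time PDE plateaus match the predicted tie line", {
  st <- relaxed_ps_state()
  f <- st$field
  rho <- f$rp + f$rm + f$r0
  tl <- tie_line(0.5, 0.1, 20)
  expect_equal(tl$nu, 0.25)
  # finite-size corrections expected at L = 2: within 2%
  expect_lt(abs(min(rho) - tl$phi_v) / tl$phi_v, 0.02)
  expect_lt(abs(max(rho) - tl$phi_l) / tl$phi_l, 0.02)
  expect_gt(tl$liquid_fraction, 0)
  expect_lt(tl$liquid_fraction, 1)
})

test_that("tie line arithmetic and domain errors", {
  tl <- tie_line(0.55, 0.15, 7.5)
  expect_equal(tl$nu, 0.15 / 0.30, tolerance = 1e-12)
  # a dilute point is single phase
  expect_error(tie_line(0.05, 0.05, 7.5), "single phase")
  # the reference dynamical-region point lies outside the binodal: its
  # tie ratio (0.88235...) has coexistence, but the point itself sits
  # below the vapor branch
  expect_equal(0.3 / (1 - 0.66), 0.88235, tolerance = 1e-4)
  expect_error(tie_line(0.36, 0.3, 7.5), "single phase")
})

test_that("interface profile connects the bulks with a localized m bump", {
  ip <- interface_profile(7.5, 0.5, half_width = 12)
  bn <- ip$coexistence
  # far fields approach the coexistence densities
  expect_equal(ip$rho[1], bn$phi_v, tolerance = 1e-4)
  expect_equal(ip$rho[length(ip$rho)], bn$phi_l, tolerance = 1e-4)
  # monotone front
  expect_true(all(diff(ip$rho) >= -1e-12))
  # magnetization vanishes in both bulks, single interior extremum
  n <- length(ip$x)
  expect_lt(abs(ip$m[1]), 1e-6)
  expect_lt(abs(ip$m[n]), 1e-6)
  expect_gt(max(ip$m), 0.05)
  pk <- which(ip$m > 0.5 * max(ip$m))
  expect_true(all(diff(pk) == 1))  # one contiguous bump
  # tie-line law holds along the whole profile by construction
  expect_equal(ip$r0, 0.5 * (1 - ip$rho), tolerance = 1e-12)
})

test_that("binodal curve sweeps into the composition plane", {
  bc <- binodal_curve(5, n_nu = 10)
  expect_true(all(c("phi_a", "phi_p", "branch") %in% names(bc)))
  expect_gt(nrow(bc), 15)
  expect_true(all(bc$phi_a >= -1e-9 & bc$phi_p >= -1e-9))
  expect_true(all(abs(bc$phi_p - bc$nu * (1 - bc$rho)) < 1e-12))
})
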