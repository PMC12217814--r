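
test_that("the q = 0 spectrum is exactly {0, 0, -2}", {
  for (p in list(ps_point_params(), tw_point_params(),
                 aplg_params(3, phi_a = 0.2, phi_p = 0.5))) {
    ev <- sort(Re(eigen(stability_matrix(0, p), only.values = TRUE)$values))
    expect_equal(ev, c(-2, 0, 0), tolerance = 1e-14)
  }
})

test_that("stability matrix matches the PDE Jacobian oracle entry-wise", {
  set.seed(42)
  for (rep in 1:4) {
    Pe <- stats::runif(1, 1, 12)
    phi_a <- stats::runif(1, 0.05, 0.7)
    phi_p <- stats::runif(1, 0.05, 0.9 - phi_a)
    q <- sample(c(0.5, 1, 2), 1)
    p <- aplg_params(Pe, phi_a = phi_a, phi_p = phi_p)
    M <- stability_matrix(q, p)
    Mo <- oracle_matrix_rich(q, p)
    expect_lt(max(abs(M - Mo)), 1e-6)
  }
})

test_that("without activity the spectrum is real and nonpositive", {
  set.seed(7)
  for (rep in 1:20) {
    phi_a <- stats::runif(1, 0, 0.8)
    phi_p <- stats::runif(1, 0, 0.95 - phi_a)
    p <- aplg_params(0, phi_a = phi_a, phi_p = phi_p)
    ev <- eigen(stability_matrix(stats::runif(1, 0.1, 20), p),
                only.values = TRUE)$values
    expect_lt(max(abs(Im(ev))), 1e-10)
    expect_lt(max(Re(ev)), 1e-10)
  }
})

test_that("spectrum is conjugated under q -> -q", {
  p <- tw_point_params()
  for (q in c(0.3, 1.7, 5)) {
    ev1 <- sort(Re(eigen(stability_matrix(q, p), only.values = TRUE)$values))
    ev2 <- sort(Re(eigen(stability_matrix(-q, p), only.values = TRUE)$values))
    expect_equal(ev1, ev2, tolerance = 1e-12)
    im1 <- sort(Im(eigen(stability_matrix(q, p), only.values = TRUE)$values))
    im2 <- sort(-Im(eigen(stability_matrix(-q, p), only.values = TRUE)$values))
    expect_equal(im1, im2, tolerance = 1e-12)
  }
})

test_that("dispersion tracks branches and flags complex dominance", {
  dr <- dispersion(cp_point_params(), q_max = 8, nq = 120L)
  expect_s3_class(dr, "aplg_dispersion")
  expect_equal(dim(dr$lambda), c(120L, 3L))
  # the CP state point has an unstable complex-dominant band
  g <- Re(dr$lambda[cbind(seq_len(120), dr$dominant)])
  i <- which.max(g)
  expect_gt(g[i], 0)
  expect_true(dr$is_complex_dominant[i])
  # the PS state point is real-dominant at its fastest-growing mode
  dr2 <- dispersion(ps_point_params(), q_max = 8, nq = 120L)
  g2 <- Re(dr2$lambda[cbind(seq_len(120), dr2$dominant)])
  expect_gt(max(g2), 0)
  expect_false(dr2$is_complex_dominant[which.max(g2)])
})

test_that("growth rates of the hydrodynamic equations match the spectrum", {
  # linear-response: integrate a small single-mode perturbation and fit the
  # complex rate from the Fourier coefficient of the total density
  set.seed(12)
  for (rep in 1:3) {
    Pe <- stats::runif(1, 2, 12)
    phi_a <- stats::runif(1, 0.1, 0.6)
    phi_p <- stats::runif(1, 0.05, 0.85 - phi_a)
    p <- aplg_params(Pe, phi_a = phi_a, phi_p = phi_p)
    q <- 1
    ev <- eigen(stability_matrix(q, p))
    ord <- order(-Re(ev$values))
    lam <- ev$values[ord[1]]
    if (Re(lam) > 25) next  # avoid nonlinear saturation within the window
    v <- ev$vectors[, ord[1]]
    g <- pde_grid(2 * pi, N = 512L)
    amp <- 1e-6
    ph <- exp(1i * q * g$x)
    f0 <- density_field(p$phi_a / 2 + amp * Re(v[1] * ph),
                        p$phi_a / 2 + amp * Re(v[2] * ph),
                        p$phi_p + amp * Re(v[3] * ph), g)
    tr <- integrate_pde(f0, p, t_end = 0.04, save_times = c(0, 0.02, 0.04),
                        scheme = "centered")
    coef_at <- function(k) {
      fr <- c(tr$rp[k, ] %*% exp(-1i * q * g$x),
              tr$rm[k, ] %*% exp(-1i * q * g$x),
              tr$r0[k, ] %*% exp(-1i * q * g$x)) / length(g$x)
      fr[which.max(Mod(fr))]
    }
    lam_fit <- log(coef_at(3) / coef_at(2)) / 0.02
    expect_lt(abs(lam_fit - lam) / abs(lam), 1e-2)
  }
})

test_that("spinodal points sit on the neutral-stability locus", {
  sp <- spinodal(7.5, resolution = 10L)
  expect_gt(nrow(sp$curve), 5)
  for (i in seq_len(nrow(sp$curve))) {
    mg <- max_growth_rate(aplg_params(7.5, phi_a = sp$curve$phi_a[i],
                                      phi_p = sp$curve$phi_p[i]))
    expect_lt(abs(mg$growth), 1e-7)
  }
})

test_that("no spinodal exists at very low Pe", {
  sp <- spinodal(1.5, resolution = 8L)
  expect_equal(nrow(sp$curve), 0L)
})
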