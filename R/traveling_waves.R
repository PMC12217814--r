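# Newton infrastructure -------------------------------------------------

# Sparse finite-difference Jacobian by column coloring.  `groups` is a list
# of integer vectors of unknown indices that may be perturbed together;
# within a group, `rows_of(j)` must be disjoint across unknowns (rows that
# are dense in the unknowns -- e.g. mass constraints -- are supplied
# analytically via `extra_triplets`).
fd_jacobian_colored <- function(F, u, F0, groups, rows_of,
                                extra_triplets = NULL) {
  n <- length(u)
  ii <- list(); jj <- list(); xx <- list()
  for (grp in groups) {
    h <- 1e-7 * (1 + abs(u[grp]))
    up <- u
    up[grp] <- up[grp] + h
    F1 <- F(up)
    dF <- F1 - F0
    for (k in seq_along(grp)) {
      j <- grp[k]
      rows <- rows_of(j)
      m <- length(ii) + 1L
      ii[[m]] <- rows; jj[[m]] <- rep.int(j, length(rows))
      xx[[m]] <- dF[rows] / h[k]
    }
  }
  if (!is.null(extra_triplets)) {
    et <- extra_triplets(u)
    m <- length(ii) + 1L
    ii[[m]] <- et$i; jj[[m]] <- et$j; xx[[m]] <- et$x
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(length(F0), n))
}

# Valid distance-3 coloring of nodes 1..N on a periodic ring: residuals at a
# node couple to unknowns within one node; nodes three apart never share a
# residual row.  The ring closure breaks the mod-3 classes unless N is a
# multiple of 3, so trailing nodes become singleton groups.
ring_colors <- function(N) {
  k <- 3L * (N %/% 3L)
  base <- lapply(0:2, function(ph) which((seq_len(k) - 1L) %% 3L == ph))
  extra <- as.list(seq_len(N)[seq_len(N) > k])
  c(base, extra)
}

# Damped Newton iteration: backtracking Armijo line search on ||F||_2 with
# a Levenberg-Marquardt fallback when the full Newton direction stalls.
newton_solve <- function(F, u0, groups, rows_of, tol = 1e-10, maxit = 40L,
                         verbose = FALSE, extra_triplets = NULL) {
  u <- u0
  F0 <- F(u)
  nrm2 <- function(v) sqrt(sum(v^2))
  n0 <- nrm2(F0)
  try_step <- function(step) {
    t1 <- 1
    while (t1 >= 1 / 4096) {
      u1 <- u + t1 * step
      F1 <- tryCatch(F(u1), error = function(e) NULL)
      if (!is.null(F1) && all(is.finite(F1)) &&
          nrm2(F1) < (1 - 1e-4 * t1) * n0)
        return(list(u = u1, F = F1, t = t1))
      t1 <- t1 / 2
    }
    NULL
  }
  for (it in seq_len(maxit)) {
    if (max(abs(F0)) < tol)
      return(list(u = u, residual = max(abs(F0)), iterations = it - 1L,
                  converged = TRUE))
    J <- fd_jacobian_colored(F, u, F0, groups, rows_of, extra_triplets)
    step <- tryCatch(as.numeric(Matrix::solve(J, -F0)),
                     error = function(e) NULL)
    acc <- if (!is.null(step) && all(is.finite(step))) try_step(step)
    else NULL
    if (is.null(acc)) {
      # Levenberg-Marquardt fallback on the normal equations
      JtJ <- Matrix::crossprod(J)
      JtF <- as.numeric(Matrix::crossprod(J, F0))
      dg <- pmax(Matrix::diag(JtJ), 1e-12)
      lam <- 1e-4
      while (is.null(acc) && lam < 1e6) {
        stepl <- tryCatch(as.numeric(Matrix::solve(
          JtJ + lam * Matrix::Diagonal(x = dg), -JtF)),
          error = function(e) NULL)
        if (!is.null(stepl) && all(is.finite(stepl))) acc <- try_step(stepl)
        lam <- lam * 10
      }
      if (is.null(acc))
        return(list(u = u, residual = max(abs(F0)), iterations = it,
                    converged = FALSE, reason = "stalled"))
    }
    u <- acc$u; F0 <- acc$F; n0 <- nrm2(F0)
    if (verbose) message("  newton it ", it, ": |F|_2 = ", signif(n0, 4),
                         " sup = ", signif(max(abs(F0)), 4),
                         " (t = ", acc$t, ")")
  }
  list(u = u, residual = max(abs(F0)), iterations = maxit,
       converged = max(abs(F0)) < tol)
}

# Traveling-wave solutions ----------------------------------------------

#' Traveling profiles at finite system size
#'
#' Solves the co-moving form of the hydrodynamic equations,
#' `-(c/L) drho_sigma/dz = (flux divergence) - sigma m`, on a periodic
#' z-grid with second-order centered differences.  Unknowns are the three
#' profiles and the speed `c`; constraints are the species means
#' (`mean(rho_a) = phi_a`, `mean(rho_0) = phi_p`; the left/right split
#' `int m = 0` follows automatically from the stationarity equations) and
#' the translational gauge `rho(z_1) = phi`.  Solved by damped Newton with
#' a sparse colored finite-difference Jacobian.
#'
#' @param params `aplg_params`.
#' @param N number of grid points.
#' @param init initial guess: a list with `rp`, `rm`, `r0`, `c` (e.g. from a
#'   relaxed [integrate_pde()] attractor and [measure_speed()]), or an
#'   `aplg_trajectory` whose final frame is used.
#' @param tol Newton residual tolerance (sup norm).
#' @param maxit maximum Newton iterations.
#' @param gauge_roll roll the initial guess so the gauge node sits at a
#'   crossing of the mean density (default `TRUE`).
#' @return object of class `aplg_wave`: `z`, profiles `rp`, `rm`, `r0`,
#'   `rho`, `m`, speed `c`, `residual`, `converged`, `regime = "finite-L"`.
#' @export
solve_finite_L <- function(params, N = 1600L, init, tol = 1e-10,
                           maxit = 40L, gauge_roll = TRUE) {
  L <- params$L
  Pe <- params$Pe
  cf <- params$coeffs
  if (inherits(init, "aplg_trajectory")) {
    f <- frame_field(init)
    sp <- measure_speed(init)
    init <- list(rp = f$rp, rm = f$rm, r0 = f$r0, c = sp$c)
  }
  ngrid <- length(init$rp)
  if (ngrid != N) { # resample
    xs <- seq(0, 1, length.out = ngrid + 1L)[-(ngrid + 1L)]
    xt <- seq(0, 1, length.out = N + 1L)[-(N + 1L)]
    rs <- function(v) stats::approx(c(xs, 1), c(v, v[1]), xout = xt)$y
    init <- list(rp = rs(init$rp), rm = rs(init$rm), r0 = rs(init$r0),
                 c = init$c)
  }
  phi <- params$phi
  if (gauge_roll) {
    rho <- init$rp + init$rm + init$r0
    dif <- rho - phi
    crossings <- which(dif * dif[c(2:N, 1)] < 0)
    if (length(crossings) > 0) {
      slopes <- abs(dif[c(2:N, 1)][crossings] - dif[crossings])
      j <- crossings[which.max(slopes)]
      roll <- function(v) v[((seq_len(N) + j - 2L) %% N) + 1L]
      init <- list(rp = roll(init$rp), rm = roll(init$rm),
                   r0 = roll(init$r0), c = init$c)
    }
  }
  dz <- L / N
  ipp <- c(2:N, 1L); imm <- c(N, 1:(N - 1L))
  res_F <- function(u) {
    rp <- u[1:N]; rm <- u[N + 1:N]; r0 <- u[2 * N + 1:N]; cc <- u[3 * N + 1]
    rho <- rp + rm + r0
    m <- rp - rm
    rf <- 0.5 * (rho + rho[ipp]); mf <- 0.5 * (m + m[ipp])
    dsf <- cf$ds(pmin(pmax(rf, 0), 1)); Df <- cf$D(rf); sf <- Df - 1
    drho <- (rho[ipp] - rho) / dz
    Gs <- function(us, sg) {
      uf <- 0.5 * (us + us[ipp])
      -dsf * (us[ipp] - us) / dz - uf * Df * drho +
        Pe * (uf * sf * mf + sg * dsf * uf) - (cc / L) * uf
    }
    Gp <- Gs(rp, 1); Gm <- Gs(rm, -1); G0 <- Gs(r0, 0)
    resp <- (Gp - Gp[imm]) / dz + m
    resm <- (Gm - Gm[imm]) / dz - m
    res0 <- (G0 - G0[imm]) / dz
    c(resp[-1], resm, res0[-1],
      mean(rp + rm) - params$phi_a,
      mean(r0) - params$phi_p,
      rp[1] + rm[1] + r0[1] - phi)
  }
  # unknown layout and coloring; constraint rows (means + gauge) are dense
  # in the node unknowns and handled analytically
  nun <- 3L * N + 1L
  nres <- nun
  node_groups <- ring_colors(N)
  groups <- c(unlist(lapply(0:2, function(s)
    lapply(node_groups, function(g) s * N + g)), recursive = FALSE),
    list(nun))
  rows_node <- function(j) {
    nb <- unique(((j - 1L + c(-1L, 0L, 1L)) %% N) + 1L)
    rp_rows <- nb[nb >= 2L] - 1L          # res_p block: nodes 2..N
    rm_rows <- (N - 1L) + nb              # res_m block: all nodes
    r0_rows <- (2L * N - 1L) + (nb[nb >= 2L] - 1L)
    c(rp_rows, rm_rows, r0_rows)
  }
  rows_of <- function(j) {
    if (j > 3L * N) return(seq_len(nres))   # c column: singleton group
    rows_node(((j - 1L) %% N) + 1L)
  }
  extra_triplets <- function(u) {
    list(i = c(rep.int(nres - 2L, 2L * N), rep.int(nres - 1L, N),
               rep.int(nres, 3L)),
         j = c(1:(2L * N), 2L * N + 1:N, 1L, N + 1L, 2L * N + 1L),
         x = c(rep(1 / N, 3L * N), rep(1, 3L)))
  }
  u0 <- c(init$rp, init$rm, init$r0, init$c)
  sol <- newton_solve(res_F, u0, groups, rows_of, tol = tol, maxit = maxit,
                      extra_triplets = extra_triplets)
  z <- (seq_len(N) - 1L) * dz
  rp <- sol$u[1:N]; rm <- sol$u[N + 1:N]; r0 <- sol$u[2 * N + 1:N]
  structure(list(z = z, rp = rp, rm = rm, r0 = r0,
                 rho = rp + rm + r0, m = rp - rm, rho_a = rp + rm,
                 c = sol$u[3 * N + 1], residual = sol$residual,
                 converged = sol$converged, iterations = sol$iterations,
                 regime = "finite-L", params = params, N = N),
            class = "aplg_wave")
}

#' @export
print.aplg_wave <- function(x, ...) {
  cat("APLG traveling solution (", x$regime, "): c =", signif(x$c, 6),
      " residual =", signif(x$residual, 3),
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$nu)) cat("  interface tie line nu =", signif(x$nu, 6), "\n")
  invisible(x)
}

#' @export
plot.aplg_wave <- function(x, ...) {
  graphics::matplot(x$z, cbind(x$rho, x$rho_a, x$r0, x$m), type = "l",
                    lty = 1, xlab = "z", ylab = "density",
                    col = c("black", "red", "blue", "gray"), ...)
  graphics::legend("topleft", c("rho", "rho_a", "rho_0", "m"),
                   col = c("black", "red", "blue", "gray"), lty = 1,
                   bty = "n")
  invisible(x)
}

# Outer (large-L) problem ------------------------------------------------

#' Linear stability of the outer (large-L) equations
#'
#' The reduced two-species system (magnetization eliminated) has plane-wave
#' growth rates `lambda = -qbar^2 * mu` with `mu` an eigenvalue of the 2x2
#' effective cross-diffusion matrix `B` evaluated at the homogeneous state;
#' `Re mu < 0` for either eigenvalue means instability at all wavenumbers
#' (the reduced system is scale free), and a complex pair at onset produces
#' smooth traveling waves with near-onset speed `c ~ -qbar * Im(mu)`.
#'
#' @param phi_a,phi_p,Pe state point.
#' @param coeffs coefficient set.
#' @return list with the matrix `B`, its eigenvalues `mu`, `unstable`
#'   (TRUE if some `Re mu < 0`), `complex_pair`, and `c_onset` (the speed
#'   scale `2*pi*|Im mu|` of the gravest periodic mode).
#' @export
outer_stability <- function(phi_a, phi_p, Pe, coeffs = aplg_coeffs()) {
  cf <- coeffs
  phi <- phi_a + phi_p
  ds <- cf$ds(phi); ds1 <- cf$ds1(phi)
  D <- cf$D(phi); s <- D - 1
  w1 <- ds + ds1 * phi_a   # d(ds(rho) rho_a)/d rho_a at fixed rho_0 ... split:
  # d(ds*ra) = ds * d(ra) + ds' * ra * d(rho); d(rho) = d(ra) + d(r0)
  Aa <- phi_a * s + ds
  B <- matrix(c(
    ds + phi_a * D + (Pe^2 / 2) * Aa * (ds + ds1 * phi_a),
    phi_a * D + (Pe^2 / 2) * Aa * (ds1 * phi_a),
    phi_p * D + (Pe^2 / 2) * phi_p * s * (ds + ds1 * phi_a),
    ds + phi_p * D + (Pe^2 / 2) * phi_p * s * (ds1 * phi_a)),
    2, 2, byrow = TRUE)
  mu <- eigen(B, only.values = TRUE)$values
  list(B = B, mu = mu, unstable = any(Re(mu) < 0),
       complex_pair = is.complex(mu) && abs(Im(mu[1])) > 1e-12,
       c_onset = 2 * pi * max(abs(Im(mu))))
}

# residual builder for the outer equations on a uniform grid segment.
# State: rho_a, rho_0 at nodes; returns face fluxes H_a, H_0 at interior
# faces (between consecutive nodes), unit segment coordinates scaled by len.
outer_face_flux <- function(ra, r0, cc, cf, Pe, dz) {
  n <- length(ra)
  i1 <- 1:(n - 1L); i2 <- 2:n
  rho <- ra + r0
  w <- cf$ds(pmin(pmax(rho, 0), 1)) * ra       # d_s(rho) * rho_a
  rf <- 0.5 * (rho[i1] + rho[i2])
  raf <- 0.5 * (ra[i1] + ra[i2]); r0f <- 0.5 * (r0[i1] + r0[i2])
  dsf <- cf$ds(pmin(pmax(rf, 0), 1)); Df <- cf$D(rf); sf <- Df - 1
  drho <- (rho[i2] - rho[i1]) / dz
  dw <- (w[i2] - w[i1]) / dz
  Ha <- -dsf * (ra[i2] - ra[i1]) / dz - raf * Df * drho -
    (Pe^2 / 2) * (raf * sf + dsf) * dw - cc * raf
  H0 <- -dsf * (r0[i2] - r0[i1]) / dz - r0f * Df * drho -
    (Pe^2 / 2) * (r0f * sf) * dw - cc * r0f
  list(Ha = Ha, H0 = H0)
}

#' Time-step the outer (large-L) dynamics
#'
#' Explicit integration of the reduced two-species cross-diffusion system
#' obtained in the large-size limit after eliminating the magnetization
#' (the dynamic counterpart of the outer traveling-wave equations), on the
#' unit periodic domain.  Used to generate attractors that seed the Newton
#' solvers.
#'
#' @param ra0,r00 initial active/passive densities (periodic nodes).
#' @param phi_a,phi_p,Pe parameters.
#' @param t_end final (outer) time.
#' @param coeffs coefficient set.
#' @param cfl time-step safety factor.
#' @param dt_save sampling interval.
#' @return list with `times`, matrices `ra`, `r0` (rows = frames).
#' @export
outer_time_step <- function(ra0, r00, phi_a, phi_p, Pe, t_end,
                            coeffs = aplg_coeffs(), cfl = 0.25,
                            dt_save = NULL) {
  N <- length(ra0)
  dz <- 1 / N
  cf <- coeffs
  if (is.null(dt_save)) dt_save <- t_end / 100
  save_times <- seq(0, t_end, by = dt_save)
  ra <- ra0; r0 <- r00
  # effective diffusivity bound for dt: d_s + rho D + Pe^2/2 * (...) * d(ds*ra)/dra
  dmax <- 1 + (Pe^2 / 2) * 1.2
  dt <- cfl * dz^2 / (2 * dmax)
  out_ra <- matrix(0, length(save_times), N)
  out_r0 <- matrix(0, length(save_times), N)
  t <- 0; k <- 1L
  out_ra[1, ] <- ra; out_r0[1, ] <- r0
  k <- 2L
  ip <- c(2:N, 1L)
  while (k <= length(save_times)) {
    fl <- outer_face_flux(c(ra, ra[1]), c(r0, r0[1]), 0, cf, Pe, dz)
    dra <- -(fl$Ha - fl$Ha[c(N, 1:(N - 1L))]) / dz
    dr0 <- -(fl$H0 - fl$H0[c(N, 1:(N - 1L))]) / dz
    step <- min(dt, save_times[k] - t)
    ra <- ra + step * dra
    r0 <- r0 + step * dr0
    if (any(!is.finite(ra)) || any(ra < -1e-8) || any(ra + r0 > 1 + 1e-8))
      stop("outer time-stepping became invalid at t = ", t)
    t <- t + step
    if (t >= save_times[k] - 1e-12) {
      out_ra[k, ] <- ra; out_r0[k, ] <- r0; k <- k + 1L
    }
  }
  list(times = save_times, ra = out_ra, r0 = out_r0)
}

#' Traveling solutions of the outer (large-L) problem
#'
#' Solves the matched-asymptotics outer equations for `(rho_a, rho_0, c)`
#' with second-order centered differences at the requested regime:
#' \describe{
#' \item{smooth}{no inner region (the tie-line ratio is above critical):
#'   periodic boundary conditions on the unit domain, species-mean
#'   constraints, translational gauge.}
#' \item{interface}{one sharp interface placed at the domain boundary:
#'   Dirichlet values are the vapor (left) and liquid (right) tie-line
#'   endpoints of the binodal at the interface ratio `nu`, which is itself a
#'   Newton unknown (initialized from `phi_p/(1-phi)`); the species means
#'   select the tie line.}
#' }
#' @param phi_a,phi_p,Pe state point.
#' @param N grid intervals.
#' @param init initial guess: list with `ra`, `r0` (node values), `c`, and
#'   optionally `nu`.
#' @param regime `"auto"`, `"smooth"` or `"interface"`.
#' @param coeffs coefficient set.
#' @param tol,maxit Newton controls.
#' @param fallback on single-interface failure, insert a second interface
#'   at the steepest interior gradient of the seed and retry with the
#'   two-interface solver (default `TRUE`).
#' @return an `aplg_wave` with `regime` `"outer-smooth"`,
#'   `"outer-interface"` or `"outer-2-interface"`; profiles are on `z` in
#'   `[0, 1]` (fraction of the domain), `c` is the O(1) wave speed.
#' @export
solve_outer <- function(phi_a, phi_p, Pe, N = 1024L, init = NULL,
                        regime = c("auto", "smooth", "interface"),
                        coeffs = aplg_coeffs(), tol = 1e-10, maxit = 60L,
                        fallback = TRUE) {
  regime <- match.arg(regime)
  phi <- phi_a + phi_p
  nu5 <- phi_p / (1 - phi)
  cn <- critical_nu(Pe, coeffs)
  if (regime == "auto")
    regime <- if (nu5 >= cn$nu_star) "smooth" else "interface"
  if (regime == "smooth")
    return(solve_outer_smooth(phi_a, phi_p, Pe, N, init, coeffs, tol,
                              maxit))
  w <- solve_outer_interface(phi_a, phi_p, Pe, N, init, coeffs, tol, maxit)
  if (!w$converged && fallback && !is.null(init$ra)) {
    # single-interface failure can signal a second interface: split the
    # seed at its steepest interior gradient and retry
    n <- length(init$ra)
    zz <- seq(0, 1, length.out = n)
    sol0 <- structure(list(z = zz, rho = init$ra + init$r0, c = init$c,
                           nu = init$nu), class = "aplg_wave")
    ii <- tryCatch(insert_interface(sol0), error = function(e) NULL)
    if (!is.null(ii) && ii$index > 4 && ii$index < n - 4) {
      i0 <- ii$index
      nu2_guess <- min(init$r0[i0] / max(1e-6, 1 - init$ra[i0] - init$r0[i0]),
                       cn$nu_star - 5e-3)
      init2 <- list(raA = init$ra[1:i0], r0A = init$r0[1:i0],
                    raB = init$ra[i0:n], r0B = init$r0[i0:n],
                    c = init$c, zstar = zz[i0], nu2 = nu2_guess,
                    nu1 = init$nu)
      w2 <- tryCatch(solve_outer_two_interface(phi_a, phi_p, Pe, N, init2,
                                               coeffs, tol, maxit),
                     error = function(e) NULL)
      if (!is.null(w2) && w2$converged) return(w2)
    }
  }
  w
}

solve_outer_smooth <- function(phi_a, phi_p, Pe, N, init, coeffs, tol,
                               maxit) {
  cf <- coeffs
  phi <- phi_a + phi_p
  dz <- 1 / N
  if (is.null(init)) stop("an initial guess is required (e.g. from outer_time_step)")
  ra0 <- init$ra; r00 <- init$r0
  if (length(ra0) != N) {
    xs <- seq(0, 1, length.out = length(ra0) + 1L)[-(length(ra0) + 1L)]
    xt <- seq(0, 1, length.out = N + 1L)[-(N + 1L)]
    rs <- function(v) stats::approx(c(xs, 1), c(v, v[1]), xout = xt)$y
    ra0 <- rs(ra0); r00 <- rs(r00)
  }
  # roll gauge node onto a mean-density crossing
  rho <- ra0 + r00
  dif <- rho - phi
  cross <- which(dif * dif[c(2:N, 1)] < 0)
  if (length(cross) > 0) {
    slopes <- abs(dif[c(2:N, 1)][cross] - dif[cross])
    j <- cross[which.max(slopes)]
    roll <- function(v) v[((seq_len(N) + j - 2L) %% N) + 1L]
    ra0 <- roll(ra0); r00 <- roll(r00)
  }
  ipp <- c(2:N, 1L); imm <- c(N, 1:(N - 1L))
  res_F <- function(u) {
    ra <- u[1:N]; r0 <- u[N + 1:N]; cc <- u[2 * N + 1]
    fl <- outer_face_flux(c(ra, ra[1]), c(r0, r0[1]), cc, cf, Pe, dz)
    resa <- (fl$Ha - fl$Ha[imm]) / dz
    res0 <- (fl$H0 - fl$H0[imm]) / dz
    c(resa[-1], res0[-1],
      mean(ra) - phi_a, mean(r0) - phi_p,
      ra[1] + r0[1] - phi)
  }
  nun <- 2L * N + 1L
  node_groups <- ring_colors(N)
  groups <- c(unlist(lapply(0:1, function(s)
    lapply(node_groups, function(g) s * N + g)), recursive = FALSE),
    list(nun))
  rows_of <- function(j) {
    if (j > 2L * N) return(seq_len(nun))
    node <- ((j - 1L) %% N) + 1L
    nb <- unique(((node - 1L + c(-1L, 0L, 1L)) %% N) + 1L)
    ra_rows <- nb[nb >= 2L] - 1L
    r0_rows <- (N - 1L) + (nb[nb >= 2L] - 1L)
    c(ra_rows, r0_rows)
  }
  extra_triplets <- function(u) {
    list(i = c(rep.int(nun - 2L, N), rep.int(nun - 1L, N), rep.int(nun, 2L)),
         j = c(1:N, N + 1:N, 1L, N + 1L),
         x = c(rep(1 / N, 2L * N), 1, 1))
  }
  sol <- newton_solve(res_F, c(ra0, r00, init$c), groups, rows_of,
                      tol = tol, maxit = maxit,
                      extra_triplets = extra_triplets)
  ra <- sol$u[1:N]; r0 <- sol$u[N + 1:N]
  structure(list(z = (seq_len(N) - 1L) * dz, rp = NULL, rm = NULL,
                 r0 = r0, rho_a = ra, rho = ra + r0,
                 m = NULL, c = sol$u[2 * N + 1], nu = NULL,
                 residual = sol$residual, converged = sol$converged,
                 iterations = sol$iterations, regime = "outer-smooth",
                 Pe = Pe, phi_a = phi_a, phi_p = phi_p, N = N),
            class = "aplg_wave")
}

#' Outer-problem initial guess from a finite-size traveling solution
#'
#' Rolls a converged finite-L profile so its sharp interface sits at the
#' domain boundary, excises the inner region (a few interface widths), and
#' stretches the remaining smooth outer part onto the unit interval with
#' the tie-line endpoint values at the ends.  Orientation is chosen with the
#' vapor endpoint at `z = 0` (profiles are mirrored if needed; mirroring
#' flips the sign of the speed).
#'
#' @param wave an `aplg_wave` from [solve_finite_L()] (or any list with
#'   periodic `rho_a`, `r0`, `c`).
#' @param Pe,nu interface parameters (defaults: the wave's `Pe` and the
#'   tie-line ratio of its mean composition).
#' @param coeffs coefficient set.
#' @return list with `ra`, `r0` (node values on `[0, 1]`), `c`, `nu`.
#' @export
outer_seed_from_wave <- function(wave, Pe = NULL, nu = NULL,
                                 coeffs = aplg_coeffs()) {
  if (is.null(Pe)) Pe <- wave$params$Pe
  if (is.null(nu)) {
    phi_a <- mean(wave$rho_a); phi_p <- mean(wave$r0)
    nu <- phi_p / (1 - phi_a - phi_p)
  }
  bn <- binodal_at_nu(Pe, nu, coeffs)
  rho <- wave$rho_a + wave$r0
  N <- length(rho)
  # the interface center is the steepest jump of the total density
  j <- which.max(abs(rho[c(2:N, 1)] - rho))
  roll <- function(v) v[((seq_len(N) + j - 1L) %% N) + 1L]
  ra <- roll(wave$rho_a); r0 <- roll(wave$r0)
  # node 1 is now just past the interface (liquid side), node N approaches
  # it from the vapor side; excise ~3 interface widths on each side
  ipf <- interface_profile(Pe, nu, half_width = 15, coeffs = coeffs)
  rr <- range(ipf$x[ipf$rho > bn$phi_v + 0.1 * (bn$phi_l - bn$phi_v) &
                    ipf$rho < bn$phi_l - 0.1 * (bn$phi_l - bn$phi_v)])
  w_int <- diff(rr)
  dz_wave <- if (!is.null(wave$params)) wave$params$L / N else 1 / N
  nex <- min(N %/% 4L, as.integer(ceiling(1.5 * w_int / dz_wave)))
  keep <- (nex + 1L):(N - nex)
  ra <- ra[keep]; r0 <- r0[keep]
  # orientation: vapor end at z = 0
  flip <- (ra[1] + r0[1]) > (ra[length(ra)] + r0[length(r0)])
  if (flip) { ra <- rev(ra); r0 <- rev(r0) }
  xs <- seq(0, 1, length.out = length(ra))
  nu_eff <- nu
  ra_v <- bn$phi_v - nu_eff * (1 - bn$phi_v)
  r0_v <- nu_eff * (1 - bn$phi_v)
  ra_l <- bn$phi_l - nu_eff * (1 - bn$phi_l)
  r0_l <- nu_eff * (1 - bn$phi_l)
  ra <- c(ra_v, ra[-c(1, length(ra))], ra_l)
  r0 <- c(r0_v, r0[-c(1, length(r0))], r0_l)
  xs <- seq(0, 1, length.out = length(ra))
  cc <- wave$c * (if (flip) -1 else 1)
  list(ra = ra, r0 = r0, c = cc, nu = nu, x = xs)
}

# Single-interface outer solve at FIXED tie-line ratio nu: box scheme with
# flux constants as unknowns, active-mass constraint imposed; returns the
# solution plus the passive-mass defect, which an outer root find over nu
# drives to zero.
outer_iface_fixednu <- function(phi_a, phi_p, Pe, N, init, nu, coeffs, tol,
                                maxit) {
  cf <- coeffs
  dz <- 1 / N
  ni <- N - 1L
  bn <- binodal_at_nu(Pe, nu, coeffs)
  if (bn$degenerate) stop("degenerate coexistence at nu = ", nu)
  ep <- c(bn$phi_v - nu * (1 - bn$phi_v), nu * (1 - bn$phi_v),
          bn$phi_l - nu * (1 - bn$phi_l), nu * (1 - bn$phi_l))
  ra0 <- init$ra; r00 <- init$r0
  if (length(ra0) != N + 1L) {
    xs <- seq(0, 1, length.out = length(ra0))
    xt <- seq(0, 1, length.out = N + 1L)
    ra0 <- stats::approx(xs, ra0, xt)$y
    r00 <- stats::approx(xs, r00, xt)$y
  }
  ra0[1] <- ep[1]; r00[1] <- ep[2]
  ra0[N + 1L] <- ep[3]; r00[N + 1L] <- ep[4]
  nun <- 2L * ni + 3L          # interior values, c, Ka, K0
  iK <- 2L * ni + 2L:3L
  trap <- function(v) dz * (sum(v) - 0.5 * v[1] - 0.5 * v[N + 1L])
  res_F <- function(u) {
    ra <- c(ep[1], u[1:ni], ep[3])
    r0 <- c(ep[2], u[ni + 1:ni], ep[4])
    fl <- outer_face_flux(ra, r0, u[2 * ni + 1], cf, Pe, dz)
    c(fl$Ha + u[iK[1]], fl$H0 + u[iK[2]], (trap(ra) - phi_a) / dz)
  }
  path_groups <- lapply(0:2, function(ph)
    which((seq_len(ni) - 1L) %% 3L == ph))
  groups <- c(unlist(lapply(0:1, function(s)
    lapply(path_groups, function(g) s * ni + g)), recursive = FALSE),
    list(2L * ni + 1L))
  nres <- 2L * N + 1L
  rows_of <- function(j) {
    if (j > 2L * ni) return(seq_len(nres))   # c column
    node <- ((j - 1L) %% ni) + 1L
    c(node, node + 1L, N + node, N + node + 1L)
  }
  extra_triplets <- function(u) {
    list(i = c(seq_len(N), N + seq_len(N), rep.int(2L * N + 1L, ni)),
         j = c(rep.int(iK[1], N), rep.int(iK[2], N), 1:ni),
         x = c(rep(1, 2L * N), rep(1, ni)))
  }
  fl0 <- outer_face_flux(ra0, r00, init$c, cf, Pe, dz)
  u0 <- c(ra0[2:N], r00[2:N], init$c,
          -stats::median(fl0$Ha), -stats::median(fl0$H0))
  sol <- newton_solve(res_F, u0, groups, rows_of, tol = tol, maxit = maxit,
                      extra_triplets = extra_triplets)
  ra <- c(ep[1], sol$u[1:ni], ep[3])
  r0 <- c(ep[2], sol$u[ni + 1:ni], ep[4])
  list(ra = ra, r0 = r0, c = sol$u[2 * ni + 1], K = sol$u[iK],
       residual = sol$residual, converged = sol$converged,
       iterations = sol$iterations,
       mass_p_defect = trap(r0) - phi_p)
}
solve_outer_interface <- function(phi_a, phi_p, Pe, N, init, coeffs, tol,
                                  maxit) {
  phi <- phi_a + phi_p
  if (is.null(init)) stop("an initial guess is required")
  nu0 <- if (!is.null(init$nu)) init$nu else phi_p / (1 - phi)
  nu_max <- critical_nu(Pe, coeffs)$nu_star - 1e-4
  # The interface tie-line ratio nu is selected by the passive mass: solve
  # the square fixed-nu problem (active mass imposed) and drive the passive
  # mass defect to zero by a guarded secant iteration over nu.
  cur <- init
  solve_at <- function(nu) {
    out <- outer_iface_fixednu(phi_a, phi_p, Pe, N, cur, nu, coeffs,
                               tol, maxit)
    if (out$converged) cur <<- list(ra = out$ra, r0 = out$r0, c = out$c)
    out
  }
  nu1 <- min(max(nu0, 1e-4), nu_max)
  s1 <- solve_at(nu1)
  if (!s1$converged)
    return(structure(list(z = seq(0, 1, length.out = N + 1L),
                          rho_a = s1$ra, r0 = s1$r0, rho = s1$ra + s1$r0,
                          c = s1$c, nu = nu1, residual = s1$residual,
                          converged = FALSE, regime = "outer-interface",
                          Pe = Pe, phi_a = phi_a, phi_p = phi_p, N = N),
                     class = "aplg_wave"))
  d1 <- s1$mass_p_defect
  step <- -sign(d1) * max(0.02, abs(nu1) * 0.03)
  nu2 <- min(max(nu1 + step, 1e-4), nu_max)
  s2 <- solve_at(nu2)
  d2 <- s2$mass_p_defect
  for (it in 1:30) {
    if (abs(d2) < 1e-10 || abs(nu2 - nu1) < 1e-12) break
    if (!s2$converged) { # shrink toward nu1
      nu2 <- (nu1 + nu2) / 2
      s2 <- solve_at(nu2); d2 <- s2$mass_p_defect
      next
    }
    dn <- if (abs(d2 - d1) > 1e-14) -d2 * (nu2 - nu1) / (d2 - d1) else 0
    dn <- sign(dn) * min(abs(dn), 0.1)
    nu1 <- nu2; d1 <- d2
    nu2 <- min(max(nu2 + dn, 1e-4), nu_max)
    s2 <- solve_at(nu2); d2 <- s2$mass_p_defect
  }
  structure(list(z = seq(0, 1, length.out = N + 1L),
                 rp = NULL, rm = NULL, r0 = s2$r0, rho_a = s2$ra,
                 rho = s2$ra + s2$r0, m = NULL, c = s2$c, nu = nu2,
                 K = s2$K, mass_p_defect = s2$mass_p_defect,
                 residual = s2$residual,
                 converged = s2$converged && abs(s2$mass_p_defect) < 1e-8,
                 iterations = s2$iterations, regime = "outer-interface",
                 Pe = Pe, phi_a = phi_a, phi_p = phi_p, N = N),
            class = "aplg_wave")
}

# Two-interface outer solve at fixed primary tie ratio nu1.  The domain
# splits into two smooth pieces: A on [0, z*] from the vapor endpoint of
# nu1 up to the vapor endpoint of a second tie line nu2, and B on [z*, 1]
# from liquid(nu2) to liquid(nu1).  The integration constants (K_a, K_0)
# are global (flux continuity through the quasi-static inner regions), and
# (z*, nu2) are unknowns pinned by the four interior Dirichlet values.
outer_two_iface_fixednu <- function(phi_a, phi_p, Pe, NA_, NB_, init, nu1,
                                    coeffs, tol, maxit) {
  cf <- coeffs
  bn1 <- binodal_at_nu(Pe, nu1, coeffs)
  if (bn1$degenerate) stop("degenerate coexistence at nu1")
  ep1 <- c(bn1$phi_v - nu1 * (1 - bn1$phi_v), nu1 * (1 - bn1$phi_v),
           bn1$phi_l - nu1 * (1 - bn1$phi_l), nu1 * (1 - bn1$phi_l))
  ep_cache <- new.env()
  endpoints2 <- function(nu2) {
    key2 <- sprintf("%.13e", nu2)
    if (!is.null(ep_cache[[key2]])) return(ep_cache[[key2]])
    bn2 <- binodal_at_nu(Pe, nu2, coeffs)
    v <- c(bn2$phi_v - nu2 * (1 - bn2$phi_v), nu2 * (1 - bn2$phi_v),
           bn2$phi_l - nu2 * (1 - bn2$phi_l), nu2 * (1 - bn2$phi_l))
    ep_cache[[key2]] <- v
    v
  }
  nu_max <- critical_nu(Pe, coeffs)$nu_star - 1e-4
  niA <- NA_ - 1L; niB <- NB_ - 1L
  # unknown layout: A interior (2 niA), B interior (2 niB), c, Ka, K0,
  # zstar, nu2
  iC <- 2L * (niA + niB) + 1L
  iK <- iC + 1:2
  iZ <- iC + 3L
  iN2 <- iC + 4L
  nun <- iN2
  res_F <- function(u) {
    zs <- u[iZ]; nu2 <- u[iN2]
    if (zs < 0.02 || zs > 0.98 || nu2 < 1e-4 || nu2 > nu_max)
      stop("parameter out of range")
    ep2 <- endpoints2(nu2)
    raA <- c(ep1[1], u[1:niA], ep2[1])
    r0A <- c(ep1[2], u[niA + 1:niA], ep2[2])
    raB <- c(ep2[3], u[2 * niA + 1:niB], ep1[3])
    r0B <- c(ep2[4], u[2 * niA + niB + 1:niB], ep1[4])
    dzA <- zs / NA_; dzB <- (1 - zs) / NB_
    flA <- outer_face_flux(raA, r0A, u[iC], cf, Pe, dzA)
    flB <- outer_face_flux(raB, r0B, u[iC], cf, Pe, dzB)
    trapA <- function(v) dzA * (sum(v) - 0.5 * v[1] - 0.5 * v[NA_ + 1L])
    trapB <- function(v) dzB * (sum(v) - 0.5 * v[1] - 0.5 * v[NB_ + 1L])
    c(flA$Ha + u[iK[1]], flA$H0 + u[iK[2]],
      flB$Ha + u[iK[1]], flB$H0 + u[iK[2]],
      (trapA(raA) + trapB(raB) - phi_a) * NA_)
  }
  nres <- 2L * (NA_ + NB_) + 1L
  path_g <- function(ni) lapply(0:2, function(ph)
    which((seq_len(ni) - 1L) %% 3L == ph))
  groups <- c(
    lapply(path_g(niA), function(g) g),
    lapply(path_g(niA), function(g) niA + g),
    lapply(path_g(niB), function(g) 2L * niA + g),
    lapply(path_g(niB), function(g) 2L * niA + niB + g),
    as.list(c(iC, iZ, iN2)))
  rows_of <- function(j) {
    if (j >= iC) return(seq_len(nres))
    if (j <= 2L * niA) {
      node <- ((j - 1L) %% niA) + 1L
      c(node, node + 1L, NA_ + node, NA_ + node + 1L)
    } else {
      node <- ((j - 2L * niA - 1L) %% niB) + 1L
      off <- 2L * NA_
      c(off + node, off + node + 1L, off + NB_ + node, off + NB_ + node + 1L)
    }
  }
  # mass row: trapezoid weights over both pieces (entered analytically),
  # K columns are unit entries on their face blocks
  et2 <- function(u) {
    zs <- u[iZ]
    dzA <- zs / NA_; dzB <- (1 - zs) / NB_
    list(i = c(seq_len(NA_), NA_ + seq_len(NA_),
               2L * NA_ + seq_len(NB_), 2L * NA_ + NB_ + seq_len(NB_),
               rep.int(nres, niA + niB)),
         j = c(rep.int(iK[1], NA_), rep.int(iK[2], NA_),
               rep.int(iK[1], NB_), rep.int(iK[2], NB_),
               1:niA, 2L * niA + 1:niB),
         x = c(rep(1, 2L * (NA_ + NB_)),
               rep(dzA * NA_, niA), rep(dzB * NA_, niB)))
  }
  fl0A <- outer_face_flux(init$raA, init$r0A, init$c, cf, Pe,
                          init$zstar / NA_)
  u0 <- c(init$raA[2:NA_], init$r0A[2:NA_],
          init$raB[2:NB_], init$r0B[2:NB_],
          init$c, -stats::median(fl0A$Ha), -stats::median(fl0A$H0),
          init$zstar, init$nu2)
  sol <- newton_solve(res_F, u0, groups, rows_of, tol = tol, maxit = maxit,
                      extra_triplets = et2)
  zs <- sol$u[iZ]; nu2 <- sol$u[iN2]
  ep2 <- tryCatch(endpoints2(nu2), error = function(e) rep(NA_real_, 4))
  raA <- c(ep1[1], sol$u[1:niA], ep2[1])
  r0A <- c(ep1[2], sol$u[niA + 1:niA], ep2[2])
  raB <- c(ep2[3], sol$u[2 * niA + 1:niB], ep1[3])
  r0B <- c(ep2[4], sol$u[2 * niA + niB + 1:niB], ep1[4])
  dzA <- zs / NA_; dzB <- (1 - zs) / NB_
  trapA <- function(v) dzA * (sum(v) - 0.5 * v[1] - 0.5 * v[NA_ + 1L])
  trapB <- function(v) dzB * (sum(v) - 0.5 * v[1] - 0.5 * v[NB_ + 1L])
  list(raA = raA, r0A = r0A, raB = raB, r0B = r0B,
       z = c(seq(0, zs, length.out = NA_ + 1L),
             seq(zs, 1, length.out = NB_ + 1L)),
       ra = c(raA, raB), r0 = c(r0A, r0B),
       c = sol$u[iC], K = sol$u[iK], zstar = zs, nu2 = nu2,
       residual = sol$residual, converged = sol$converged,
       iterations = sol$iterations,
       mass_p_defect = trapA(r0A) + trapB(r0B) - phi_p)
}

#' Two-interface traveling solutions of the outer problem
#'
#' Solves the outer equations with two inner regions: the primary interface
#' at the domain boundary (tie ratio `nu1`) and a second interface at an
#' interior position `z*` (tie ratio `nu2`), both following tie lines of
#' the binodal.  `(z*, nu2)` are Newton unknowns; `nu1` is selected by the
#' passive-mass constraint through a secant iteration, as in the
#' single-interface solver.
#'
#' @param phi_a,phi_p,Pe state point.
#' @param N total grid intervals (split between the pieces by `z*`).
#' @param init list with `raA`, `r0A`, `raB`, `r0B` (piece node values),
#'   `c`, `zstar`, `nu2`, and optionally `nu1`.
#' @param coeffs coefficient set.
#' @param tol,maxit Newton controls.
#' @return an `aplg_wave` with `regime = "outer-2-interface"`, fields
#'   `zstar`, `nu` (primary), `nu2`.
#' @export
solve_outer_two_interface <- function(phi_a, phi_p, Pe, N = 512L,
                                      init, coeffs = aplg_coeffs(),
                                      tol = 1e-10, maxit = 60L) {
  phi <- phi_a + phi_p
  nu0 <- if (!is.null(init$nu1)) init$nu1 else phi_p / (1 - phi)
  nu_max <- critical_nu(Pe, coeffs)$nu_star - 1e-4
  NA_ <- max(16L, as.integer(round(N * init$zstar)))
  NB_ <- max(16L, N - NA_)
  cur <- init
  resample_piece <- function(v, n_new) {
    stats::approx(seq(0, 1, length.out = length(v)), v,
                  seq(0, 1, length.out = n_new + 1L))$y
  }
  cur$raA <- resample_piece(cur$raA, NA_); cur$r0A <- resample_piece(cur$r0A, NA_)
  cur$raB <- resample_piece(cur$raB, NB_); cur$r0B <- resample_piece(cur$r0B, NB_)
  solve_at <- function(nu1) {
    out <- outer_two_iface_fixednu(phi_a, phi_p, Pe, NA_, NB_, cur, nu1,
                                   coeffs, tol, maxit)
    if (out$converged)
      cur <<- list(raA = out$raA, r0A = out$r0A, raB = out$raB,
                   r0B = out$r0B, c = out$c, zstar = out$zstar,
                   nu2 = out$nu2)
    out
  }
  nu1 <- min(max(nu0, 1e-4), nu_max)
  s1 <- solve_at(nu1)
  wrap <- function(s, nu1) {
    structure(list(z = s$z, rp = NULL, rm = NULL, r0 = s$r0, rho_a = s$ra,
                   rho = s$ra + s$r0, m = NULL, c = s$c, nu = nu1,
                   nu2 = s$nu2, zstar = s$zstar, K = s$K,
                   mass_p_defect = s$mass_p_defect, residual = s$residual,
                   converged = s$converged && abs(s$mass_p_defect) < 1e-8,
                   iterations = s$iterations, regime = "outer-2-interface",
                   Pe = Pe, phi_a = phi_a, phi_p = phi_p, N = N),
              class = "aplg_wave")
  }
  if (!s1$converged) return(wrap(s1, nu1))
  d1 <- s1$mass_p_defect
  step <- -sign(d1) * max(0.02, abs(nu1) * 0.03)
  nu2v <- min(max(nu1 + step, 1e-4), nu_max)
  s2 <- solve_at(nu2v)
  d2 <- s2$mass_p_defect
  for (it in 1:30) {
    if ((s2$converged && abs(d2) < 1e-10) || abs(nu2v - nu1) < 1e-12) break
    if (!s2$converged) {
      nu2v <- (nu1 + nu2v) / 2
      s2 <- solve_at(nu2v); d2 <- s2$mass_p_defect
      next
    }
    dn <- if (abs(d2 - d1) > 1e-14) -d2 * (nu2v - nu1) / (d2 - d1) else 0
    dn <- sign(dn) * min(abs(dn), 0.1)
    nu1 <- nu2v; d1 <- d2
    nu2v <- min(max(nu2v + dn, 1e-4), nu_max)
    s2 <- solve_at(nu2v); d2 <- s2$mass_p_defect
  }
  wrap(s2, nu2v)
}

#' Steepest-gradient location for interface insertion
#'
#' Returns the location `z*` of the maximal total-density gradient of a
#' converged (or failed) traveling solution, used to seed a second
#' interface; ties are broken toward smaller `z`.
#'
#' @param solution an `aplg_wave`.
#' @return list with `z_star`, `index`, `max_gradient`.
#' @export
insert_interface <- function(solution) {
  rho <- solution$rho
  n <- length(rho)
  z <- solution$z
  periodic <- is.null(solution$nu)
  if (periodic) {
    gr <- abs(rho[c(2:n, 1)] - rho) / diff(z[1:2])
  } else {
    gr <- abs(diff(rho)) / diff(z[1:2])
  }
  if (max(gr) < 1e-8) stop("flat profile: no interface location")
  i <- which(gr == max(gr))[1]
  list(z_star = z[i] + diff(z[1:2]) / 2, index = i, max_gradient = max(gr))
}

#' No-traveling-phase-separation check
#'
#' For a converged traveling solution, detects flat bulk plateaus (regions
#' where `|drho/dz|` falls below a threshold over at least a tenth of the
#' domain) and asserts the exact-hydrodynamics theorem: a profile moving at
#' `c != 0` cannot have two plateaus of different density (evaluating the
#' integrated total-density balance in each bulk forces equal densities).
#' A stationary solution (`c = 0`) may have unequal plateaus.
#'
#' @param solution an `aplg_wave`.
#' @param slope_tol plateau slope threshold (default 1e-2 in profile units
#'   per domain length).
#' @param density_tol equality tolerance for plateau densities.
#' @param min_frac minimum plateau extent as a fraction of the domain.
#' @return list with `pass`, `n_plateaus`, `plateau_densities`, `c`,
#'   `applicable` (TRUE when `c != 0` and at least two plateaus exist).
#' @export
no_traveling_ps_check <- function(solution, slope_tol = NULL,
                                  density_tol = 1e-4, min_frac = 0.1) {
  rho <- solution$rho
  n <- length(rho)
  z <- solution$z
  dzl <- diff(z[1:2])
  span <- if (is.null(solution$nu)) max(z) + dzl else max(z)
  gr <- abs(c(diff(rho), rho[1] - rho[n])) / dzl
  if (is.null(slope_tol)) slope_tol <- 0.05 * max(max(gr), 1e-12)
  flat <- gr < slope_tol
  # contiguous runs (periodic wrap)
  r <- rle(flat)
  idx <- cumsum(r$lengths)
  runs <- data.frame(start = c(1, utils::head(idx, -1) + 1), end = idx,
                     flat = r$values, len = r$lengths)
  if (nrow(runs) > 1 && runs$flat[1] && runs$flat[nrow(runs)]) {
    runs$len[1] <- runs$len[1] + runs$len[nrow(runs)]
    runs$start[1] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), ]
  }
  plat <- runs[runs$flat & runs$len * dzl >= min_frac * span, , drop = FALSE]
  dens <- apply(plat, 1, function(rw) {
    i <- as.integer(rw["start"]); j <- as.integer(rw["end"])
    ii <- if (i <= j) i:j else c(i:n, 1:j)
    mean(rho[ii])
  })
  moving <- abs(solution$c) > 1e-6
  applicable <- moving && length(dens) >= 2
  pass <- !applicable || (max(dens) - min(dens) < density_tol)
  list(pass = pass, n_plateaus = length(dens), plateau_densities = dens,
       c = solution$c, applicable = applicable)
}
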