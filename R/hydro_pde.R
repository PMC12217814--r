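#' Periodic finite-volume grid
#'
#' @param L domain length.
#' @param dx target cell width (the actual width is `L/N` with `N = round(L/dx)`).
#' @param N number of cells (alternative to `dx`).
#' @return list with `x` (cell centers), `dx`, `N`, `L`.
#' @export
pde_grid <- function(L, dx = NULL, N = NULL) {
  if (is.null(N)) {
    stopifnot(!is.null(dx), dx > 0)
    N <- max(4L, as.integer(round(L / dx)))
  }
  dx <- L / N
  list(x = (seq_len(N) - 0.5) * dx, dx = dx, N = as.integer(N), L = L)
}

#' Density field on a periodic grid
#'
#' Container for the three species densities `rho_plus`, `rho_minus`,
#' `rho_zero` on a 1D finite-volume grid, with derived fields
#' `rho = rho_+ + rho_- + rho_0`, `rho_a = rho_+ + rho_-` and the
#' magnetization `m = rho_+ - rho_-`.
#'
#' @param rp,rm,r0 per-cell densities of right-active, left-active and
#'   passive particles.
#' @param grid grid from [pde_grid()].
#' @param time time stamp.
#' @return object of class `aplg_field`.
#' @export
density_field <- function(rp, rm, r0, grid, time = 0) {
  stopifnot(length(rp) == grid$N, length(rm) == grid$N, length(r0) == grid$N)
  if (any(rp < -1e-12 | rm < -1e-12 | r0 < -1e-12 | rp + rm + r0 > 1 + 1e-12))
    stop("densities must be nonnegative with total <= 1")
  structure(list(rp = rp, rm = rm, r0 = r0, grid = grid, time = time),
            class = "aplg_field")
}

#' @export
print.aplg_field <- function(x, ...) {
  cat("APLG density field: N =", x$grid$N, " L =", x$grid$L,
      " t =", x$time, "\n")
  cat("  means: rho_a =", signif(mean(x$rp + x$rm), 6),
      " rho_0 =", signif(mean(x$r0), 6), "\n")
  invisible(x)
}

#' Time derivatives of the hydrodynamic equations
#'
#' Evaluates the right-hand side of the exact hydrodynamic equations in one
#' space dimension with a first-order finite-volume discretization:
#' centered two-point diffusive fluxes, upwinded advective fluxes on the
#' local advective velocity, and the orientation-flip reaction `-sigma*m`.
#'
#' @param field an `aplg_field`.
#' @param params an `aplg_params`.
#' @param scheme `"upwind"` (robust default, used by the time stepper) or
#'   `"centered"` (second-order advective fluxes, used for linearization
#'   oracles and convergence studies).
#' @return list of per-species derivative vectors `dp`, `dm`, `d0`.
#' @export
pde_rhs <- function(field, params, scheme = c("upwind", "centered")) {
  scheme <- match.arg(scheme)
  cf <- params$coeffs
  out <- aplg_rhs_cpp(field$rp, field$rm, field$r0, field$grid$L, params$Pe,
                      cf$ds_coef, cf$D_coef, upwind = scheme == "upwind")
  if (any(!is.finite(c(out$dp, out$dm, out$d0))))
    stop("non-finite derivative: invalid state")
  out
}

#' Initial conditions for PDE runs
#'
#' Builds a homogeneous state `rho_{+/-} = phi_a/2`, `rho_0 = phi_p`
#' perturbed by (a) mean-subtracted per-cell uniform noise and/or (b) the
#' real part of a dominant unstable eigenvector at the most unstable
#' admissible wavenumber `q = 2*pi*k/L`.  For complex dominant eigenvalues
#' the `"left"` / `"right"` kinds select the branch whose phase velocity
#' `-Im(lambda)/q` is negative / positive; `"pair"` superposes both
#' conjugate branches (the counter-propagating seed).  Mean densities equal
#' `phi_sigma` exactly after perturbation.
#'
#' @param params `aplg_params`.
#' @param grid grid from [pde_grid()].
#' @param kind one of `"noise"`, `"left"`, `"right"`, `"pair"` (the mode
#'   kinds add the noise term as well).
#' @param noise_amplitude uniform noise amplitude (absolute, default 1e-3).
#' @param mode_amplitude eigenmode amplitude (default 1e-2).
#' @param seed integer seed for the noise.
#' @param k_mode optional integer mode index; default: the most unstable.
#' @param force_mode allow seeding with a linearly stable (e.g. marginal)
#'   mode at finite amplitude; by default a stable mode raises an error.
#' @return an `aplg_field`.
#' @export
make_initial_condition <- function(params, grid,
                                   kind = c("noise", "left", "right", "pair"),
                                   noise_amplitude = 1e-3,
                                   mode_amplitude = 1e-2,
                                   seed = 1L, k_mode = NULL,
                                   force_mode = FALSE) {
  kind <- match.arg(kind)
  N <- grid$N
  base <- list(rp = rep(params$phi_a / 2, N), rm = rep(params$phi_a / 2, N),
               r0 = rep(params$phi_p, N))
  pert <- list(rp = numeric(N), rm = numeric(N), r0 = numeric(N))
  if (kind != "noise") {
    qs <- 2 * pi * seq_len(max(4L, N %/% 2L)) / grid$L
    gr <- vapply(qs, function(q) max(Re(eigen(stability_matrix(q, params),
                                              only.values = TRUE)$values)), 0)
    if (is.null(k_mode)) {
      if (max(gr) <= 0 && !force_mode)
        stop("no unstable admissible mode at this state point")
      k_mode <- which.max(gr)
    } else if (gr[k_mode] <= 0 && !force_mode)
      stop("requested mode is linearly stable")
    q <- 2 * pi * k_mode / grid$L
    M <- stability_matrix(q, params)
    ev <- eigen(M)
    ord <- order(-Re(ev$values))
    lam <- ev$values[ord]; vec <- ev$vectors[, ord, drop = FALSE]
    # among the dominant-growth pair, select by phase velocity -Im(lambda)/q
    top <- which(Re(lam) > max(Re(lam)) - 1e-10)
    pick_branch <- function(sign_v) {
      vph <- -Im(lam[top]) / q
      i <- top[order(sign_v * vph, decreasing = TRUE)[1]]
      v <- vec[, i]
      v / max(abs(v))
    }
    add_mode <- function(v) {
      ph <- exp(1i * q * grid$x)
      list(rp = Re(v[1] * ph), rm = Re(v[2] * ph), r0 = Re(v[3] * ph))
    }
    md <- switch(kind,
      left  = add_mode(pick_branch(-1)),
      right = add_mode(pick_branch(+1)),
      pair  = {
        a <- add_mode(pick_branch(-1)); b <- add_mode(pick_branch(+1))
        list(rp = (a$rp + b$rp) / 2, rm = (a$rm + b$rm) / 2,
             r0 = (a$r0 + b$r0) / 2)
      })
    for (f in names(pert)) pert[[f]] <- pert[[f]] + mode_amplitude * md[[f]]
  }
  if (noise_amplitude > 0) {
    set.seed(seed)
    for (f in names(pert)) {
      z <- stats::runif(N, -noise_amplitude, noise_amplitude)
      pert[[f]] <- pert[[f]] + (z - mean(z))
    }
  }
  for (f in names(pert)) pert[[f]] <- pert[[f]] - mean(pert[[f]])
  density_field(base$rp + pert$rp, base$rm + pert$rm, base$r0 + pert$r0, grid)
}

#' Integrate the hydrodynamic equations
#'
#' Forward-Euler time stepping of the 1D hydrodynamic equations with
#' adaptive time step (diffusive and advective CFL limits, halved further on
#' positivity violation).  Species means are conserved to machine precision
#' by the conservative flux form.
#'
#' @param ic initial `aplg_field`.
#' @param params `aplg_params`.
#' @param t_end final time.
#' @param dt_save sampling interval for stored frames.
#' @param cfl CFL safety factor (default 0.9).
#' @param save_times optional explicit vector of sampling times.
#' @param scheme `"upwind"` (robust for sharp interfaces) or `"centered"`
#'   (two-point centered advective fluxes; less numerical diffusion, used
#'   for quantitative speed measurements on resolved profiles).
#' @return an `aplg_trajectory`: list with `times`, frame matrices
#'   `rp`, `rm`, `r0` (rows = times), `grid`, `params`.
#' @export
integrate_pde <- function(ic, params, t_end, dt_save = 1, cfl = 0.9,
                          save_times = NULL,
                          scheme = c("upwind", "centered")) {
  stopifnot(inherits(ic, "aplg_field"), t_end > ic$time)
  scheme <- match.arg(scheme)
  if (is.null(save_times))
    save_times <- unique(c(seq(ic$time, t_end, by = dt_save), t_end))
  cf <- params$coeffs
  out <- aplg_integrate_cpp(ic$rp, ic$rm, ic$r0, ic$grid$L, params$Pe,
                            cf$ds_coef, cf$D_coef, save_times, ic$time, cfl,
                            upwind = scheme == "upwind")
  structure(list(times = out$times, rp = out$rp, rm = out$rm, r0 = out$r0,
                 grid = ic$grid, params = params, nsteps = out$nsteps),
            class = "aplg_trajectory")
}

#' @export
print.aplg_trajectory <- function(x, ...) {
  cat("APLG trajectory:", length(x$times), "frames, t in [",
      x$times[1], ",", x$times[length(x$times)], "], N =", x$grid$N, "\n")
  invisible(x)
}

#' Extract one frame of a trajectory as a density field
#' @param traj an `aplg_trajectory`.
#' @param i frame index (default: last).
#' @export
frame_field <- function(traj, i = length(traj$times)) {
  density_field(traj$rp[i, ], traj$rm[i, ], traj$r0[i, ], traj$grid,
                time = traj$times[i])
}

#' Measure the propagation speed of a traveling profile
#'
#' Tracks the circular cross-correlation shift of the total density between
#' stored frames over the last fraction of the run (FFT correlation with
#' parabolic sub-grid refinement), accumulates the shift, and fits a line
#' through shift-vs-time.  Positive `c` means rightward motion; the reported
#' speed is `c = L * (wave velocity)` following the co-moving convention
#' `rho_sigma(x - c t / L)`.
#'
#' @param traj an `aplg_trajectory`.
#' @param window_frac fraction of the run used (default final 20%).
#' @return list with `c` (profile speed times L), `velocity` (wave velocity),
#'   and the per-interval shifts.
#' @export
measure_speed <- function(traj, window_frac = 0.2) {
  nt <- length(traj$times)
  i0 <- max(2L, ceiling(nt * (1 - window_frac)))
  N <- traj$grid$N
  rho <- traj$rp + traj$rm + traj$r0
  shift_of <- function(a, b) {
    # circular shift of b relative to a, in cells (positive = rightward)
    xc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
    j <- which.max(xc)
    jm <- if (j == 1) N else j - 1
    jp <- if (j == N) 1 else j + 1
    den <- xc[jm] - 2 * xc[j] + xc[jp]
    frac <- if (abs(den) > 1e-30) 0.5 * (xc[jm] - xc[jp]) / den else 0
    sh <- (j - 1) + frac
    if (sh > N / 2) sh <- sh - N
    sh
  }
  idx <- i0:nt
  shifts <- vapply(seq_along(idx)[-1], function(kk) {
    shift_of(rho[idx[kk - 1], ], rho[idx[kk], ])
  }, 0)
  cum <- cumsum(c(0, shifts)) * traj$grid$dx
  tt <- traj$times[idx]
  fit <- stats::lm.fit(cbind(1, tt - tt[1]), cum)
  vel <- fit$coefficients[2]
  list(c = unname(vel * traj$grid$L), velocity = unname(vel), shifts = shifts)
}

#' Distance from the homogeneous state
#'
#' Grid-weighted composite norm `d_H = (sum_sigma ||rho_sigma - phi_sigma||_2)^(1/2)`
#' (outer square root over a sum of L2 norms, reproducing the classifier
#' convention).
#' @param field an `aplg_field`.
#' @param params `aplg_params`.
#' @export
distance_from_uniform <- function(field, params) {
  dx <- field$grid$dx
  nrm <- function(f) sqrt(sum(f^2) * dx)
  sqrt(nrm(field$rp - params$phi_a / 2) + nrm(field$rm - params$phi_a / 2) +
       nrm(field$r0 - params$phi_p))
}
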