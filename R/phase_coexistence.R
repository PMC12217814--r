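#' Effective free-energy terms for phase coexistence
#'
#' For stationary phase-separated profiles the passive density is slaved to
#' the total density, `rho_0 = nu (1 - rho)` with `nu = phi_p / (1 - phi)`,
#' and the magnetization obeys `m = rho_x / (Pe (1 - rho))` (vanishing flux
#' constants).  Substituting into the stationary magnetization balance and
#' integrating once collapses the system to a single scalar condition
#' `g(rho, rho_x, rho_xx) = g0(rho) + Lambda(rho) rho_x^2 - kappa(rho) rho_xx
#'  = const`, with
#' \deqn{g_0(\rho) = Pe\, d_s(\rho)\,[(1+\nu)\rho - \nu] - (2/Pe) \log(1-\rho),}
#' \deqn{\Lambda(\rho) = \frac{1}{Pe}\left[\frac{s(\rho) - d_s(\rho)}{(1-\rho)^2}
#'   - \frac{D(\rho)}{1-\rho}\right], \qquad
#'   \kappa(\rho) = \frac{d_s(\rho)}{Pe\,(1-\rho)}.}
#' `kappa > 0` on (0,1) and the bulk term grows with `Pe * rho_a`.
#'
#' @param Pe Peclet number (> 0).
#' @param nu passive-to-vacancy ratio (>= 0).
#' @param coeffs transport-coefficient set.
#' @return list of vectorized callables `g0`, `g0p` (derivative in `rho`),
#'   `Lambda`, `kappa`, `kappap`, and `g(rho, rho_x, rho_xx)`.
#' @export
effective_terms <- function(Pe, nu, coeffs = aplg_coeffs()) {
  stopifnot(Pe > 0, nu >= 0)
  cf <- coeffs
  g0 <- function(rho)
    Pe * cf$ds(rho) * ((1 + nu) * rho - nu) - (2 / Pe) * log1p(-rho)
  g0p <- function(rho)
    Pe * (cf$ds1(rho) * ((1 + nu) * rho - nu) + cf$ds(rho) * (1 + nu)) +
      (2 / Pe) / (1 - rho)
  Lambda <- function(rho) {
    D <- cf$D(rho)
    ((D - 1 - cf$ds(rho)) / (1 - rho)^2 - D / (1 - rho)) / Pe
  }
  kappa <- function(rho) cf$ds(rho) / (Pe * (1 - rho))
  kappap <- function(rho)
    (cf$ds1(rho) * (1 - rho) + cf$ds(rho)) / (Pe * (1 - rho)^2)
  g <- function(rho, rho_x, rho_xx)
    g0(rho) + Lambda(rho) * rho_x^2 - kappa(rho) * rho_xx
  list(g0 = g0, g0p = g0p, Lambda = Lambda, kappa = kappa, kappap = kappap,
       g = g)
}

#' Critical passive-to-vacancy ratio
#'
#' Coexistence at given `Pe` exists for `nu` below a critical value:
#' `g0(rho; nu)` is non-monotonic iff `nu < nu_star(Pe)`.  Since
#' `dg0/drho` is linear in `nu` with positive slope, the boundary is
#' `nu_star = max_rho nu(rho)` where `nu(rho)` solves `dg0/drho = 0`.
#'
#' @param Pe Peclet number.
#' @param coeffs coefficient set.
#' @return list with `nu_star` and the critical density `rho_c` (the
#'   merged binodal densities at onset); `nu_star < 0` means no coexistence
#'   at any `nu` (Pe below the pure-active critical point).
#' @export
critical_nu <- function(Pe, coeffs = aplg_coeffs()) {
  cf <- coeffs
  nu_of_rho <- function(rho) {
    num <- Pe * (cf$ds1(rho) * rho + cf$ds(rho)) + (2 / Pe) / (1 - rho)
    den <- Pe * (cf$ds1(rho) * (rho - 1) + cf$ds(rho))
    -num / den
  }
  op <- stats::optimize(nu_of_rho, c(1e-6, 1 - 1e-6), maximum = TRUE,
                        tol = 1e-12)
  list(nu_star = op$objective, rho_c = op$maximum)
}

# Internal: quadrature tables for the coexistence construction at (Pe, nu).
# R'(rho) = mu(rho) is the integrating factor that makes the gradient terms
# of g an exact second derivative in R: mu'/mu = -(2*Lambda + kappa')/kappa.
# Grid is uniform in rho up to 0.95 and geometric in (1 - rho) beyond, to
# resolve the logarithmic divergence of g0 at full packing.
coex_tables <- function(Pe, nu, coeffs = aplg_coeffs(), n = 3000L) {
  et <- effective_terms(Pe, nu, coeffs)
  rho <- c(seq(1e-8, 0.95, length.out = n),
           1 - exp(seq(log(0.05), log(1e-5), length.out = 600L))[-1])
  h <- (2 * et$Lambda(rho) + et$kappap(rho)) / et$kappa(rho)
  lnmu <- -pracma::cumtrapz(rho, h)[, 1]
  lnmu <- lnmu - stats::approx(rho, lnmu, 0.5)$y  # gauge: mu(0.5) = 1
  mu <- exp(lnmu)
  g0v <- et$g0(rho)
  R <- pracma::cumtrapz(rho, mu)[, 1]
  Phi <- pracma::cumtrapz(rho, g0v * mu)[, 1]
  lnmu_f <- stats::splinefun(rho, lnmu, method = "natural")
  list(rho = rho, mu = mu, g0v = g0v, R = R, Phi = Phi, et = et,
       lnmu_f = lnmu_f,
       mu_f = function(r) exp(lnmu_f(r)),
       R_f = stats::splinefun(rho, R, method = "monoH.FC"),
       Phi_f = stats::splinefun(rho, Phi, method = "natural"))
}

#' Coexisting bulk densities at fixed tie-line ratio
#'
#' Solves the two coexistence conditions -- equal `g0` in both phases and the
#' common-tangent (equal-intercept) condition on the effective free energy
#' `Phi(R)` with `dPhi/dR = g0` -- for the vapor and liquid total densities
#' `phi_v <= phi_l` at given `(Pe, nu)`.  The transformed density `R(rho)`
#' is obtained by quadrature of the integrating factor; its gauge does not
#' affect the solution.  Above the critical `nu` the degenerate critical
#' result `phi_v = phi_l = rho_c` is returned.
#'
#' @param Pe Peclet number.
#' @param nu passive-to-vacancy ratio.
#' @param coeffs coefficient set.
#' @param tol root tolerance on the tangent condition.
#' @return object of class `aplg_coexistence`: `phi_v`, `phi_l`, `nu`, `Pe`,
#'   `degenerate`, endpoints in the `(phi_a, phi_p)` plane for both phases
#'   (`rho_0 = nu (1 - rho)` exactly), `gbar` (common `g0` value), and the
#'   effective terms.
#' @export
binodal_at_nu <- function(Pe, nu, coeffs = aplg_coeffs(), tol = 1e-12) {
  cn <- critical_nu(Pe, coeffs)
  endpoints <- function(phi_v, phi_l) {
    r0 <- nu * (1 - c(phi_v, phi_l))
    data.frame(phase = c("vapor", "liquid"),
               rho = c(phi_v, phi_l),
               phi_a = c(phi_v, phi_l) - r0, phi_p = r0)
  }
  et <- effective_terms(Pe, nu, coeffs)
  if (nu >= cn$nu_star) {
    res <- list(phi_v = cn$rho_c, phi_l = cn$rho_c, nu = nu, Pe = Pe,
                degenerate = TRUE, endpoints = endpoints(cn$rho_c, cn$rho_c),
                gbar = et$g0(cn$rho_c), terms = et, tables = NULL)
    class(res) <- "aplg_coexistence"
    return(res)
  }
  tb <- coex_tables(Pe, nu, coeffs)
  # spinodal densities of g0 (local extrema of g0): g0' = 0
  g0p <- et$g0p
  rs1 <- stats::uniroot(g0p, c(1e-6, cn$rho_c), tol = 1e-14)$root
  rs2 <- stats::uniroot(g0p, c(cn$rho_c, 1 - 1e-6), tol = 1e-14)$root
  # for a trial vapor density, the matching liquid density with equal g0
  liquid_of <- function(pv) {
    target <- et$g0(pv)
    hi <- 1 - 2e-5  # within the quadrature tables
    if (et$g0(hi) < target || et$g0(rs2) > target) return(NA_real_)
    stats::uniroot(function(r) et$g0(r) - target, c(rs2, hi), tol = 1e-14)$root
  }
  # equal-intercept (common tangent) residual on Phi(R), computed as
  # int_{pv}^{pl} (g0 - g0(pv)) dR by adaptive quadrature: the weight
  # R'(rho) grows like (1-rho)^-4, so a fixed grid cannot resolve the
  # near-liquid contribution at large Pe
  tangent_res <- function(pv) {
    pl <- liquid_of(pv)
    if (!is.finite(pl)) return(NA_real_)
    g0v <- et$g0(pv)
    f <- function(r) (et$g0(r) - g0v) * exp(tb$lnmu_f(r))
    val <- 0
    brk <- sort(unique(pmin(pmax(c(pv, rs1, rs2, pl - 0.1 * (pl - rs2),
                                   pl), pv), pl)))
    for (k in seq_len(length(brk) - 1L)) {
      if (brk[k + 1L] - brk[k] < 1e-14) next
      iv <- tryCatch(stats::integrate(f, brk[k], brk[k + 1L],
                                      rel.tol = 1e-10, abs.tol = 1e-12,
                                      subdivisions = 400L)$value,
                     error = function(e) NA_real_)
      if (!is.finite(iv)) return(NA_real_)
      val <- val + iv
    }
    val
  }
  # Bracket the tangent root on the feasible vapor window.  Feasibility of
  # the equal-g0 partner requires g0(rs2) <= g0(pv) <= g0(hi); the root can
  # hug either edge (it approaches the lower edge at large Pe, and rs1 near
  # the critical point), so both ends are scanned geometrically.
  lo <- 1e-7
  hi <- 1 - 2e-5
  g_lo <- et$g0(rs2)
  pv_lo <- if (et$g0(lo) >= g_lo) lo else
    stats::uniroot(function(r) et$g0(r) - g_lo, c(lo, rs1),
                   tol = 1e-15)$root
  pv_hi <- if (et$g0(rs1) <= et$g0(hi)) rs1 * (1 - 1e-12) else
    stats::uniroot(function(r) et$g0(r) - et$g0(hi), c(lo, rs1),
                   tol = 1e-15)$root
  wid <- pv_hi - pv_lo
  offs <- exp(seq(log(1e-10), log(1), length.out = 120L))
  vgrid <- sort(unique(c(pv_lo + wid * offs, pv_hi - wid * offs,
                         seq(pv_lo, pv_hi, length.out = 120L))))
  vgrid <- vgrid[vgrid > pv_lo & vgrid < pv_hi]
  fv <- vapply(vgrid, tangent_res, 0)
  ok <- which(is.finite(fv))
  flip <- ok[which(diff(sign(fv[ok])) != 0)]
  if (length(flip) == 0)
    stop("no coexistence bracket found at Pe = ", Pe, ", nu = ", nu)
  i <- flip[1]
  i2 <- ok[ok > i][1]
  root <- stats::uniroot(tangent_res, c(vgrid[i], vgrid[i2]),
                         tol = tol)$root
  phi_v <- root
  phi_l <- liquid_of(phi_v)
  res <- list(phi_v = phi_v, phi_l = phi_l, nu = nu, Pe = Pe,
              degenerate = FALSE, endpoints = endpoints(phi_v, phi_l),
              gbar = et$g0(phi_v), terms = et, tables = tb,
              rho_s = c(rs1, rs2))
  class(res) <- "aplg_coexistence"
  res
}

#' @export
print.aplg_coexistence <- function(x, ...) {
  cat("APLG coexistence at Pe =", x$Pe, " nu =", signif(x$nu, 6), "\n")
  if (x$degenerate) cat("  degenerate (at/above critical nu): rho_c =",
                        signif(x$phi_v, 6), "\n")
  else cat("  phi_v =", signif(x$phi_v, 8), " phi_l =", signif(x$phi_l, 8),
           "\n")
  invisible(x)
}

#' Tie line through a state point
#'
#' For `(phi_a, phi_p)` inside the binodal, computes the tie-line ratio
#' `nu = phi_p / (1 - phi)`, the coexisting vapor/liquid endpoints in the
#' `(phi_a, phi_p)` plane, and the lever-rule volume fraction of liquid.
#'
#' @param phi_a,phi_p state point.
#' @param Pe Peclet number.
#' @param coeffs coefficient set.
#' @return list with `nu`, `endpoints`, `phi_v`, `phi_l`, `liquid_fraction`.
#' @export
tie_line <- function(phi_a, phi_p, Pe, coeffs = aplg_coeffs()) {
  phi <- phi_a + phi_p
  stopifnot(phi < 1)
  nu <- phi_p / (1 - phi)
  bn <- binodal_at_nu(Pe, nu, coeffs)
  if (bn$degenerate || phi <= bn$phi_v || phi >= bn$phi_l)
    stop("state point is outside the binodal: single phase")
  list(nu = nu, endpoints = bn$endpoints, phi_v = bn$phi_v, phi_l = bn$phi_l,
       liquid_fraction = (phi - bn$phi_v) / (bn$phi_l - bn$phi_v),
       coexistence = bn)
}

#' Binodal curve in the (phi_a, phi_p) plane
#'
#' Sweeps the tie-line ratio `nu` from the pure-active limit to the critical
#' value and collects the coexisting endpoints.  The curve runs along the
#' vapor branch to the critical point and back along the liquid branch.
#'
#' @param Pe Peclet number.
#' @param n_nu number of tie lines.
#' @param coeffs coefficient set.
#' @return data frame with `nu`, `branch`, `rho`, `phi_a`, `phi_p`.
#' @export
binodal_curve <- function(Pe, n_nu = 40L, coeffs = aplg_coeffs()) {
  cn <- critical_nu(Pe, coeffs)
  if (cn$nu_star <= 0) stop("no coexistence at Pe = ", Pe)
  nus <- cn$nu_star * (1 - (1 - seq(0, 1, length.out = n_nu + 1L)[-(n_nu + 1L)])^2)
  rows <- lapply(nus, function(nu) {
    bn <- tryCatch(binodal_at_nu(Pe, nu, coeffs), error = function(e) NULL)
    if (is.null(bn)) return(NULL)
    data.frame(nu = nu, branch = bn$endpoints$phase, rho = bn$endpoints$rho,
               phi_a = bn$endpoints$phi_a, phi_p = bn$endpoints$phi_p)
  })
  crit <- data.frame(nu = cn$nu_star, branch = "critical", rho = cn$rho_c,
                     phi_a = cn$rho_c - cn$nu_star * (1 - cn$rho_c),
                     phi_p = cn$nu_star * (1 - cn$rho_c))
  out <- rbind(do.call(rbind, rows), crit)
  v <- out[out$branch != "liquid", ]
  l <- out[out$branch == "liquid", ]
  rbind(v[order(v$nu), ], l[order(-l$nu), ])
}

#' Stationary liquid-vapor interface profile
#'
#' Integrates the first-order reduction of the stationary profile equation:
#' with `Psi(rho)` the excess of `Phi` over its common tangent, the interface
#' obeys `rho_x = sqrt(2 Psi / (kappa mu))`, a monotone front connecting
#' `phi_v` (x -> -Inf) to `phi_l` (x -> +Inf).  The translational gauge is
#' fixed by `rho(0) = (phi_v + phi_l)/2`.  The magnetization follows from
#' `m = rho_x / (Pe (1 - rho))` and the passive density from
#' `rho_0 = nu (1 - rho)`.
#'
#' @param Pe Peclet number.
#' @param nu tie-line ratio (must admit coexistence).
#' @param half_width half-width of the returned x-grid.
#' @param n number of grid points.
#' @param coeffs coefficient set.
#' @return object of class `aplg_interface`: `x`, `rho`, `m`, `r0`, `rho_a`,
#'   `rp`, `rm`, plus the underlying coexistence result.
#' @export
interface_profile <- function(Pe, nu, half_width = 10, n = 801L,
                              coeffs = aplg_coeffs()) {
  bn <- binodal_at_nu(Pe, nu, coeffs)
  if (bn$degenerate) stop("no interface: degenerate coexistence at this nu")
  tb <- bn$tables
  et <- bn$terms
  # Psi(rho) = excess of Phi over its common tangent, computed on a
  # profile-specific grid (geometric refinement toward both endpoints,
  # where the integrand of Psi is largest)
  del0 <- bn$phi_l - bn$phi_v
  rg <- sort(unique(c(
    bn$phi_v + del0 * exp(seq(log(1e-6), log(0.05), length.out = 400L)),
    seq(bn$phi_v + 0.05 * del0, bn$phi_l - 0.05 * del0, length.out = 1500L),
    bn$phi_l - del0 * exp(seq(log(0.05), log(1e-6), length.out = 400L)))))
  psig <- pracma::cumtrapz(rg, (et$g0(rg) - bn$gbar) * exp(tb$lnmu_f(rg)))[, 1]
  Psi_f <- stats::splinefun(rg, psig, method = "monoH.FC")
  Psi <- function(r) pmax(0, Psi_f(r))
  slope <- function(r) sqrt(2 * Psi(r) / (et$kappa(r) * tb$mu_f(r)))
  mid <- (bn$phi_v + bn$phi_l) / 2
  # x(rho) by quadrature from the midpoint; the integrand diverges only
  # logarithmically-in-x at the bulk endpoints (exponential tails), so a
  # relative margin eps covers many interface widths
  del <- bn$phi_l - bn$phi_v
  eps <- 1e-4 * del
  rr <- sort(unique(c(
    bn$phi_v + del * exp(seq(log(1e-4), log(0.05), length.out = 300L)),
    seq(bn$phi_v + 0.05 * del, bn$phi_l - 0.05 * del, length.out = 1200L),
    bn$phi_l - del * exp(seq(log(0.05), log(1e-4), length.out = 300L)))))
  sl <- slope(rr)
  keep <- is.finite(sl) & sl > 0
  rr <- rr[keep]; sl <- sl[keep]
  xx <- pracma::cumtrapz(rr, 1 / sl)[, 1]
  x0 <- stats::approx(rr, xx, mid)$y
  xx <- xx - x0
  x <- seq(-half_width, half_width, length.out = n)
  rho <- stats::approx(xx, rr, x, rule = 2)$y
  m <- slope(rho) / (Pe * (1 - rho))
  m[!is.finite(m) | rho <= bn$phi_v + eps | rho >= bn$phi_l - eps] <- 0
  r0 <- nu * (1 - rho)
  rho_a <- rho - r0
  structure(list(x = x, rho = rho, m = m, r0 = r0, rho_a = rho_a,
                 rp = (rho_a + m) / 2, rm = (rho_a - m) / 2,
                 coexistence = bn),
            class = "aplg_interface")
}

#' @export
print.aplg_interface <- function(x, ...) {
  bn <- x$coexistence
  cat("APLG interface profile: Pe =", bn$Pe, " nu =", signif(bn$nu, 6),
      " phi_v =", signif(bn$phi_v, 6), " phi_l =", signif(bn$phi_l, 6), "\n")
  invisible(x)
}
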