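#' Linear stability matrix of the homogeneous state
#'
#' Linearizing the hydrodynamic equations about the homogeneous state
#' `rho_{+/-} = phi_a/2`, `rho_0 = phi_p` with a plane-wave perturbation
#' `delta * A_sigma * exp(lambda t + i q x)` yields the eigenvalue problem
#' `lambda A = M(q) A` with `M` a 3x3 complex matrix assembled from the
#' analytic derivatives of `d_s`, `D`, `s` at the total density `phi`.
#' At `q = 0` the spectrum is exactly `{0, 0, -2}`: two conserved densities,
#' and the magnetization relaxing at rate 2.
#'
#' @param q wavenumber.
#' @param params `aplg_params`.
#' @return complex 3x3 matrix in the basis `(A_+, A_-, A_0)`.
#' @export
stability_matrix <- function(q, params) {
  cf <- params$coeffs
  phi <- params$phi
  a <- params$phi_a / 2
  p <- params$phi_p
  Pe <- params$Pe
  ds <- cf$ds(phi); dsp <- cf$ds1(phi)
  D <- cf$D(phi); s <- D - 1
  iqPe <- 1i * q * Pe
  q2 <- q * q
  M <- matrix(0i, 3, 3)
  M[1, 1] <- -q2 * (ds + a * D) - iqPe * (a * s + ds + a * dsp) - 1
  M[1, 2] <- -q2 * a * D - iqPe * (-a * s + a * dsp) + 1
  M[1, 3] <- -q2 * a * D - iqPe * a * dsp
  M[2, 1] <- -q2 * a * D - iqPe * (a * s - a * dsp) + 1
  M[2, 2] <- -q2 * (ds + a * D) + iqPe * (a * s + ds + a * dsp) - 1
  M[2, 3] <- -q2 * a * D + iqPe * a * dsp
  M[3, 1] <- -q2 * p * D - iqPe * p * s
  M[3, 2] <- -q2 * p * D + iqPe * p * s
  M[3, 3] <- -q2 * (ds + p * D)
  M
}

#' Maximal growth rate over wavenumber
#'
#' `max_q Re(lambda_dom(q))` over a continuous range of wavenumbers
#' (hydrodynamic limit) or restricted to admissible modes `q = 2 pi k / L`.
#'
#' @param params `aplg_params`.
#' @param q_max upper wavenumber bound for the search (default scales with
#'   a diffusive balance estimate).
#' @param L_restrict if not `NULL`, restrict to `q = 2 pi k / L_restrict`.
#' @return list with `growth` (the supremum), `q_star` (arg max) and
#'   `complex_dominant` (is the dominant eigenvalue complex at `q_star`).
#' @export
max_growth_rate <- function(params, q_max = NULL, L_restrict = NULL) {
  gr1 <- function(q) {
    ev <- eigen(stability_matrix(q, params), only.values = TRUE)$values
    max(Re(ev))
  }
  if (is.null(q_max)) q_max <- max(10, 2.5 * params$Pe)
  if (!is.null(L_restrict)) {
    qs <- 2 * pi * seq_len(max(1L, floor(q_max * L_restrict / (2 * pi)))) /
      L_restrict
    g <- vapply(qs, gr1, 0)
    i <- which.max(g)
    qst <- qs[i]; gst <- g[i]
  } else {
    qs <- seq(1e-4, q_max, length.out = 80L)
    g <- vapply(qs, gr1, 0)
    i <- which.max(g)
    lo <- qs[max(1L, i - 1L)]; hi <- qs[min(length(qs), i + 1L)]
    op <- stats::optimize(gr1, c(lo, hi), maximum = TRUE, tol = 1e-10)
    qst <- op$maximum; gst <- op$objective
  }
  ev <- eigen(stability_matrix(qst, params), only.values = TRUE)$values
  dom <- ev[which.max(Re(ev))]
  list(growth = gst, q_star = qst,
       complex_dominant = abs(Im(dom)) > 1e-8)
}

#' Dispersion relation of the homogeneous state
#'
#' Eigen-decomposition of the stability matrix on a wavenumber grid with
#' continuous branch tracking (branches matched between adjacent `q` by
#' maximal eigenvector overlap; ties broken by eigenvalue proximity).
#'
#' @param params `aplg_params`.
#' @param q_max largest wavenumber.
#' @param nq number of grid points.
#' @return object of class `aplg_dispersion`: `q`, complex matrix
#'   `lambda` (nq x 3, tracked branches), `dominant` (branch index per q),
#'   `is_complex_dominant`, eigenvector array `vectors` (3 x 3 x nq).
#' @export
dispersion <- function(params, q_max = 10, nq = 200L) {
  stopifnot(q_max > 0)
  qs <- seq(0, q_max, length.out = nq)
  lam <- matrix(0i, nq, 3)
  vecs <- array(0i, c(3, 3, nq))
  prev <- NULL
  for (k in seq_len(nq)) {
    ev <- eigen(stability_matrix(qs[k], params))
    ord <- seq_len(3)
    if (!is.null(prev)) {
      # assign each previous branch the unassigned eigenvector of maximal overlap
      ov <- abs(Conj(t(prev)) %*% ev$vectors)
      ord <- integer(3)
      taken <- rep(FALSE, 3)
      for (b in seq_len(3)) {
        j <- order(ov[b, ], decreasing = TRUE)
        j <- j[!taken[j]][1]
        ord[b] <- j; taken[j] <- TRUE
      }
    } else {
      ord <- order(-Re(ev$values))
    }
    lam[k, ] <- ev$values[ord]
    vecs[, , k] <- ev$vectors[, ord, drop = FALSE]
    prev <- ev$vectors[, ord, drop = FALSE]
  }
  dom <- max.col(Re(lam))
  structure(list(q = qs, lambda = lam, dominant = dom,
                 is_complex_dominant =
                   abs(Im(lam[cbind(seq_len(nq), dom)])) > 1e-8,
                 vectors = vecs, params = params),
            class = "aplg_dispersion")
}

#' @export
print.aplg_dispersion <- function(x, ...) {
  g <- Re(x$lambda[cbind(seq_along(x$q), x$dominant)])
  i <- which.max(g)
  cat("APLG dispersion:", length(x$q), "wavenumbers up to", max(x$q), "\n")
  cat("  max growth", signif(g[i], 6), "at q =", signif(x$q[i], 6),
      if (x$is_complex_dominant[i]) "(complex)" else "(real)", "\n")
  invisible(x)
}

#' @export
plot.aplg_dispersion <- function(x, ...) {
  g <- Re(x$lambda)
  graphics::matplot(x$q, g, type = "l", lty = 1, xlab = "q",
                    ylab = "Re lambda", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Spinodal curve
#'
#' Locus in the `(phi_a, phi_p)` plane where the maximal growth rate over
#' continuous wavenumber vanishes, traced by bisection along rays from an
#' interior unstable point.  Returns an empty curve when no unstable region
#' exists at this `Pe`.
#'
#' @param Pe Peclet number.
#' @param resolution number of rays.
#' @param coeffs coefficient set.
#' @param tol bisection tolerance on the ray parameter.
#' @return object of class `aplg_spinodal`: data frame with `phi_a`,
#'   `phi_p`, `q_star`, `complex_dominant`, plus the ray center.
#' @export
spinodal <- function(Pe, resolution = 72L, coeffs = aplg_coeffs(),
                     tol = 1e-9) {
  stopifnot(Pe > 0)
  gr <- function(phi_a, phi_p) {
    if (phi_a < 0 || phi_p < 0 || phi_a + phi_p >= 1) return(-Inf)
    max_growth_rate(aplg_params(Pe, phi_a = phi_a, phi_p = phi_p,
                                coeffs = coeffs))$growth
  }
  # coarse scan for an interior unstable point
  aa <- seq(0.05, 0.9, by = 0.05)
  best <- c(NA, NA); bestg <- 0
  for (a in aa) for (p in seq(0.0, 0.9 - a, by = 0.05)) {
    g <- gr(a, p)
    if (g > bestg) { bestg <- g; best <- c(a, p) }
  }
  if (!is.finite(bestg) || bestg <= 0) {
    return(structure(list(curve = data.frame(phi_a = numeric(0),
                                             phi_p = numeric(0),
                                             q_star = numeric(0),
                                             complex_dominant = logical(0)),
                          center = NULL, Pe = Pe), class = "aplg_spinodal"))
  }
  ctr <- best
  # nudge an on-axis center into the interior so downward rays are usable
  if (ctr[2] < 0.005 && gr(ctr[1], 0.005) > 0) ctr[2] <- 0.005
  th <- seq(0, 2 * pi, length.out = resolution + 1L)[-(resolution + 1L)]
  rows <- lapply(th, function(t1) {
    u <- c(cos(t1), sin(t1))
    # bracket: find r with g < 0
    rhi <- 0.05
    repeat {
      pt <- ctr + rhi * u
      if (gr(pt[1], pt[2]) < 0) break
      rhi <- rhi * 1.4
      if (rhi > 3) return(NULL)
    }
    rlo <- 0
    while (rhi - rlo > tol) {
      rmid <- (rlo + rhi) / 2
      pt <- ctr + rmid * u
      if (gr(pt[1], pt[2]) > 0) rlo <- rmid else rhi <- rmid
    }
    pt <- ctr + 0.5 * (rlo + rhi) * u
    # rays whose neutral crossing is the domain boundary (axes or full
    # packing) are not spinodal points
    if (pt[1] < 1e-7 || pt[2] < 1e-7 || pt[1] + pt[2] > 1 - 1e-7)
      return(NULL)
    mg <- max_growth_rate(aplg_params(Pe, phi_a = pt[1], phi_p = pt[2],
                                      coeffs = coeffs))
    # the marginal mode sits at q -> 0, so real-vs-complex character is
    # read from the small-q (reduced two-species) matrix
    os <- outer_stability(pt[1], pt[2], Pe, coeffs)
    data.frame(phi_a = pt[1], phi_p = pt[2], q_star = mg$q_star,
               complex_dominant = os$complex_pair)
  })
  curve <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(list(curve = curve, center = ctr, Pe = Pe),
            class = "aplg_spinodal")
}

#' @export
print.aplg_spinodal <- function(x, ...) {
  cat("APLG spinodal at Pe =", x$Pe, ":", nrow(x$curve), "points\n")
  if (nrow(x$curve) > 0)
    cat("  complex-dominant fraction:",
        signif(mean(x$curve$complex_dominant), 3), "\n")
  invisible(x)
}

#' Bogdanov-Takens points on the spinodal
#'
#' Locates the co-dimension-two points where the dominant stability
#' eigenvalue switches between real and complex along the spinodal arc,
#' by bisection in the ray angle between spinodal points of opposite
#' character.
#'
#' @param Pe Peclet number.
#' @param sp optional precomputed [spinodal()] result.
#' @param coeffs coefficient set.
#' @return data frame of `(phi_a, phi_p)` points (possibly empty).
#' @export
bogdanov_takens_points <- function(Pe, sp = NULL, coeffs = aplg_coeffs()) {
  if (is.null(sp)) sp <- spinodal(Pe, coeffs = coeffs)
  cv <- sp$curve
  n <- nrow(cv)
  if (n == 0 || all(cv$complex_dominant) || !any(cv$complex_dominant))
    return(data.frame(phi_a = numeric(0), phi_p = numeric(0)))
  ctr <- sp$center
  ang <- atan2(cv$phi_p - ctr[2], cv$phi_a - ctr[1])
  point_at <- function(a) {
    u <- c(cos(a), sin(a))
    g1 <- function(r) max_growth_rate(aplg_params(Pe, phi_a = ctr[1] + r * u[1],
                                                  phi_p = max(0, ctr[2] + r * u[2]),
                                                  coeffs = coeffs))
    rlo <- 0; rhi <- 0.05
    while (g1(rhi)$growth > 0) { rhi <- rhi * 1.4; if (rhi > 3) break }
    for (it in 1:45) {
      rmid <- (rlo + rhi) / 2
      if (g1(rmid)$growth > 0) rlo <- rmid else rhi <- rmid
    }
    r <- (rlo + rhi) / 2
    pa <- ctr[1] + r * u[1]; pp <- max(1e-6, ctr[2] + r * u[2])
    list(phi_a = pa, phi_p = pp,
         complex = outer_stability(pa, pp, Pe, coeffs)$complex_pair)
  }
  out <- list()
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (cv$complex_dominant[k] != cv$complex_dominant[k2]) {
      a1 <- ang[k]; a2 <- ang[k2]
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      f1 <- cv$complex_dominant[k]
      for (it in 1:25) {
        am <- a1 + d / 2
        pm <- point_at(am)
        if (pm$complex == f1) { a1 <- am } else { a2 <- a1 + d }
        d <- d / 2
      }
      pm <- point_at(a1 + d / 2)
      out[[length(out) + 1L]] <- data.frame(phi_a = pm$phi_a, phi_p = pm$phi_p)
    }
  }
  if (length(out) == 0) data.frame(phi_a = numeric(0), phi_p = numeric(0))
  else do.call(rbind, out)
}
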