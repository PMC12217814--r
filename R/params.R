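#' Model parameters for the active-passive lattice gas
#'
#' Bundles the four dimensionless parameters that govern the hydrodynamic
#' behavior: the Peclet number `Pe` (self-propulsion strength), the rescaled
#' horizontal domain length `L`, and the active and passive volume fractions
#' `phi_a`, `phi_p`.  Optionally carries the microscopic set
#' (`D_T`, `D_R`, `v0`, `h`, `aspect`) used by the lattice simulator; when the
#' microscopic set is supplied it must be consistent with
#' `Pe = v0 / sqrt(D_T * D_R)` and `L = ell_x * sqrt(D_R / D_T)`.
#' In nondimensional units `D_T = D_R = 1` and `v0 = Pe`.
#'
#' @param Pe Peclet number (>= 0; 0 recovers the three-species symmetric
#'   exclusion process).
#' @param L dimensionless horizontal domain length (> 0).
#' @param phi_a active volume fraction in `[0, 1]`.
#' @param phi_p passive volume fraction in `[0, 1]`; `phi_a + phi_p <= 1`.
#' @param h lattice spacing for particle simulations (rescaled units).
#' @param aspect vertical-to-horizontal domain ratio `ell_y / ell_x` for
#'   lattice runs (default 1/4, the kymograph geometry).
#' @param coeffs transport-coefficient set, see [aplg_coeffs()].
#' @return An object of class `aplg_params`.
#' @examples
#' p <- aplg_params(Pe = 7.5, L = 25, phi_a = 0.36, phi_p = 0.3)
#' p$phi
#' @export
aplg_params <- function(Pe, L = 1, phi_a = 0, phi_p = 0, h = 0.025,
                        aspect = 0.25, coeffs = aplg_coeffs()) {
  stopifnot(is.numeric(Pe), length(Pe) == 1L, Pe >= 0,
            is.numeric(L), L > 0,
            is.numeric(phi_a), is.numeric(phi_p))
  if (phi_a < 0 || phi_p < 0 || phi_a + phi_p > 1 + 1e-12)
    stop("volume fractions must satisfy phi_a, phi_p >= 0 and phi_a + phi_p <= 1")
  if (Pe > 0 && h > 2 / Pe)
    stop("lattice spacing h exceeds 2/Pe: backward jump rate would be negative")
  structure(list(Pe = Pe, L = L, phi_a = phi_a, phi_p = phi_p,
                 phi = phi_a + phi_p, h = h, aspect = aspect,
                 coeffs = coeffs),
            class = "aplg_params")
}

#' @export
print.aplg_params <- function(x, ...) {
  cat("APLG parameters: Pe =", x$Pe, " L =", x$L,
      " phi_a =", x$phi_a, " phi_p =", x$phi_p,
      " (phi =", x$phi, ")\n")
  invisible(x)
}
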