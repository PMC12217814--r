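#' Transport coefficients of the exclusion process
#'
#' The hydrodynamic equations involve the self-diffusion coefficient
#' `d_s(rho)` of a tagged particle in the symmetric simple exclusion process,
#' together with the collective coefficients `D(rho) = (1 - d_s(rho))/rho`
#' and `s(rho) = D(rho) - 1`.  `d_s` has no closed form; by default we use
#' the cubic polynomial approximation
#' \deqn{d_s(\rho) = (1-\rho)\left(1 - \alpha\rho +
#'   \frac{\alpha(2\alpha-1)}{2\alpha+1}\rho^2\right), \quad \alpha = \pi/2 - 1,}
#' which matches the exact value and first derivative at `rho = 0` and
#' `rho = 1`.  The coefficient set is pluggable: any polynomial `d_s` with
#' `d_s(0) = 1` may be supplied through its coefficient vector, and all
#' derived quantities (`D`, `s`, analytic derivatives) follow automatically.
#' `D` is computed by exact polynomial division of `1 - d_s(rho)` by `rho`,
#' so the `rho -> 0` limit `D(0) = -d_s'(0)` is evaluated analytically and
#' never involves division by zero.
#'
#' @param ds_coef coefficients of the polynomial `d_s(rho)` in increasing
#'   powers of `rho`; must satisfy `ds_coef[1] == 1` (i.e. `d_s(0) = 1`).
#' @return An object of class `aplg_coeffs`: a list of vectorized functions
#'   `ds`, `ds1` (first derivative), `ds2` (second derivative), `D`, `D1`,
#'   `s`, `s1`, plus the polynomial coefficient vectors `ds_coef`, `D_coef`
#'   used by the compiled integrator.
#' @examples
#' cf <- aplg_coeffs()
#' cf$ds(0.5)           # about 0.36202
#' cf$D(0)              # 1 + pi/2 - 1 = pi/2
#' @export
aplg_coeffs <- function(ds_coef = NULL) {
  if (is.null(ds_coef)) {
    alpha <- pi / 2 - 1
    beta <- alpha * (2 * alpha - 1) / (2 * alpha + 1)
    # (1 - rho)(1 - alpha rho + beta rho^2), expanded
    ds_coef <- c(1, -(1 + alpha), alpha + beta, -beta)
  }
  stopifnot(is.numeric(ds_coef), abs(ds_coef[1] - 1) < 1e-14)
  # D(rho) = (1 - ds(rho))/rho: since ds(0) = 1, 1 - ds is divisible by rho
  D_coef <- -ds_coef[-1]
  polyval <- function(cf) {
    force(cf)
    function(rho) {
      out <- rep(cf[length(cf)], length(rho))
      if (length(cf) > 1L)
        for (k in seq(length(cf) - 1L, 1L)) out <- out * rho + cf[k]
      out
    }
  }
  polyder <- function(cf) {
    if (length(cf) <= 1L) return(0)
    cf[-1] * seq_len(length(cf) - 1L)
  }
  ds1_coef <- polyder(ds_coef)
  structure(list(
    ds  = polyval(ds_coef),
    ds1 = polyval(ds1_coef),
    ds2 = polyval(polyder(ds1_coef)),
    D   = polyval(D_coef),
    D1  = polyval(polyder(D_coef)),
    s   = function(rho) polyval(D_coef)(rho) - 1,
    s1  = polyval(polyder(D_coef)),
    ds_coef = ds_coef, D_coef = D_coef
  ), class = "aplg_coeffs")
}

#' Self-diffusion coefficient d_s(rho)
#'
#' Evaluates the tagged-particle self-diffusion coefficient of the symmetric
#' exclusion process (polynomial approximation by default), together with its
#' analytic first derivative.
#'
#' @param rho density in `[0, 1]` (vectorized).
#' @param coeffs coefficient set from [aplg_coeffs()].
#' @param deriv if `TRUE`, also return the derivative.
#' @return `d_s(rho)`, or a list `(ds, ds1)` when `deriv = TRUE`.
#' @export
self_diffusion <- function(rho, coeffs = aplg_coeffs(), deriv = FALSE) {
  if (any(rho < 0 | rho > 1)) stop("density out of range [0, 1]")
  if (deriv) list(ds = coeffs$ds(rho), ds1 = coeffs$ds1(rho))
  else coeffs$ds(rho)
}

#' Collective coefficients D(rho) and s(rho)
#'
#' `D(rho) = (1 - d_s(rho))/rho` and `s(rho) = D(rho) - 1`.  The `rho -> 0`
#' limit is taken analytically (polynomial division), so `rho = 0` is valid
#' input.  The identity `rho * D(rho) + d_s(rho) = 1` holds exactly.
#'
#' @inheritParams self_diffusion
#' @return list with components `D` and `s` (vectorized over `rho`).
#' @export
cross_coefficients <- function(rho, coeffs = aplg_coeffs()) {
  if (any(rho < 0 | rho > 1)) stop("density out of range [0, 1]")
  D <- coeffs$D(rho)
  list(D = D, s = D - 1)
}
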