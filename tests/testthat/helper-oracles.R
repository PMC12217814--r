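# Numerical Jacobian oracle: apply the centered-scheme rhs to single-mode
# perturbations of the homogeneous state and project back onto the mode;
# Richardson extrapolation in the grid spacing removes the O(dx^2)
# discretization bias.
oracle_matrix <- function(q, params, N) {
  L <- 2 * pi / q
  g <- pde_grid(L, N = N)
  base <- list(rep(params$phi_a / 2, N), rep(params$phi_a / 2, N),
               rep(params$phi_p, N))
  eps <- 1e-7
  M <- matrix(0i, 3, 3)
  for (j in 1:3) {
    for (part in 1:2) {
      pert <- if (part == 1) cos(q * g$x) else sin(q * g$x)
      fp <- base; fp[[j]] <- fp[[j]] + eps * pert
      fm <- base; fm[[j]] <- fm[[j]] - eps * pert
      dp <- pde_rhs(density_field(fp[[1]], fp[[2]], fp[[3]], g), params,
                    scheme = "centered")
      dm <- pde_rhs(density_field(fm[[1]], fm[[2]], fm[[3]], g), params,
                    scheme = "centered")
      for (s in 1:3) {
        resp <- (list(dp$dp, dp$dm, dp$d0)[[s]] -
                 list(dm$dp, dm$dm, dm$d0)[[s]]) / (2 * eps)
        coefc <- sum(resp * exp(-1i * q * g$x)) * 2 / N
        M[s, j] <- M[s, j] + (if (part == 1) coefc else 1i * coefc) / 2
      }
    }
  }
  M
}

oracle_matrix_rich <- function(q, params) {
  (4 * oracle_matrix(q, params, 1024L) - oracle_matrix(q, params, 512L)) / 3
}
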