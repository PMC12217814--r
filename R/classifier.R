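#' Classifier metrics of a PDE trajectory
#'
#' Computes, per stored frame, the approximate propagation speed
#' `c_tilde(t) = ||dt rho_sigma||_2 / ||dx rho_sigma||_2` (all three species
#' stacked into one vector in numerator and denominator; time derivative by
#' finite differences of consecutive frames, space derivative by centered
#' differences) and the distance from the uniform state
#' `d_H(t) = (sum_sigma ||rho_sigma(.,t) - phi_sigma||_2)^(1/2)` (outer
#' square root over a sum of norms, as the classifier convention).
#' Norms are grid-weighted L2 norms (`sqrt(sum(f^2) dx)`); the weighting
#' cancels in `c_tilde`.
#'
#' @param traj an `aplg_trajectory`.
#' @param params `aplg_params` (defaults to the trajectory's).
#' @return data frame with `time`, `c_tilde`, `d_H` (the first frame has
#'   `c_tilde = NA`; an exactly homogeneous frame yields `c_tilde = 0`).
#' @export
trajectory_metrics <- function(traj, params = traj$params) {
  nt <- length(traj$times)
  if (nt < 2) stop("need at least two frames to difference in time")
  N <- traj$grid$N
  dx <- traj$grid$dx
  ip <- c(2:N, 1L); im <- c(N, 1:(N - 1L))
  nrm <- function(v) sqrt(sum(v^2) * dx)
  ct <- rep(NA_real_, nt)
  dh <- numeric(nt)
  for (k in seq_len(nt)) {
    fr <- cbind(traj$rp[k, ], traj$rm[k, ], traj$r0[k, ])
    dh[k] <- sqrt(nrm(fr[, 1] - params$phi_a / 2) +
                  nrm(fr[, 2] - params$phi_a / 2) +
                  nrm(fr[, 3] - params$phi_p))
    if (k > 1) {
      dtk <- traj$times[k] - traj$times[k - 1]
      dtv <- (fr - cbind(traj$rp[k - 1, ], traj$rm[k - 1, ],
                         traj$r0[k - 1, ])) / dtk
      dxv <- (fr[ip, ] - fr[im, ]) / (2 * dx)
      den <- nrm(c(dxv))
      ct[k] <- if (den < 1e-14) 0 else nrm(c(dtv)) / den
    }
  }
  data.frame(time = traj$times, c_tilde = ct, d_H = dh)
}

#' Classify the long-time state of a trajectory
#'
#' Applies the threshold rules on the observation window
#' `T* = [t* - window, t*]`:
#' \enumerate{
#' \item `sup d_H < 0.05` : homogeneous (H);
#' \item `d_H(t*) >= 0.05` and `sup c_tilde < 0.01` : phase separated (PS);
#' \item additionally `c_tilde(t*) >= 0.01` and `sup |c_tilde'| < 1e-5` :
#'   traveling (T);
#' \item else (`sup |c_tilde'| >= 1e-5`) : counter-propagating (CP).
#' }
#' The default profile uses the printed thresholds (`d_H` 0.05, `c_tilde`
#' 0.01, drift 1e-5, `t* >= 700`, window 500); scaled-down runs may pass a
#' shorter `t_star`/`window` (the drift rule then applies over the shorter
#' window).  `c_tilde'` is computed by smoothed finite differences
#' (five-point moving-average window) to keep sampling noise out of the
#' T/CP decision.
#'
#' @param traj an `aplg_trajectory` (or a metrics data frame from
#'   [trajectory_metrics()]).
#' @param params `aplg_params`; defaults to the trajectory's.
#' @param t_star decision time (default: last frame time; the printed
#'   protocol requires >= 700).
#' @param window observation window length (default `min(500, t_star/2)`).
#' @param thresholds named list overriding `d_H`, `c_tilde`, `drift`.
#' @return object of class `aplg_classification`: `label` in
#'   `c("H", "PS", "T", "CP")` (or `"undetermined"`), plus the metrics and
#'   decision quantities.
#' @export
classify <- function(traj, params = NULL, t_star = NULL, window = NULL,
                     thresholds = list()) {
  if (inherits(traj, "aplg_trajectory")) {
    if (is.null(params)) params <- traj$params
    met <- trajectory_metrics(traj, params)
  } else met <- traj
  th <- utils::modifyList(list(d_H = 0.05, c_tilde = 0.01, drift = 1e-5),
                          thresholds)
  if (is.null(t_star)) t_star <- max(met$time)
  if (is.null(window)) window <- min(500, t_star / 2)
  sel <- met$time >= t_star - window & met$time <= t_star
  m <- met[sel, ]
  if (nrow(m) < 5) stop("too few frames in the observation window")
  iend <- nrow(m)
  # smoothed c_tilde and its drift
  ct <- m$c_tilde
  ct[1] <- ct[2]
  k5 <- stats::filter(ct, rep(1 / 5, 5), sides = 2)
  k5[is.na(k5)] <- ct[is.na(k5)]
  dctdt <- diff(as.numeric(k5)) / diff(m$time)
  sup_dH <- max(m$d_H)
  dH_end <- m$d_H[iend]
  sup_ct <- max(ct, na.rm = TRUE)
  ct_end <- as.numeric(k5[iend])
  sup_drift <- max(abs(dctdt))
  label <- if (sup_dH < th$d_H) "H"
  else if (dH_end >= th$d_H && sup_ct < th$c_tilde) "PS"
  else if (dH_end >= th$d_H && ct_end >= th$c_tilde &&
           sup_drift < th$drift) "T"
  else if (dH_end >= th$d_H && ct_end >= th$c_tilde) "CP"
  else "undetermined"
  structure(list(label = label, metrics = met, t_star = t_star,
                 window = window, sup_d_H = sup_dH, d_H_end = dH_end,
                 sup_c_tilde = sup_ct, c_tilde_end = ct_end,
                 sup_drift = sup_drift, thresholds = th),
            class = "aplg_classification")
}

#' @export
print.aplg_classification <- function(x, ...) {
  cat("APLG steady-state classification:", x$label, "\n")
  cat("  window [", x$t_star - x$window, ",", x$t_star, "]:",
      " sup d_H =", signif(x$sup_d_H, 4),
      " sup c~ =", signif(x$sup_c_tilde, 4),
      " sup |dc~/dt| =", signif(x$sup_drift, 3), "\n")
  invisible(x)
}
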