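#' Initialize a lattice state
#'
#' Independent per-site placement: a right-active particle with probability
#' `phi_a/2`, left-active with `phi_a/2`, passive with `phi_p`, empty
#' otherwise.  Site codes: 0 empty, 1 right-active, 2 left-active, 3 passive.
#'
#' @param params `aplg_params` (uses `phi_a`, `phi_p`, `h`, `L`, `aspect`).
#' @param nx,ny lattice dimensions; default `nx = round(L/h)`,
#'   `ny = round(aspect * nx)`.
#' @param seed integer seed.
#' @return object of class `aplg_lattice`: `occ` (integer matrix), `h`,
#'   `time`, species counts.
#' @export
initialize_lattice <- function(params, nx = NULL, ny = NULL, seed = 1L) {
  h <- params$h
  if (is.null(nx)) nx <- max(4L, as.integer(round(params$L / h)))
  if (is.null(ny)) ny <- max(4L, as.integer(round(params$aspect * nx)))
  set.seed(seed)
  u <- stats::runif(nx * ny)
  occ <- matrix(0L, nx, ny)
  pa2 <- params$phi_a / 2
  occ[u < pa2] <- 1L
  occ[u >= pa2 & u < params$phi_a] <- 2L
  occ[u >= params$phi_a & u < params$phi_a + params$phi_p] <- 3L
  structure(list(occ = occ, h = h, nx = nx, ny = ny, time = 0,
                 counts = c(plus = sum(occ == 1L), minus = sum(occ == 2L),
                            passive = sum(occ == 3L))),
            class = "aplg_lattice")
}

#' @export
print.aplg_lattice <- function(x, ...) {
  cat("APLG lattice:", x$nx, "x", x$ny, " h =", x$h, " t =", x$time, "\n")
  cat("  counts:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' Event rates at a lattice site
#'
#' Enumerates the events available to the particle at `site = c(i, j)` with
#' their rates (nondimensional units): passive particles jump at rate
#' `1/h^2` per neighbor; active particles jump at `1/h^2 + sigma*Pe/(2h)`
#' right, `1/h^2 - sigma*Pe/(2h)` left, `1/h^2` vertically, and flip
#' orientation at rate 1.  Jumps into occupied sites are retained as events
#' (they are aborted when executed), so the rates are configuration
#' independent.
#'
#' @param state `aplg_lattice`.
#' @param site integer pair (1-based).
#' @param params `aplg_params`.
#' @return data frame with columns `event`, `rate`, `blocked`.
#' @export
site_rates <- function(state, site, params) {
  i <- site[1]; j <- site[2]
  code <- state$occ[i, j]
  if (code == 0L) stop("site is empty")
  h <- state$h
  if (params$Pe > 0 && h > 2 / params$Pe)
    stop("h > 2/Pe: negative backward jump rate")
  rj <- 1 / h^2
  wrap <- function(i, n) ((i - 1) %% n) + 1
  nbr <- list(right = c(wrap(i + 1, state$nx), j),
              left  = c(wrap(i - 1, state$nx), j),
              up    = c(i, wrap(j + 1, state$ny)),
              down  = c(i, wrap(j - 1, state$ny)))
  sg <- if (code == 1L) 1 else if (code == 2L) -1 else 0
  drift <- if (code == 3L) 0 else params$Pe / (2 * h)
  rates <- c(right = rj + sg * drift, left = rj - sg * drift,
             up = rj, down = rj)
  blocked <- vapply(nbr, function(s) state$occ[s[1], s[2]] != 0L, TRUE)
  out <- data.frame(event = names(rates), rate = unname(rates),
                    blocked = unname(blocked))
  if (code %in% c(1L, 2L))
    out <- rbind(out, data.frame(event = "flip", rate = 1, blocked = FALSE))
  out
}

#' Exact stochastic simulation of the lattice gas
#'
#' Continuous-time Gillespie simulation with exclusion (blocked jumps are
#' retained as null events, keeping per-particle total rates configuration
#' independent and event selection O(1)).  Species counts are conserved;
#' orientation flips exchange right- and left-active particles.
#'
#' @param state initial `aplg_lattice`.
#' @param params `aplg_params`.
#' @param t_end final time.
#' @param save_times snapshot times for the kymograph record (default 50
#'   evenly spaced).
#' @param seed integer seed.
#' @param track if `TRUE`, also track per-particle net displacements and
#'   flip counts (for diffusion/flip statistics).
#' @return object of class `aplg_lattice_run`: `times`, per-species column
#'   count matrices `kymo_p`, `kymo_m`, `kymo_0` (rows = times, columns = x),
#'   `final` (an `aplg_lattice`), `nevents`, and optionally `dx`, `dy`,
#'   `nflips`.
#' @export
gillespie_run <- function(state, params, t_end, save_times = NULL,
                          seed = 1L, track = FALSE) {
  stopifnot(inherits(state, "aplg_lattice"), t_end > state$time)
  if (is.null(save_times))
    save_times <- seq(state$time, t_end, length.out = 50L)
  set.seed(seed)
  out <- aplg_gillespie_cpp(state$occ, state$h, params$Pe, state$time,
                            save_times, track)
  fin <- state
  fin$occ <- out$occupancy
  fin$time <- t_end
  fin$counts <- c(plus = sum(fin$occ == 1L), minus = sum(fin$occ == 2L),
                  passive = sum(fin$occ == 3L))
  res <- list(times = out$times, kymo_p = out$kymo_p, kymo_m = out$kymo_m,
              kymo_0 = out$kymo_0, final = fin, nevents = out$nevents,
              h = state$h, ny = state$ny, L = state$nx * state$h)
  if (track) { res$dx <- out$dx; res$dy <- out$dy; res$nflips <- out$nflips }
  structure(res, class = "aplg_lattice_run")
}

#' @export
print.aplg_lattice_run <- function(x, ...) {
  cat("APLG lattice run:", length(x$times), "snapshots to t =",
      max(x$times), ";", format(x$nevents, big.mark = ","), "events\n")
  invisible(x)
}

#' Mesoscopic density estimate
#'
#' Converts per-column particle counts into smoothed local volume fractions:
#' for each x, particles within horizontal distance `r` are counted
#' (top-hat window; `kernel = "gaussian"` uses Gaussian weights of standard
#' deviation `r` instead), averaged over the vertical direction and
#' normalized by the window site count.
#'
#' @param run `aplg_lattice_run` (or a single `aplg_lattice` state).
#' @param r smoothing radius in rescaled units (default 0.1); must be at
#'   least one lattice spacing.
#' @param kernel `"tophat"` (default) or `"gaussian"`.
#' @param frame which snapshot (default: last).
#' @return list with `x`, densities `rp`, `rm`, `r0`, `rho`, `rho_a`, `m`.
#' @export
mesoscopic_density <- function(run, r = 0.1, kernel = c("tophat", "gaussian"),
                               frame = NULL) {
  kernel <- match.arg(kernel)
  if (inherits(run, "aplg_lattice")) {
    cnt <- function(code) {
      tabulate(rep(seq_len(run$nx), run$ny)[c(run$occ) == code], run$nx)
    }
    h <- run$h; ny <- run$ny; nx <- run$nx
    kp <- cnt(1L); km <- cnt(2L); k0 <- cnt(3L)
  } else {
    h <- run$h; ny <- run$ny
    nx <- ncol(run$kymo_p)
    if (is.null(frame)) frame <- nrow(run$kymo_p)
    kp <- run$kymo_p[frame, ]; km <- run$kymo_m[frame, ]; k0 <- run$kymo_0[frame, ]
  }
  if (r < h) stop("smoothing radius r must be at least the lattice spacing h")
  w <- as.integer(floor(r / h))
  offs <- -w:w
  wt <- if (kernel == "tophat") rep(1, length(offs)) else
    exp(-0.5 * (offs * h / r)^2)
  sm <- function(cnt) {
    out <- numeric(nx)
    for (k in seq_along(offs)) {
      out <- out + wt[k] * cnt[((seq_len(nx) - 1 + offs[k]) %% nx) + 1]
    }
    out / (sum(wt) * ny)
  }
  rp <- sm(kp); rm <- sm(km); r0 <- sm(k0)
  list(x = (seq_len(nx) - 0.5) * h, rp = rp, rm = rm, r0 = r0,
       rho = rp + rm + r0, rho_a = rp + rm, m = rp - rm)
}
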