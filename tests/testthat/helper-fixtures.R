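# Shared small fixtures built in code.

ps_point_params <- function() aplg_params(20, L = 2, phi_a = 0.5, phi_p = 0.1)
cp_point_params <- function() aplg_params(20, L = 2, phi_a = 0.3, phi_p = 0.6)
tw_point_params <- function() aplg_params(7.5, L = 25, phi_a = 0.36, phi_p = 0.3)

# Relaxed phase-separated state at the strong-activity PS fixture (cached).
relaxed_ps_state <- local({
  cache <- NULL
  function(dx = 0.01, t_end = 60) {
    if (!is.null(cache)) return(cache)
    p <- ps_point_params()
    g <- pde_grid(2, dx = dx)
    ic <- make_initial_condition(p, g, "noise", seed = 3)
    tr <- integrate_pde(ic, p, t_end = t_end, dt_save = t_end / 40,
                        scheme = "centered")
    cache <<- list(field = frame_field(tr), params = p, traj = tr)
    cache
  }
})

# Traveling attractor at the reference traveling-wave fixture (cached).
traveling_attractor <- local({
  cache <- NULL
  function(t_end = 500) {
    if (!is.null(cache)) return(cache)
    p <- tw_point_params()
    g <- pde_grid(25, dx = 0.05)
    ic <- make_initial_condition(p, g, "left", mode_amplitude = 0.05,
                                 seed = 11, k_mode = 1L, force_mode = TRUE)
    tr <- integrate_pde(ic, p, t_end = t_end, dt_save = 1)
    cache <<- list(traj = tr, params = p)
    cache
  }
})
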