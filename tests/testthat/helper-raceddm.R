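# shared fixtures: noise-free parameter sets use a vanishing diffusion
# constant so trajectories are deterministic to numerical tolerance
noise_free <- function(a, tr, v_e, v_b = NA_real_, xb = 0,
                       sso = NA_real_) {
  process_params(a = a, tr = tr, v_e = v_e, v_b = v_b, xb = xb,
                 sigma = 1e-9, sso = sso)
}

dpm_truth <- function() preset_params("dpm")

reactive_design_small <- function() {
  task_design("reactive", n_go = 40, n_stop_per_ssd = 8)
}

proactive_design_small <- function() {
  task_design("proactive", n_per_cue = 30)
}

# light optimizer settings for smoke/determinism tests (not recovery)
tiny_fit_config <- function(seed = 1L) {
  fit_config(n_sim_per_eval = 1500L, n_sim_search = 800L, n_screen = 10L,
             n_multistart = 2L, basin_max_iter = 5L,
             basin_fail_limit = 3L, basin_local_maxit = 30L,
             simplex_maxit = 60L, nm_restarts = 1L, n_restarts = 3L,
             dt = 0.0025, seed = seed, profile_grid = FALSE)
}
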