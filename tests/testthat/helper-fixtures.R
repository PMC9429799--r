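# Small fixtures built in code, shared across test files.

tiny_trials <- function() {
  data.frame(
    participant_id = "p01",
    inspection_identity = c("face", "face", "noise", "noise"),
    preview = c("preview", "outline", "preview", "outline"),
    choice = c("face", "noise", "face", "noise"),
    fixation_duration_ms = c(350, 420, 380, 510),
    stringsAsFactors = FALSE)
}

small_experiment <- function(n_participants = 2, trials_per_condition = 64,
                             seed = 7, ...) {
  cfg <- synthetic_config(n_participants = n_participants,
                          trials_per_condition = trials_per_condition,
                          n_stimuli_per_category = 32, ...)
  simulate_experiment(cfg, seed = seed)
}

# fit options used by speed-sensitive tests: reduced quadrature and
# evaluation points, chained restarts (see methods vignette)
study_fit_options <- function(seed = 1L, maxit = 700) {
  fit_options(n_restarts = 3, n_sv = 4, n_sz = 1, n_st0 = 2,
              max_points = 32, maxit = maxit, seed = seed)
}
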