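# Synthetic dual-saccade experiments.
#
# The generator reproduces the study design: a 2 x 2 within-participant
# design (inspection-target identity x peripheral preview), 256 trials per
# condition (1024 per participant), 128 stimuli per category counterbalanced
# so that each stimulus serves four times as inspection target and eight
# times as selection target, with conditions randomly interleaved.  Choices
# and fixation durations are produced by the Wiener diffusion process whose
# condition-wise drift rates and non-decision times default to the fitted
# group means of the study's winning model variant; a population layer adds
# between-participant parameter variability.

#' Configuration of the synthetic experiment generator
#'
#' Defaults encode the study conditions: 36 participants, 256 trials per
#' condition, 128 stimuli per category.  The generating model is the variant
#' in which drift rate and non-decision time vary across conditions while
#' boundary separation, starting point and the variability parameters are
#' shared; drift-rate means are 0.607 (FP), 0.320 (FO), -0.024 (NP), 0.096
#' (NO) and non-decision-time means 208, 211, 183, 192 ms.  The shared
#' parameters (a = 1, zr = 0.5, sv = 0.3, sz = 0.1, st0 = 80 ms) and the
#' between-participant SDs (v 0.25, t0 30 ms, a 0.15) are documented
#' generator choices.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Trials in each of the four conditions.
#' @param population_means Data frame with columns `condition`, `a`, `zr`,
#'   `v`, `t0`, `sv`, `sz`, `st0` (seconds), one row per condition.
#' @param population_sds Named numeric vector of between-participant SDs of
#'   the shared offset for each parameter (drawn once per participant and
#'   added to all conditions).
#' @param condition_sds Named numeric vector of SDs of additional
#'   condition-specific participant offsets, applied to parameters the
#'   generating variant varies across conditions.  The defaults are sized so
#'   the total per-condition between-participant SD (sqrt of shared^2 +
#'   specific^2) reproduces the dispersion of the fitted drift rates
#'   (per-condition SD about 0.8) and non-decision times (about 110 ms)
#'   observed across the study's participants.
#' @param n_stimuli_per_category Stimuli per category (faces, noise patches).
#' @param seed Master seed; per-participant substream seeds are derived from
#'   it deterministically.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 36,
                             trials_per_condition = 256,
                             population_means = default_population_means(),
                             population_sds = c(a = 0.15, zr = 0, v = 0.25,
                                                t0 = 0.030, sv = 0, sz = 0,
                                                st0 = 0),
                             condition_sds = c(v = 0.75, t0 = 0.105),
                             n_stimuli_per_category = 128,
                             seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            n_stimuli_per_category >= 2)
  sds <- c(a = 0, zr = 0, v = 0, t0 = 0, sv = 0, sz = 0, st0 = 0)
  sds[names(population_sds)] <- population_sds
  csds <- c(a = 0, zr = 0, v = 0, t0 = 0, sv = 0, sz = 0, st0 = 0)
  csds[names(condition_sds)] <- condition_sds
  if (any(sds < 0) || any(csds < 0))
    stop("synthetic_config: SDs must be >= 0", call. = FALSE)
  pm <- as.data.frame(population_means)
  stopifnot(all(c("condition", PARAM_NAMES) %in% names(pm)),
            setequal(pm$condition, CONDITIONS))
  for (i in seq_len(nrow(pm))) validate_ddm_params(pm[i, PARAM_NAMES])
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 population_means = pm,
                 population_sds = sds,
                 condition_sds = csds,
                 n_stimuli_per_category = as.integer(n_stimuli_per_category),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_population_means <- function() {
  data.frame(condition = CONDITIONS,
             a = 1.0, zr = 0.5,
             v = c(0.607, 0.320, -0.024, 0.096),
             t0 = c(0.208, 0.211, 0.183, 0.192),
             sv = 0.3, sz = 0.1, st0 = 0.080)
}

# Deterministic substream seeds from a master seed.
derive_seeds <- function(master, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Build the counterbalanced trial design
#'
#' Per participant: `trials_per_condition` trials of each of FP/FO/NP/NO,
#' randomly interleaved; inspection location (up/down) and face side
#' (left/right) balanced within condition; each stimulus used equally often
#' as inspection target (within its identity conditions) and as selection
#' target, and never in two roles within one trial.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed (defaults to the config's master seed).
#' @return Data frame with one row per trial: `participant_id`,
#'   `trial_index`, `condition`, `inspection_identity`, `preview`,
#'   `inspection_location`, `face_side`, `inspection_stimulus`,
#'   `selection_face`, `selection_noise`.
#' @export
build_design <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  tpc <- config$trials_per_condition
  nstim <- config$n_stimuli_per_category
  if ((2L * tpc) %% nstim != 0L)
    stop(sprintf(paste0(
      "build_design: infeasible counterbalancing: 2 x trials_per_condition ",
      "(%d) must be a multiple of n_stimuli_per_category (%d) so that every ",
      "stimulus serves equally often as inspection target"),
      2L * tpc, nstim), call. = FALSE)
  if (tpc %% 2L != 0L)
    stop("build_design: trials_per_condition must be even to balance ",
         "inspection location and face side within condition", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  seeds <- derive_seeds(seed, config$n_participants)
  out <- vector("list", config$n_participants)
  faces <- sprintf("face_%03d", seq_len(nstim))
  noises <- sprintf("noise_%03d", seq_len(nstim))
  for (p in seq_len(config$n_participants)) {
    set.seed(seeds[p])
    cond <- sample(rep(CONDITIONS, each = tpc))
    n <- length(cond)
    loc <- character(n); side <- character(n)
    for (cc in CONDITIONS) {
      idx <- which(cond == cc)
      loc[idx] <- sample(rep(c("up", "down"), tpc / 2))
      side[idx] <- sample(rep(c("left", "right"), tpc / 2))
    }
    identity <- ifelse(substr(cond, 1, 1) == "F", "face", "noise")
    insp <- character(n)
    insp[identity == "face"] <- sample(rep(faces, (2L * tpc) / nstim))
    insp[identity == "noise"] <- sample(rep(noises, (2L * tpc) / nstim))
    sel_face <- resolve_selection(sample(rep(faces, (4L * tpc) / nstim)),
                                  insp, identity == "face")
    sel_noise <- resolve_selection(sample(rep(noises, (4L * tpc) / nstim)),
                                   insp, identity == "noise")
    out[[p]] <- data.frame(
      participant_id = sprintf("p%02d", p),
      trial_index = seq_len(n),
      condition = cond,
      inspection_identity = identity,
      preview = ifelse(substr(cond, 2, 2) == "P", "preview", "outline"),
      inspection_location = loc,
      face_side = side,
      inspection_stimulus = insp,
      selection_face = sel_face,
      selection_noise = sel_noise,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Deterministically repair clashes between the inspection stimulus and the
# same-category selection stimulus by pairwise swaps.
resolve_selection <- function(sel, insp, same_category) {
  conflict <- which(same_category & sel == insp)
  n <- length(sel)
  for (i in conflict) {
    if (sel[i] != insp[i] || !same_category[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      ok_i <- !same_category[i] || sel[j] != insp[i]
      ok_j <- !same_category[j] || sel[i] != insp[j]
      if (ok_i && ok_j) {
        tmp <- sel[i]; sel[i] <- sel[j]; sel[j] <- tmp
        break
      }
    }
  }
  if (any(same_category & sel == insp))
    stop("build_design: could not resolve stimulus-role conflicts",
         call. = FALSE)
  sel
}

#' Draw participant-level diffusion parameters
#'
#' Participant parameters are the population condition means plus normal
#' participant offsets.  For parameters the generating variant holds
#' constant across conditions (equal population means), one shared offset is
#' drawn per participant, so those parameters stay constant within a
#' participant; parameters the generating variant varies (drift rate and
#' non-decision time under the default generator) receive the shared offset
#' plus a condition-specific offset with SD `condition_sds`, giving each
#' participant an idiosyncratic condition pattern around the population
#' means -- reproducing the large interindividual differences in the modeled
#' data.  Draws violating the legality constraints (`a > 0`,
#' `zr +/- sz/2` inside (0,1), `t0 >= st0/2`) are rejected and redrawn; an
#' overall rejection rate above 50% raises an error advising narrower SDs.
#'
#' @inheritParams build_design
#' @return Data frame with one row per participant x condition and columns
#'   `participant_id`, `condition`, and the seven parameters (seconds).
#' @export
sample_population_params <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  seeds <- derive_seeds(seed + 1L, config$n_participants)
  pm <- config$population_means
  pm <- pm[match(CONDITIONS, pm$condition), ]
  sds <- config$population_sds
  varied <- vapply(PARAM_NAMES, function(nm)
    diff(range(pm[[nm]])) > 0, TRUE)
  csds <- config$condition_sds
  draw_one <- function() {
    par <- pm[, PARAM_NAMES]
    for (nm in PARAM_NAMES) {
      par[[nm]] <- par[[nm]] + rnorm(1, 0, sds[[nm]])
      if (varied[[nm]] && csds[[nm]] > 0)
        par[[nm]] <- par[[nm]] + rnorm(4, 0, csds[[nm]])
    }
    par
  }
  is_legal <- function(par)
    all(par$a > 0, par$sv >= 0, par$sz >= 0, par$st0 >= 0,
        par$zr - par$sz / 2 > 0, par$zr + par$sz / 2 < 1,
        par$t0 - par$st0 / 2 >= 0)
  # probe the rejection rate once, deterministically, before sampling
  set.seed(derive_seeds(seed + 3L, 1L))
  probe_illegal <- mean(!vapply(seq_len(200), function(i)
    is_legal(draw_one()), TRUE))
  if (probe_illegal > 0.5)
    stop(sprintf(paste0("sample_population_params: %.0f%% of parameter ",
                        "draws violate the legality constraints; narrow ",
                        "the population SDs"), 100 * probe_illegal),
         call. = FALSE)
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    set.seed(seeds[p])
    repeat {
      par <- draw_one()
      if (is_legal(par)) break
    }
    out[[p]] <- cbind(data.frame(participant_id = sprintf("p%02d", p),
                                 condition = CONDITIONS,
                                 stringsAsFactors = FALSE),
                      par)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a session from a design and participant parameters
#'
#' Runs the Wiener diffusion simulator trial by trial under each trial's
#' condition parameters; the upper boundary maps to `choice = "face"`, and
#' the fixation duration is decision time plus non-decision time, in ms.
#'
#' @param params Participant x condition parameter table as returned by
#'   [sample_population_params()].
#' @param design Trial design as returned by [build_design()].
#' @param seed Seed for the trial-level noise.
#' @param dt Simulator step size in seconds.
#' @return A `ddm_session`.
#' @export
simulate_session <- function(params, design, seed = 1L, dt = 5e-4) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  participants <- unique(design$participant_id)
  seeds <- derive_seeds(seed + 2L, length(participants))
  rows <- vector("list", length(participants))
  for (ip in seq_along(participants)) {
    pid <- participants[ip]
    set.seed(seeds[ip])
    d <- design[design$participant_id == pid, ]
    choice <- character(nrow(d)); rt <- numeric(nrow(d))
    for (cc in CONDITIONS) {
      idx <- which(d$condition == cc)
      if (length(idx) == 0) next
      pr <- params[params$participant_id == pid & params$condition == cc, ]
      if (nrow(pr) != 1)
        stop("simulate_session: missing parameters for ", pid, "/", cc,
             call. = FALSE)
      pp <- ddm_params(a = pr$a, zr = pr$zr, v = pr$v, t0 = pr$t0,
                       sv = pr$sv, sz = pr$sz, st0 = pr$st0)
      sim <- simulate_trials(length(idx), pp, dt = dt)
      choice[idx] <- ifelse(sim$upper, "face", "noise")
      rt[idx] <- sim$rt
    }
    rows[[ip]] <- data.frame(
      participant_id = d$participant_id,
      inspection_identity = d$inspection_identity,
      preview = d$preview,
      condition = d$condition,
      choice = choice,
      fixation_duration_ms = rt * 1000,
      inspection_location = d$inspection_location,
      face_side = d$face_side,
      trial_index = d$trial_index,
      stringsAsFactors = FALSE)
  }
  new_session(do.call(rbind, rows),
              metadata = list(generator = "wiener_ddm", seed = seed))
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: builds the design, draws participant parameters and
#' simulates the session, all from one master seed, returning the ground
#' truth alongside the data for parameter-recovery studies.
#'
#' @inheritParams build_design
#' @param dt Simulator step size in seconds.
#' @return A list with elements `session`, `params` (generating truth),
#'   `design`, `config`, `seed`.
#' @examples
#' cfg <- synthetic_config(n_participants = 2, trials_per_condition = 64,
#'                         n_stimuli_per_category = 32)
#' exp <- simulate_experiment(cfg, seed = 7)
#' exp$session
#' @export
simulate_experiment <- function(config, seed = config$seed, dt = 5e-4) {
  design <- build_design(config, seed)
  params <- sample_population_params(config, seed)
  session <- simulate_session(params, design, seed, dt = dt)
  session$metadata$config <- config
  session$metadata$seed <- seed
  list(session = session, params = params, design = design, config = config,
       seed = seed)
}
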