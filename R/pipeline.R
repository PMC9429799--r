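# End-to-end analysis pipeline: session -> descriptive/inferential group
# statistics -> SMART time-course contrasts -> eight-variant diffusion fits
# -> model selection -> parameter effects.  Stage order mirrors the study's
# results: selection behavior first, then time courses, then modeling.

#' Pipeline configuration
#'
#' Bundles the stage configurations and one master seed.  Either a trial CSV
#' (`input_csv`) or a synthetic-generator configuration must be supplied.
#'
#' @param synthetic A [synthetic_config()] used when no input file is given.
#' @param input_csv Optional path to a trial table; read with `dialect`.
#' @param dialect A [trial_dialect()] for the input file.
#' @param fit A [fit_options()].
#' @param smart A [smart_config()].
#' @param trim Outlier fraction for [trim_outliers()] before fitting
#'   (0 = fit the full data, the study's primary choice).
#' @param run_fits Whether to run the (expensive) eight-variant fitting
#'   stage.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_csv = NULL, dialect = trial_dialect(),
                            fit = fit_options(), smart = smart_config(),
                            trim = 0, run_fits = TRUE, seed = 1L) {
  structure(list(synthetic = synthetic, input_csv = input_csv,
                 dialect = dialect, fit = fit, smart = smart, trim = trim,
                 run_fits = run_fits, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' The four selection time-course contrasts
#'
#' Face-vs-noise inspection within outline and within preview, and
#' preview-vs-outline within face and within noise inspection.
#'
#' @return Named list of condition pairs.
#' @export
default_contrasts <- function() {
  list(face_vs_noise_outline = list(a = "FO", b = "NO"),
       face_vs_noise_preview = list(a = "FP", b = "NP"),
       preview_vs_outline_face = list(a = "FP", b = "FO"),
       preview_vs_outline_noise = list(a = "NP", b = "NO"))
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes: load or simulate trials -> session validation -> group
#' statistics (fixation-duration 2x2x2 ANOVA, face-choice 2x2 ANOVA and
#' per-condition Wilcoxon tests against chance) -> the four SMART contrasts
#' -> per-participant eight-variant fits -> information-weight model
#' selection -> parameter effects of the winning variant.  All tables are
#' written as CSV/JSON under `out_dir` together with a run manifest listing
#' every artifact, the configuration digest and seeds; a failing stage
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  artifacts <- character(0)
  timing <- list()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timing[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    message(sprintf("[pipeline] %s done (%.1fs)", name, timing[[name]]))
    res
  }

  # -- data -----------------------------------------------------------
  truth <- NULL
  session <- stage("data", {
    if (!is.null(config$input_csv)) {
      read_trials(config$input_csv, config$dialect)
    } else {
      ex <- simulate_experiment(config$synthetic, seed = config$seed)
      truth <- ex$params
      emit_csv(ex$params, "generating_parameters.csv")
      ex$session
    }
  })
  emit_csv(session$trials, "trials.csv")
  report <- stage("validate", validate_session(session))
  emit_json(list(n_trials = report$n_trials,
                 condition_counts = as.data.frame.matrix(
                   as.matrix(report$condition_counts)),
                 duration_range_ms = report$duration_range,
                 empty_cells = report$empty_cells),
            "session_report.json")
  if (config$trim > 0) session <- trim_outliers(session, config$trim)

  # -- group statistics ------------------------------------------------
  stats_out <- stage("group_stats", {
    fix_tab <- cell_means(session, "fixation_duration", "2x2x2")
    fix_anova <- rm_anova(fix_tab, na.action = "exclude")
    ch_tab <- cell_means(session, "face_choice", "2x2")
    ch_anova <- rm_anova(ch_tab, na.action = "exclude")
    wil <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc) {
      x <- ch_tab$cells$value[condition_code(
        ch_tab$cells$inspection_identity, ch_tab$cells$preview) == cc]
      wilcoxon_signed_rank(x[!is.na(x)], 0.5)
    })
    list(fix_anova = fix_anova, ch_anova = ch_anova, wilcoxon = wil,
         ch_tab = ch_tab)
  })
  eff <- rbind(cbind(measure = "fixation_duration_2x2x2",
                     stats_out$fix_anova$effects),
               cbind(measure = "face_choice_2x2",
                     stats_out$ch_anova$effects))
  emit_csv(eff, "group_effects.csv")
  emit_json(lapply(stats_out$wilcoxon, function(w)
    w[c("W", "n", "p", "method")]), "choice_vs_chance_wilcoxon.json")

  # -- SMART time courses ----------------------------------------------
  smart_out <- stage("smart", {
    lapply(default_contrasts(), function(ct)
      smart_contrast(session, ct$a, ct$b, config$smart))
  })
  cl <- do.call(rbind, lapply(names(smart_out), function(nm) {
    res <- smart_out[[nm]]
    if (nrow(res$clusters) == 0)
      return(data.frame(contrast = nm, start_ms = NA, end_ms = NA,
                        strength = NA, p = NA, significant = FALSE,
                        t_crit = res$t_crit))
    cbind(contrast = nm, res$clusters, t_crit = res$t_crit)
  }))
  emit_csv(cl, "smart_clusters.csv")
  curves <- do.call(rbind, lapply(names(smart_out), function(nm) {
    res <- smart_out[[nm]]
    data.frame(contrast = nm, time_ms = res$grid, group_a = res$group_a,
               group_b = res$group_b, ci_halfwidth = res$ci_halfwidth)
  }))
  emit_csv(curves, "smart_timecourses.csv")

  # -- diffusion modeling ----------------------------------------------
  manifest_fits <- NULL
  if (config$run_fits) {
    fits <- stage("ddm_fits", {
      lapply(stats::setNames(session$participants, session$participants),
             function(pid)
        fit_all_variants(session$trials[session$trials$participant_id == pid,
                                        ],
                         config$fit))
    })
    fit_rows <- do.call(rbind, lapply(names(fits), function(pid) {
      do.call(rbind, lapply(fits[[pid]], function(f)
        cbind(participant_id = pid, variant = f$variant$label, f$params,
              ks = unname(f$ks_by_condition), objective = f$objective,
              log_likelihood = f$log_likelihood, bic = f$bic, k = f$k)))
    }))
    emit_csv(fit_rows, "variant_fits.csv")
    weights <- t(vapply(fits, function(pf)
      information_weights(vapply(pf, `[[`, 0.0, "bic")),
      numeric(length(all_variants()))))
    sel <- stage("model_selection", select_model(weights))
    emit_csv(cbind(participant_id = rownames(weights),
                   as.data.frame(weights)), "information_weights.csv")
    emit_json(list(selected_variant = sel$variant$label,
                   k = sel$variant$k,
                   mean_weights = sel$mean_weights), "model_selection.json")
    par_eff <- stage("parameter_effects", {
      win <- sel$variant$label
      pe_rows <- do.call(rbind, lapply(names(fits), function(pid)
        cbind(participant_id = pid, fits[[pid]][[win]]$params)))
      parameter_effects(pe_rows)
    })
    pe_tab <- do.call(rbind, lapply(names(par_eff), function(nm)
      cbind(parameter = nm, par_eff[[nm]]$anova$effects)))
    emit_csv(pe_tab, "parameter_effects.csv")
    manifest_fits <- list(selected_variant = sel$variant$label)
  }

  manifest <- list(
    created = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    config_digest = config_digest(config),
    input = if (is.null(config$input_csv)) "synthetic" else config$input_csv,
    n_participants = length(session$participants),
    n_trials = nrow(session$trials),
    selection = manifest_fits,
    artifacts = artifacts,
    timing_s = timing,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("saccadeddm")))
  emit_json(manifest, "manifest.json")
  invisible(manifest)
}
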