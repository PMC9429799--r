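#!/usr/bin/env Rscript
# Stage 4: diffusion modeling.  Eight model variants (every subset of
# {v, a, t0} free across conditions) are fitted per participant by the KS
# criterion; BIC information weights are averaged across participants to
# select the winning variant.  A 12-participant subset keeps this stage to
# a few minutes on one CPU; the selection is about the variant ranking, not
# about per-participant precision.

library(saccadeddm)

out <- "results/analysis"
session <- read_trials(file.path(out, "trials.csv"))
pids <- head(session$participants, 12)
opts <- fit_options(n_restarts = 3, n_sv = 4, n_sz = 1, n_st0 = 2,
                    max_points = 32, maxit = 700, seed = 2026L)

fits <- lapply(stats::setNames(pids, pids), function(pid) {
  f <- fit_all_variants(
    session$trials[session$trials$participant_id == pid, ], opts)
  cat(sprintf("%s: best objective %.4f (%s), best BIC %s\n", pid,
              min(vapply(f, `[[`, 0, "objective")),
              names(which.min(vapply(f, `[[`, 0, "objective"))),
              names(which.min(vapply(f, `[[`, 0, "bic")))))
  f
})

fit_rows <- do.call(rbind, lapply(names(fits), function(pid)
  do.call(rbind, lapply(fits[[pid]], function(f)
    cbind(participant_id = pid, variant = f$variant$label, f$params,
          ks = unname(f$ks_by_condition), objective = f$objective,
          log_likelihood = f$log_likelihood, bic = f$bic, k = f$k)))))
readr::write_csv(fit_rows, file.path(out, "variant_fits.csv"))

W <- t(vapply(fits, function(pf)
  information_weights(vapply(pf, `[[`, 0.0, "bic")), numeric(8)))
readr::write_csv(cbind(participant_id = rownames(W), as.data.frame(W)),
                 file.path(out, "information_weights.csv"))
sel <- select_model(W)
cat("\nmean information weights:\n")
print(sel$mean_weights, digits = 3)
cat("selected variant:", sel$variant$label, "\n")
jsonlite::write_json(list(selected_variant = sel$variant$label,
                          mean_weights = sel$mean_weights),
                     file.path(out, "model_selection.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
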