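#!/usr/bin/env Rscript
# Stage 5: statistics on the fitted parameters of the selected variant:
# condition means/SEs, 2x2 repeated-measures ANOVAs on drift rate and
# non-decision time, per-condition t tests of drift against zero, and a
# comparison with the generating parameters.

library(saccadeddm)

out <- "results/analysis"
sel <- jsonlite::read_json(file.path(out, "model_selection.json"))
fits <- readr::read_csv(file.path(out, "variant_fits.csv"),
                        show_col_types = FALSE)
win <- fits[fits$variant == sel$selected_variant, ]
cat("selected variant:", sel$selected_variant, "|", nrow(win) / 4,
    "participants\n\n")

pe <- parameter_effects(as.data.frame(win))
print(pe)
cat("\nDrift rate vs 0 by condition:\n")
for (cc in names(pe$v$t_vs_zero)) {
  tz <- pe$v$t_vs_zero[[cc]]
  cat(sprintf("  %s: mean %.3f, t(%d) = %.2f, p = %.4f\n", cc, tz$mean,
              tz$df, tz$t, tz$p))
}

truth <- readr::read_csv(file.path(out, "generating_parameters.csv"),
                         show_col_types = FALSE)
truth <- truth[truth$participant_id %in% win$participant_id, ]
for (nm in intersect(c("v", "t0"), names(pe))) {
  tru <- tapply(truth[[nm]], truth$condition, mean)
  est <- stats::setNames(pe[[nm]]$means$mean, pe[[nm]]$means$condition)
  cat(sprintf("\n%s: generating condition means vs recovered:\n", nm))
  print(round(rbind(generating = tru[names(est)], recovered = est), 3))
}

pe_tab <- do.call(rbind, lapply(names(pe), function(nm)
  cbind(parameter = nm, pe[[nm]]$anova$effects)))
readr::write_csv(pe_tab, file.path(out, "parameter_effects.csv"))
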