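#!/usr/bin/env Rscript
# Stage 2: group-level behavior.  Fixation durations enter a 2x2x2
# repeated-measures ANOVA (inspection identity x preview x selection
# outcome); face-choice proportions enter a 2x2 ANOVA and per-condition
# Wilcoxon signed-rank tests against chance (0.5).

library(saccadeddm)

out <- "results/analysis"
session <- read_trials(file.path(out, "trials.csv"))

fix_tab <- cell_means(session, "fixation_duration", "2x2x2")
cat(sprintf("participants with empty cells (listwise excluded): %d\n",
            length(unique(fix_tab$missing$participant))))
fix_anova <- rm_anova(fix_tab, na.action = "exclude")
cat("\nFixation durations, 2x2x2 ANOVA:\n")
print(fix_anova)

ch_tab <- cell_means(session, "face_choice", "2x2")
ch_anova <- rm_anova(ch_tab, na.action = "exclude")
cat("\nFace-choice proportion, 2x2 ANOVA:\n")
print(ch_anova)

cat("\nChoice vs chance (Wilcoxon signed-rank, 0.5):\n")
for (cc in c("FP", "FO", "NP", "NO")) {
  idx <- paste0(ifelse(ch_tab$cells$inspection_identity == "face", "F", "N"),
                ifelse(ch_tab$cells$preview == "preview", "P", "O")) == cc
  w <- wilcoxon_signed_rank(ch_tab$cells$value[idx], 0.5)
  cat(sprintf("  %s: W = %.1f, n = %d, p = %.4f (%s)\n",
              cc, w$W, w$n, w$p, w$method))
}

eff <- rbind(cbind(measure = "fixation_duration_2x2x2", fix_anova$effects),
             cbind(measure = "face_choice_2x2", ch_anova$effects))
readr::write_csv(eff, file.path(out, "group_effects.csv"))
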