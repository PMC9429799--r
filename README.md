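# saccadeddm

Drift-diffusion and smoothed time-course analysis of dual-saccade target
selection.

## The problem

In dual-saccade choice experiments an observer first fixates an
*inspection target* — a face or a phase-scrambled noise patch, either
previewed peripherally or hidden behind an elliptic outline — and then
makes a second saccade to one of two peripheral *selection targets* (one
face, one noise patch).  Each trial yields a choice (which target class
was selected) and a fixation duration on the inspection target, treated as
the reaction time of the selection decision.  The scientific question is
whether foveal processing of the inspected target and its peripheral
preview merely delay the onset of the selection process or interfere with
the selection itself.

`saccadeddm` implements the complete analysis chain for such data, plus a
synthetic experiment generator so every stage is testable without any
download:

* **Wiener diffusion core** — first-passage-time densities and CDFs for
  two absorbing boundaries with across-trial variability in drift
  (`Normal(v, sv)`), starting point (`Uniform(zr ± sz/2)`) and
  non-decision time (`Uniform(t0 ± st0/2)`), plus an exact-crossing
  trial simulator.  Choices and signed response times
  (`+RT` for face, `−RT` for noise choices) follow the defective
  distributions of the two boundaries.
* **Eight-variant model family** — every subset of `{v, a, t0}` may vary
  across the four conditions (FP, FO, NP, NO = inspection identity ×
  preview); `zr, sv, sz, st0` are always shared.  Fits minimize the
  trial-count-weighted Kolmogorov–Smirnov distance per participant;
  variants are compared by BIC information weights
  `w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2)`.
* **SMART time courses** — per-participant Gaussian kernel smoothing
  (SD 48 ms) of the choice outcome over fixation duration on a 1-ms grid
  (100–750 ms), density-weighted group aggregation, and cluster-based
  permutation inference (1000 permutations, cluster strength = summed
  |t|, `t_crit` = 95th percentile of permuted maxima).
* **Group statistics** — all-two-level repeated-measures ANOVAs computed
  exactly via within-participant contrasts (`F = t²`, df = (1, n−1)),
  paired/one-sample t tests, and an exact Wilcoxon signed-rank test.

## Worked example

Simulate a small experiment at the study's generating values, fit the
drift/non-decision-time variant to one participant, and test a time-course
contrast:

```r
library(saccadeddm)

cfg <- synthetic_config(n_participants = 3, trials_per_condition = 256)
ex  <- simulate_experiment(cfg, seed = 21)
ex$session
#> Dual-saccade session: 3072 trials, 3 participant(s)
#>   trials per condition: FO=768, FP=768, NO=768, NP=768

fit <- fit_variant(ex$session$trials[ex$session$trials$participant_id == "p01", ],
                   variant_spec(c("v", "t0")),
                   fit_options(fast = TRUE))
fit$params[, c("condition", "v", "t0")]
#>   condition      v    t0       (generating truth for p01:
#> 1        FP  1.708 0.052        v  1.478, 0.293, -0.994, -0.275;
#> 2        FO  0.377 0.125        t0 0.074, 0.135,  0.207,  0.164)
#> 3        NP -0.845 0.214
#> 4        NO -0.125 0.170
```

Numbers printed by the full pipeline (`analysis/` scripts, 36 simulated
participants, seed 2026): the face-choice 2×2 ANOVA shows the inspection
identity effect (`F(1,35) = 9.61, p = 0.004`), choices are above chance
only when a face is inspected (Wilcoxon `p = 0.0001` for FP, `p = 0.02`
for FO, `p > 0.18` for NP/NO), model selection over 12 participants picks
the `t0+v` variant (mean information weight 0.51 vs 0.32 for the runner-up
`t0`), and the per-condition drift means are recovered within 0.09 of the
generating values with drift different from zero only for face inspection
(`t(11) = 3.95, p = 0.002` in FP).

The numbered scripts run the stages in order:

```sh
Rscript analysis/01_simulate.R          # design + diffusion generator
Rscript analysis/02_descriptives.R      # fixation/choice ANOVAs, Wilcoxon
Rscript analysis/03_smart.R             # four SMART contrasts
Rscript analysis/04_fit_ddm.R           # 8-variant fits, model selection
Rscript analysis/05_parameter_effects.R # parameter battery vs truth
```

Each writes its tables under `results/analysis/`.

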