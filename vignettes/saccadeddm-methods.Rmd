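---
title: "Models and methods behind saccadeddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saccadeddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

`saccadeddm` analyzes dual-saccade choice experiments.  On every trial an
observer first fixates an *inspection target* — a face or a phase-scrambled
noise patch, which may have been visible peripherally beforehand
(*preview*) or hidden behind an elliptic *outline* — and then makes a
second saccade to one of two peripheral *selection targets* (one face, one
noise patch).  Two quantities summarize each trial: which target class the
second saccade selected, and the *fixation duration* on the inspection
target, treated as the reaction time of the selection decision.  The
experimental design crosses inspection identity (face/noise) with preview
(preview/outline), yielding four conditions coded FP, FO, NP, NO, with 256
trials per condition per participant.

The analysis asks whether foveal processing of the inspected target and its
peripheral preview merely delay the start of the selection process, or
interfere with the selection process itself.  The package implements the
complete chain: a synthetic experiment generator, the Wiener diffusion
first-passage machinery, an eight-variant model family fitted per
participant by a Kolmogorov–Smirnov criterion with BIC information-weight
model selection, a smoothed time-course analysis with cluster-based
permutation inference (SMART), and the group-level test battery.

## The diffusion model

Choices and fixation durations are modeled as a Wiener diffusion between
two absorbing boundaries.  Evidence starts at $z = z_r \cdot a$ between the
boundaries $0$ and $a$ and accumulates with drift $v$ and unit diffusion
constant; absorption at $a$ maps to a face choice, absorption at $0$ to a
noise choice, and the observed time is the decision time plus a
non-decision time $t_0$.  Three across-trial variabilities follow the
standard parameterization: drift is $\mathrm{Normal}(v, s_v)$, the relative
start is $\mathrm{Uniform}(z_r \pm s_z/2)$, and the non-decision time is
$\mathrm{Uniform}(t_0 \pm s_{t0}/2)$.  Time is in seconds internally;
trial tables store milliseconds and are converted exactly once at the
module boundary.

Analytic quantities are computed from two complementary series for the
defective first-passage CDF at a boundary.  The small-time branch is the
image expansion, whose terms integrate in closed form to pairs of
$\Phi$-terms evaluated via log-$\Phi$ for stability; the large-time branch
is the termwise-integrated sine series, evaluated with multiply-only
recurrences for $\exp(-\lambda_k t)$ and $\sin(k\pi w)$.  The switch sits
at $t/a^2 = 0.08$ with adaptive truncation at an absolute tolerance of
$10^{-9}$; the unit tests verify both branches against high-precision
quadrature of the density (observed agreement is at the $10^{-10}$ level).
Densities use the standard small-/large-time selection rule that picks the
series needing fewer terms at a $10^{-7}$ target error.

The distribution of the *signed* response variable ($+$RT for face, $-$RT
for noise choices) is marginalized over the three variabilities by
Gauss–Hermite quadrature in drift (15 nodes by default) and Gauss–Legendre
quadrature in start point and non-decision time (7 nodes each); a test
doubles all node counts and verifies the CDF is unchanged to $10^{-6}$.
Trial simulation uses Euler–Maruyama steps of 0.5 ms with the
Brownian-bridge crossing correction (the probability
$\exp(-2\,\delta_1\delta_2/\Delta t)$ that the within-step path crossed a
boundary despite interior endpoints).  Without the bridge correction the
step discretization biases the simulated distribution by roughly the
kernel of a 1–2% KS distance; with it, $10^5$ simulated trials agree with
the analytic CDF to about $10^{-3}$, i.e. within Monte-Carlo error.

## Fitting and model selection

Each participant is fitted separately.  Trials map to the signed response
variable per condition; the objective is the trial-count-weighted sum of
per-condition KS distances between the empirical CDF and the marginal
model CDF, evaluated on both sides of every empirical jump.  The KS
criterion is the study's choice because it is robust to outliers; the
likelihood criterion (`ml_objective()`) is exposed for robustness
comparisons and returns $+\infty$ when any trial falls below the minimum
non-decision time.

Eight variants free every subset of $\{v, a, t_0\}$ across the four
conditions; $z_r$, $s_v$, $s_z$, $s_{t0}$ are always shared (starting-point
differences are excluded on parsimony grounds: target sides were balanced
and no prior information distinguished conditions).  The parameter count is
$k = 7 + 3\,|\mathrm{free}|$.

Optimization is a Nelder–Mead simplex on transformed parameters: $\log a$,
$\mathrm{logit}\, z_r$, raw $v$, $\log t_0$, $\log s_v$, and logit
*fractions* for $s_z$ and $s_{t0}$ relative to their legal ranges given
$z_r$ and $\min_c t_0$, so every vector decodes to a legal parameter set.
Restarts are *chained*: each restart re-initializes the simplex at the best
point found so far (the first from a data-driven start — boundary 1.0,
drift from the inverted choice probability, $t_0$ at 85% of the fastest
trial — later ones with a small seeded jitter).  Chaining recovers the
simplex from premature collapse in the 13–16-dimensional variants far more
cheaply than independent jittered starts of equal budget.
`fit_all_variants()` additionally warm-starts every variant from the
best-fitting variant nested inside it, which keeps the best-objective
monotonicity across nested variants at modest restart counts.

Model selection uses BIC information weights
$w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)$,
$\Delta_i = \mathrm{BIC}_i - \min_j \mathrm{BIC}_j$, averaged across
participants; the winner is the variant with the highest mean weight, with
machine-precision ties broken toward smaller $k$.  Because the KS-fitted
parameters are not maximum-likelihood estimates, the fitted $t_0$ can sit
above the fastest observed trials, where the pure first-passage density
vanishes and single trials would dominate the BIC by dozens of nats.  The
BIC log-likelihood is therefore evaluated under a fixed 2% uniform
contaminant over the observed signed-RT range — the standard contaminant
model for response times — which caps per-trial penalties while leaving
the ranking of well-fitting variants untouched.  `ml_objective()` is *not*
mixed: it keeps the pure density so the outlier sensitivity of the
likelihood criterion remains visible.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which every downstream stage is validated.  Defaults are the study design
(36 participants, 256 trials/condition, 128 stimuli per category).  Designs
are counterbalanced exactly: conditions randomly interleaved per
participant; inspection location (above/below fixation) and face side
(left/right) balanced within condition; each stimulus serving four times as
inspection target and eight times as selection target, never in two roles
within a trial (enforced by deterministic pairwise swaps, with an explicit
arithmetic error when the requested counts cannot be counterbalanced).

The generating model is the winning variant: drift rate and non-decision
time vary across conditions (v = 0.607, 0.320, −0.024, 0.096 and t0 = 208,
211, 183, 192 ms for FP, FO, NP, NO), while boundary separation (1.0),
starting point (0.5) and the variabilities ($s_v$ = 0.3, $s_z$ = 0.1,
$s_{t0}$ = 80 ms) are shared — the latter five values are plausible
conventional choices, since the study reports only the condition-wise drift
and non-decision-time means.  Between-participant variability has two
layers: a shared offset per parameter (SDs: v 0.25, t0 30 ms, a 0.15) and,
for the parameters the generating variant varies, condition-specific
offsets (v SD 0.75, t0 SD 105 ms) sized so the total per-condition SD
reproduces the dispersion of the fitted parameters across the study's
participants (SE $\times \sqrt{36}$ ≈ 0.8–1.3 for drift, ≈ 110 ms for
non-decision time).  This condition-specific layer matters: with it, the
per-participant evidence for freeing a parameter reflects the
interindividual differences the study reports; without it every
participant carries only the small fixed condition effects, and the BIC's
$3\ln(1024) \approx 21$-nat penalty per freed parameter makes model
recovery a coin flip.  Draws violating parameter legality are rejected and
redrawn; a deterministic 200-draw probe raises an error when more than half
of draws would be rejected.

One master seed drives everything through deterministically derived
per-participant substreams, so a (config, seed) pair reproduces a session
byte-for-byte.  The generator does *not* emulate: gaze kinematics, display
timing, stimulus-level perceptual effects, sequential dependencies, lapses
or contaminant responses, or any effect of inspection location / face side
(balanced nuisance factors with no effect).  Passing tests therefore show
that the pipeline recovers what the diffusion model generates at the
study's design size — not that real data are free of contaminants or model
misspecification.

## SMART time courses

Per participant, the binary outcome (face chosen) is kernel-smoothed over
fixation duration on a 1-ms grid spanning 100–750 ms with a Gaussian kernel
of SD 48 ms ("width" is read as the SD, the convention of the method's
reference implementation; it is a config field).  The group curve weights
each participant at each time point by their kernel data density.  The
paired comparison computes, at every grid point, a weighted paired t
statistic: weights (summed across the two conditions) are normalized to
sum to the number of contributing participants, the weighted mean and
frequency-weighted variance use $df = n - 1$, so equal weights reduce the
statistic to the ordinary paired t.  Clusters are maximal runs of
consecutive points with $|t|$ above the two-sided $\alpha = 0.05$
threshold; cluster strength is the summed $|t|$.  The permutation null
swaps the two conditions' curves (with their weights) within participants
— algebraically a sign flip of the difference curves, which allows all
1000 permutations to be evaluated as one matrix product.  The critical
value $t_{crit}$ is the 95th percentile of the permuted maximal cluster
strengths; each observed cluster's p value is its position in that
distribution with a floor of $1/(\text{permutations}+1)$, so p = 0 is
never reported.  All clusters are returned; the strongest one is the
headline row.  Confidence bands are the two-sided critical t times the
weighted SE of the paired difference, halved for display around each of
the two curves.  The one-sample (baseline) mode compares a single
condition's curves against chance level 0.5 by the same machinery.

## Group statistics

All factors are two-level, so every repeated-measures ANOVA effect is
computed exactly as the square of a within-participant contrast t
statistic with df = (1, n−1) — the classical decomposition, verified in
the tests against `aov()` with an error stratum.  Missing cells (e.g. a
participant who never chose noise in some condition) either raise an error
naming the participants or, in the pipeline, trigger logged listwise
deletion.  Choice proportions are tested against chance with a Wilcoxon
signed-rank test: zeros dropped; exact p for n ≤ 25 from the full
positive-rank-sum distribution via a generating-function recursion on
doubled midranks (ties handled exactly, verified against $2^6$
enumeration); otherwise the normal approximation with continuity and tie
corrections.  All tests are two-sided at $\alpha = 0.05$ with no
multiplicity correction, matching the study's conventions.

## Study sizes and speed settings

The package's simulation studies (tests and the acceptance script) run at
sizes chosen once for a single CPU: parameter recovery uses 12
participants at the full 256 trials/condition; model-selection recovery
uses replicate experiments of 3 participants; SMART calibration uses 500
null experiments of 8 participants at 200 permutations.  Speed-sensitive
fits use the documented reduced settings of `fit_options()` (chained
restarts, 4/1/2 quadrature nodes, 32 KS evaluation points per condition,
700 iterations per restart); the recovery benchmarks in the test suite
show no material accuracy loss relative to the full settings at these
problem sizes, and the full-quality defaults remain the function defaults.

## Known limitations

* BIC from KS-fitted parameters is a pragmatic desk definition; the
  original fitting tool's internal criterion may rank near-tied variants
  differently, so replication targets on deposited data should be read at
  qualitative tolerance.
* The weighted-t and aggregation formulas of the SMART reference
  implementation are not published in full; this package's definitions are
  stated above and exact numerical equality of cluster statistics with
  published values is not promised — the target is the same pattern of
  significant contrasts with overlapping windows.
* No hierarchical estimation: participants are fitted independently, as in
  the study.
* The simulator caps paths at 30 s; for the parameter ranges used here the
  truncation probability is negligible.
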