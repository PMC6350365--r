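---
title: "Methods: drug-response analysis on PDX trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-response analysis on PDX trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxresponse)
```

## The data and the four trial patterns

A PDX trial is a long-format table of repeated tumor-volume measurements:
one row per animal per day, with columns `tumor_id` (the PDX line), `arm`
(treatment or vehicle), `animal_id`, `day` (days post treatment start,
T0), `volume` (mm³) and optionally `tumor_type` and `body_weight` (g).
Units are fixed; there is no conversion. Day 0 is the baseline: an animal
whose earliest measurement is not at day 0 is flagged by
`validate_trial()` rather than silently rebased, because every relative
metric in the package is anchored at T0.

Designs are classified by `infer_pattern()` on three counts: the number of
tumors, the maximum number of non-control arms per tumor, and the median
number of animals per tumor×arm cell. `1AN` (one tumor, several arms,
several animals), `T1N` (tumor panel, one treatment arm), `TA1` (panel ×
panel, one animal per arm) and `TAN` (several of everything) route the
pipeline: between-arm statistics need within-arm replication and therefore
run for `1AN`/`TAN` only; TGI needs a control arm and runs for
`1AN`/`T1N`/`TAN`; response labeling is per-animal and runs everywhere.
Degenerate designs (e.g. a single arm) map to the nearest code and carry a
`degenerate` flag instead of failing.

Missing measurements are handled by day alignment, never interpolation:
analyses that need aligned timepoints (mixed ANOVA, the permutation test,
end-volume endpoints, TGI) use the intersection of days across the animals
or arms involved; per-animal analyses (growth rates, labeling) use each
animal's own days. Interpolation would manufacture data at exactly the
points where PDX measurement schedules are raggedest. Animals sacrificed
early simply contribute the days they have; trajectories ending before a
standard's eligibility window are labeled PD and flagged
`insufficient follow-up` rather than dropped.

The control arm is taken from an explicit label when given, otherwise by
case-insensitive match against *vehicle*, *control*, *untreated*. TGI
refuses to run without one; labeling does not need one.

## Between-arm statistics

Endpoint analyses reduce each animal to one number. Because PDX lines
engraft heterogeneously, baseline volumes differ across animals and the
classical end-of-study volume comparison inherits that spread. The
package's default endpoint is therefore a per-animal **growth rate**, with
`slope_log` — the least-squares slope of ln V against day — as the default
method: tumor growth is near-exponential over a 3-week window, the slope
uses every timepoint, and it is exactly the generating parameter of the
simulator, so recovery is testable to machine precision. `ratio_log`
(two-point log ratio) and `diff` (mm³/day) are available for short or
zero-crossing series.

`one_way_test()` runs fixed-effects ANOVA or Kruskal–Wallis (mid-ranks,
tie-corrected) on those values. `scheirer_ray_hare()` extends the rank
approach to two crossed factors: all N observations are ranked together,
two-way ANOVA sums of squares are formed on the ranks, and
H = SS_term/(SS_total/(N−1)) is referred to χ² on the term's usual df.
With a single-level second factor this reduces *exactly* to the
tie-corrected Kruskal–Wallis statistic, which the tests assert at 1e−9.
The factor pair is the caller's choice (arm × tumor or arm × day); empty
cells are refused because rank sums of squares are not uniquely
decomposable in incomplete designs.

`mixed_anova()` is the split-plot layout: arm between subjects (tested
against subjects-within-arm), day and arm×day within (tested against the
day×subject residual), restricted to the complete common-day grid. In
balanced designs the between-arm F equals one-way ANOVA on per-animal
means — a classical identity the acceptance tests verify at 1e−9.
Sphericity rarely holds for growing tumors (variance inflates with time),
so Greenhouse–Geisser corrected p-values are always reported alongside;
ε is estimated from the pooled within-arm covariance via orthonormal
contrasts. A term whose sum of squares is numerically nil (identical arms)
would be 0/0 in floating point and is reported as F = 0, p = 1.

`fit_lmm()` models ln(V + 1) (admitting zeros after regression) with fixed
effects day, arm and day×arm — vehicle as reference, so each `day:arm`
coefficient is an arm's growth-rate difference versus vehicle — and a
per-animal random intercept plus, by default, a random day slope. A
singular random-slope fit is downgraded to intercept-only with a note, a
non-convergent fit is an error. Contrasts are Wald z; the omnibus arm
p-value is a likelihood-ratio test of ML refits with and without the arm
terms. Parameter recovery is checked by simulating from the model itself:
over 200 replicates at 8 animals/arm, every fixed effect must lie within
3 SE of truth in at least 95 % of fits.

### The growth-curve permutation test

For an arm pair, a two-sample statistic is computed per shared day — a
pooled-variance t by default, or a tie-corrected rank-sum z
(`mean_wilcox`) — and averaged over days into S. Animal labels are then
permuted *as whole trajectories* (repeated measures of one animal stay
together) and p = #{|S_perm| ≥ |S_obs|}/B, the plain proportion, with no
add-one smoothing. When the number of distinct assignments C(n, n₁) is at
most 20,000 the test enumerates all of them and is exact — at 8 vs 8
animals that is C(16,8) = 12,870, so the common PDX arm sizes always get
the exact test. The canonical oracle: 3 vs 3 animals with the treatment
strictly below control at every day gives p = 2/20, since only the
observed split and its mirror attain the maximal |S|. Days with zero
within-group variance in both groups carry no information for t and are
skipped with a note; Welch-type variance was deliberately not made the
default to match the pooled-t convention of growth-curve comparison.
Pairwise p-values are Holm-adjusted by default (`bonferroni`, `BH`
available). Given a seed the Monte-Carlo mode is bit-reproducible.

## Tumor growth inhibition

TGI = (1 − F(V_T)/F(V_C)) × 100 %, where V_T and V_C are the treatment and
control **arm center curves** — per-day mean by default, median available —
and F is one of: `diff` (V_t − V_0), `ratio` (V_t/V_0), `auc` (trapezoidal
area from day 0 to t). The AUC integrates the center curve rather than
averaging per-animal AUCs, for consistency with the other two functionals'
use of arm means; it does not baseline-subtract before integrating (the
ratio F_T/F_C cancels common scale, and subtraction would reintroduce the
control-shrinkage degeneracy below at one remove). All three functionals
are invariant to rescaling all volumes by a common positive constant, and
TGI is monotone decreasing in the treatment's day-t center — both are
property-tested.

When the control arm does not grow (F_C ≤ 0 under `diff`/`auc`), the ratio
changes sign and the formula stops meaning "inhibition"; those rows are
reported `defined = FALSE` with note `control not growing` instead of a
sign-flipped number. TGI above 100 % (treated tumors regressing below
baseline) is meaningful and reported as is. Day 0 is never an evaluation
day (F_C = 0 identically for `diff`/`auc`).

## Response labeling

Per-animal change from baseline is ΔV%(t) = 100·(V_t − V_0)/V_0. Three
standards are implemented; every cutoff is a field of
`response_thresholds()` because mouse-strain growth kinetics legitimately
shift them.

* **npdxe** — BestResponse = min ΔV% over days ≥ `min_day` (default 10);
  BestAvgResponse = min over eligible t of the running mean of ΔV% over
  (0, t]. Day 0's identically-zero ΔV% is excluded from the running mean —
  including it would only dilute every average toward zero by a
  trajectory-independent amount. Levels, tested in order: CR if best < −95
  and avg < −40; PR if best < −50 and avg < −20; SD if best < 35 and
  avg < 30; else PD.
* **pptp** — on relative tumor volume RTV = V_t/V_0: CR if the volume ever
  drops below 100 mm³ (the measurable-disease floor — the one deliberately
  scale-dependent criterion); else PR if min RTV ≤ 0.5; else PD if end
  RTV > 1.25; else SD. The original protocol's PD1/PD2 time-to-event split
  and maintained-CR distinction are collapsed to PD and CR.
* **rc** — volume-adapted RECIST on the last day's ΔV%: CR ≤ −95,
  PR ≤ −65, PD ≥ +73, SD between.

The mean-dominates-min inequality BestAvg ≥ Best is a theorem when every
post-baseline day is eligible (`min_day = 0`): each running mean is at
least the minimum of its terms. Under the day-10 window it can fail for
trajectories that dip sharply before day 10 and rebound after — the
eligible minimum then exceeds a running mean that still remembers the dip.
The 1,000-trajectory dominance property is therefore tested at
`min_day = 0`, where it is exact; the windowed metrics are tested on fixed
worked trajectories instead.

Arm indices are RR = (nCR + nPR)/n and DCR = (nCR + nPR + nSD)/n, printed
as percentages rounded half-up to 2 decimals (banker's rounding would turn
a 28.575 into 28.57 or 28.58 depending on parity — half-up matches how
such tables are conventionally reported). `rank_arms()` sorts by DCR then
RR by default, ties broken alphabetically for stability.

## The simulator

`simulate_trial()` draws
V_{a,t} = V_{a,0} · exp((g_tumor + g_animal − e_arm)·t) · ε_{a,t}, with
baseline V_{a,0} lognormal, g_tumor ~ N(mean, sd²) per tumor (inter-tumor
heterogeneity), g_animal ~ N(0, sd²) per animal (intra-tumor
heterogeneity), e_arm a fixed per-arm reduction of log growth, and ε
lognormal measurement noise; body weight gets a mild arm-dependent trend
around 22 g. The exponential kernel was chosen over Gompertz because its
log-slope *is* the generating parameter: the noiseless limit recovers
g − e to machine precision through `endpoint_values(slope_log)`, which
pins the whole estimation chain. Defaults mirror a standard three-week
efficacy study — one tumor, five treatments plus vehicle, eight animals
per arm, measurements every 3 days to day 21 — with baseline 200 mm³
(CV 0.25), control log-growth 0.08/day (≈ 5-fold growth over the study),
tumor SD 0.02, animal SD 0.02, noise CV 0.08, and arm effects evenly
spaced 0.02–0.10/day so the strongest arm sits near net-zero growth and
yields a mix of SD and PD calls, the weakest is near-indistinguishable
from vehicle. `simulate_null()` zeroes all arm effects for calibration
studies. Everything is reproducible from the single integer seed.

What the generator does *not* emulate: Gompertz-type growth deceleration
at large volumes, measurement-triggered sacrifice (informative dropout),
caliper floor effects at very small volumes, and correlated noise within a
measurement session. Passing calibration and recovery tests on this
kernel therefore demonstrates correctness of the statistical machinery
under clean exponential growth, not robustness to those real-data
features.

## Numerical and design notes

* Permutation p-values compare |S_perm| ≥ |S_obs| − 1e−12 to absorb
  floating-point ties; exhaustive mode includes the observed assignment by
  construction, making the exact p strictly positive.
* Type-I calibration of the permutation test, Kruskal–Wallis and ANOVA on
  growth rates is asserted over 500 null trials (8 animals/arm, 8
  timepoints) against the binomial 99 % interval around α = 0.05; the LMM
  recovery study uses 200 replicates. These sizes keep the full suite
  around two minutes while leaving the binomial bands tight enough to
  catch miscalibration of a few points.
* SEM is undefined for n = 1 and reported absent, not zero.
* `read_trial()` reads everything as text and coerces numerics itself so
  that a malformed day or volume is reported with its row, then enforces
  uniqueness of (tumor, arm, animal, day) as a fatal error. Round-tripping
  through `write_trial()` is exact.
* The NIBR-PDXE dialect carries no animal-id column (one animal per
  model×treatment cell); ids are synthesized as `<tumor_id>:<arm>`.

## Known limitations

Volume-based readouts only: hematologic tumors and bioluminescence
measurements need different response definitions and are out of scope, as
are dose–response/IC50 fitting, growth-delay (T − C) and survival-type
endpoints. The Scheirer–Ray–Hare decomposition assumes a crossed,
non-empty design. The permutation test conditions on the complete
common-day grid of an arm pair; heavily ragged schedules lose days rather
than animals.
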