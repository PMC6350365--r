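# pdxresponse

Drug-response analysis for patient-derived xenograft (PDX) preclinical
trials.

PDX trials measure tumor volume repeatedly in mice carrying engrafted
patient tumors, across treatment arms and a vehicle (control) arm. Designs
vary along three axes — how many tumor lines, how many arms, how many
animals per arm — giving four common patterns, coded with `1` for single
and a letter for multiple:

| Code | Tumors | Arms | Animals/arm | Typical question |
|------|--------|------|-------------|------------------|
| 1AN  | 1      | many | many        | which treatment for *this* tumor? |
| T1N  | many   | 1    | many        | how good is *this* treatment across tumors? |
| TA1  | many   | many | 1           | high-throughput screen (one mouse per arm) |
| TAN  | many   | many | many        | both inter- and intra-tumor heterogeneity |

`pdxresponse` implements the three standard ways to quantify response on
such data, routed per pattern:

1. **Between-arm statistics** on endpoint volumes or per-animal growth
   rates (the least-squares slope of ln V against day): one-way ANOVA,
   Kruskal–Wallis, the Scheirer–Ray–Hare rank test for two crossed factors,
   mixed-design (split-plot) ANOVA with Greenhouse–Geisser correction, a
   linear mixed model (`lme4`), and a growth-curve **permutation test**
   that averages a per-day two-sample statistic over days and permutes
   whole animals between arms (exact by enumeration when the number of
   label assignments is small).
2. **Tumor growth inhibition**, TGI = (1 − F(V_T)/F(V_C)) × 100 %, for
   three volume functionals F on the arm center curve: V_t − V_0, V_t/V_0,
   and the trapezoidal area under the curve.
3. **Animal-level response labels** (CR / PR / SD / PD) under three
   adjustable standards — NPDXE (BestResponse / BestAvgResponse), PPTP
   (relative tumor volume), and relative-change criteria — with per-arm
   response rate RR = (nCR + nPR)/n and disease control rate
   DCR = (nCR + nPR + nSD)/n.

A synthetic-trial generator (`simulate_trial()`) with an exponential-growth
kernel, inter-tumor and intra-animal heterogeneity and lognormal
measurement noise provides ground-truth datasets for all four patterns.
Figures include arm mean ± SEM curves, per-animal spaghetti plots,
TGI-over-time, stacked response-level bars and waterfall plots.

## Worked example

Simulate a single-tumor trial with five treatment arms plus vehicle, eight
animals per arm, measured every 3 days for three weeks, then analyse it:

```r
library(pdxresponse)

trial <- simulate_trial(sim_config("1AN", n_arms = 5, n_animals = 8, seed = 101))
infer_pattern(trial)
#> <pattern_code> 1AN | 1 tumor(s), 5 non-control arm(s), median 8 animal(s)/cell

compute_tgi(trial, f_kind = "diff", at = "end")[, c("arm", "day", "tgi_percent")]
#>   arm           day tgi_percent
#> 1 Treatment_1    21        28.9
#> 2 Treatment_2    21        78.6
#> 3 Treatment_3    21        87.7
#> 4 Treatment_4    21       103.
#> 5 Treatment_5    21       104.
```

TGI near 0 % means the arm grew like the vehicle; 100 % means complete
growth inhibition; above 100 % the treated tumors regressed below their
baseline volume. The permutation test compares whole growth curves:

```r
perm <- permutation_curve_test(trial, n_perm = 1000, seed = 202)
perm[perm$arm_b == "Vehicle", c("arm_a", "statistic", "p_raw", "p_adjusted")]
#>   arm_a       statistic    p_raw p_adjusted
#> 1 Treatment_1    -0.522 0.559       1
#> 2 Treatment_2    -3.32  0.00264     0.0238
#> 3 Treatment_3    -3.74  0.000932    0.00932
#> 4 Treatment_4    -4.96  0.000155    0.00233
#> 5 Treatment_5    -5.94  0.000155    0.00233
```

Every arm except `Treatment_1` separates from vehicle after Holm
adjustment. Labeling each animal and ranking arms by disease control:

```r
calls <- label_responses(trial, "npdxe")
rank_arms(arm_indices(calls))[, c("arm", "n_cr", "n_pr", "n_sd", "n_pd", "rr_pct", "dcr_pct")]
#>   arm          n_cr  n_pr  n_sd  n_pd rr_pct dcr_pct
#> 1 Treatment_5     0     1     7     0   12.5   100
#> 2 Treatment_4     0     0     7     1    0      87.5
#> 3 Treatment_3     0     0     6     2    0      75
#> 4 Treatment_2     0     0     5     3    0      62.5
#> 5 Treatment_1     0     0     0     8    0       0
#> 6 Vehicle         0     0     0     8    0       0
```

`run_pipeline(trial, "results/")` does all of the above plus the figures
and writes a JSON manifest. Real data comes in through `read_trial()`,
which accepts any delimited long-format table via a column map and ships a
preset for the NIBR PDX-encyclopedia export:

```r
ds <- read_trial("pdxe_volumes.csv", dialect = "nibr-pdxe")
```

A command-line front end for the same operations is installed at
`inst/scripts/pdxresponse-cli` (subcommands `run`, `stats`, `tgi`,
`response`, `simulate`).

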