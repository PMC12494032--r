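# tregfate

Fate-mapping analysis of tissue regulatory T cell (Treg) pool ontogeny.

Tamoxifen-inducible fate mapping heritably labels the Tregs present during
a short recombinase-activity window. Pulsing cohorts of mice in successive
weeks of life and reading the tagged fraction of each tissue's Treg pool at
a common adult age yields a *cumulative* labelling curve per tissue: a
pulse in week *w* marks (up to tagging efficiency *E*) every Treg generated
in weeks 1..*w*. `tregfate` is for researchers analyzing such designs. It
provides:

* **Simulation** — a cohort-structured birth/label/division/loss model per
  tissue (`tissue_schedule`, `pulse_design`, `simulate_cohort()`) with an
  exact expectation engine (`evolve_expectation()`) usable as an oracle,
  including an 8-day trapezoidal activity kernel, per-tissue efficiency,
  Beta-Binomial per-mouse scatter, residency (two loss classes split at a
  birth-day cutoff), proliferation (Ki67-like) observables, and
  transcription-factor subsets.
* **Reconstruction** — the retrospective decomposition of the adult pool by
  generation week: per-group medians `F_w`, efficiency correction
  `min(F_w / E, 1)`, weighted isotonic (pool-adjacent-violators) fit of the
  cumulative curve, differencing `p_w = F̂_w − F̂_{w−1}` with a
  "generated later" tail, percentile bootstrap CIs, and a 10×10
  largest-remainder waffle allocation.
* **Turnover** — label-decay kinetics in weeks:
  `F(t) = π_res + (F0 − π_res)·exp(−r·(t − t1))` with box constraints
  (`fit_decay()`, profiled constrained least squares), two-point rates
  `r = ln(F1/F2)/Δt` and half-lives (`two_point_rate()`), and
  constant-pool persistence ratios (`persistence_ratio()`).
* **Phenotype statistics** — paired Wilcoxon signed-rank tests of marker
  proportions in tagged versus untagged Tregs of the same mice, with an
  exact null distribution up to 25 pairs (exact under ties) and
  Benjamini–Hochberg control across marker panels (`marker_report()`).

## Worked example

Simulate the bundled seven-tissue reference scenario (pulses in weeks 1–6,
8 mice per group, analysis at 8 weeks of age) and reconstruct the skin
pool's composition by generation week:

```r
library(tregfate)

sc <- paper_scenario()
cohort <- simulate_cohort(sc, seed = 42)
est <- reconstruct_composition(cohort, "skin", efficiency = 0.99,
                               B = 500, seed = 42)
est
#> Treg pool composition by generation week -- skin
#>  tissue week increment  ci_lo  ci_hi cumulative_corrected
#>    skin    1   0.57146 0.5500 0.6240                0.571
#>    skin    2   0.30859 0.2467 0.3443                0.880
#>    skin    3   0.02172 0.0000 0.0601                0.902
#>    skin    4   0.02146 0.0000 0.0506                0.923
#>    skin    5   0.00707 0.0000 0.0433                0.930
#>    skin    6   0.01162 0.0000 0.0530                0.942
#>    skin   >6   0.05808 0.0167 0.0772                   NA
#> Waffle (100 cells): w1=57 w2=31 w3=2 w4=2 w5=1 w6=1 tail=6
```

About 57% of this simulated skin pool derives from Tregs generated in the
first week of life and 88% from the first two weeks — the strong neonatal
bias the scenario encodes — with tight bootstrap intervals on the early
increments and a 6-cell "generated later" tail on the waffle grid.

Turnover in aging skin (week-1 pulse chased to 28 weeks of age):

```r
aged <- simulate_cohort(sc, seed = 43, tissues = "skin", pulse_weeks = 1,
                        analysis_day = 7 * c(8, 12, 16, 20, 24, 28))
med <- sapply(7 * c(8, 12, 16, 20, 24, 28), function(ad) {
  g <- aged[aged$analysis_day == ad, ]
  median(g$n_tagged / g$n_cells)
})
fit_decay(c(8, 12, 16, 20, 24, 28), med)
#> Label-decay fit
#>              F0         plateau   rate_per_week half_life_weeks
#>          0.5937          0.0000          0.0320         21.6600
two_point_rate(0.60, 8, 0.35, 28)   # from summary fractions directly
#> r = 0.0269 /week, half-life = 25.7 weeks
```

Tissue-Treg markers in tagged versus untagged VAT Tregs (week-1 pulse),
with exact paired p-values (`2/2^8 = 0.0078` at n = 8) and BH q-values:

```r
marker_report(cohort[cohort$pulse_week == 1, ], "VAT",
              markers = c("KLRG1", "ST2", "CCR2"))
#>   marker n median_tag median_untag delta       p       q
#> 1    ST2 8      0.736        0.244 0.492 0.00781 0.00781
#> 2  KLRG1 8      0.670        0.228 0.442 0.00781 0.00781
#> 3   CCR2 8      0.596        0.204 0.392 0.00781 0.00781
```

The whole pipeline (cohort CSV, per-tissue and per-subset compositions,
decay fits, marker reports, run log) is driven by
`run_pipeline(scenario, out_dir)`; a thin command-line wrapper with
`simulate | reconstruct | turnover | phenotype | all` subcommands ships in
`inst/cli/tregfate.R`.

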