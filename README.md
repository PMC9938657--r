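# isoturn

Analysis of compensatory-growth feeding trials in juvenile Pacific white
shrimp (*Litopenaeus vannamei*) that use stable nitrogen isotopes to ask
how feed restriction and refeeding repartition the drivers of tissue
renewal. It is aimed at aquaculture nutrition researchers who have
per-tank weight and feed records, muscle δ¹⁵N time series after a diet
switch, and (optionally) 16S OTU count tables.

## The model at the core

After a switch to a diet with a distinct δ¹⁵N signature, muscle tissue
drifts from its baseline toward equilibrium with the new diet following
the exponential incorporation model

```
C(t) = Cn + (C0 − Cn) · e^−(k+m)t
```

with `C0` the baseline (‰), `Cn` the asymptote (‰), `k` the exponential
growth rate (day⁻¹, measured from weights as `k = ln(FW/IW)/days`) and `m`
the metabolic turnover rate (day⁻¹), the single parameter estimated by
constrained nonlinear least squares in `fit_turnover()`. Derived
quantities:

* nitrogen residence half-time `t50 = ln 2 / (k + m)`,
* contribution split: growth `100·k/(k+m)` %, turnover `100·m/(k+m)` %.

Around the fit: zootechnical metrics (`WG = 100(FW−IW)/IW`,
`SGR = 100(ln FW − ln IW)/days`, `FI`, `FCR = FI/(FW−IW)`, survival),
one-way ANOVA + Tukey HSD + compact-letter displays (`group_compare()`),
Shannon and Chao1 alpha-diversity estimators for OTU tables, seeded
cohort simulators, and a config-driven pipeline (`run_pipeline()`) with a
thin CLI (`inst/cli/isoturn`).

## Worked example

Simulate a three-regime trial (Control; 70% restriction × 3 d; 70%
restriction × 6 d) and run the two report stages:

```r
library(isoturn)

cohort <- simulate_cohort(default_treatments(), sim_config(seed = 1))

rec  <- performance_table(cohort$weights, cohort$feed,
                          survival = vapply(cohort$treatments, `[[`, 0, "survival_pct"))
summ <- performance_summary(rec)
summ[c("treatment", "wg_pct", "wg_pct_sd", "sgr", "fcr", "survival_pct")]
#>   treatment wg_pct wg_pct_sd  sgr  fcr survival_pct
#> 1   Control    658      15.1 5.79 1.83          100
#> 2        T3    686      14.6 5.89 1.80           97
#> 3        T6    631      10.6 5.68 1.79           93

rep <- turnover_report(cohort$isotopes, cohort$weights, n_boot = 500, seed = 1)
rep$table[c("treatment", "k", "m", "k_contribution_pct", "m_contribution_pct",
            "t50", "letters")]
#>   treatment      k      m k_contribution_pct m_contribution_pct   t50 letters
#> 1   Control 0.0584 0.0374               61.0               39.0  7.24       a
#> 2        T3 0.0620 0.0103               85.7               14.3  9.58       b
#> 3        T6 0.0619 0.0000              100.0                0.0 11.20       c

print(rep$fits$Control)
#> Isotope incorporation model: C(t) = Cn + (C0 - Cn) * exp(-(k + m) t)
#>   fit window: days 7-35, n = 15 observations
#>   k  = 0.0584 day^-1 (supplied)
#>   m  = 0.0374 day^-1 (SE 0.0031)
#>   Cn = 14.31 permil (fixed), C0 = 8.53 permil
#>   t50 = 7.2 days;  contribution k/m = 61% / 39%
```

Reading the output: the control animals renew muscle nitrogen fastest
(highest `m`, shortest half-time ≈ 7 days, with roughly 61% of the
isotopic change driven by growth and 39% by turnover), while previously
restricted animals reach the same isotopic equilibrium mainly through
compensatory tissue accretion — lower `m`, longer `t50`, growth share
rising toward 100%. Letters mark treatments whose turnover rates differ
(bootstrap difference intervals at α = 0.05). The T6 estimate sitting
exactly at 0 is the non-negativity constraint at work on a low-turnover
noisy series; the fit carries a `boundary` flag when this happens.

Comparing performance across regimes:

```r
group_compare(rec$wg_pct, rec$treatment)
#> One-way ANOVA: F_2,6 = 12.37, p = 0.007 (alpha = 0.05)
#>   T3         mean =   686.2793  a
#>   Control    mean =   657.9353  ab
#>   T6         mean =   631.0595  b
```

`plot(rep$fits$Control)` draws the observed points with the full `k + m`
curve and the growth-only (`m = 0`) curve, showing the isotopic change
attributable to growth alone.

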