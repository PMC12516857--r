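# twophaseprev

Prevalence estimation for **two-phase psychiatric epidemiology designs**:
a high-sensitivity screen (phase 1) selects participants for structured
diagnostic interviews (phase 2), and population prevalence is recovered by
combining both phases with an adjustment for interview non-response. The
package implements the full analysis pipeline for a community cohort of
late adolescents in which lifetime prevalences of 20 mental health
disorders (M.I.N.I. psychiatric modules, ADDIS substance use disorders,
NODS gambling, IGDS gaming) are reported by sexual-orientation group
(asexual, homosexual, bisexual, heterosexual — classified from attraction
items, gender-separated) and by gender-discontent status (pooled over
legal genders), with relative risks against same-gender heterosexuals or
all others.

## The estimator

For a group of size $T$, with $D$ interviewed members meeting a diagnosis,
$ND$ interviewed members not meeting it, and $NI$ screen-positives not
interviewed, the adjusted prevalence is

```
P = (D + (D / (D + ND)) * NI) / T
```

i.e. non-interviewed screen-positives are assumed to carry the diagnosis
rate of the interviewed ones (missing at random given screen status), and
screen-negatives are assumed diagnosis-free. Where one school sub-cohort
was never screened for gambling/gaming (NS1 members), the adjusted
prevalence PD2 of a fully screened reference subset is imputed to them:

```
P = (D + (D / (D + ND)) * NI + PD2 * NS1) / T
```

Relative risks are ratios of adjusted prevalences (undefined unless both
are positive); significance is a Pearson chi-square without continuity
correction on adjusted case counts, star-coded at p < 0.05/0.01/0.001.
Because the raw data such designs produce cannot be shared, the package
ships a seeded synthetic-cohort generator (`generate_cohort()`) mirroring
the sampling design — latent diagnoses per stratum, instrument-level
screens with configurable sensitivity/specificity, person-level interview
response, and the asymmetric sub-cohort gambling/gaming screening rule —
so the whole pipeline is testable end to end.

## Worked example

```r
library(twophaseprev)

# the adjustment formula on explicit counts
estimate_prevalence(two_phase_counts(D = 5, ND = 15, NI = 8, T = 200))
#> adjusted prevalence: 0.0350 (3.5%)
#> two-phase counts: D=5 ND=15 NI=8 T=200
```

Of 20 interviewed screen-positives, 25% met the diagnosis; that rate is
imputed to the 8 non-interviewed screen-positives, giving (5 + 2)/200 =
3.5% lifetime prevalence.

```r
# a full synthetic analysis under the default study conditions
sim <- generate_cohort(cohort_config(seed = 1))
report <- run_pipeline(sim$cohort, quiet = FALSE, on_inestimable = "na")
#> cohort n=949; screen-selected=744; interviewed=364 (48.9% of selected)
#> orientation responders=917; GD responders=941; GD group=19 (2.0%)
#> dropped all-zero column(s): male_asexual, male_homosexual

subset(report$estimates, group == "female_bisexual" & entity == "depression")
#>             group     entity composite  D ND NI NS1 PD2   T         P percent_1dp inestimable
#> 1 female_bisexual depression     FALSE 23 21 45  NA  NA 112 0.4153815        41.5       FALSE

subset(report$comparisons, group == "female_bisexual" & entity == "depression")
#>             group           reference     entity       RR    chi2            p stars small_expected
#> 1 female_bisexual female_heterosexual depression 2.101011 22.6145 1.979851e-06   ***          FALSE
```

Here 23 of 44 interviewed screen-positive bisexual girls met lifetime
depression; imputing that rate to the 45 not interviewed gives an adjusted
prevalence of 41.5% in this simulated cohort, 2.10 times the heterosexual
girls' rate (chi-square 22.6, p < 0.001). `render_table(report,
"markdown")` renders the full wide table (percent columns with stars, RR
columns, composite rows, mean-diagnoses row; all-zero group columns
dropped and logged), and `render_table(report, "csv")` emits the long
results table. A thin command-line wrapper with `simulate`, `analyze`,
`replicate-table1` and `recovery` verbs lives at
`system.file("cli", "twophaseprev.R", package = "twophaseprev")`.

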