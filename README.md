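# abproteoforms

Quantification of β-amyloid (Aβ) proteoforms in brain extracts from tandem
mass spectrometry, built around a label-free estimator of the fraction of
Aβ carrying isoaspartate at position 7 (isoD7-Aβ).

## The problem

Aβ accumulates in the brain as senile plaques, and specific proteoforms —
N-/C-terminally truncated forms and post-translationally modified forms
(pyroglutamate at E3, Met35 oxidation, deamidation of Q15/N27, and above
all isomerization of D7) — are enriched in plaques and implicated in
aggregation. Isomerization of Asp to isoAsp is **mass-silent**: isoD7-Aβ
and normal Aβ have identical masses and fragment masses, so it cannot be
seen as a mass shift. It can, however, be *quantified* from fragmentation
behavior: in CID spectra of the LysC fragment Aβ(1–16)
(`DAEFRHDSGYEVHHQK`, MH⁺ ≈ 1954.88 Da), backbone cleavage next to the
isoAsp residue is more efficient, so the intensities of the marker
fragments **b6, b7 and y10** rise with isoD7 content while the base
fragments **b11 and y11** do not.

The estimator is a classical calibration / inverse-prediction design. For
binary mixtures of synthetic norm- and isoD7-Aβ(1–16) at design fractions
f = 0, 10, …, 100 %, the marker/base intensity ratio r is measured and a
least-squares line

    r = a·f + b

is fitted (binary mixing of two pure-species fragment yields with a
species-insensitive base fragment makes r exactly linear in f). An unknown
sample is measured as the mean ratio r̄ over its replicate MS/MS spectra
(20 per sample in the standard design) and inverse-predicted:

    f̂ = (r̄ − b) / a,   clamped to [0, 100] %

with uncertainty propagated through the inverse slope. Cohort-level
dynamics are then tested with tie-corrected Kendall τ-b against age,
Mann–Whitney U between age phases, and z-score (> 3) outlier screening.

Because no raw data are deposited with the underlying study, the package
ships a first-class synthetic-data generator (`simulate_spectrum`,
`simulate_cohort`, `write_fixture_bundle`) that emulates the stated world —
a 24-animal 5xFAD-like ageing cohort (ages 2–23 months), logistic total-Aβ
accumulation plateauing near 10 ng/mg, isoD7 rising linearly 8 % → 30 %
between 7 and 23 months, ≈13 % Met35 oxidation, 6–8 % pyroGlu-E3,
deamidation peaking near 12 months, missed cleavages rising after 16
months — and returns the generating truth alongside, so every estimator is
tested by parameter recovery.

## Worked example

```r
library(abproteoforms)

# calibration: simulated 0-100% binary-mixture design, 3 replicates/point
curve <- calibrate_from_series(
  simulate_calibration_series(step_pct = 10, reps = 3,
                              spectrum_sim_config(noise_cv = 0.05), seed = 7))
print(curve)
#> ab_calibration (linear): ratio = 0.00442 * f% + 0.3939, residual sd 0.0527, n = 33

# simulated ageing cohort: 24 animals, 20 MS/MS spectra each
cohort <- simulate_cohort(cohort_config(n_psms_per_sample = 200L), seed = 42)
est <- vapply(cohort$spectra, function(sp)
  estimate_sample(sp, curve)$fraction_pct, 0)
data.frame(age = cohort$truth$age_months,
           true = round(cohort$truth$true_iso_pct, 1),
           estimated = round(est, 1))[c(1, 8, 12, 16, 20, 24), ]
#>  age true estimated
#>    2  8.0      13.2
#>    7  7.5       8.3
#>    9 22.2      24.2
#>   12 18.1      16.6
#>   16 27.0      26.3
#>   23 36.1      36.8

kendall_trend(cohort$truth$age_months, est)
#> Kendall tau-b = 0.390, p = 0.0089 (normal, n = 24)

# proteoform accounting from the cohort's PSM table
recs <- validate_psm_records(cohort$psm)
ptm_occupancy(recs, 35, "oxidation")        # 0.133
missed_cleavage_fraction(recs)              # 0.114
terminal_distribution(recs, "N", species_filter = "human")
#>    -1     1     2     3     4     5     6     7     8     9    10    11
#> 0.016 0.757 0.017 0.062 0.013 0.043 0.011 0.021 0.026 0.020 0.008 0.005
```

The estimated isoD7 fractions track each animal's generating truth within
a few percentage points; the positive τ with p < 0.05 recovers the rising
trend injected by the generator (the per-animal scatter comes from the
configured 5-point between-animal SD plus measurement noise). The N-terminal
distribution recovers the configured truncation probabilities (D1 dominant
at ~0.78, elevated cleavage at E3 and R5).

## Command line

A thin CLI over the same functions is installed at
`inst/cli/abproteoforms.R`:

```sh
Rscript inst/cli/abproteoforms.R simulate --out fixtures/ --seed 42
Rscript inst/cli/abproteoforms.R calibrate --spectra fixtures/calibration.mgf \
    --design fixtures/design.csv --out curve.json
Rscript inst/cli/abproteoforms.R quantify-iso --curve curve.json \
    --spectra fixtures/m01_age02.mgf --out estimates.csv
Rscript inst/cli/abproteoforms.R trend --input estimates.csv --out trend.json
```

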