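---
title: "Quantifying Abeta proteoforms and the isoD7 fraction from tandem MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Abeta proteoforms and the isoD7 fraction from tandem MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abproteoforms)
```

## The measurement model

Isomerization of aspartate-7 of β-amyloid (Aβ) to isoaspartate is
mass-silent: the isoD7 and normal proteoforms of the LysC fragment
Aβ(1–16) are isobaric, as is every one of their b/y fragments. What
changes is fragmentation *efficiency*: in CID, backbone cleavage adjacent
to isoAsp is favored, so the intensities of the fragments b6, b7 and y10
of Aβ(1–16) grow with isoD7 content while b11 and y11 are insensitive.
The package quantifies the isoD7 fraction through the ratio

$$ r = \frac{I_\text{marker}}{I_\text{base}}, \qquad
   \text{marker} \in \{b_6, b_7, y_{10}\},\;
   \text{base} \in \{b_{11}, y_{11}\} $$

calibrated against designed binary mixtures of the two pure synthetic
forms, 0–100 % isoD7 in 10 % steps. For a sample, $r$ is measured in each
of its replicate MS/MS spectra (20 in the standard design), the
per-spectrum ratios are averaged, and the mean is inverse-predicted
through the calibration fit.

### Why a straight line

If the pure norm form yields marker intensity $M_n$ and the pure iso form
$M_i$ per unit amount, while the base fragment yields $B$ from both, a
mixture with iso fraction $f$ gives, in expectation,

$$ E[r] \approx \frac{(1-f)M_n + f M_i}{B}, $$

linear in $f$. The linearity rests on two assumptions: the base fragment
yield is identical for the two forms, and replicate noise is
multiplicative with modest CV so the ratio of expectations approximates
the expectation of the ratio. `fit_calibration()` therefore defaults to
least squares on a line; if the replicate-mean ratios are non-monotone by
more than twice the linear fit's residual SD — curvature a line cannot
carry — it falls back to a shape-constrained monotone (isotonic)
interpolant through the replicate means, and records which fit was used.
A design whose fitted slope is not positive is rejected outright
("non-monotone calibration"): a flat curve carries no information about
$f$.

Inverse prediction clamps results to the physical range [0, 100] % and
flags the clamping rather than extrapolating; its reported SD is the
first-order propagation of the calibration residual SD through the
inverse slope, and `estimate_sample()` additionally reports the
between-spectrum ratio SD mapped through the same slope.

Two ambiguities in the source method were decided as follows. *Mean of
per-spectrum ratios* is the default aggregation (it matches the stated
"average intensity ratio over 20 spectra"); ratioing the accumulated
spectrum is available via `average = "accumulated"`. Note that the mean
of ratios carries a small upward bias of order $\mathrm{CV}^2_\text{base}$
(about +1 % of the ratio at the default 10 % noise CV) because
$E[1/I_\text{base}] > 1/E[I_\text{base}]$; at the package's default noise
this is ≈ 1 percentage point at mid-range and is well inside the
estimator's stochastic SE, so no bias correction is applied. Second, the
b6/b11 channel is the default and b7/y10 against b11/y11 are exposed as
alternatives; the generator applies the same enhancement to all three
markers, and a test checks that channel choice does not move the estimate
beyond its combined uncertainty.

## Fragment-mass arithmetic and matching

Theoretical singly-protonated b/y ladders use standard monoisotopic
residue masses; $b_n$ = sum of the first $n$ residues + proton, $y_n$
adds water. Every complementary pair obeys
$b_n + y_{L-n} = \mathrm{MH}^+ + m_\text{proton}$, which the tests use as
an internal identity and which an independent summation oracle checks to
1e-6 Da. Modifications are positional mass deltas (Unimod values);
pyroglutamate is restricted to the peptide N-terminus, and isoAsp is a
zero-mass flag — deliberately so, since its mass-silence is the reason
the ratio method exists. Only b/y ions are modeled: the quantification
spectra are CID, and electron-based c/z chemistry is out of scope.

Peak matching assigns each theoretical ion its nearest observed centroid
within a tolerance (default **0.05 Da**, the fragment tolerance of the
standard search settings; precursor matching at 30 ppm equivalence is the
same order for this precursor), one peak per ion, ties broken by smaller
mass error, then higher intensity, then lower m/z. Replicate accumulation
sums clustered centroids (greedy gap clustering at 0.02 Da,
intensity-weighted cluster m/z): the instrument's own accumulation method
is not documented, and summed centroids conserve total intensity exactly
and are permutation-invariant, both of which are tested.

## Proteoform accounting

PSM tables (CSV/TSV with `sample_id, age_months, peptide, start, end,
mods, intensity`; `mods` encoded `pos:name;...` in Aβ coordinates, with
−1 for the Met preceding D1) are validated row by row — coordinates,
length consistency, species recomputed from the sequence — and rejects
are reported, not silently dropped.

* **Terminal distributions** are intensity-weighted and normalized within
  the LysC families: N-terminal truncation over peptides ending at K16
  (the Aβ(X–16) family), C-terminal over peptides starting at G29
  (Aβ(29–X)). Intensity weighting (rather than PSM counting) follows the
  plotted "relative MS intensity" convention; counting is a one-line
  change and the normalization-to-1 invariant is tested at 1e-9.
* **PTM occupancy** at a site is the intensity share of covering records
  that carry the modification. For N-terminus-restricted modifications
  (pyroglutamate) the denominator is further restricted to records whose
  peptide starts at the site: an Aβ(1–16) record covers E3 but cannot
  chemically carry pyroGlu-E3, and including it would deflate the
  occupancy by the (biologically unrelated) truncation rate.
  Phosphorylation occupancies are reported but flagged low-confidence;
  CID alone does not localize Aβ phosphosites reliably.
* **Missed cleavages**: LysC cuts after K16 and K28, so any record whose
  span strictly contains either lysine is a missed-cleavage product; the
  fraction is intensity-weighted.
* **Abundance series** (`Ab1_16` ⊆ `AbX_16` ⊆ `total_Nterm`, the last
  being every peptide within positions ≤ 16) are averaged per age over
  the animals at that age, since the default cohort has 1–3 animals per
  age; shared-region peptides (17–42, identical between species) are
  never counted in species-specific series.

## Cohort statistics

`kendall_trend()` computes τ-b — the tie-corrected variant, because
cohort ages are heavily tied — with an exact two-sided p-value (from the
exact null distribution of the concordant-pair count) for tie-free data
with n ≤ 10 and the tie-corrected normal approximation otherwise. An
exact permutation p under heavy ties is combinatorially out of reach at
useful n; the normal approximation's calibration at cohort size is
verified by a type-I simulation in the test suite. `mann_whitney()`
counts U directly over pairs (half-weight for ties) with the
tie-corrected, continuity-corrected normal p-value. `detect_outliers()`
implements the z > 3 screen; note the algebraic ceiling
$z_\max = (n-1)/\sqrt{n}$, which makes flags impossible below n = 11 —
the function returns honest all-clear rather than an error there.
`group_by_phase()` bins ages at {≤6, 7–9, 10–14, >14} months by default,
mirroring the described accumulation phases (slow early rise,
intermediate plateau at 6–8 months, rapid accumulation from 9–12,
saturation later); the exact published grouping is not printed anywhere,
so the edges are fully overridable.

## What the generator emulates — and what it does not

The synthetic world is fixed by the stated study design, not tuned to
tests:

| parameter | default | provenance |
|---|---|---|
| cohort | 24 animals: 2× at 2, 8, 9, 10, 12, 14, 16 mo; 3× at 3, 7 mo; 1× at 4, 17, 18, 23 mo | stated design |
| spectra/sample | 20 | stated design |
| calibration design | 0–100 % in 10 % steps | stated design |
| isoD7 trajectory | linear, (7 mo, 8 %) → (23 mo, 30 %) | stated result ("more or less constant" growth) |
| between-animal isoD7 SD | 5 pct points | chosen: boxplot spread is not printed numerically |
| total Aβ | logistic, human plateau 10 ng/mg at midpoint 10.5 mo, rate 0.7/mo; murine plateau 0.2, midpoint 8, rate 0.8 | plateau stated; midpoints/rates chosen to reproduce the described phases (rapid growth after 9 mo, murine saturated by 12, human ~50× higher late) |
| Met35 oxidation | 0.13 | stated |
| pyroGlu-E3 | 0.07 (of E3-starting peptides) | stated 6–8 % |
| deamidation | Gaussian in age, peak 0.05 (Q15) / 0.03 (N27) at 12 mo, SD 4 mo | stated peak near 12 mo |
| truncation starts | D1 0.78, elevated at E3/R5/S8–G9, M(−1) 0.01 | described pattern |
| C-terminal ends | 42: 0.94, 40: 0.04, 41/43: 0.01 | stated percentages |
| missed cleavage | 0.05 + 0.25·logistic(age − 17) | described jump after 16 mo |
| intensity noise | log-normal, fragment CV 0.10; PSM sdlog 0.35 | chosen, typical MALDI/LC-MS technical variability |
| marker enhancement | ×2 (b6/b11 ratio doubles over 0→100 %) | chosen: no reference spectra are printed |

Spectra are fragment sticks plus uniform background (excluded from a
±0.1 Da guard band around theoretical ions) with Gaussian m/z jitter
(0.002 Da). Everything is a pure function of (config, seed).

Deliberately **not** emulated: isotope envelopes, charge states > 1,
chromatography and ion mobility, matrix/suppression structure beyond
multiplicative noise, inter-batch effects, the database search itself
(its output table format is the interface), and real inter-animal
biological covariance. A green recovery test therefore establishes that
the estimators are correct and well-calibrated *under this generative
model* — unbiased inverse prediction, nominal coverage of the binomial
recovery bands, correct trend power — not that the pipeline is robust to
every artifact of real MALDI data. The PSM intensity noise (sdlog 0.35)
was chosen moderate so that intensity-weighted proportions stay within a
few percent of count-weighted ones; with realistic order-of-magnitude
intensity spreads, binomial-SE recovery bands would need the effective
sample size correction they famously require.

## Numerical choices and degenerate inputs

* Calibration requires ≥ 3 distinct fractions spanning ≥ 50 percentage
  points; constant ratios are an error, not a zero-slope fit.
* Inverse predictions outside [0, 100] % clamp and flag rather than
  error: a fraction is physically bounded.
* A missing base fragment is an error (the ratio is undefined); a missing
  marker yields ratio 0 with a warning (consistent with "below detection").
* `accumulate()` refuses mixed precursors beyond the bin tolerance.
* Exactly duplicate m/z centroids are merged on construction.
* The matrix-effect check compares slopes/intercepts of curves fitted on
  identical designs with Welch-type t-tests at α = 0.05 per coefficient
  (verdict "comparable" when none is significant); with two coefficients
  this gives a familywise type-I around 8–10 %, which is what the ≥ 90 %
  comparable-rate expectation reflects.

## Known limitations

* The published cohort τ = 0.88 (p = 1.06×10⁻⁷) cannot be reproduced:
  the per-animal raw values are not deposited, and even the unit of
  analysis (animals vs preparations) is ambiguous. The package instead
  verifies trend *power* on the stated trajectory with the stated noise.
* The calibration's linearity argument holds for intensity ratios of
  well-resolved centroids; saturated detectors or overlapping isobaric
  background would bend it, and only the monotone fallback would notice.
* Human-brain levels (isoD7 ≈ 76 %) are far outside the murine calibration
  mid-range; estimates there lean on the upper end of the design where a
  single calibration line is least constrained.
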