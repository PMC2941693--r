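---
title: "Developing and validating peptide-spectrum match metrics with fraglod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating peptide-spectrum match metrics with fraglod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglod)
```

## The problem

Matching tandem mass spectra to theoretical peptides is the core of
shotgun-proteomics protein identification. A *metric* maps a (candidate
peptide, observed spectrum) pair to a similarity score; identification
engines differ mostly in the information their metrics exploit. `fraglod`
is not an identification engine: it is a workbench for *developing* metrics
— for asking whether a new piece of knowledge about the fragmentation
process (mass-dependent match rates, instrument mass-error drift, peak
intensity structure) measurably improves the separation between correct and
random peptide assignments on a given dataset, at the level of individual
fragments.

## The scoring model

All probability scoring is built on log-odds (LOD) scores, natural
logarithms throughout:

$$\mathrm{featureLOD} = \ln\frac{P(\mathrm{correct}\mid E)}{P(\mathrm{random}\mid E)},
\qquad
\mathrm{peptideLOD} = \sum_{i} \mathrm{featureLOD}_i .$$

A score of 0 means a feature is as likely under a correct as under a random
assignment; the peptide score is the sum over matched fragments, which
assumes (approximate) independence of the per-fragment evidence.

Four metrics of increasing data-dependence are provided:

1. **Metric 1 (basic).** $P(\mathrm{correct}) = 0.5$ for every matched
   fragment (about half of the considered peaks are identifiable in
   correct matches). $P(\mathrm{random}) = 2\,|\Delta m|\,\rho$, where
   $\rho$ is the spectrum peak density (peaks per Dalton) and $\Delta m$
   the observed-minus-expected mass error: the chance a uniformly placed
   peak falls inside the error window. The pinned example: 100 peaks
   spanning 150–1150 Da give $\rho = 0.1$; an error of 0.25 Da gives
   $P(\mathrm{random}) = 0.05$ and a fragment LOD of $\ln(0.5/0.05) = 2.3$.
   The natural-log base is fixed by that printed value (base 10 would give
   1.0).
2. **Metric 2.** Replaces the constant 0.5 with the empirical proportion of
   theoretical fragments matched in high-confidence assignments
   ($Z > 6$), tabulated per 200 Da fragment-mass bin and per parent charge
   class (1+ and 2+ separately; rare 3+ parents use the fixed average of
   all 1+ and 2+ proportions).
3. **Metric 3.** Builds the same table for *random* assignments — every
   decoy candidate in the precursor window, no Z requirement — normalizes
   both tables to unit sum, and scores a matched fragment as the log-ratio
   of normalized correct to normalized random mass-bin weights. The score
   becomes a pure function of fragment mass.
4. **Metric 4.** Multiplies metric 3's correct-match probability by a
   Gaussian weight for the observed mass error,
   $w = \exp(-(\Delta m - \mu_b)^2 / 2\sigma_b^2)$, with $(\mu_b,
   \sigma_b)$ the sample moments of correct-assignment errors in 100 Da
   bins. This models instrument drift: the error mean typically grows with
   fragment mass. We use the max-normalized kernel ($w \in (0,1]$, $w = 1$
   at the bin mean) because the alternative — a density value — has units
   of 1/Da and would shift every score by a constant depending on bin
   width; on the LOD scale the choice only affects an additive offset
   shared by all candidates of a spectrum.

Confidence is expressed as a **Z score**: the number of sample standard
deviations a candidate's peptide LOD lies above the mean of decoy
candidates (reversed-protein database) drawn from the same precursor
window. The conventional acceptance threshold is $Z = 3.29$; empirical
tables are trained on $Z > 6$ assignments.

### The intensity network

The complex metric predicts fragment peak intensities with a multilayer
perceptron: 8 inputs, 8 sigmoidal hidden units, one output. Inputs are ion
type (0–4 for none/immonium/y/a/b), parent charge, fragment charge, parent
length, fragment/parent length ratio, fragment/parent H+K+R ratio, and the
identities of the residues flanking the cleavage site, coded as 20 evenly
spaced values on $[0,1]$ in order of increasing hydrophobicity. The
training target is $\ln$ of peak intensity after normalizing each spectrum
to a maximum of 100. Per candidate, observed and predicted intensities over
the matched fragments are normalized to sum to 100 and compared by dot
product against a null of all wrap-around rotations of the predicted
vector (identity excluded); the resulting Z is **added** to the metric 4 Z.

## Pipeline and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `noise_fraction` | 0.005 | Remove peaks below this fraction of summed intensity (sum-based, not base-peak-based, because noise scales with total fragmentation). |
| `precursor_tol` | 2.5 Da | Candidate precursor window half-width. |
| `fragment_tol` | 0.5 Da | Fragment match tolerance. |
| `min_y_hits` | 2 | Minimum y-series hits to retain a candidate (undocumented in the original description; 2 keeps the filter permissive). |
| `min_prelim` | 0.05 | Minimum preliminary intensity-proportion score; ~0.30 can suit MALDI data. |
| `min_decoys` / `max_decoys` | 20 / 50 | Decoy population per spectrum; the decoy window (only) widens up to ±10 Da, and at most 50 nearest-mass decoys are scored. |
| `z` train threshold | 6 | High-confidence cut for table/network training. |

Preliminary scoring uses the top $4N$ peaks with
$N = \mathrm{round}(M/114)$ (average residue mass 114 Da, floored at 1),
and the y1+, b1+ and immonium ion set, plus y2+ when the parent charge is
at least 2. Probability scoring uses y, b and a ions with up to two water
and two ammonia losses per fragment (y2+ again conditional on charge);
whether immonium ions also join probability scoring is exposed as an
option, default off.

## Numerical choices

* Floors: random-match probability $\ge 10^{-4}$; $|\Delta m| \ge 0.005$
  Da; error-PDF $\sigma \ge 0.01$ Da; Z-denominator $\ge 10^{-6}$;
  normalized distribution bins $\ge 10^{-9}$. These keep LODs finite at
  exact matches and degenerate nulls.
* Bins are lower-exclusive/upper-inclusive, labelled by upper edge, first
  bin = everything at or below the width; missing bins fall back to the
  nearest populated bin.
* Fragment matching is a greedy one-to-one assignment ordered by absolute
  error, ties broken by lower theoretical then lower observed m/z, so
  scoring is deterministic; a peak's intensity is never counted twice.
* Monoisotopic masses; proton 1.007276, water 18.010565, ammonia
  17.026549 Da. Immonium m/z = residue − CO + proton (Leu 86.0964).
* Hydrophobicity ordering uses the Kyte–Doolittle scale (ties broken
  alphabetically); the source description names no scale.
* "Epoch" for the quasi-Newton network training is one full-batch BFGS
  iteration (`stats::optim` with analytic gradients); the hidden layer is
  sigmoidal but the output unit is linear, since the log-intensity target
  is unbounded below.
* Isoelectric points solve the Henderson–Hasselbalch net-charge equation
  by bisection on pH ∈ [0, 14] to |charge| < 1e-4, with an EMBOSS-style
  pKa set; fragment termini are treated as standard amino/carboxy groups,
  a deliberate simplification for b ions (whose true C-terminus is an
  oxazolone/acylium, not a carboxylate).

## What the synthetic generator emulates

`sim_config()` states a world in which the empirical structure the
data-driven metrics assume is known exactly: y/b fragments appear with a
probability that ramps with the 200 Da mass bin (0.3 → 0.9 by default,
mirroring the rising match proportions seen on real MALDI data), mass
errors are Gaussian with a mass-proportional drift (slope 2e-4 Da/Da,
σ = 0.05 Da), intensities follow a deterministic log-linear function of
length ratio, H+K+R ratio and ion type (so the network has recoverable
signal), and a spectrum carries 20 uniform noise peaks. Charges 1/2/3 are
drawn with probabilities 0.4/0.5/0.1. Each spectrum has its own RNG stream
derived from (seed, ordinal), so generation is order-independent and
byte-reproducible.

What it does **not** emulate: isotope envelopes, correlated noise,
chimeric spectra, neutral-loss peak structure, retention time, or
instrument-specific intensity response. A green end-to-end test therefore
establishes that the estimators recover the structure they assume and that
the pipeline ranks true peptides first when their ions are present — not
that the defaults are optimal for any particular instrument.

## Calibration remarks

On noise-only spectra the mean best-candidate Z sits slightly above zero
(about +0.4 in the acceptance run) rather than at zero: reported
candidates are conditioned on passing the y-hit and preliminary-score
filters, while the decoy null is drawn from the bare mass window. This
selection asymmetry is inherent to the pipeline design and worth keeping
in mind when interpreting Z thresholds near zero; at the working
thresholds (3.29 and above) it is immaterial. Separately, the
"2 standard errors" drift-recovery property is asserted as binomial
coverage (≥80% of bins within 2 SE, all within 4 SE) because with ~20
bins the all-bins event would fail most runs under a perfect estimator.

The mapping of $Z = 3.29$ to a "95% confidence level" in the original
description does not match the two-sided normal point (1.96); the 3.29
cutoff is kept as the default without endorsing that mapping.

## Known limitations

* Whole-protein reversal is the only decoy construction; peptide-level
  reversal is not offered.
* Fragment charges above 2+, c/z/x ions and isotope envelopes are out of
  scope.
* Variable-modification enumeration is capped at 64 forms per base
  peptide (with a warning) to bound combinatorial blow-up.
* The text report renders fragment LODs at 2 decimals and prints their sum
  as the peptide LOD, so the report is internally consistent at print
  precision; full-precision values live in the TSV summary.
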