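---
title: "The high-resolution PRM quantification workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The high-resolution PRM quantification workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmquant)
```

`prmquant` implements an isotope-dilution PRM quantification workflow for
low-abundance signaling proteins, together with a synthetic orbitrap-PRM
acquisition generator that makes every stage testable without instrument
data. This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was open.

## The quantification model

Each target peptide is monitored as a light (endogenous) / heavy
(stable-isotope-labeled internal standard, SIL) precursor pair. The heavy
peptide is chemically identical — same sequence, retention time, fragment
pattern and response — shifted by the label mass (+8.0142 Da for
¹³C₆¹⁵N₂-Lys, +10.0083 Da for ¹³C₆¹⁵N₄-Arg, applied to every y ion).
Quantification proceeds in two modes:

* **single-point**: amount = (Σ light areas / Σ heavy areas) × spiked IS
  amount, over the transitions detected in the heavy standard;
* **curve**: amount = (response − intercept)/slope from a weighted linear
  calibration over a dilution series.

Copies per cell follow from unit bookkeeping: with `L` µg of peptide loaded
and `p` ng total protein per cell (default 0.20 ng, a BCA-type per-cell
protein mass), the column carries `L·1000/p` cell equivalents, and
`copies = amount[amol]·10⁻¹⁸·N_A / n_cells` with `N_A = 6.022×10²³ mol⁻¹`.
The defaults reproduce the reference point 100 amol on a 1 µg load →
12,044 copies per cell.

## Acceptance criteria

A pair is **accepted** only if all of the following hold, with every failed
criterion named in `rejection_reasons`:

| criterion | default | note |
|---|---|---|
| transition mass deviation | < 5 ppm | applied per transition: a fragment is *identified* only when its intensity-weighted mean deviation passes; a precursor whose signal-bearing transitions average ≥ 5 ppm is rejected outright |
| identified transitions | ≥ 2 per label | |
| peak shape | Gaussian fit R² ≥ 0.8 | |
| co-elution | \|ΔRT(light, heavy)\| ≤ max(0.05 min, one duty cycle) | |
| transition ratios | light-vs-heavy area dot product ≥ 0.85 | |
| library match | dot product vs. library spectrum ≥ 0.85 | |

The dot product is the normalized spectral similarity
`Σaᵢbᵢ/√(Σaᵢ²Σbᵢ²)`; it is symmetric and scale invariant, 0 for orthogonal
patterns and 1 for identical ones. The 0.85/0.8 thresholds and the RT
tolerance are package defaults — the underlying criteria ("identical
retention time and transition ratios", "Gauss distribution form") are
qualitative, so the numbers are configurable via
`acceptance_thresholds()`. XIC extraction uses ±10 ppm, deliberately wider
than the 5 ppm identification filter: extraction has to tolerate the very
error it is meant to measure.

## Calibration and the limit of quantification

Calibration regresses response on nominal amount with **1/x weighting** by
default — the targeted-MS convention for series spanning two to three
orders of magnitude, where absolute residuals grow with concentration.
Per level, the back-calculated deviation is `100·|x̂ − x|/x` with
`x̂ = (response − intercept)/slope`. The **LOQ** is the lowest level with
deviation < 20 % such that *every higher level also passes*
(`contiguous = TRUE`). The contiguity rule resolves an ambiguity in the
verbal "lowest concentration with less than 20 % deviation" definition: it
prevents a noisy mid-curve level from being skipped. It can be toggled
off. Levels whose pair fails QC contribute no response and count as
failing the rule, so an undetected level caps the LOQ from below; a series
with fewer than three QC-passing levels yields an undetermined curve
rather than an error.

## The acquisition simulator

The generator emulates the study conditions: a panel of **21 light/heavy
peptide pairs for the 8 core UPR proteins** (four published assay
sequences, the rest synthetic tryptic-like stand-ins), retention times
spread over a 75-min gradient, heavy spikes of 29.5–490.4 amol, dilution
series of 7 two-fold steps from 59–980.8 amol (so the bottom levels land
at 0.46–7.66 amol), and reference endogenous amounts placed so copy
numbers span ~400 (XBP1) to ~60,000 (ATF6).

Physics, per scheduled scan of a precursor:

* **elution**: Gaussian peak, FWHM 0.25 min (configurable; typical ~30 s
  base width for this gradient class);
* **ion statistics**: accumulated ions `N = min(AGC, rate·t_inj)` with
  `rate = amount · response_factor · gauss(rt)`; the realized total is
  Poisson and fragment counts are multinomial over the library pattern.
  Short fill times therefore degrade the spectral dot product (shot
  noise), exactly the lever the 500 ms setting addresses. AGC behaviour is
  a hard cap (3×10⁶ charges default), with no predictive-AGC model;
* **mass error**: centroid error σ(ppm) ∝ FWHM(m/z, R_eff)/√N with
  orbitrap scaling `R_eff = R₂₀₀·√(200/m/z)`. The single proportionality
  constant (C = 9.6 at reference ion count 1000) was set once so the model
  reproduces the qualitative regime boundaries — mean |error| above 5 ppm
  at 60k and ≤ 2 ppm at 240k at the reference point — and was not
  revisited afterwards. Doubling resolution halves σ;
* **interference**: chemical noise is a constant-rate Poisson baseline
  (0.05 ions/ms per transition) plus optional co-isolating interferents: a
  species whose precursor offset falls within half the isolation width
  contributes near-isobaric fragment counts (default +4 ppm offset, broad
  2-min elution), merging into the target centroid intensity-weighted.
  The default offset of 0.6 m/z makes the interferent visible at 1.6 m/z
  isolation and invisible at 0.4, reproducing the S/N argument for narrow
  isolation;
* **scheduling**: every precursor is scanned once per duty cycle while its
  2-min RT window is open; the cycle is `n_active · (max(t_inj,
  transient(R)) + overhead)` with the standard transient table
  (15k→32 ms … 240k→512 ms at m/z 200). Inter-scan spacing therefore
  equals the cycle implied by the concurrent target count.

Everything is seeded: identical (panel, settings, truth) inputs give
bit-identical acquisitions, and each acquisition's truth (amounts,
interferents, seed) travels with it, including through the CSV sidecar.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: profile-mode spectra and centroiding artifacts,
MS1 signals, retention-time drift between runs, matrix-dependent ionization
suppression, peptide-specific fragmentation changes with collision energy,
detector saturation below the AGC cap, and real chromatographic tailing.
Absolute LOQs and copy numbers measured on simulated data characterize the
simulator's noise model, not an instrument; the package therefore treats
published instrument-derived values (LOQ ranges, copy numbers, induction
folds) as simulation parameters and *ordering* properties — e.g. LOQ at
240k/500 ms ≤ the 60 ms and 30k alternatives — never as numeric targets.

## Scheduler

Candidates come from an in-silico tryptic digest (cleavage after K/R, not
before P, 0–2 missed cleavages). A candidate is proteotypic when it is
unique in the supplied proteome (exact substring), has no missed cleavage
and no **ragged end** — operationalized as a flanking K/R run (previous two
residues both K/R, or the next residue K/R), which makes the cleavage
register ambiguous; the term is used in the field without a formal
definition, so this package fixes one. Selection is greedy — neediest
protein first, then the candidate eluting farthest from already-selected
targets — with a hard feasibility check that adding a 2-min window never
pushes the concurrency profile above 3 pairs. Greedy rather than exact
optimization mirrors how such methods are curated by hand and is
deterministic for a fixed input order; infeasible coverage is reported,
never silently violated. RT prediction for unannotated candidates uses a
Kyte–Doolittle hydropathy surrogate mapped onto the gradient; it is a
placeholder for a real RT predictor and only needs rank plausibility.

## Numerical choices

* Apex picking smooths the summed trace with a 5-point moving average —
  minimal smoothing against apex jitter at the low scan rates the long
  duty cycle causes.
* Peak boundaries walk from the apex to the nearer of a local minimum or
  the 1 %-of-apex height crossing; the relative rule is robust across the
  peak-width and height changes of the injection-time sweep.
* Areas are trapezoidal; fragment areas over shared boundaries are exactly
  additive.
* The Gaussian shape score is the R² of a weighted log-quadratic fit
  (Guo's method): deterministic, no starting values, and degenerate traces
  (flat, anti-Gaussian) score 0 by the curvature sign check; fewer than 5
  positive points is "not evaluable" rather than 0.
* A transition counts as detected when its in-boundary maximum exceeds 3×
  its off-peak baseline with ≥ 3 nonzero points — a conventional S/N≥3
  detection rule, needed because the Poisson baseline makes raw areas
  nonzero everywhere.
* Negative back-calculated amounts clamp to zero with a warning; they are
  legitimate near blank levels.
* Protein aggregation is the unweighted mean over peptides (median behind
  a flag); dispersion combines between-peptide spread with propagated
  replicate SDs.

## Problem sizes

The test suite and experiment functions run deliberately scaled problems
chosen as representative rather than exhaustive: panel subsets of 1–4
pairs for per-operation checks, the full 21-pair panel for end-to-end
acceptance runs, 5–20 seeds for stochastic properties, 10 seeds × 3
parameter sets for LOQ ordering, and 2–3 replicates × 3 timepoints × 3
conditions for the time-course experiment. These sizes keep a full run in
the minutes range on one CPU while leaving every stochastic check with
enough replication to be meaningful.

## Known limitations

* The mass-error, noise and interference models are the simplest forms
  that reproduce the qualitative instrument trade-offs; they are not
  fitted to any instrument.
* The panel's synthetic sequences stand in for unpublished assay peptides;
  only four sequences are real published assay peptides, and one of them
  (APLSPSLLIR) has a conflicting protein attribution in the literature —
  the panel defaults to GADD34 and carries an `ambiguous_protein` flag.
* Quantification near the detection floor (hundreds of copies per cell) is
  shot-noise limited; fold-change recovery for such proteins has wide
  dispersion at small replicate counts, which is physical, not a defect.
* mzML support is read-only chromatogram lists (plus a minimal writer for
  interoperability tests); vendor raw files, Skyline documents and
  profile-mode data are out of scope.
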