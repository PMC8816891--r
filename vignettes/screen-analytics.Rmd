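---
title: "Screen analytics for nAChR antagonist discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screen analytics for nAChR antagonist discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nachrscreen)
library(dplyr)
```

## The analysis problem

Antagonists of nicotinic acetylcholine receptors (nAChRs) are found in a
membrane-potential screen by their ability to suppress the fluorescence
signal evoked by an EC90 concentration of agonist. Each 384-well plate
carries the test compounds (premixed with agonist at 10 µM final compound
concentration), twelve DMSO-only wells that anchor the zero-signal level,
twelve EC90-agonist wells that anchor the full-signal level, and a
12-point, 3-fold mecamylamine titration (100 µM down to ≈0.56 nM) as an
in-plate antagonist control. Because repeated full-plate control
experiments show a reproducible edge artifact, every well within two rows
or two columns of the plate edge is excluded outright rather than
corrected — this is why the package offers no B-score or surface-fit
spatial correction.

The pipeline implemented here takes the two fluorescence reads per well
(a dye baseline before compound addition, and a final read after) through:

1. background subtraction (`subtract_background()`),
2. per-plate QC — control CV, signal-to-background (S:B), Z′-factor,
   positional-bias diagnostics — with a strict gate
   CV < 10 %, S:B > 4, Z′ > 0.5 (`qc_plates()`, `gate_plate()`),
3. control-anchored normalization to the normalized fluorescent signal
   (NFS), with the zero-control mean at 0 and the positive-control mean
   at 1 (`normalize_plates()`),
4. hit selection at mean − 3 SD of each run's pooled test-well NFS
   distribution, with duplicate-run confirmation (`screen_result()`),
5. orthogonal validation by ⁸⁶Rb⁺ efflux and the 3 × SD rule
   (`efflux_validation()`), and
6. cross-subtype selectivity classification (`selectivity_profiles()`).

All stages are driven by tibbles and compose with the pipe; fitted
concentration-response objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Key statistics

The Z′-factor combines control variability and dynamic range,

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{zero})}{|\mu_{pos} - \mu_{zero}|},$$

and is invariant under common affine rescaling of both control series —
gain or offset changes of the plate reader cannot move it. NFS is the
linear rescaling

$$\mathrm{NFS}_w = \frac{S_w - \mu_{zero}}{\mu_{pos} - \mu_{zero}},$$

computed per plate from the *retained* control means (below), so the
anchoring invariants hold exactly by construction, and percent inhibition
is $100(1 - \mathrm{NFS})$. The hit threshold is computed per run, pooling
the test wells of all QC-passing plates in that run, because the run — not
the plate — is the replication unit of the screen design; a well is a hit
iff its NFS is *strictly* below mean − 3 SD.

Concentration-response curves use the four-parameter logistic on
log₁₀ concentration,

$$y = b + \frac{t - b}{1 + (x_{50}/x)^{h}},$$

with the Hill slope kept positive through a log parameterization and
direction (rising agonist curve vs. falling antagonist curve) handled by
curve orientation, which avoids the sign ambiguity of a free slope. The
agonist anchor concentration is derived from a fit as
$\mathrm{EC}_{90} = \mathrm{EC}_{50} \cdot 9^{1/h}$.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| QC gate | CV < 0.10, S:B > 4, Z′ > 0.5 | — | conventional minima for a screening-quality assay; strict inequalities |
| `outlier_k` | 3 | robust SD | control outliers trimmed at median ± k·1.4826·MAD; removal capped at 25 % of wells |
| `hit_sd_multiplier` | 3 | SD | the mean − 3 SD hit rule |
| `validation_sd_multiplier` | 3 | SD | efflux validation vs. no-drug control spread |
| compound conc. | 10 µM | molar | single-dose screening concentration |
| EC90 agonist | 20 µM (α3β4), 500 nM (α4β2, α6/3β2β3) | molar | subtype-specific anchor concentrations |

The MAD-based outlier rule is a design choice: the screening literature
agrees control outliers must be removed before normalization but rarely
states how. Median/MAD trimming is robust, deterministic, and bounded (it
can never discard more than a quarter of the control wells), and with
k = 3 it removes essentially nothing from clean Gaussian controls.

## What the synthetic generator emulates — and what it does not

No raw plate data from a real screen are distributed, so the package
includes a first-class, seeded generator of complete screens
(`simulate_screen()`), efflux experiments (`simulate_efflux()`), and
concentration-response tables (`simulate_dose_response()`). Its defaults
define the study conditions used throughout the tests:

* **Library and geometry.** 2,298 compounds over 12 plates per run
  (204 interior test wells per plate), two runs, three receptor-subtype
  assay contexts. Control wells occupy fixed interior columns 3 (zero),
  4 (positive) and 5 (titration), rows C–N; real screens vary this, and
  nothing downstream depends on the positions.
* **Signal model.** A test well's expected final read is
  `baseline + floor + (ceiling − floor)(1 − I)`, with the compound's
  fractional inhibition `I = efficacy / (1 + (IC50/10 µM)^h)`. The
  floor/ceiling pairs (100 AU and ≈14,900 / 6,250 / 6,500 AU) give
  noiseless S:B near 148, 61 and 64 for the three subtypes — the regimes a
  well-optimized membrane-potential assay reaches.
* **Noise.** Multiplicative Gaussian well noise at CV 5 % (inside the
  0.025–0.095 per-plate control-CV band such assays realize), log-normal
  plate-to-plate drift at 5 %, a baseline read at 10 % of the floor with
  its own noise, and an optional multiplicative edge bias (off by default;
  the edge artifact is real but unquantified, and edge wells are excluded
  regardless). These defaults put simulated plate Z′ in roughly 0.75–0.9.
* **Planted truth.** Six selectivity groups sized 26 / 6 / 5 / 20 / 10 / 15:
  α3β4-selective (24 high-efficacy at > 75 % inhibition, 2 low), α4β2-only,
  α6/3β2β3-only and both-β2 antagonists at ≤ 50 % efficacy, ten
  all-three-subtype antagonists, and fifteen *fluorescence artifacts* —
  compounds that depress the dye signal at every subtype but have zero
  effect on channel-mediated ion flux, so they score as primary hits and
  then fail orthogonal validation. Planted IC50 is 1 µM with Hill slope
  1.0 (slopes for such antagonists are rarely reported; 1.0 is the neutral
  choice for a single-site antagonist).

The generator is phenomenological at the well level. It does not simulate
dye-equilibration kinetics, channel gating, compound autofluorescence
spectra, carryover, or dispense failures; plate noise is homoscedastic in
CV. Passing tests therefore demonstrate that the *analysis* is correct and
well-calibrated under realistic noise — not that any particular real
screen would achieve these hit rates.

Because the planted actives are the selectivity fixture (82 compounds),
per-subtype primary-hit counts in simulation (≈50) sit above what a real
single screen of this size reports; the group sizes, efficacy classes and
artifact fraction are the quantities the fixture is designed to pin down.

## Numerical choices

* **Sample SD (n − 1) throughout** — control counts are small (n = 12).
* **4PL fitting** uses Levenberg–Marquardt on the residual function
  directly (`minpack.lm::nls.lm`) rather than an `nls`-style wrapper: the
  wrapper's post-fit model construction fails on exactly noiseless data
  (zero residual), which the recovery tests exercise on purpose.
  Initialization is deterministic from the data — asymptotes from the
  response extremes, midpoint from the concentration nearest
  half-maximum, Hill slope 1 — so a fit is a pure function of its input.
* **Canonicalization**: fitted asymptotes are relabeled so `top ≥ bottom`;
  the orientation sign flips with the swap, which leaves the fitted curve
  itself unchanged.
* **Degenerate inputs**: constant responses are flagged unconverged (no
  sigmoid exists); plates whose control means coincide are degenerate —
  their wells get `NA` NFS and their compounds leave the evaluable pool.
* **Ties at thresholds** resolve against the call: NFS exactly at the hit
  threshold is not a hit, inhibition exactly at 3 × SD is not validated,
  75 % inhibition exactly is not "high-efficacy", CV exactly 0.10 fails
  QC. All four follow the strict wording of the respective rules.
* **Negative net signals** (baseline above final read) are kept and
  flagged, not clipped — clipping would bias the test-well NFS
  distribution that sets the hit threshold.

## Open design points resolved here

* **Evaluable compounds.** The mechanism by which a screen drops a
  compound from the evaluable denominator is rarely published. Here a
  compound is evaluable iff every plate carrying it passed QC (and was
  non-degenerate) in every run; `screen_rates()` then computes
  primary/adjusted hit rates over evaluable compounds and percent data
  passing QC against the library size.
* **Validation spread.** The 3 × SD efflux rule needs a spread estimate;
  this package pools the per-well inhibition of the no-antagonist control
  wells across the three experiments, rather than using a per-experiment
  SD — more degrees of freedom, one declared convention.
* **Mixed selectivity patterns.** A compound validated at α3β4 plus
  exactly one β2 subtype fits none of the six named groups; the classifier
  assigns explicit `A3B4_AND_A4B2` / `A3B4_AND_A6` labels so that it is
  total over all eight flag combinations.
* **Which CV defines the reported "CV range".** The per-plate
  positive-control CV; its min–max across a screen's plates is what
  `report_tables()` summarizes.

## Problem sizes used in the test suite

The suite favors fixtures large enough to exercise the statistics but
small enough to run in seconds: single-module tests use 204–612-compound
screens (1–3 plates per run); the control-CV calibration check uses 25
simulated plates; the EC50-recovery study uses the 12-point, 4-replicate
design over 200 seeds; and the end-to-end planted-truth check runs the
full 2,298-compound, three-subtype, duplicate-run screen (72 plates),
which the vectorized generator produces in well under a minute.

## Known limitations

* Hit calling is a fixed SD cutoff, exactly as specified for this design —
  no multiple-testing machinery, no per-plate robust z-scores.
* The efflux model treats counts as Gaussian-with-CV; at very low cpm a
  Poisson model would be more faithful.
* `ic50_table()` averages IC50s across time points; it does not test for a
  time trend before averaging.
* Fit standard errors come from the local curvature (delta method on
  log₁₀ EC50); no profile or bootstrap intervals.
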