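---
title: "Identifying and quantifying dinucleoside polyphosphate RNA caps from LC-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying dinucleoside polyphosphate RNA caps from LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npncaps)
```

## The problem

Bacterial RNA polymerases can initiate transcription with non-canonical
substrates, leaving a small molecule covalently attached to the RNA 5' end —
a non-canonical cap. Beyond the established NAD and CoA caps, dinucleoside
polyphosphates (NpnN: two nucleosides joined 5'-to-5' through a chain of
*n* phosphates, such as Ap3A or Gp4G) occur as caps on *E. coli* small RNA,
in both unmethylated and methylated forms. `npncaps` packages the
computational side of that discovery workflow so it can be rerun, audited
and stress-tested on simulated data:

1. enumerate the candidate cap space and its theoretical ion *m/z* values;
2. annotate centroided LC-MS peak lists of nuclease-digested sRNA against
   that library within a ppm tolerance, rejecting species that also appear
   in a no-digestion negative control;
3. confirm candidates by nitrogen counting from paired
   ^14^N/^15^N metabolic-labelling runs;
4. discriminate internal-bridge caps from terminal-polyphosphate isomers by
   predicted in-source and MS^n^ fragments;
5. quantify: standard-addition calibration, relative EIC abundance between
   growth phases, decapping-enzyme classification, gel densitometry
   percentages and first-order cleavage kinetics.

A seeded generator (`synth_truth()`, `simulate_run()`, `simulate_assays()`)
produces every input the pipeline consumes together with its ground truth,
so each stage is testable end to end without any instrument data.

## The mass and ion model

All *m/z* arithmetic is exact monoisotopic arithmetic over an element table
shipped as a TSV (`element_masses()`), with electron-inclusive ion masses:
a deprotonated ion weighs the neutral minus a hydrogen atom plus an
electron, and m/z = ion mass / z. This convention is not a matter of taste
at five-decimal precision: published high-resolution "calc." values for
synthesized cap standards are reproduced to 5 decimals only when the
electron is carried (see `ion_mz_from_formula()`), and the package treats
those four printed values as golden tests of the engine.

A cap's neutral formula follows one condensation rule:

$$\textrm{cap} = \textrm{nucleoside}_1 + \textrm{nucleoside}_2 +
  \mathrm{H}_{n+2}\mathrm{P}_n\mathrm{O}_{3n+1} - 2\,\mathrm{H_2O} +
  k\,\mathrm{CH_2}$$

for *n* bridge phosphates and *k* methyl groups. Methyl position tags
(N1, N2, N6, N7, 2'-O) are carried as metadata and validated against the
base, but do not change mass — every methylation is +CH~2~, and a ribose
2'-O-methyl is represented as a tag on its nucleoside rather than a
distinct sugar type. NAD and CoA enter as stored formula overrides. The
unordered base pair is canonicalised alphabetically so ApnG and GpnA are
one candidate.

^15^N labelling is modelled as complete substitution (the labelling growth
uses ^15^NH~4~Cl as the sole nitrogen source); each nitrogen then adds
0.9970349 Da. Partial incorporation and isotope-envelope simulation are out
of scope — only monoisotopic peaks are modelled.

## Candidate space and annotation

`default_cap_library()` holds purine caps (A/G pairs), bridge lengths 2–6,
0–2 methyls, as [M−H]^−^ and [M−2H]^2−^ ions — the only cap ion species
observed in negative mode — in both label states, plus NAD and CoA.
Pyrimidine bases are supported by the type system but excluded from the
default space, mirroring the species actually reported; pass
`bases = c("A","G","C","U")` to widen.

`match_peaks()` assigns each library ion the peak minimising |ppm error|
within tolerance, breaking ppm ties toward the more intense peak. Defaults:

* `tol_ppm = 20` — published detected values sit up to ~35 ppm from theory
  across the instruments used, so 20 ppm per run is a forgiving but not
  promiscuous window (the survey criterion uses 50 ppm when matching the
  printed values themselves);
* `min_intensity = 50` counts — the stated survey cutoff below which ions
  were not considered;
* one peak per ion, but a peak may serve several ions: isobars are resolved
  downstream by ^15^N pairing and fragmentation, not by the matcher.

Retention time is carried on every peak but not used for matching; no RT
model is in scope. `eic_area()` sums centroid intensities inside a ppm
window (optionally an RT window) — with centroided input and no peak-shape
model, summed intensity is the area surrogate.

`control_filter()` accepts an annotation only if the no-digestion control's
EIC area at the same *m/z* is at most `max_control_fraction = 0.05` of the
sample area. The control reportedly shows *no* cap or nucleotide signal, so
the threshold exists purely to absorb the noise floor; anything present
without digestion is non-covalently bound contamination.

## Nitrogen counting

For a species observed at `mz14` and `mz15` in paired runs at charge *z*,

$$N = \mathrm{round}\left(\frac{(mz_{15}-mz_{14})\,z}{0.9970349}\right)$$

with the residual against the nearest integer hypothesis accepted up to
0.03 Da — about half the spread between printed pairs and theory, and small
enough to separate N from N±1 decisively at these masses (one nitrogen is
worth ~1 Da against ~5 mDa of mass error). Every NpnN cap carries exactly
ten nitrogens, which is the published confirmation signature.

One caveat the implementation is explicit about: an even nitrogen count at
z = 2 aliases exactly to half that count at z = 1 (10 N at z = 2 shifts by
4.985 Th, indistinguishable from 5 N at z = 1), so the residual alone
detects charge misassignment only for odd N. `pair_runs()` therefore takes
the charge from the library entry rather than re-deriving it from the
shift.

## Fragment rules

The fragment module is deliberately rule-based, not a combinatorial
bond-breaking engine: the only fragments used as structural evidence are
phosphoester cleavages and water loss.

* `insource_stability()`: an internal-bridge NpnN survives the ion source
  intact; its isomer with a terminal polyphosphate tail (p~n−1~NpN) sheds
  HPO~3~ (79.96633 Da at z = 1) stepwise down to pNpN. Observing the intact
  ion with no ladder is what proves the internal bridge.
* `predict_msn_fragments()`: phosphoester cleavage on either side of the
  bridge yields the mono-/di-/tri-phosphorylated nucleoside (bounded by the
  bridge length), with and without water loss, methyls staying on their
  side. Unit-resolution instruments print these selections at one decimal,
  so matching them uses an absolute ±0.5 Th window, not ppm.

Fragment intensities (e.g. what fraction fragments in-source) are
instrument-dependent and not predicted.

## Quantification

* `percent_capped()` implements Ar~cap~/(Ar~p~+Ar~cap~)×100 — the only
  reading of the published gel formula bounded by 100 — and is invariant
  under common rescaling of both band areas.
* `standard_addition()` fits the spiked response by ordinary least squares
  and reports the x-intercept magnitude c₀ = b/a in spike units, with a
  delta-method confidence interval from the (a, b) covariance; the source
  assays report only mean ± SD of triplicates, so first-order propagation
  is the proportionate choice. Slope ≤ 0 ("no response") and negative
  intercept ("below blank") are errors, not estimates.
* `relative_abundance()` reports both the ratio of replicate means and the
  mean of per-replicate ratios, since the published "more than two-fold"
  comparison does not say which convention it used.
* `classify_decapping()` uses a cleaved-fraction threshold of 0.5 per
  enzyme: the observed regimes ("completely cleaved within 1 h" vs
  "remained unchanged") sit far from this boundary, so the default is
  insensitive; the class ordering is monotone in the threshold.
* `kinetics_curve()` normalises to the 0-minute aliquot as 100% and fits a
  single exponential on log-remaining (positive points only). The
  normalised curve is the primary output; the rate k and half-life ln2/k
  are convenience summaries, since the source data are fraction-vs-time
  with no stated model.

## What the generator emulates — and what it does not

`simulate_run()` emits, per seed: cap ions with Gaussian *m/z* error
(σ = 3 ppm, the high-resolution regime) and log-normal intensities (median
5 × 10⁴ counts, sdlog 0.5); dominant AMP/GMP/CMP/UMP digestion peaks
(~10⁶ counts); 150 uniform background peaks on 150–1000 Th with exponential
intensities (mean 300 counts), shared between sample and control to emulate
non-covalently bound contamination; a matched ^15^N run in which every
nitrogenous peak moves by N × 0.9970349/z while the nitrogen-free
background stays put. `simulate_assays()` draws standard-addition series at
the three reported concentration scales (75, 1200, 1900 fmol/µg), kinetics
on the sampled time grid (0, 0.5, 1, 2, 5, 10, 20, 40 min) with true rates
0.32/min (a fast cap substrate: ~80% cleaved by 5 min) and ln2/40 (the slow
5'-ppp substrate: 50% at 40 min), decapping areas following the
methylation truth table, and gel lanes at capped fractions 0.27–0.46.
Area noise is multiplicative log-normal at 5% — areas are positive and
reported as mean ± SD over triplicates, which a CV-style model matches.

Passing the recovery suites on these runs shows the pipeline's logic is
sound at realistic mass accuracy and abundance spread. It does **not**
show robustness to what the generator omits: chromatographic peak shapes
and co-elution, profile-mode data, RT drift between runs, partial ^15^N
incorporation, isotope envelopes overlapping the monoisotopic window, or
matrix-dependent ionisation suppression. Absolute abundances measured from
real extracts (e.g. how much NAD cap a microgram of sRNA carries) are
properties of the biology, not of this code, and are not reproduced here.

## Numerical and design notes

* Atomic masses to ≥ 6 decimals; proton 1.00727647 Da; electron
  5.485799 × 10⁻⁴ Da. Formula arithmetic is integer element counts;
  subtraction below zero is an error, which doubles as the
  fragment-conservation check.
* Formula addition requires matching label states — mixing a natural and a
  ^15^N formula is a caught error, not a silent mass blend.
* Library ordering is deterministic (ascending neutral mass) so exports
  diff cleanly; duplicate (structure, ion) pairs are rejected at build
  time.
* The generators save and restore the caller's RNG state, so
  `simulate_run(truth, seed)` is a pure function of its arguments.
* Problem sizes in the shipped tests: 20 seeded pipeline replicates for
  recovery/false-discovery, 100 replicates for the standard-addition and
  kinetics estimator checks — enough for the 5% recovery bands at CV 5%
  noise while keeping the whole suite in seconds.

## Known limitations

Annotation is one-dimensional (*m/z* only); two caps whose compositions
collide within tolerance are separated only if their ^15^N shifts or
fragments differ. Methyl *positions* are never inferred from data — they
are metadata an analyst attaches after comparing retention
times/fragmentation against synthetic standards, which is how the
positional assignments (N7-G plus 2'-O, and N6-A) were made in the source
study. The kinetics fit assumes first-order decay throughout the series;
biphasic behaviour will be summarised, not detected.
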