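---
title: "Estimating cell wall polysaccharide composition from linkage data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell wall polysaccharide composition from linkage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycolinker)
```

## The measurement and the inverse problem

Methylation (linkage) analysis derivatises a cell wall to partially
methylated alditol acetates (PMAAs), one species per combination of
monosaccharide, ring form and substituted carbon positions. GC-MS peak
areas therefore measure *linkages*, not polymers: a profile is a vector
of molar% over codes like `4-Glcp` or `2,3,5-Araf`, summing to 100.
Uronic acids are carboxyl-reduced to 6,6-dideuterio neutral sugars
before derivatisation so that galacturonan and glucuronan linkages
survive and remain distinguishable; the package carries that provenance
as a `uronic_origin` flag on parsed codes and attempts no mass-shift
arithmetic on spectra.

The scientific question runs the other way: which *polysaccharides*
made those linkages? That inverse problem is under-determined — 4-Glcp
can be cellulose, xyloglucan backbone or glucomannan glucose; t-Araf
decorates four different polymer families. `glycolinker` resolves it
with an explicit, deterministic allocation model rather than an
optimisation, so every number in the output can be traced to a rule.

## Stage 1: from peaks to profiles

`parse_peak_table()` reads `peak_id, rt_min, area` CSV/TSV tables with
optional inline spectra (`mz:intensity;...`) and pre-assigned linkages.
Identification against a reference library (`read_spectrum_library()`,
MSP-style text or JSON) uses a cosine similarity over greedily paired
fragments: candidate ion pairs within `mz_tolerance` (default 0.5 Da,
unit-resolution quadrupole data) are accepted in decreasing order of
intensity product, each ion used once. Matching is deterministic; ties
rank by linkage-code string order. A peak is assigned only when the top
hit scores at least the threshold (default 0.7) *and* falls inside the
library entry's retention window when one is provided — fragmentation
patterns of positional isomers can be near-identical, and retention
separates them.

`compute_molar_composition()` pools areas per linkage, divides by
per-linkage response factors, and normalises to 100. Factors default
to 1 — the conventional relative-area reading of PMAA data — because
published profiles of this kind are rarely effective-carbon-response
corrected; a user-supplied factor table restores rigour when standards
are available. `aggregate_replicates()` computes per-linkage mean and
sample standard deviation (n − 1), treating a linkage absent from a
replicate as a measured zero: molar% is compositional, and
non-detection is information, not missingness. Input profiles may sum
to 100 ± 0.5 to absorb rounding in hand-entered tables; computed
profiles are exact to 1e-9.

`compute_yields()` tracks recovered mass per fraction as percent of
starting mass. Losses are expected (dialysis, washes), so yields may
sum below 100; totals above 102% raise an over-recovery flag.

## Stage 2: the three-pass allocator

`allocate_linkages()` distributes each linkage's molar% over the
classes of an assignment table (default: the standard dicot table with
eleven reporting classes — AB, AG-I, AG-II/ET, HX, XG, CA, CE, RG-I,
HG, HM, UA). Extensin is merged with AG-II as one reporting class
because extensin's glycan linkage types are a subset of AG-II's;
3-Glcp is read as callose because dicot walls lack mixed-linkage
glucan; t-Fucp is carried under both AG-II/ET and XG.

* **Pass 1** hands every exclusively mapped linkage to its class.
* **Pass 2** applies stoichiometric rules in a fixed order.
  *4-GalAp*: RG-I receives `min(4-GalAp, 2-Rhap + 2,4-Rhap)` under the
  alternating-backbone assumption, the rest is HG. *4-Glcp*: XG takes up
  to `4,6-Glcp × 1/3` (XXXG motif), HM up to `4-Manp × 1/3`
  (glucomannan Glc:Man), cellulose takes the remainder. *Shared
  terminals* split in proportion to branch-point demand — the weighted
  sum of each candidate class's already-allocated demand-set linkages
  (2,3,4-Xylp counts twice for heteroxylan: a doubly branched backbone
  residue bears two arabinosyl termini). Zero demand everywhere sends
  the full amount to the first candidate in table row order, a
  deterministic fallback preferred over silently dropping signal.
* **Pass 3** collects unmapped linkages into UA.

The two ratio constants, the demand sets, the class map and the
fraction overrides are all data (`load_assignment_table()` accepts
YAML/JSON), not code. The published protocol this table descends from
does not print its partition arithmetic; the constants here are the
assumptions its polymer models imply (XXXG xyloglucan, alternating
RG-I backbone, 1:3 glucomannan), stated once and exposed for tuning.
How terminal galactose and fucose were split between AG-II/ET, XG and
HM in any particular published dataset is not recoverable; the
demand-proportional rule is this package's documented, configurable
choice.

The one fraction-specific rule: in the pooled EDTA + Na₂CO₃ extract
and the 4 M KOH extract, the CE × 4-Glcp pair is suppressed, because
cellulose does not solubilise in those extractants. The leftover
4-Glcp joins xyloglucan rather than UA — the rule reassigns
solubilised backbone glucose, it does not discard it.

Row conservation (allocated + UA = input, per linkage, to 1e-9) is an
invariant, tested over randomised profiles and against an independent
single-linkage brute-force oracle in the test suite.

## Stage 3: antibody screens

ELISA and MAPP ODs are processed with three composable steps:
`subtract_background()` (corrected = max(0, od − background); negatives
floored because below-background means no binding), `average_replicates()`
(triplicate means, count retained), `collapse_dilutions()` (default
`max`, the strongest in-range spot; `mean` or a named dilution are
alternatives — the combination rule used in published MAPP work is
not standardised, so the mode is explicit and logged).
`build_heatmap()` orders probe rows by epitope group and columns by
the extract series, exporting corrected means losslessly with no
hidden normalisation; per-extract carbohydrate amounts are reported
alongside, not divided through.

## Stage 4: isolate analytics

`aggregate_cazome()` sums dbCAN-style family counts into functional
categories per genome. The bundled table of six canola-meal
*Bacteroides* isolates and two wild-type reference strains keeps GH27's
printed double listing (debranching *and* oligosaccharide-degrading) —
both rows count toward their category totals, with a warning — because
that is how the source table's totals add up. `flag_enrichment()` uses
strict inequality against the paired reference ("more members", so
equality is not enrichment). `cazome_ratio()` reports table-scoped
grand-total quotients and records that scope: ratios computed over a
curated family subset are not genome-wide CAZyme ratios, and the
package does not present them as such.

`classify_growth()` turns manual OD600 readings into a three-way call.
Published descriptions of such screens say "moderate growth" and "low
density" without numbers; the package makes the split explicit:
high-efficiency requires the blank-corrected 24 h OD to reach 25% of
the glucose control's and an absolute floor of 0.1; clearing only the
floor is low; otherwise none. Both parameters are arguments and are
echoed in the output. The label is monotone in the 24 h OD by
construction.

## The forward simulator

`generate_cell_wall()` mixes per-class polymer templates — each a
linkage distribution implied by degree of polymerisation, branch
fraction and motif ratios — into a noiseless profile; `add_noise()`
perturbs each linkage with a zero-truncated Gaussian of sd = CV × mean
and renormalises (the simplest compositional noise consistent with
mean-and-whisker replicate data); `generate_fractionation()` splits
class masses across fractions by an extraction-efficiency matrix with
exact mass conservation; `generate_antibody_plate()` and
`generate_growth_curves()` produce linear-response plates and logistic
curves. All generators are bitwise reproducible under a fixed seed.

Two design points matter for interpreting test results:

* **Templates are demand-matched.** Default templates emit shared
  terminal residues at exactly their class's branch-point demand (e.g.
  the arabinan template emits one t-Araf per 2,5-Araf; the heteromannan
  template sets glucose to `4-Manp × 1/3`), and only non-reducing
  termini, at 1/DP. This makes the inverse problem well-posed by
  construction: the zero-noise round trip recovers the true composition
  to 1e-9, which validates the allocator's arithmetic. It does *not*
  show that real walls satisfy these assumptions — real xyloglucan
  deviates from pure XXXG, real arabinans carry double branches,
  fucosylation couples t-Fucp demand across classes. Template
  parameters (`fuc_fraction`, `double_branch_fraction`, finite `dp`,
  mismatched ratios) deliberately break the matching for stress
  testing.
* **Noise is compositional but uncorrelated.** Real PMAA replicates
  share derivatisation and injection effects across linkages; the
  simulator's independent per-linkage noise is optimistic about
  cancellation. The recovery bound tested (every class within
  2 molar% at CV 5%, triplicates, 100 trials; observed maximum ≈ 1.6)
  is therefore a statement about the pipeline, not about instrument
  performance.

Default study conditions: four replicates for whole walls and three
per fraction is the replication structure the aggregation defaults
mirror; simulated recovery uses a ten-class mixture (CE 25, HG 15,
XG 14, AB 12, RG-I 8, HX 8, AG-II/ET 6, CA 5, AG-I 4, HM 3 molar%)
chosen as a realistic dicot oilseed wall, at CV 5% and n = 3. Property
suites use 200–1000 randomised cases per invariant; these sizes keep
the full suite under half a minute while the extreme-value statistics
they check are already stable.

## Numerical choices and degenerate inputs

* Ties in spectral ranking break lexicographically; greedy pairing
  breaks intensity-product ties by smaller m/z difference.
* Zero total adjusted area, unassigned peaks, mixed-fraction
  aggregation, non-summing compositions and negative masses all raise
  errors naming the offending records rather than propagating NaN.
* A noise draw that zeroes an entire replicate (possible only at
  extreme CV) falls back to the noiseless profile rather than dividing
  by zero.
* `linkage_profile()` accepts totals within ±0.5 of 100 for
  hand-entered data; everything computed internally is exact to 1e-9.

## Known limitations

* Composition is relative (molar%); absolute mg/g composition and
  cross-linking between the pectic side-chain polymers and RG-I are out
  of scope.
* The allocator's constants are assumptions, not fits; walls rich in
  mixed-linkage glucan (grasses) or fucogalactoxyloglucan need a
  different table, which the config format supports.
* Spectral matching assumes centroided unit-resolution spectra;
  retention-index calibration and peak deconvolution belong upstream.
* The growth classifier reads a single late time point; it does not fit
  growth rates or lags.
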