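---
title: "Screening for stress-limiting lipokines and their effectors"
author: "lipokineScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for stress-limiting lipokines and their effectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipokineScreen)
```

## The scientific problem

Cells under cytotoxic stress remodel their membrane glycerophospholipids.
One recurring signature is the coordinate depletion of phosphatidylinositol
(PI) species that carry monounsaturated fatty acids (MUFAs, exactly one
double bond), while stress-kinase signalling — read out as phospho-p38 MAPK
— rises. A lipid whose abundance tracks (inversely) with a stress readout
across many unrelated stressors, and whose supplementation blunts the
stress response, behaves as a *stress-limiting lipokine*; PI(18:1/18:1) is
the prototype. Downstream, proteins that (a) sit in stress-signalling
pathways, (b) respond concordantly to chemically distinct stressors, and
(c) are preferentially rescued by the active lipid over a saturated control
lipid are candidate *effectors* of that lipokine (the phosphatase subunit
Ppp2ca is the prototype).

This package implements that entire computational chain as reusable,
tested components, together with seeded synthetic-data generators so the
chain can be validated end to end without any external download.

## Data model

All tabular data live in an `AbundanceExperiment`, a thin
`SummarizedExperiment` subclass: one feature × sample assay, the design
(`treatment`, `timepoint_h`, `replicate`, optional `normalizer`) in
`colData`, parsed lipid annotation in `rowData`, and an `abundanceScale`
slot tracking the normalisation stage (`raw_intensity` → `absolute` →
`proportion_pct` / `pct_of_control`). Validity enforces non-negative
values, unique (treatment, timepoint, replicate) triples and non-negative
times, so malformed designs fail at construction, not mid-pipeline.

Lipid names are parsed by `parseSpecies()`. Chain order is treated as
**unordered**: targeted MRM acquisition detects fatty-acyl fragment anions
without positional (sn-1/sn-2) assignment, so `PI(18:1/16:0)` and
`PI(16:0/18:1)` are the same species and the canonical form sorts chains
by carbons, then double bonds. Sum-composition names (`PI(36:2)`) are
accepted but marked chain-unresolved — they denote a mixture of isobaric
species — and are *excluded with a warning* from MUFA aggregation rather
than silently dropped or guessed. Ether/plasmalogen (`O-`/`P-`) and
sphingoid-base notations are rejected outright; supporting them
half-heartedly would corrupt saturation statistics.

## Quantification conventions

* **Relative proportions** rescale each (subclass, sample) block to sum to
  100, matching how targeted lipidomics is conventionally reported
  ("percent of subclass"). Proportions make samples comparable when
  absolute recovery varies; the scale-invariance property (multiplying a
  subclass-sample by any constant leaves proportions unchanged) is tested
  explicitly.
* **Percent of control** divides by the *mean* of the vehicle replicates
  at the same timepoint. We deliberately use the vehicle mean rather than
  any replicate pairing: the underlying experiments are independent
  replicates without a pairing structure. The vehicle-group mean is then
  exactly 100 at every timepoint, which doubles as a self-check.
* **Zeros** are kept as zeros for proportions. For log-scale testing a
  pseudo-proportion ε (default 1e-3 percentage points) is added before
  log10; this only matters for censored species and is configurable in
  `fdrConfig()`.
* **Uptake QC** for supplementation experiments passes at a ≥30% relative
  increase of the supplemented species' proportion, boundary inclusive —
  "at least 30%" includes 30%.

## The co-regulation network

Networks are built from **mean condition profiles**: one column per
(treatment, timepoint) cell, replicates averaged, vehicle cells included
(they anchor the baseline). Correlation needs at least 3 cells; features
with missing cells are compared pairwise on shared cells. An edge joins
two species iff Pearson *r* **strictly** exceeds 0.7, and a species is
flagged against the external readout iff *r* is **strictly** below −0.6 —
both relations are printed as strict inequalities wherever these
thresholds are used, and we keep them strict. No p-value is attached to
edges: the screen thresholds the correlation itself. Clusters are plain
connected components (igraph); isolates are singleton clusters. Exports
(SIF, GraphML) are deterministically ordered so re-exports are
byte-identical.

One design question is which cells form the correlation support when
several stressors are available. We default to pooling *all* cells of the
experiment into one support vector — the broader the support, the more a
high correlation means shared regulation rather than a single-condition
coincidence — and expose the profile matrix so callers can subset cells
before `buildNetwork()` if they want a per-stressor network.

## The differential screen

Per feature, an unpaired **pooled-variance Student t** (two-sided) is
computed on log10 values; Welch's form is available behind a flag but is
not the default, since the screens this mirrors use the classical pooled
test. The base of the log transform does not affect the t statistic
(effects are reported on the raw percentage scale regardless); we use
log10 for interpretability.

The effect size is the **mean difference of percentage changes**: every
replicate is expressed as `100·(x − ref_mean)/ref_mean` and the effect is
the mean change in the treatment group minus the mean change in the
reference group, in percentage points.

Multiplicity is handled by the **two-stage adaptive linear step-up
procedure** (Benjamini, Krieger & Yekutieli 2006) at q = 0.05:

1. Stage 1: linear step-up at q′ = q/(1+q); r₁ rejections.
2. If r₁ = 0, stop (no discoveries); if r₁ = m, all are discoveries.
3. Otherwise estimate m₀ = m − r₁ and re-run the step-up at q′·m/m₀.

The procedure name pins down the rejection set but not an "adjusted
p-value". We define adjusted values by the step-up-min form
`min(1, min_{j≥i} p_(j)·(1+q)·m₀/j)` so that thresholding `adjusted ≤ q`
reproduces the two-stage rejection set *exactly*; that equivalence, and
agreement with an independently coded definitional oracle over 1000 random
p-vectors, are asserted in the test suite. m is the number of features
actually tested: features failing preconditions (zero reference mean) are
excluded *before* m is counted, and the full species panel — not each
subclass separately — forms one family, matching how the screens are
presented per figure.

## The effector filter

Protein changes are means over replicates of `100·value/vehicle_mean −
100`, signed percentage points. The three criteria are:

* **(i) pathway membership** in any user-supplied set (plain text lists;
  pathway databases are versioned and curated outside this package);
* **(ii) concordance**: same sign and |change| ≥ 20 points under *every*
  stressor — "≥" is inclusive, and direction is sign-agnostic (an
  up-regulated protein can be rescued downward);
* **(iii) preferential rescue**: attenuation (|stress effect| minus
  |co-treatment effect|, same-sign) ≥ 10 points by the test lipid and
  ≥ 10 points larger than the control lipid's attenuation. All thresholds
  are on the same percent-of-vehicle scale as criterion (ii). A
  co-treatment that overshoots past vehicle (sign flip) is credited only
  down to zero effect: "diminishing" an effect means moving it toward
  baseline, and unbounded overshoot credit would reward artifacts.

The thresholds are applied to **mean** changes (not per-replicate), which
is how such filters are conventionally summarised; the audit table retains
every change and flag so the decision for any protein can be re-derived by
eye.

## Synthetic data: what it emulates, and what it does not

`simulateLipidome()` emulates a multi-stressor time-course: 9 cytotoxic
treatments plus vehicle, timepoints 0.17/6/24/48 h, 3 independent
replicates — the design shape of the experiments this pipeline targets.
Species baselines are log-normal; a planted cluster of 6 MUFA-containing
PI species shares one latent depletion trajectory falling linearly in time
to 1 − depth (default depth 0.6) under every non-vehicle treatment;
replicate noise is multiplicative log-normal (default SD 0.1 on the
natural-log scale, i.e. ~10% CV — typical for targeted MS). Noise is
multiplicative because MS intensity error is proportional and positivity
must be preserved. `simulateReadout()` produces a per-cell readout
`baseline + coupling·(1 − latent) + Gaussian noise` (defaults 1, 1.5,
0.05), so the planted species are anti-correlated with it by construction
and exactly −1 in the noiseless limit. `simulateProteome()` plants a
Ppp2ca-like effector (−35/−30/−40 points under the three stressors,
rescued to −15 by the test lipid but only to −35 by the control) among 200
null proteins with additive noise of 5 points on the percent scale —
additive there because that is the scale the filter operates on.

What the generators do **not** model: missing-not-at-random censoring,
isotopic interference, batch effects, chromatographic drift, correlated
noise between species sharing fragments, or peptide-to-protein inference
ambiguity. Passing the recovery tests therefore demonstrates that the
*algorithms* are correct and calibrated under their stated assumptions —
not that real data meet those assumptions.

In the noiseless limits every planted parameter is recovered exactly
(tested); with default noise, the planted cluster is recovered as one
connected component at the 0.7 threshold, all planted species are flagged
at −0.6, and the planted effector is the unique nominee — these
end-to-end recoveries are acceptance-tested with fixed seeds.

## Numerical and reproducibility choices

* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state, so library code never perturbs a user's stream; identical
  seeds give byte-identical tables and pipeline manifests (hash-checked).
* The FDR calibration in `scripts/acceptance.R` uses 2000 replicates of
  m = 200 features (n = 5 per group, 25% true effects of shift 2.0 —
  roughly 80% marginal power per effect at α = 0.05); at that size the
  Monte-Carlo standard error of the FDR estimate is ~0.1 percentage
  points, small against the 5% level being verified, and the run completes
  in seconds.
* Correlations use `stats::cor` with pairwise-complete observations and a
  minimum of 3 shared cells; below that the correlation is reported
  missing and the pair gets no edge, with a warning.
* Ties and ordering: cluster lists are sorted (size, then first member),
  edges (from, to) lexicographically with `from < to`, cells by treatment
  appearance then timepoint — all outputs are deterministic.
* The orchestration layer is the R API itself: `runPipeline()` takes one
  config (list or YAML/JSON) holding every stage threshold with the
  screening defaults (0.7, −0.6, 0.05, 20, 10, 10, 30), validates it
  before any computation, and writes a manifest (config echo, seed,
  package version, md5 per output) so a run can be audited and repeated;
  a shell wrapper would add nothing over `Rscript -e`.

## Known limitations

* The lipid grammar covers the diacyl/lyso/triacyl classes used by this
  pipeline (PC, PE, PS, PI, LPI, SM, TAG, CE, FA, CoA); it is not a
  general lipidomics nomenclature engine (no ether lipids, no oxidised
  species, no mass computation).
* The network is a plain thresholded correlation graph — no partial
  correlations, no soft thresholding, no edge significance — because the
  screen it implements thresholds r directly.
* `two_sample_t` assumes (approximate) log-normality; the screen's other
  companions (ANOVA/Tukey, mixed models, normality tests) are ordinary
  statistics available in base R and are deliberately out of scope here.
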