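---
title: "Peptide-level differential abundance for ubiquitylation screens: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-level differential abundance for ubiquitylation screens: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubiquant)
library(dplyr)
```

## Scope and data model

`ubiquant` starts downstream of database search and XIC extraction: its
input is a flat, long-format peptide quantification table (TSV), the common
denominator of exported label-free quantification reports. Vendor raw
files, mzML and search-engine native formats are deliberately out of scope,
as are identification-level FDR and peptide-to-protein inference for shared
peptides. Missing intensities are encoded as `NA`, never 0: an unobserved
XIC carries no area, and a zero would corrupt every log-scale statistic
downstream (readers and the log2 transform both enforce this contract).

Three experiment layouts are built in (`screen_designs()`), matching a
typical E3-ligase substrate screen of parental cells against
catalytically-dead clones: a fractionated whole proteome (3 vs 6 biological
replicates, 6 fractions), a diGly site-level ubiquitylome (3 vs 3, two MS
injections per sample) and a pan-UB protein-level ubiquitylome (4 vs 8).
Ubiquitylation sites use 1-based protein coordinates with the canonical key
`"<protein>_K<position>"`.

A peptide carrying two or more GG remnants contributes one observation to
*each* of its sites. Search reports rarely state how multiply-modified
evidence should be divided, and silently dropping it would bias exactly the
multiply-ubiquitylated features a ligase screen cares about; duplication is
the transparent choice and is stated prominently here because conventions
differ between tools.

## The preprocessing chain

1. **Fraction summation.** High-pH fractionation splits one peptide's signal
   over a few fractions; areas are summed per (peptide, condition,
   replicate, injection) cell, ignoring missing fractions. A cell is
   missing only if every fraction is.
2. **Technical-replicate merging.** Repeated injections are averaged on the
   *linear* intensity scale — XICs are areas, and the merge happens before
   any log transform. A value measured once passes through unchanged.
   Whether other pipelines average on the linear or log scale is rarely
   documented; linear is this package's recorded assumption.
3. **Shared proteotypic peptides.** Only proteotypic peptides quantify a
   feature. Within a feature, a peptide enters the model only if it has at
   least one non-missing observation in *each* condition ("shared"). A
   stricter reading (presence in every replicate) would make the separate
   ≥ 3-replicate detection filter redundant, so sharing is defined at the
   peptide level. No cap is applied to the number of shared peptides by
   default — an optional `top_n` knob (highest total intensity first)
   exists for compatibility with capped-matching quantifiers, but unlimited
   is the default and the tested configuration.
4. **Condition-specific features.** Features whose observations all lie in
   one condition are not discarded: they are flagged (`a_only` / `b_only`),
   skipped by the model, and carried to candidate selection on the
   detection filter alone. Inventing a pseudo-p-value for them would
   overstate the evidence; the flag keeps them honest. Detection counts are
   recorded *before* the shared-peptide filter, so specific features have
   meaningful counts.

## Normalization

Log2 intensities of each biological replicate are corrected for location
and spread using the replicate's **total signal** (all quantified peptide
observations, not per-feature): for replicate $j$ with median $m_j$ and
robust scale $s_j$,

$$x' = \frac{x - m_j}{s_j}\,\bar s + \bar m,$$

with $\bar m$, $\bar s$ the across-replicate means, so intensities stay in
a familiar range while all replicates end with identical medians and
scales. The scale estimator is the MAD (scaled by 1.4826), chosen for
robustness; the IQR (scaled by 1.349) is available via
`scale_estimator = "iqr"`. `normalization = "median"` centres without
rescaling; `"none"` is the identity.

Two caveats are worth stating plainly:

* The output is unique only up to the common anchors $\bar m, \bar s$:
  warping one replicate column changes the anchors and hence shifts all
  columns by a common affine map. The standardized values
  $(x - m_j)/s_j$ — everything the inference sees, up to that common map —
  are invariant, and that is the form the test suite checks.
* Any data-dependent normalization perturbs injected effects at a small but
  nonzero level whenever changed features move one condition's median or
  MAD. The exact-recovery checks therefore run with
  `normalization = "none"`, which isolates the estimator; with the default
  normalization and a realistic (~1%) fraction of changed features the
  perturbation is of the order of 0.01–0.03 log2 units (measured by the
  acceptance script's bias figure).

A per-replicate Anderson–Darling normality check (`nortest::ad.test`,
requiring ≥ 8 values) is logged in the normalization report. It is
**advisory only** — it never gates the pipeline, because no remediation is
defined for a failing replicate; it exists so an analyst can spot a
pathological injection.

## Outlier removal

Within each feature × condition cell, observations are first centred on
their peptide's mean across all replicates of both conditions — otherwise
ordinary ionization differences between peptides would masquerade as
outliers — and then filtered with Tukey's fences: retain values in
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$, $k = 1.5$ by default.
Quartiles use linear interpolation (R's type 7, under which $Q_1$ of
$\{1,2,3,4\}$ is 1.75); the convention is stated because fence membership
depends on it. Cells with fewer than 4 values pass unfiltered — quartiles
of two or three points carry no outlier information. Zero-IQR cells retain
everything (all values sit exactly at the fences). Re-filtering the
retained values against the *original* fences removes nothing.

## The per-feature model

The fixed-effects two-factor model

$$\log_2 x_{p,c,r} = \mu + \beta_p + \delta\,\mathbf 1[c = b] + \varepsilon$$

absorbs peptide ionization differences in $\beta_p$ and treats biological
replicates as independent observations (the residual). $\hat\delta$ is the
log2 fold change of condition b over condition a; its two-sided p-value
uses the t-distribution with the residual degrees of freedom. A
single-peptide feature reduces exactly to the two-sample equal-variance
t-test. Alternatives — replicates as a blocking factor, mixed effects,
moderated (empirical-Bayes) variance — are deliberate non-goals for this
version: the fixed-effects form is the simplest model consistent with
"adjusted on peptides and biological replicates", and the package records
it as its own choice at the API surface. Degenerate fits are flagged, not
guessed at: fewer than 2 observations in a condition, no residual degrees
of freedom, an inestimable condition contrast, or (near-)zero residual
variance each yield a missing p-value with a `note`, and such features are
excluded from the multiple-testing family.

Benjamini–Hochberg adjustment (step-up, via `stats::p.adjust`) runs over
the *tested* features only; condition-specific and degenerate features are
excluded from the family count m, since BH's m must count hypotheses that
were actually tested. The test suite and acceptance script verify the
implementation against the literal $O(m^2)$ step-up definition,
exhaustively for short vectors and on random length-200 vectors with ties.

## Candidate selection and integration

Candidates satisfy, with the default configuration
(`quant_config()`): linear fold ≥ 2 in the experiment's direction
(inclusive — "minimum 2-fold"), adjusted p ≤ 0.05 (inclusive), and at
least one peptide identified in ≥ 3 biological replicates of *either*
condition (the filter takes the max of the per-condition detection
counts). Condition-specific features join when their presence pattern
matches the direction — observed only in the test condition counts as an
increase there, observed only in the reference as a decrease — and they
pass the detection filter in the condition where they exist (applying it
in the condition where they are absent would be vacuous).

Cross-experiment integration is at the protein level: site-level candidate
sets are first projected to their distinct proteins
(`collapse_sites_to_proteins()`, provenance mapping retained), then all
pairwise and full intersections are computed with deterministic
lexicographic ordering. Heatmap tables render the linear fold
$2^{|\hat\delta|}$ with a direction flag and significance stars
(`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001). Stars are computed from the
*adjusted* p-value — the quantity the selection criterion thresholds —
and condition-specific members render as `"specific"` with no stars.
Protein-level values repeat on each site row of the same protein, so
site-resolution information is never collapsed away in the display.

## The synthetic-data generator

`simulate_experiment()` draws, for feature $f$, peptide $p$, replicate $r$
of condition $c$ and injection $t$:

$$\log_2 x = B_f + P_p + R_{c,r} + \Delta_f\,\mathbf 1[c=b] + \varepsilon + \tau_t$$

with $B_f \sim N(20, 2)$ (log2 XIC areas), $P_p \sim N(0, 1)$ — peptide
ionization efficiency dominates between-peptide variance in real LFQ data,
and the SD is exposed as `sigma_peptide` — $R_{c,r} \sim N(0, 0.3)$ shared
by every peptide in the replicate, $\varepsilon \sim N(0, 0.5)$ and
$\tau \sim N(0, 0.2)$ per injection (the injection term is drawn even for
single-injection designs, where it simply adds to the residual). Default
rates: 1% of features changed — screens of this kind report hit rates of
0.6–1.3% — with a +1.5 log2 effect, 0.5% specific to each condition, 1%
outlier observations shifted by +4 log2 units, and 5% missing
observations. Missingness is missing-completely-at-random by default; an
intensity-dependent mode (logistic in log2 intensity, low-abundance rows
more likely missing) stresses the detection filter the way real LFQ data
would. Fractionated designs split each injection's linear intensity over
one or two randomly chosen fractions (a peptide elutes in few adjacent
high-pH fractions — an emulation choice, not a claim about any dataset)
with proportions summing to 1, so fraction summation recovers the pre-split
intensity exactly; missingness applies to the emitted rows, i.e. after
splitting. Exactly `round(rate × n_features)` features receive each flag,
so truth bookkeeping is exact by construction.

All randomness flows from one RNG stream keyed by `seed` and consumed in a
fixed documented order (feature flags → baselines → peptide counts → site
positions → peptide offsets → replicate effects → residuals → injection
noise → outliers → fractions → missingness), with fixed-length vectorized
draws, so adding a parameter later cannot silently reshuffle existing
draws within a major version.

What the generator does *not* emulate: retention times, charge states,
spectra, identification errors, interference/co-elution, batch structure
beyond per-replicate location/scale, or correlated missingness across
peptides of a feature. Passing tests therefore demonstrate the statistical
machinery is correct under the stated generative model — not that any
particular real dataset satisfies that model.

## The deterministic toy fixture

`fixture_toy_table()` is the hand-constructed end-to-end surface: six
features under the 4-vs-8 protein-level design — 4-fold up, 4-fold down,
one feature per condition-specific pattern, a 4-peptide null and a
single-peptide null — plus a planted non-proteotypic peptide, a missing
cell and one gross outlier observation. Peptide offsets are chosen so that
each replicate column's median falls inside a run of null-feature values
and the MAD is identical across conditions by construction; residual noise
(SD 0.15, fixed internal seed) makes the fits non-degenerate while keeping
repeated calls bit-identical. Even so, a robust normalization estimated
from 13 values per column is jumpy at the cluster gaps, which attenuates
the planted effects visibly (the +2 planted log2 fold is recovered at
about +1.6): a reminder of what median/MAD normalization does to very
small tables, and the reason the golden-file test freezes the complete
output rather than asserting round numbers.

## Null calibration and problem sizes

The variance components above were fixed, once, so that the global-null
simulation is calibrated: with no injected effects, no outliers and no
missingness (the textbook null for checking a sampling distribution —
robustness to contamination is exercised separately), the raw p-values of
the pan-UB design are close to uniform and the proportion of features at
adjusted p ≤ 0.05 stays far below the nominal level. The suite checks this
with a Kolmogorov–Smirnov test on 500 features and the achieved
false-discovery proportion over 20 simulation replicates.

One honest caveat, measured rather than assumed: testing *after* trimming
is mildly anticonservative. Tukey's fences at k = 1.5 remove the most
extreme ~0.7% of observations even when the data contain no true outliers,
deflating the residual variance estimate; under the clean global null the
raw p-values fall at or below 0.05 for about 8% of features instead of 5%
(disabling the fences restores the exact nominal level). This is an
inherent property of the fence-then-test procedure, not of this
implementation, and it is one reason candidate selection thresholds the
*adjusted* p-value, the fold change and the detection filter jointly: the
BH-adjusted discovery proportion under the global null stays near zero
(about 0.001 in the 20-replicate check). Effect recovery under realistic
noise uses five simulations of 2000 features (5 peptides each, 1% changed
at +1.5 log2): mean bias of $\hat\delta$ stays within 0.05 log2 units and
the empirical power at the screen thresholds is essentially 1. These
problem sizes give Monte-Carlo standard errors comfortably below the
asserted margins while keeping the whole suite in the minutes range.

## Known limitations

* The linear model uses raw (unmoderated) per-feature variance; with very
  few peptides and replicates, limma-style moderation would gain power.
* No imputation: features missing everywhere in one condition become
  condition-specific rather than estimated; intensity-dependent missingness
  biases fold changes of low-abundance features as it does in all LFQ
  pipelines without imputation.
* Site localization is taken at face value; ambiguity scoring is out of
  scope, and site positions are assumed correct as annotated.
* TSV is the only exchange format; mzTab/mzIdentML importers are non-goals.
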