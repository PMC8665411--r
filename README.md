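# ubiquant

Label-free quantitative (LFQ) differential-abundance analysis for
E3-ubiquitin-ligase substrate screens, implemented as a tidyverse-native R
package.

## The problem

To find the substrates of an E3 ligase such as RNF111, a screen compares a
catalytically inactivated clone against the parental cell line in up to
three complementary mass-spectrometry experiments:

* a **whole proteome** (degradative substrates accumulate when the ligase is
  dead — candidates *increase*),
* a **diGly ubiquitylome**: K-ε-GG immunoprecipitation quantifies individual
  ubiquitylation sites (candidates *decrease*),
* a **pan-UB ubiquitylome**: pan-ubiquitin nanobody enrichment quantifies
  ubiquitylated proteins (candidates *decrease*).

The raw material is a long table of peptide extracted-ion-chromatogram (XIC)
intensities, one row per peptide per (condition, biological replicate,
technical replicate, fraction) cell. `ubiquant` takes such tables from
search-engine output to candidate lists and cross-experiment integration,
and ships a synthetic-data generator with known ground truth so that every
stage can be tested against an oracle.

## The statistical model

For each quantified feature (protein accession or ubiquitylation site
`protein_K<position>`), after

1. summing XICs across fractions,
2. averaging technical replicates (linear scale),
3. restricting to proteotypic peptides *shared* between the two conditions,
4. log2 transform and per-replicate median-and-scale normalization of the
   total signal (median centring, MAD-based scale matching), and
5. Tukey's-fences outlier removal (k = 1.5, on peptide-centred residuals,
   within each feature × condition cell),

the package fits, per feature, the fixed-effects linear model

    log2 x_{p,c,r} = mu + beta_p + delta * 1[c = KO] + eps,   eps ~ N(0, s^2)

where `beta_p` are peptide main effects ("adjusted on peptides") and
biological replicates enter as independent observations ("adjusted on
replicates"). `delta-hat` is the log2 fold change KO/parental, tested with a
two-sided t-test on the residual degrees of freedom; p-values are adjusted
with the Benjamini–Hochberg step-up procedure across the tested features.
Features quantified in a single condition carry no p-value and enter the
candidate list on the detection filter alone. Candidates satisfy

* |fold change| ≥ 2 in the experiment's direction (boundary included),
* adjusted p ≤ 0.05,
* at least one peptide identified in ≥ 3 biological replicates of either
  condition.

Site-level candidate sets are collapsed to proteins before Venn-style
cross-experiment intersection; heatmap tables annotate linear folds with
significance stars (`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001).

## Worked example

The built-in deterministic fixture is a pan-UB-style design (4 parental vs
8 KO replicates) with six planted features: a 4-fold increase, a 4-fold
decrease, one protein per condition-specific pattern, and two nulls.

```r
library(ubiquant)

fx  <- fixture_toy_table()
res <- fx$table |>
  sum_fractions() |>
  merge_technical_replicates() |>
  run_differential()

res[, c("feature_id", "log2_fc", "adj_p", "detect_reps_a",
        "detect_reps_b", "specific_flag")]
#> # A tibble: 6 × 6
#>   feature_id  log2_fc     adj_p detect_reps_a detect_reps_b specific_flag
#>   <chr>         <dbl>     <dbl>         <int>         <int> <chr>
#> 1 FEAT_AONLY  NA      NA                    4             0 a_only
#> 2 FEAT_BONLY  NA      NA                    0             8 b_only
#> 3 FEAT_DOWN   -1.90    3.40e-20             4             8 none
#> 4 FEAT_NULL   -0.0396  6.47e- 1             4             8 none
#> 5 FEAT_SINGLE -0.147   9.22e- 2             4             8 none
#> 6 FEAT_UP      1.61    2.42e-20             4             8 none
```

The planted 4-fold decrease is recovered at −1.90 log2 units (the robust
normalization of a 6-feature toy table attenuates it slightly; see the
methods vignette), both nulls sit far from the cuts, and the two
condition-specific proteins carry no model statistics. Selecting
ubiquitylome-style candidates (decrease in KO):

```r
cand <- select_candidates(res, quant_config(direction = "decrease"),
                          "toy ubiquitylome")
cand[, c("feature_id", "log2_fc", "adj_p", "is_specific")]
#> <candidate_set 'toy ubiquitylome'> 2 members (1 condition-specific), direction decrease, fold >= 2, adj p <= 0.05
#> # A tibble: 2 × 4
#>   feature_id log2_fc     adj_p is_specific
#>   <chr>        <dbl>     <dbl> <lgl>
#> 1 FEAT_AONLY   NA    NA        TRUE
#> 2 FEAT_DOWN    -1.90  3.40e-20 FALSE
```

`FEAT_AONLY` — present only in the parental cells, i.e. lost in the KO — is
selected as a decrease-consistent condition-specific candidate.
`autoplot(res)` draws the volcano plot; `simulate_experiment()`,
`run_pipeline()` and `intersect_candidates()` scale the same workflow to
full multi-experiment screens with written results, integration reports and
a reproducibility manifest.

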