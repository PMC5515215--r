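# quorumflow

Analysis of community-level quorum sensing (QS) and quorum quenching (QQ) in
activated sludge, for microbial ecologists and environmental engineers who
study how signalling shapes floccular and granular biofilm communities.

Bacteria in sludge bioreactors communicate through *N*-acyl homoserine
lactones (AHLs), diffusible signals named by acyl chain length and C3
substitution (C6-HSL, 3OC8-HSL, 3OC12-HSL, ...). Other community members
enzymatically destroy those signals — quorum quenching — and the balance of
the two activities tracks whether the biomass stays as loose flocs or
assembles into dense granules. quorumflow implements the complete numeric
workflow for studying that balance:

* **Tag profiling** (`match_degenerate()`, `extract_v6_tags()`,
  `filter_tags()`, `build_tag_table()`, `top_n_tags()`, `profile_tags()`) —
  fast community profiling that scans each sequencing read with the
  degenerate universal V6 primer 5'-CGACRRCCATGCANCACCT-3' and takes the
  33 nt downstream of each match as a taxon tag. Two literal filters remove
  artefacts: a tag must be seen in ≥ 2 reads, and no single read type
  (identical full-read sequence) may account for ≥ 50 % of its coverage.
* **Degradation kinetics** (`fit_zero_order()`, `fit_first_order()`,
  `select_model()`, `adsorption_fraction()`, `compare_half_lives()`,
  `chain_length_trend()`) — half-life estimation from 5 µM spiking
  time-courses under zero-order (t½ = C₀ / 2k) and first-order
  (t½ = ln 2 / k) kinetics, partitioning of adsorptive vs enzymatic loss
  using heat-inactivated and sterile-medium controls, Holm–Šidák multiple
  comparisons, and the half-life vs chain-length trend.
* **LC-MS/MS quantification** (`fit_calibration()`,
  `extraction_efficiency()`, `quantify()`, `confirm_identity()`) —
  matrix-matched calibration over 0.5–200 µg/l with detection and
  quantification limits at signal-to-noise 3.3 and 10
  (LOD = 3.3 σ/slope, LOQ = 10 σ/slope), spike-recovery correction, and
  MRM identity confirmation by retention time, two transition ions and
  their intensity ratio.
* **Isolate screening** (`classify_isolate()`, `summarize_categories()`,
  `quench_spectrum()`) — producer / quencher / both / neither calls from
  biosensor and residual-AHL assays, with panel percentages and the
  quenching spectrum over short (3OC6), medium (3OC8) and long (3OC12)
  chain test signals.
* **Community–signal correlation** (`correlate_community()`,
  `pearson_matrix()`, `fdr_adjust()`, `classify_relationships()`,
  `cluster_taxa()`, `compare_stages()`) — Pearson correlation of the top-50
  taxon abundances against AHL concentration profiles, Benjamini–Hochberg
  FDR pooled over all pairs, positive/negative/neutral classification,
  Euclidean/complete-linkage clustering, and floc-vs-granule stage
  comparison with per-AHL fold changes.
* **Synthetic data with ground truth** (`gen_reads()`, `gen_decay()`,
  `gen_calibration()`, `gen_community_series()`, `gen_isolates()`) — seeded
  generators for every input above, each returning the planted truth, so
  the entire pipeline is testable end to end. `run_pipeline()` chains all
  stages on synthetic data with provenance-stamped TSV output.

Results follow tidyverse conventions: data frames in, tibbles out, broom
`tidy()`/`glance()` methods on fitted objects, and ggplot2 `autoplot()`
methods for decay fits, calibration curves and correlation heatmaps.

## Worked example

Simulate a C6-HSL spiking experiment (true half-life 1.95 h, 20 % adsorption,
10 % measurement noise), estimate the adsorptive loss from the controls and
fit the decay:

```r
library(quorumflow)
library(dplyr)

d <- gen_decay("C6-HSL", order = 1, rate_constant = log(2) / 1.95,
               adsorption_fraction = 0.2, noise_cv = 0.1, seed = 42)

ads <- adsorption_fraction(filter(d, condition == "sww_control"),
                           filter(d, condition == "heat_inactivated"))
ads$fraction
#> [1] 0.1516

live <- filter(d, condition == "live")
fit <- select_model(fit_zero_order(live), fit_first_order(live))
fit
#> <kinetic_fit> order 1, status: ok
#>   k = 0.3537 1/h, C0 = 3.599 uM, t1/2 = 1.96 +/- 0.23 h, R2 = 0.9462
```

The model selector picks first-order kinetics and recovers the planted
half-life (1.96 ± 0.23 h against a truth of 1.95 h); the adsorption
estimate (15 %) sits in the 10–30 % range typical of sludge biomass, and the
fitted C₀ of 3.6 µM reflects the 5 µM spike after the adsorptive drop.

Classify a synthetic 330-isolate panel and summarise its QS/QQ structure:

```r
iso <- gen_isolates(330, seed = 1)
summarize_categories(classify_isolate(iso$assays))
#> # A tibble: 1 × 6
#>       n producer_any quencher_any  both either neither
#>   <int>        <dbl>        <dbl> <dbl>  <dbl>   <dbl>
#> 1   330         9.09         62.1  4.24   67.0    33.0
```

About 9 % of isolates produce AHLs, 62 % quench at least one, and the
inclusion–exclusion identity `either = producer_any + quencher_any - both =
100 - neither` holds by construction.

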