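---
title: "Methods behind quorumflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind quorumflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumflow)
```

quorumflow analyses community quorum sensing (QS) and quorum quenching (QQ)
in activated sludge: who produces *N*-acyl homoserine lactone (AHL) signals,
who destroys them, how fast, and how the balance correlates with community
composition as floccular biomass assembles into granules. This vignette
explains the models each stage implements, the parameters that matter, the
noise assumptions behind the synthetic-data generators, and the numerical
choices made where the design was genuinely open.

## Tag-based community profiling

Community composition is profiled by a fast tag method rather than full
amplicon processing: every sequencing read is scanned with the degenerate
universal primer for the 16S rRNA hypervariable region V6,
5'-CGACRRCCATGCANCACCT-3' (19 nt; R = A/G, N = A/C/G/T), and the 33
nucleotides immediately downstream of each exact match are taken as the V6
tag, a proxy for a taxon.

Matching is exact (zero mismatches) with each primer position accepting the
IUPAC expansion of its code. Two deliberate choices:

* **An `N` in the read matches only primer code `N`.** An ambiguous base
  call is not evidence for a specific base, so it cannot satisfy `R` or a
  fixed position; it is, however, no worse than any concrete base where the
  primer itself accepts anything.
* **Single-strand scanning by default.** Reads are scanned as given;
  `scan_revcomp = TRUE` additionally scans reverse complements for
  libraries where orientation is not guaranteed.

Positions are 1-based, the R convention. Overlapping matches are all
reported, and every match with at least 33 nt remaining yields a tag
occurrence, attributed to the read's full sequence — its *read type*.

Two literal filters then remove artefacts:

1. a tag must be observed in at least `min_reads = 2` covering reads
   (sequencing-error-derived tags are overwhelmingly singletons);
2. a tag is removed when any single read type accounts for
   `max_type_fraction = 0.5` or more of its coverage (identical duplicated
   reads generated from a single template).

Read literally, these rules interact: a tag covered by exactly two reads is
always removed — two identical reads are one type at 100 %, two distinct
reads are each exactly 50 % — so the effective minimum viable coverage is
three distinct reads. We implement the rules as stated and expose both
thresholds; the consequence is documented rather than patched, because any
re-interpretation (e.g. requiring two distinct *types*) would silently
change which tags survive.

Per-sample tag counts are assembled over the union of surviving tags with
per-sample relative abundances; `top_n_tags()` ranks by mean relative
abundance across samples (descending, ties broken lexicographically by tag
sequence so selection is deterministic) with a default of 50, the
conventional number of dominant community members to carry into the
correlation analysis.

## AHL degradation kinetics

Degradation experiments spike a synthetic AHL at C₀ = 5 µM into three
matched microcosms: live sludge, heat-inactivated sludge and a sterile
synthetic-wastewater (SWW) control. The package models residual
concentration under both candidate rate laws,

* zero order: C(t) = C₀ − k·t, with half-life t½ = C₀ / (2k);
* first order: C(t) = C₀·e^(−kt), with half-life t½ = ln 2 / k,

and `select_model()` keeps whichever attains the higher r² computed **on
the raw concentration scale** (so the two fits are comparable; a log-scale
r² for the exponential would not be). Ties within 10⁻⁶ go to first order,
the default expectation for enzymatic signal loss.

First-order fitting is log-linear least squares followed by a nonlinear
refinement pass (Levenberg–Marquardt on the raw scale, started at the
log-linear estimates, falling back to them if the refinement fails). Zero
concentrations are floored before the log transform at half the smallest
positive observation by default — a standard left-censoring device; pass
`floor = LOQ/2` when the instrument limit is known. A series whose trailing
zeros exceed half its points is refused outright: there is no information
left to fit. Half-life standard errors come from the delta method (for the
zero-order case using the full intercept/slope covariance, since C₀ and k
are correlated).

Adsorption to biomass is estimated from the two controls at the two early
timepoints (immediately after addition and at 1 h, accepting the nearest
point within ±0.25 h):
`fraction = 1 − mean(heat) / mean(SWW)`, clamped to [0, 1] with a warning
when noise puts the heat-inactivated control above the SWW control.
`correct_adsorption()` optionally rescales a live series by 1/(1−fraction)
at t > 0 so the fitted decay reflects enzymatic loss only.

Group comparisons (live vs heat-inactivated per AHL) use Welch's t-test —
the paper-convention pooled test assumes equal variances that spiking
experiments rarely justify — with Holm–Šidák step-down adjustment across
AHLs, implemented directly (`adj₍ᵢ₎ = max_{j≤i} 1 − (1 − p₍ⱼ₎)^(m−j+1)`)
because base R's `p.adjust()` does not provide it. The chain-length trend
is summarised per C3-substitution class by the Spearman rank correlation of
half-life against acyl chain length, with an `inverse_trend` flag when it
is negative; classes with fewer than three AHLs are skipped.

## LC-MS/MS-style quantification

Calibration is an ordinary least-squares line of peak area on standard
concentration over the matrix-matched working range 0.5–200 µg/l (at least
three distinct levels). Detection and quantification limits follow the
signal-to-noise convention: LOD = 3.3·σ/slope and LOQ = 10·σ/slope, so
LOQ/LOD = 10/3.3 is an invariant of every fitted curve. When no baseline
noise measurement is supplied, σ defaults to the residual standard
deviation of the calibration fit — the instrumental S/N basis is not
available to a reanalysis, and calibration residuals are the closest
observable proxy.

Sample areas are inverse-predicted, censored against LOD/LOQ, and corrected
for extraction efficiency (mean recovery of standards spiked at 5 and
50 µg/l into heat-inactivated sludge supernatant; values above 1.5 are
rejected as implausible). Concentrations below the LOD are reported as 0
with an explicit `below_lod` flag rather than `NA`: the downstream
correlation analysis needs complete numeric series, and the flag preserves
the censoring information.

Identity confirmation mirrors multiple-reaction-monitoring practice: accept
a peak as the target analyte only if the retention time is within
`rt_tol = 0.2` min of the reference, both characteristic transition ions are
present, and the transition intensity ratio agrees with the reference
within ±30 % — compared on the log scale
(`|log(observed/reference)| ≤ log(1.3)`) so that a halved and a doubled
ratio are treated symmetrically. The criteria themselves are standard; the
tolerance values are conventional MRM confirmation windows and are exposed
as arguments. Every rejection lists each failed criterion.

## Isolate QS/QQ phenotyping

An isolate is called a **producer** only when both lines of evidence agree:
at least one biosensor (A136, CV026 or JBA357) was activated *and* at least
one AHL was confirmed by LC-MS/MS. A biosensor spot without a confirmed
signal is not a production call. It is a **quencher** when, for at least
one of the three test AHLs (short 3OC6-HSL, medium 3OC8-HSL, long
3OC12-HSL; 5 µM, 2 h), the residual fraction relative to the pH-matched
sterile control is at most `quench_threshold = 0.5`. The underlying agar
bioassay is semi-quantitative and fixes no numeric cut-off; ≥ 50 % signal
reduction within 2 h is our operational definition, exposed as a parameter,
and the classification is monotone in it (lowering the threshold never adds
quenchers). Records whose control culture finished above pH 7.3 are
rejected, because alkaline lactonolysis would mimic enzymatic quenching.

The two flags combine into the exhaustive categories producer / quencher /
both / neither. Panel summaries report percentages satisfying the
inclusion–exclusion identity `either = producer_any + quencher_any − both =
100 − neither`, and the quenching spectrum partitions quenchers into
long-chain-only versus long-plus-short/medium degraders.

## Community–signal correlation

The taxa-by-time relative-abundance matrix (top 50 tags) and the
AHL-by-time concentration matrix share a timepoint axis (at least three
points). Every taxon×AHL pair gets a Pearson correlation with a two-sided
p-value from the t reference distribution on n−2 degrees of freedom.
Multiple testing is controlled by Benjamini–Hochberg FDR **pooled over all
pairs** (not per AHL): the analysis treats the whole matrix as one family,
which matches how the heatmap is read. Pairs are classified positive when
r > r_min and q < α, negative when r < −r_min and q < α, neutral otherwise;
defaults are α = 0.05 and r_min = 0, so the neutral class absorbs all
non-significant pairs. Zero-variance rows (a taxon absent throughout) give
undefined correlations, are classed neutral, and are imputed as 0 only for
clustering, with a message.

Clustering of taxa by their correlation profiles uses Euclidean distance
with complete linkage (merge heights are then monotone), cut into k = 3
flat clusters by default — the number of blocks typically distinguished in
such heatmaps. Heatmap ordering follows the dendrogram leaf order, with the
conventional green (+1) to red (−1) colour scale and significance stars at
q < 0.05 / 0.01 / 0.001.

`compare_stages()` contrasts two stages analysed with identical settings —
refusing mismatched α or r_min — reporting per-class percentage shifts and
per-AHL ratios of stage mean concentrations with a fold-change flag
(default threshold 3).

## What the synthetic generators emulate — and what they do not

Every pipeline input has a seeded generator returning planted ground truth,
which is what makes the test suite meaningful.

* **Reads** (`gen_reads()`): 75-nt single-end reads with a fixed 5-nt
  flanking context, the primer site with degenerate positions concretised
  uniformly per read (so degeneracy-aware matching is actually exercised),
  the planted 33-nt tag, and random bases to the read end. Substitution
  errors are applied uniformly across the read at the plan's
  per-base rate, so they can also break the primer site; the truth table
  records which reads still support the planted tag and applies the two
  literal filters to them. Random post-tag bases make biological replicates
  distinct read types, matching the duplicate-removal rationale. Quality
  strings are constant Q30 placeholders. Sequencing depth, read length and
  the error profile of the original instrument runs are not published, so
  the defaults are generic short-read values, not calibrated to the study;
  the generator does not model quality-dependent errors, indels or chimeras.
* **Decay series** (`gen_decay()`): the SWW control stays at C₀ (abiotic
  loss is negligible at pH ≤ 8.3), the heat-inactivated control shows only
  an instantaneous adsorptive drop (default 20 %, within the 10–30 %
  typically observed), and the live series adds zero- or first-order decay.
  Noise is multiplicative lognormal with unit mean, parameterised by a
  coefficient of variation — concentrations are positive and chemical
  measurement error scales with signal; nothing in the source data
  identifies the real error law, so this conventional choice is stated
  rather than fitted. Concentrations are truncated at zero.
* **Calibration tables** (`gen_calibration()`): a line over the nine
  standard levels 0.5–200 µg/l with additive Gaussian area noise, the
  conventional model for integrated peak areas.
* **Community series** (`gen_community_series()`): each AHL follows an
  independent standard-normal latent series z; a taxon planted with sign s
  and effect size e follows x = s·e·z + √(1−e²)·noise_sd·ε, so at the
  default noise_sd = 1 the population Pearson correlation is exactly s·e,
  and e = 1 gives r = ±1 regardless of noise. Latent series are mapped
  affinely to positive abundance/concentration scales (Pearson correlation
  is unaffected; the truncation at zero is a rare tail event). Each taxon
  is planted against at most one AHL so the target structure is exactly
  realisable. Real AHL series are mutually correlated and autocorrelated in
  time; the generator's independent timepoints make the null calibration of
  the FDR check cleaner but mean that passing tests do not speak to
  temporal autocorrelation effects.
* **Isolate panels** (`gen_isolates()`): categories drawn multinomially,
  defaulting to the observed floccular-panel mixture (5.2 % producer-only,
  53.3 % quencher-only, 4.8 % both, 36.7 % neither); every planted quencher
  degrades the long-chain 3OC12-HSL and 23 % additionally degrade short-
  and/or medium-chain signals. Assay noise defaults to zero so planted
  categories round-trip exactly through `classify_isolate()`; set
  `noise_cv > 0` for realism.

All generators are bit-reproducible under a fixed seed (`withr::with_seed`
scopes the RNG), and `run_pipeline()` expands one global seed into
deterministic per-stage child seeds so a stage can be re-run in isolation
with identical randomness.

## Numerical choices and problem sizes

Degenerate matching uses compiled regular expressions (one character class
per primer position, inside a zero-width lookahead so overlapping matches
are reported); the test suite checks it against an exhaustive-expansion
substring-search oracle on inputs up to 60 nt. Complete-linkage clustering
is `stats::hclust`; tests verify it against a brute-force agglomeration
oracle on instances of up to six leaves. BH adjustment is
`stats::p.adjust(method = "BH")`, checked against the hand-applied step-up
rule. First-order regression is checked against grid-search-plus-simplex
SSE minimisation on random noisy series.

The stochastic checks use problem sizes chosen to bound Monte-Carlo error
while keeping the default suite fast: 200 seeded replicates (8 timepoints
over 0–6 h, CV 10 %) for half-life recovery, where the mean estimate is
required within 5 % of truth; 500 seeded small matrices for the
complete-null FDR check; 100 seeds for generator-recovery means; 200 seeds
of 199-resample bootstraps for calibration-slope coverage. The full suite
runs in about a minute on one CPU.

## Known limitations

* The tag profiler assigns no taxonomy; tags are opaque identifiers to be
  matched against reference databases externally. Chimera detection and
  quality-based trimming are out of scope.
* Kinetics are empirical rate laws; no mechanistic (Michaelis–Menten)
  enzyme model, and no pH-dependent lactonolysis model (spontaneous
  degradation is negligible over pH 6.7–8.3).
* Quantification starts from integrated peak areas; chromatogram peak
  detection and ionisation effects are instrument-side. The conversion to
  pmol per gram biomass (`ug_per_l_to_pmol_per_g()`) requires molar mass
  and biomass concentration that must be supplied.
* Correlation analysis is contemporaneous and pairwise: no time-lagged
  relationships, no network inference, and no causal claims about whether
  QS/QQ shifts drive granulation or follow it.
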