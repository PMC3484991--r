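---
title: "flcscreen methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flcscreen methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcscreen)
```

This vignette documents the statistical machinery behind the fetal Leydig
cell candidate-gene screen: the models and their assumptions, the tunable
parameters and their defaults, the numerical choices, and — importantly —
what the synthetic study does and does not demonstrate about real microarray
data.

## The screening problem

Fetal Leydig cells cannot be purified cleanly at the gestational ages where
steroidogenesis begins, so no single experiment yields their transcriptome.
The screen instead intersects several imperfect views: *Mafb*+ sorted
interstitial cells (Leydig-enriched but contaminated), *Sox9*+ Sertoli and
*Pou5f1*+ gonocyte fractions (negative controls), whole-testis developmental
time courses, a species-differential phthalate exposure (DBP suppresses rat
but not mouse fetal Leydig steroidogenic genes), and a testis-vs-ovary
contrast. A gene must show the Leydig fingerprint in **every** view — or be
absent from the platform that would test it — to survive.

## Normalization: a simplified RMA

Classical RMA operates on probe-level data: a sequence-aware background
model, quantile normalization, and median-polish summarization of the probes
of each probe set. This package ingests *gene-level* signal matrices, so the
pipeline is deliberately simplified:

- **Background**: a flat shift `max(x - floor, 1)` on the linear scale.
  There is no sequence information at gene level, so no GC model is
  attempted; this is a documented simplification, not an approximation of
  GCRMA numerics. The default `floor = 0` passes synthetic data through
  untouched; the knob exists for real signal matrices with an additive
  background offset.
- **Quantile normalization**: each array is mapped onto the across-array
  mean of order statistics. Ties take the average of the tied
  order-statistic means (average rank), so equal inputs stay equal. After
  this step every array has the identical empirical distribution — the
  property the tests assert exactly.
- **log2 transform**, then **median polish** only where replicate probe rows
  per gene exist (`probe_map`). The polish alternates row- and
  column-median sweeps until the change in the median absolute residual
  falls below `tol` (default 0.01 log2 units) or `max_iter` (default 10)
  sweeps; the per-sample summary is `overall + column effect`. On exactly
  additive blocks the decomposition is exact with zero residuals.

Renormalizing an already-log2 dataset is a no-op with a warning: the
normalization contract is linear-in, log2-out.

## Moderated differential expression

Each cascade contrast is a two-group comparison (the multi-age designs are
handled as the pairwise contrasts the cascade names). For gene *g*, the fit
is the pooled two-sample model: group means on the log2 scale, pooled
variance *s²_g* on *d_g = n₁ + n₂ − 2* degrees of freedom. The
empirical-Bayes prior assumes *σ²_g* follows a scaled inverse chi-square
with *d₀* degrees of freedom and scale *s₀²*; the moments of
*log s²_g* give

- *trigamma(d₀/2) = var(log s²) − trigamma(d_g/2)*, solved by root finding
  on (10⁻³, 10⁷), and
- *s₀²* from *mean(log s²)* with the digamma/log correction.

When the observed dispersion of *log s²* does not exceed its sampling
component the prior degenerates to a point mass (*d₀ = ∞*). On that branch
we estimate *s₀²* by the plain moment estimator `mean(s²)` — unbiased under
the point-mass model and exact when all gene variances are identical —
rather than by back-transforming `mean(log s²)`, whose digamma correction
inflates a noiseless common variance by `exp(log(d/2) − digamma(d/2))`.

Shrinkage and testing follow the standard moderated-t formulas (`moderate()`
documentation). Degenerate genes (*s̃² = 0*, only possible with *d₀ = 0*)
get *p = 0* when the fold change is nonzero and *p = 1* otherwise, and are
flagged rather than silently dropped. FDR adjustment is Benjamini–Hochberg —
the conventional default where only "FDR-corrected" is specified.
Unpaired fits are assumed for the exposure time courses.

## The cascade: rule semantics

Numerical conventions, fixed once:

- **Strict inequalities everywhere**, exactly as the thresholds are printed
  (`>110`, `>200`, `>1`, `<1`, `<0.25`). A signal of exactly 110 fails the
  floor; a ratio of exactly 1 survives the cull.
- **Signal thresholds** (steps 1–2) compare the *arithmetic mean of
  linear-scale normalized signals* in the group — 110 and 200 are linear
  Affymetrix signal magnitudes, not log units.
- **Expression ratios** are linear folds `2^logFC` of the group means.
- **Step 4 is a logical OR** over the GD14-vs-GD11 and GD14-vs-GD12
  contrasts, matching the "GD11 or GD12" phrasing.
- **Steps 5–6 accept any qualifying contrast** (any acute time point or the
  subchronic arm). No consistency across arms is required; the source
  protocol pools them without stating a combination rule.
- **Carry-over** applies at steps 4–6 only: a gene absent from every
  platform a step consults passes unfiltered. Steps 1–3 and 7 run on the
  sorted-cell platform that defines the universe, so absence there is a
  data error, not a carry.
- The cascade is order-sensitive by construction (counts per step depend on
  order), but the final set is the intersection of the per-step predicates;
  a property test verifies this set-algebra equivalence so reordering
  cull-only steps cannot change the outcome.

Every decision is recorded: `audit_trail(result, gene)` returns each step's
verdict with the numeric values that were compared against the thresholds.

## The synthetic study

`generate_study()` produces the nine dataset types of the original design
with planted ground truth. Defaults (`default_paper_config()`) encode the
study conditions:

| parameter | default | units / rationale |
|---|---|---|
| `n_genes` | 28,000 | the screen's stated universe |
| `n_leydig/sertoli/gonocyte_markers` | 12 / 17 / 135 | the known marker sets the screen tracked |
| `background_mean` | 6 (linear 64) | below the 110 signal floor |
| `background_sd` | 0.8 | gene-to-gene spread of baseline log2 signal |
| `marker_high_level` | 10 (linear 1024) | above the 200 ceiling, typical of a robustly expressed transcript |
| `leydig_gd_effect` | 8 | GD11→GD13 linear induction; the known steroidogenic genes span ~1.3–44, and 8 sits in the well-detectable middle |
| `contamination` | 0.1 | "modest" off-target admixture in sorted fractions |
| `dbp_rat_suppression` | 0.3 | strong (≈70%) suppression of rat Leydig lipid/steroid genes |
| `replicate_sd` | 0.25 | log2 replicate noise typical of RMA-summarized arrays |
| `replicates_per_group` | 3 | the design's group size |
| `platform_absent_fraction` | 0.1 | genes missing from each 3′ chip |

Model structure:

- **Noise** is additive Gaussian on the log2 scale — the standard
  lognormal model for RMA-summarized signals. No noise model is stated in
  the source; this is the field default.
- **Contamination mixes linear-scale expectations**:
  `(1−c)·own + c·mean(other fractions)`. Admixture is of cells, and
  physical mixtures add transcripts, so mixing happens on the linear scale,
  not the log scale.
- **Age profiles**: Leydig markers rise linearly in log2 signal from GD11
  to their peak (GD13 in sorted *Mafb*+ cells, GD14 in whole testis).
  Sertoli and gonocyte markers are constitutively high in their own
  fraction and in whole testis. All planted testis programs are absent in
  the ovary dataset.
- **Exposure**: rat DBP arms multiply Leydig-marker signals by
  `dbp_rat_suppression`; mouse arms are unaffected. The rat acute arms are
  generated at the four time labels (1, 3, 6, 18 h) with a single shared
  suppression fold — per-time kinetics are out of scope.
- **Seeding**: one master seed; each dataset draws from a deterministic
  substream, so any dataset can be regenerated independently and
  identical configs give byte-identical studies.
- **Masks**: each 3′ platform independently loses `platform_absent_fraction`
  of genes, recorded as absence flags (never numeric rows). Planted markers
  are never masked unless `allow_marker_masking = TRUE`.

**What the generator does not emulate.** One shared dynamic range across
chip generations (the real Gene 1.0 ST and 3′ platforms differ); no
probe-level effects, batch structure, array outliers, or fold/variance
dependence; contamination identical across fractions; marker effects
homogeneous within a class. Passing the synthetic recovery test shows the
*pipeline logic* is correct under the stated conditions — it does not show
the screen's operating characteristics on real arrays, where the published
protocol itself lost 4 of 12 known Leydig genes. Indeed the same mechanism
appears here: at some seeds a planted Leydig marker with a high baseline
crosses the 200-unit gonocyte ceiling through admixture and is discarded at
step 2, which is faithful behavior, not a failure of the filter.

## Diagnostics

The contamination profile compares each marker class's mean signal in each
sorted fraction against the background (non-marker genes) of that fraction,
flagging the class when its mean exceeds background mean + 2 SD. The
comparison runs on the **linear scale** — the scale on which the source
presents fraction marker levels and on which the cascade's signal
thresholds are stated; on the log scale, Jensen's inequality eats much of
the admixture signal and the flag would sit on a knife edge at realistic
contamination. Enrichment of the candidate list is the exact hypergeometric
upper tail (`P(X ≥ overlap)`), cross-checked against brute-force
enumeration in the tests.

## Validation statistics

- **ΔΔCt**: technical duplicates are averaged on the Ct scale before ΔCt —
  standard practice, unstated in the source. Wells above 34 cycles are
  non-detects and are excluded and flagged, never imputed; an undetected
  endogenous control is an error, and an undetected calibrator makes the
  whole target uncomputable. Quantities are invariant to per-sample Ct
  shifts (the control subtraction cancels them).
- **ANOVA + Dunnett**: the F-test is the classical one-way ANOVA; Dunnett
  comparisons use adjusted p-values `P(max_j |T_j| ≥ |t_i|)` under the
  multivariate-t null, evaluated by seeded Monte Carlo (default 10⁵ draws)
  so results are reproducible to the stated tolerance; the adjusted p is
  clamped at the raw p from below, as Monte Carlo noise must not undercut
  the multiplicity bound. Two groups are referred to the pooled t-test, per
  the analysis protocol's own rule. The protocol's sentence that p-values
  *greater* than 0.05 were considered significant is treated as a typo for
  *less*.
- **4PL curves**: least squares via Levenberg–Marquardt with data-driven
  starting values (asymptotes from the extreme standards, inflection at the
  geometric mid-concentration, unit slope). Inversion is the closed-form
  logistic solve; responses outside the open asymptote interval are
  errors, and estimates under the configured sensitivity floor (e.g.
  4.5 pM) are flagged rather than censored.

## Problem sizes in the test suite

The acceptance checks run the full 28,000-gene screen (seconds), a 10⁵-gene
prior-recovery simulation, 200 null runs of 10,000 genes for FDR
calibration, and 10⁶-draw Monte Carlo for the Dunnett critical value —
sizes chosen so the whole suite completes in well under a minute of compute
per block while keeping Monte Carlo error far inside the asserted
tolerances.

## Known limitations

- Symbol-level gene matching only; probe-set resolution and ortholog
  mapping beyond shared symbols are out of scope. Multi-row genes collapse
  to the row with the highest mean signal *before* filtering (the common
  3′-array convention; the original's rule and timing are unstated).
- One parameterized normalization path stands in for the original's split
  GCRMA/RMA treatment of whole-testis vs sorted-cell data.
- Two-group contrasts only — no multi-factor linear models, array weights,
  or duplicate correlation.
- The replay of the original study's published normalized tables requires
  those externally distributed files; the package ships the interface
  (`read_de_table()`, `run_cascade()`) and the synthetic mirror, not the
  data.
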