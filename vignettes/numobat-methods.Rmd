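---
title: "Morphometric species delimitation with numobat: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric species delimitation with numobat: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numobat)
```

## The problem

Cryptic ant species overlap broadly in every single measurement, so species
boundaries cannot be drawn from one character. Numeric morphology-based
alpha taxonomy (NUMOBAT) instead records a battery of linear measurements —
here the 22 characters of `trait_names()`, in micrometres — on several
workers per nest, and treats the *nest sample* (all workers from one
colony) as the unit of analysis: workers of one nest are full sisters, so
their mean is a low-noise estimate of the colony phenotype.

`numobat` implements the full delimitation workflow used for the
Ponto-Mediterranean *Temnothorax nylanderi* species-group (18 species, five
species complexes), plus an identification engine for new material:

1. **Exploratory nest-centroid clustering** (`nest_centroid_matrix()`,
   `agglomerate()`): nest-mean trait vectors are z-scored per column and
   clustered agglomeratively under average linkage (UPGMA) and Ward's
   criterion in parallel.
2. **Congruence hypothesis with wild-cards**
   (`congruence_hypothesis()`): nests classified congruently by both
   linkages at a cut of *k* groups receive that group as a hypothesis;
   nests on which the linkages disagree are *wild-cards* — no hypothesis
   imposed.
3. **Iterative confirmatory LDA** (`wildcard_iterate()`): a linear
   discriminant model is fitted on the workers of hypothesis-bearing
   nests; each wild-card nest is assigned to the class with the highest
   *nest-mean posterior probability*; the fit is repeated until
   assignments are stable. Validation is by leave-one-out
   cross-validation at the individual or whole-nest level
   (`classification_matrix()`).
4. **A posteriori complex-level LDA** (`complex_scores()`,
   `reduce_discriminant()`): within each species complex, discriminant
   scores visualize the species, and a greedy forward search returns the
   shortest linear function of raw measurements that still separates two
   taxa with high cross-validated success — the "reduced discriminant
   function" of printed diagnoses.
5. **Decision-tree key induction** (`build_tree()`, `loocv_tree()`,
   `node_ttest()`, `render_key()`): CART (Gini impurity, binary splits,
   thresholds midway between adjacent observed values) on nest-mean
   ratios, validated by leave-one-nest-out refits and per-node Welch
   t-tests, rendered as a numbered dichotomous key.
6. **Identification engine** (`classify_key()`, `printed_functions()`,
   `classify_by_function()`): the published 19-couplet worker key and
   every printed discriminant function (D2–D7, coefficients per
   micrometre) with their published score statistics.

## Models and conventions

**Cephalic size.** `CS = (CL + CWb)/2` is the body-size measure; most
shape descriptors are trait/CS ratios (`compute_ratios()`).

**LDA.** Classical pooled-covariance LDA (via MASS) with **equal class
priors** by default: the survey's sampling intensity per species is not a
population prior. Proportional priors sit behind `prior =
"proportional"`. Posteriors are Gaussian-LDA posteriors; each specimen
row sums to 1 and nest rows are arithmetic means of member rows. Axis
signs are fixed (first nonzero coefficient positive) so fits are
reproducible. A singular pooled covariance aborts with advice unless
`ridge > 0`, which whitens with a ridge-regularized covariance.

**Nest-level cross-validation** removes the *entire* nest before
refitting, since workers of one nest are not independent; holding out
single workers of a nest whose sisters remain in the training set would
leak.

**Reduced discriminant functions** use within-group unit-variance
scaling and an intercept that centres the two group score means
symmetrically about zero — the `±x` pairs of printed diagnoses. The
forward search stops at `max_terms` (default 4) or when the best
leave-one-out gain falls below 0.5 percentage points; it errors below 50%
success.

**Agglomeration** is Lance–Williams on Euclidean distances; Ward uses
the Ward.D2 convention (squared distances inside the update, heights on
the original scale) — stated explicitly because software dialects
differ. Merge heights carry no halving. Ties break on the smallest
(row, column) pair, so trees are deterministic; the implementation is
checked against a brute-force average-linkage oracle and against
`stats::hclust` in the tests. The standardization step is deliberately
pluggable (`scale_fun`): the exact standardization of the original
nest-centroid script is not restated in its source publication, so
column z-scoring is adopted and isolated behind one argument.

**Group matching** across the two linkages is greedy maximum-overlap
with deterministic tie-breaks. On the well-separated partitions this
operation is used for, greedy matching is exact; no assignment-problem
solver is needed.

**Key engine.** Thresholds are strict as printed: a value exactly at a
threshold — or inside a printed dead zone, such as a propodeal spine
angle between 28.5 and 30 degrees — is flagged a tie, never silently
assigned. Antennomere count defaults to 12 (all species but one);
geographic couplets use region enumerations, reflecting the two nodes of
the published tree that were replaced by distribution data. The key
operates on nest means; `single_specimen = TRUE` attaches the published
greater-than-95% reliability caveat.

Print-inherited quirks are preserved and flagged, with one exception.
The bracketed range on the second lobe of couplet 11 is inconsistent
with a CL/CWb ratio and is stored but marked unreliable. Couplet 6,
however, prints its comparison *transposed relative to its own branch
ranges*: the lobe printed "SPST/CS < 0.283" carries the branch range
[0.278, 0.331] and leads to the long-spined *T. parvulus* (whose
spine ratio lies above the threshold). Encoded literally, the couplet
misroutes four species; with the lobes swapped, every one of the 18
built-in species profiles keys out to its own leaf (a test asserts
this). The engine therefore encodes the swapped direction and keeps an
explanatory note on the couplet.

## The synthetic generator

No individual-level survey table is distributable with the package, so
every downstream stage is exercised on hierarchical synthetic data
(`generate_morph_data()`). For species *s*, nest *j*, worker *i*:

$$CS_{sji} = \mu_s + u_j + e_i, \qquad
  r_{sji} = \bar r_s + \beta_r\,(CS_{sji}-\mu_s) + v_{rj} + \epsilon_{ri}$$

with normal nest effects ($u_j$, $v_{rj}$) and worker residuals
splitting each variance by `nest_effect_sd_fraction` (default 0.3; the
true within/between-nest split is unreported, so it is exposed as a
parameter). Generation happens in *ratio space* (CS plus dimensionless
ratios) and traits are reconstructed as ratio × CS, which matches the
size-relative analysis and guarantees positive traits; CL and CWb are
solved from CS and the CL/CWb ratio. Allometry is a per-ratio slope
$\beta_r$ on centred CS (default 0).

**Calibration.** `species_profiles()` carries one row per species. CS
and ten ratios per species use the printed per-species statistics, with
sd imputed from the printed individual range by the documented
approximation `sd = (max − min)/4` (the central ~95% of a normal spans
about 4 sd). The remaining eleven trait/CS ratios are not printed per
species; their means were *solved* from the printed discriminant-score
group means and the key's branch statistics, so that evaluating the
printed functions on profile-mean specimens reproduces the printed
score pattern, and unconstrained ratios use genus-typical constants.
Held-out printed quantities not used in the solve (a second set of
discriminant group means, the quick FRS/SL ratio 0.398, the nest-level
SPST/CL mean 0.282) are reproduced within ≈0.1 score units or 0.003
ratio units, which supports the calibration. Two print inconsistencies
are resolved in the profiles: one species' PoOC/CL mean is printed
outside its own printed range (the midrange is used), and one species
lacks a printed PoOC/CL (a congener's value is used). The profiles are
a synthetic calibration consistent with printed summaries — not a copy
of any unpublished data table.

**Default scale** is the study's: 18 species × 29 nests × 3 workers =
522 nests, 1566 workers (the survey had 526 and 1693).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: trait–trait covariance beyond the shared CS
factor (real nest centroids cluster more cleanly than independent ratio
noise allows), measurement-operator error structure, the ±2 µm
quantization (optional rounding only), spatial or collection structure.
The package's cluster-recovery claims are therefore made under
explicitly well-separated profiles, below.

## Separation and recovery

The recovery guarantee is conditional on separation: with profiles whose
ratio-mean vectors are pairwise at least 6 pooled sds apart, nest-centroid
clustering cut at k = 18 recovers the species partition with ARI ≥ 0.95,
and the induced decision tree exceeds 90% leave-one-nest-out success.
Two details matter and are design choices of this package:

* **The condition is uniform.** The realistic built-in profiles scaled
  until their *closest* pair reaches 6 sd still fail recovery (ARI ≈
  0.87): distant pairs dominate the column variances, z-scoring
  compresses exactly the dimensions separating the closest (cryptic)
  pair, and cutting UPGMA at a fixed k peels outlier nests into
  singleton clusters while merging the siblings. This mirrors the
  biology — the group's sibling species are *not* morphometrically
  well separated, which is why the original workflow needs the
  confirmatory LDA chain at all.
* **Validation profiles are axis-sparse.** `well_separated_profiles()`
  displaces each species along a few random ratio axes (congeners
  typically diverge in a handful of characters), scaled so the minimum
  pairwise separation equals the requested value; recovery is then
  evaluated on ratio-space nest centroids. At separation 7 both
  linkages reach ARI 1.0 and the tree exceeds 90% LOOCV; the tests
  assert the ≥6-sd precondition before asserting recovery.

## Numerical choices and degenerate inputs

* Ratios are computed in double precision; CSV export serializes with 17
  significant digits so write/read round trips are bit-identical.
* Constant trait columns are dropped from the centroid matrix with a
  warning, never an error; `NaN` distances are fatal.
* The trait plausibility window defaults to [40, 2000] µm: the waist
  measurements NOH and SPL implied by the printed ratios fall below
  100 µm, so a higher floor would reject valid workers. The window is an
  argument, and `window = NULL` disables it.
* Nests whose workers carry conflicting species labels are kept but
  flagged `ambiguous` and excluded from supervised fitting; the source
  workflow states no rule, and silently dropping data seemed worse.
* Wild-card iteration caps at `max_iter` (default 20) and returns the
  last state flagged non-converged rather than erroring; all-wild-card
  input (no seed labels) is an error.
* The decision tree exposes `min_leaf` (default 3 nests), `max_depth`
  and `cp` (default 0.001); the original analysis does not report its
  control parameters. Node t-tests are Welch; raw p-values are reported
  with Holm-adjusted values alongside, since the original reports none.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full pipeline at the
study scale (522 nests / 1566 workers) once, the brute-force clustering
oracle on 1000 random instances of up to 8 leaves, and the recovery
studies on 18 × 8 nests of 3 workers — sizes chosen so the whole suite
completes in well under a minute while still exercising every stage at
the survey's own scale.

## Known limitations

* The printed classification rates of the original survey (94% / 93% /
  98.5%) can only be reproduced from the original individual-level
  measurement table, which cannot be redistributed here; the refit
  machinery ships ready (`read_morph_csv()` on the survey dialect +
  `classification_matrix()`), and the corresponding acceptance tests
  fail visibly until that file is supplied.
* Synthetic data under the built-in profiles are *more* separable to
  LDA than the real survey (no shared within-species covariance
  structure), so individual-level rates on synthetic data run a few
  points above the printed ones.
* No quadratic discriminant analysis, no kernel methods, no surrogate
  splits for missing data, and no automatic choice of the cluster
  count k: support across a k range is reported
  (`cluster_support()`), the choice stays with the analyst.
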