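# numobat

Numeric morphology-based alpha taxonomy (NUMOBAT) for ant workers:
species delimitation from linear morphometrics, and identification of
new material, built around the workflow used for the Ponto-Mediterranean
*Temnothorax nylanderi* species-group (18 species).

Cryptic species in this group overlap in every single measurement, so
delimitation works on 22 measurements (µm) per worker, aggregated to
**nest-sample means** (all workers of a colony are sisters), and runs as
a chain:

1. **Nest-centroid clustering** — z-scored nest means under UPGMA and
   Ward linkage in parallel (`nest_centroid_matrix()`, `agglomerate()`);
2. **Congruence hypothesis** — nests classified congruently by both
   linkages at a k-group cut get that group as hypothesis, disagreements
   become *wild-cards* (`congruence_hypothesis()`);
3. **Iterative confirmatory LDA** — fit on workers of labeled nests,
   assign each wild-card nest to the class with the highest nest-mean
   posterior, repeat to convergence (`wildcard_iterate()`), validated by
   individual- and whole-nest leave-one-out cross-validation
   (`classification_matrix()`);
4. **Complex-level LDA** — discriminant scatterplot scores and the
   shortest "reduced discriminant function" separating two taxa with
   high cross-validated success (`complex_scores()`,
   `reduce_discriminant()`);
5. **Decision-tree key** — CART on nest-mean ratios with
   leave-one-nest-out validation and node t-tests, rendered as a
   numbered dichotomous key (`build_tree()`, `loocv_tree()`,
   `render_key()`);
6. **Identification engine** — the published 19-couplet worker key and
   the printed discriminant functions D2–D7 with their score bands
   (`classify_key()`, `printed_functions()`, `classify_by_function()`).

A hierarchical generator (`generate_morph_data()`) draws synthetic
surveys — species, nest and worker levels, ratio-space model, allometry
slopes — calibrated to the printed per-species statistics
(`species_profiles()`), so the whole pipeline is testable without the
original survey table. See the methods vignette
(`vignettes/numobat-methods.Rmd`) for models, parameters and design
decisions.

## Worked example

```r
library(numobat)

# a synthetic survey: 18 species x 6 nests x 3 workers
d     <- generate_morph_data(nests_per_species = 6, workers_per_nest = 3,
                             seed = 42)
nests <- aggregate_nests(d)

# steps 1-3: cluster, congruence hypothesis, wild-card LDA
m   <- nest_centroid_matrix(nests)
du  <- agglomerate(dist(m), "upgma")
dw  <- agglomerate(dist(m), "ward")
hyp <- congruence_hypothesis(du, dw, k = 18)
hyp
#> Cluster hypothesis: 108 nests, k = 18, wild-cards: 27
fit <- wildcard_iterate(d, hyp)
fit
#> Wild-card LDA: 108 nests, 15 classes, 3 iteration(s), converged

# whole-nest leave-one-out validation of the species labels
classification_matrix(d, d$species, mode = "loocv", level = "nest")
#> Classification matrix (loocv, nest level): 108 units, overall success 96.3%
```

The 27 wild-cards are nests on which the two linkages disagreed; the
iterative LDA assigns each to the class with the highest nest-mean
posterior. With only 6 nests per species several sibling species fuse at
the k = 18 cut (15 recovered classes) — the cryptic pairs of this group
genuinely overlap, which is why the confirmatory chain exists.

Identify a nest with the published key (nest means; thresholds strict,
ties flagged):

```r
classify_key(c(`SPST/CS` = 0.40), spine_angle_deg = 22)
#> Key identification: laconicus
#>   path: 1 -> 2 -> 3
```

Score a worker with a printed discriminant function (coefficients per
µm; negative scores take the first-named side):

```r
classify_by_function("D3_lichtensteini_laconicus",
                     c(PoOC = 200, FRS = 190, SPST = 200))
#>    score     taxon   band   tie
#> 1 2.5718 laconicus inside FALSE
```

`band` says whether the score falls inside the published 5–95%
percentile band of the assigned taxon; scores outside every band are
flagged `ambiguous/atypical`.

Induce a fresh dichotomous key from the nest means and render it:

```r
tr <- build_tree(nests, nests$species)
cat(render_key(tr)[1:4], sep = "\n")
#> 1. SPTI/CS > 0.393665338907312 [0.396579, 0.446371] ...2
#> -  SPTI/CS < 0.393665338907312 [0.260531, 0.390752] ...3
#> 2. EL/CS > 0.251283176479095 [0.252771, 0.263016] ...flavicornis
#> -  EL/CS < 0.251283176479095 [0.230167, 0.249795] ...laconicus
```

Each lobe shows the split feature, threshold and the branch's observed
[min, max]; `loocv_tree()` adds leave-one-nest-out success and
`node_ttest()` Welch t-tests per node.

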