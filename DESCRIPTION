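Package: numobat
Title: Numeric Morphology-Based Alpha Taxonomy for Ant Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative species delimitation from linear
    morphometric measurements of social-insect workers, built around the
    workflow used for the Ponto-Mediterranean Temnothorax nylanderi
    species-group: nest-centroid agglomerative clustering (UPGMA and Ward)
    of standardized nest means, iterative wild-card linear discriminant
    analysis with nest-mean posterior assignment and leave-one-out cross
    validation, cross-validated decision-tree induction of dichotomous
    identification keys, an identification engine encoding the published
    19-couplet worker key and the printed linear discriminant functions,
    and a hierarchical synthetic-data generator (species, nest and worker
    levels) calibrated to the printed per-species trait statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ape,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
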