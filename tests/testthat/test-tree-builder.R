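# decision-tree key induction: forced splits, impurity, validation, t-tests,
# rendering and the round trip through the key engine

make_gap_nests <- function(n_per = 8, means = c(0.30, 0.36), seed = 1) {
  # two classes fully separated by SPST/CS with a gap
  p <- species_profiles()[c(8, 7), ]
  p$SPST_mean <- means
  p$SPST_sd <- 0.004
  d <- generate_morph_data(p, nests_per_species = n_per, workers_per_nest = 3,
                           seed = seed)
  aggregate_nests(d)
}

test_that("a clean two-class gap forces a root split inside the gap", {
  nests <- make_gap_nests()
  tr <- build_tree(nests, nests$species, features = c("SPST/CS", "FRS/CS"))
  expect_equal(tr$nodes$feature[1], "SPST/CS")
  expect_gt(tr$nodes$threshold[1], 0.30)
  expect_lt(tr$nodes$threshold[1], 0.36)
  expect_equal(mean(predict(tr) == nests$species), 1)
  # branch summary: threshold strictly between the two branch means
  expect_gt(tr$nodes$threshold[1], min(tr$nodes$yes_mean[1], tr$nodes$no_mean[1]))
  expect_lt(tr$nodes$threshold[1], max(tr$nodes$yes_mean[1], tr$nodes$no_mean[1]))
})

test_that("pure single-class input yields a single leaf and a one-line key", {
  nests <- make_gap_nests()
  one <- nests[nests$species == "lichtensteini", ]
  tr <- build_tree(one, one$species)
  expect_null(tr$nodes)
  expect_match(render_key(tr), "single taxon")
  expect_equal(unique(predict(tr)), "lichtensteini")
})

test_that("every split strictly decreases total Gini impurity", {
  d <- generate_morph_data(species_profiles()[1:5, ], nests_per_species = 6,
                           workers_per_nest = 3, sd_scale = 0.5, seed = 8)
  nests <- aggregate_nests(d)
  tr <- build_tree(nests, nests$species)
  gini <- function(lbl) 1 - sum((table(lbl) / length(lbl))^2)
  for (i in seq_len(nrow(tr$nodes))) {
    rows <- numobat:::.route_rows(tr, tr$nodes$couplet[i])
    parent <- c(rows$yes, rows$no)
    g_par <- gini(tr$labels[parent]) * length(parent)
    g_kids <- gini(tr$labels[rows$yes]) * length(rows$yes) +
      gini(tr$labels[rows$no]) * length(rows$no)
    expect_lt(g_kids, g_par)
  }
})

test_that("tree induction is invariant to nest ordering", {
  nests <- make_gap_nests(n_per = 10)
  tr1 <- build_tree(nests, nests$species, features = c("SPST/CS", "EL/CS"))
  perm <- sample(nrow(nests))
  tr2 <- build_tree(nests[perm, ], nests$species[perm],
                    features = c("SPST/CS", "EL/CS"))
  expect_equal(tr1$nodes$threshold, tr2$nodes$threshold)
  expect_equal(tr1$nodes$feature, tr2$nodes$feature)
})

test_that("rendered couplets round-trip through the key engine unchanged", {
  d <- generate_morph_data(species_profiles()[c(2, 7, 12, 16), ],
                           nests_per_species = 7, workers_per_nest = 3,
                           sd_scale = 0.4, seed = 12)
  nests <- aggregate_nests(d)
  tr <- build_tree(nests, nests$species)
  pred <- predict(tr)
  via_key <- identify_nests(nests, tr$key)
  expect_equal(via_key$taxon, pred)

  # JSON serialization preserves classifications
  path <- tempfile(fileext = ".json")
  write_key(tr$key, path)
  via_json <- identify_nests(nests, read_key(path))
  expect_equal(via_json$taxon, pred)

  # the text rendering shows one couplet pair per internal node
  txt <- render_key(tr)
  expect_equal(sum(grepl("^[0-9]+\\.", txt)), nrow(tr$nodes))
})

test_that("single-couplet tree renders as exactly one couplet pair", {
  nests <- make_gap_nests()
  tr <- build_tree(nests, nests$species, features = "SPST/CS")
  txt <- render_key(tr)
  expect_length(txt, 2)
  expect_match(txt[1], "^1\\. SPST/CS")
  expect_match(txt[2], "^-")
})

test_that("leave-one-nest-out validation: perfect separation, permutation null, degenerate class", {
  nests <- make_gap_nests(n_per = 8)
  lv <- loocv_tree(nests, nests$species, features = c("SPST/CS", "EL/CS"))
  expect_equal(lv$overall, 1)
  expect_true(all(lv$per_node$success == 1))

  # shuffled labels: success near 1/k
  set.seed(55)
  d <- generate_morph_data(species_profiles()[1:2, ], nests_per_species = 20,
                           workers_per_nest = 2, seed = 14)
  n2 <- aggregate_nests(d)
  sh <- sample(rep(c("a", "b"), length.out = nrow(n2)))
  lvs <- loocv_tree(n2, sh, features = c("SPST/CS", "EL/CS", "FRS/CS"))
  expect_lt(abs(lvs$overall - 0.5), 4 * sqrt(0.25 / nrow(n2)))

  # a single-nest class is reported unscorable, not scored
  n3 <- make_gap_nests(n_per = 6)
  n3$species[1] <- "loner"
  lv3 <- suppressWarnings(loocv_tree(n3, n3$species, features = "SPST/CS"))
  expect_length(lv3$unscorable, 1)
})

test_that("node t-tests are decisive at real splits and Welch-corrected", {
  nests <- make_gap_nests(n_per = 10)
  tr <- build_tree(nests, nests$species, features = "SPST/CS")
  tt <- node_ttest(tr)
  expect_lt(tt$p[1], 1e-6)
  expect_true("p_holm" %in% names(tt))
  expect_true(all(tt$p_holm >= tt$p, na.rm = TRUE))
  # Welch df falls below the pooled df because branch variances differ
  n_yes <- length(numobat:::.route_rows(tr, 1)$yes)
  n_no <- length(numobat:::.route_rows(tr, 1)$no)
  expect_lt(tt$df[1], n_yes + n_no - 2 + 1e-9)
  # selecting one couplet returns only that row
  expect_equal(nrow(node_ttest(tr, couplet = 1)), 1)
})

test_that("a geographic feature can replace a morphometric couplet post hoc", {
  nests <- make_gap_nests(n_per = 6)
  nests$region <- ifelse(nests$species == "lichtensteini",
                         "EUROPE_MAINLAND", "ANATOLIA_OR_CRETE")
  tr <- build_tree(nests, nests$species, features = "SPST/CS")
  yes_leaf <- tr$key$couplets[["#1"]]$yes
  no_leaf <- tr$key$couplets[["#1"]]$no
  geo <- numobat:::.couplet(1, "region", "region",
                            yes = yes_leaf, no = no_leaf,
                            yes_set = unique(nests$region[nests$species == yes_leaf]),
                            no_set = unique(nests$region[nests$species == no_leaf]))
  tr2 <- replace_couplet(tr, 1, geo)
  out <- identify_nests(nests, tr2$key)
  expect_equal(out$taxon, nests$species)
})
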