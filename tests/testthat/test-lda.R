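# confirmatory LDA: fits against the Fisher oracle, posteriors, wild-card
# iteration, LOOCV matrices, complex scores, reduced functions

make_two_class <- function(n = 50, gap = 10, sd = 1, seed = 1) {
  set.seed(seed)
  df <- make_specimens(2 * n, paste0("N", 1:(2 * n)))
  df$SPST <- c(rnorm(n, 170, sd), rnorm(n, 170 + gap, sd))
  df$species <- rep(c("a", "b"), each = n)
  df
}

test_that("a 1-D two-class fit puts the decision boundary near the midpoint", {
  set.seed(2)
  df <- data.frame(specimen_id = 1:100, nest_id = paste0("N", 1:100),
                   v = c(rnorm(50, 0), rnorm(50, 10)),
                   species = rep(c("a", "b"), each = 50))
  m <- fit_lda(df, df$species, traits = "v")
  # oracle: equal covariance, equal priors -> boundary at the mean midpoint
  grid <- data.frame(specimen_id = 1:1001, v = seq(-5, 15, 0.02))
  post <- predict_posteriors(m, grid)
  boundary <- grid$v[which.min(abs(post$a - 0.5))]
  expect_gt(boundary, 3)
  expect_lt(boundary, 7)
})

test_that("fits are invariant to class-name permutation and bounded by the axis rank", {
  d <- generate_morph_data(species_profiles()[1:4, ], nests_per_species = 4,
                           workers_per_nest = 3, seed = 9)
  m1 <- fit_lda(d, d$species)
  relab <- c(angulinodis = "w", angustifrons = "x", lucidus = "y", similis = "z")
  m2 <- fit_lda(d, relab[d$species])
  p1 <- predict_posteriors(m1, d)$predicted
  p2 <- predict_posteriors(m2, d)$predicted
  expect_equal(relab[p1], p2, ignore_attr = TRUE)   # identical partition
  expect_lte(ncol(m1$scaling), 3)                   # <= classes - 1 axes
})

test_that("two-class coefficient direction matches the Fisher oracle up to scale", {
  df <- make_two_class(seed = 3)
  df$ML <- df$ML + rnorm(nrow(df), 0, 4)
  m <- fit_lda(df, df$species, traits = c("SPST", "ML"))
  w_or <- fisher_direction(as.matrix(df[, c("SPST", "ML")]), df$species)
  ratio <- m$scaling[, 1] / w_or
  expect_lt(abs(ratio[1] - ratio[2]) / abs(ratio[1]), 1e-6)
})

test_that("posterior rows sum to one; symmetric and extreme cases behave", {
  df <- make_two_class(seed = 4)
  m <- fit_lda(df, df$species, traits = "SPST")
  post <- predict_posteriors(m, df)
  expect_true(all(abs(rowSums(post[, c("a", "b")]) - 1) < 1e-9))

  # equidistant specimen (midpoint of the fitted class means): posterior 0.5/0.5
  mid <- df[1, ]; mid$SPST <- mean(m$means)
  pm <- predict_posteriors(m, mid)
  expect_equal(pm$a, 0.5, tolerance = 1e-6)

  # far into class a: posterior > 0.999
  far <- df[1, ]; far$SPST <- 120
  expect_gt(predict_posteriors(m, far)$a, 0.999)
})

test_that("nest posterior rows are arithmetic means of member rows", {
  df <- make_two_class(seed = 5)
  df$nest_id <- rep(paste0("N", 1:20), each = 5)
  m <- fit_lda(df, df$species, traits = "SPST")
  post <- predict_posteriors(m, df)
  np <- nest_posteriors(post)
  for (nid in c("N1", "N11")) {
    expect_equal(np$a[np$nest_id == nid],
                 mean(post$a[df$nest_id == nid]), tolerance = 1e-12)
  }
})

test_that("wild-card iteration is a fixpoint without wild-cards and resolves seeded ones", {
  d <- generate_morph_data(species_profiles()[c(7, 8), ], nests_per_species = 6,
                           workers_per_nest = 3, sd_scale = 0.5, seed = 13)
  nests <- unique(d$nest_id)
  truth <- vapply(nests, function(id) unique(d$species[d$nest_id == id]), "")
  hyp0 <- data.frame(nest_id = nests, label = truth, stringsAsFactors = FALSE)
  w0 <- wildcard_iterate(d, hyp0)
  expect_true(w0$converged)
  expect_equal(w0$iterations, 1L)
  expect_equal(w0$labels, setNames(truth, nests))

  # one wild-card nest generated inside a class cloud is assigned to it
  hyp1 <- hyp0
  wc_nest <- nests[truth == "laconicus"][1]
  hyp1$label[hyp1$nest_id == wc_nest] <- "WILDCARD"
  w1 <- wildcard_iterate(d, hyp1)
  expect_true(w1$converged)
  expect_equal(unname(w1$labels[wc_nest]), "laconicus")
  # idempotent once converged
  hyp2 <- data.frame(nest_id = names(w1$labels), label = unname(w1$labels))
  w2 <- wildcard_iterate(d, hyp2)
  expect_equal(w2$labels, w1$labels)

  hyp_all <- hyp0; hyp_all$label <- "WILDCARD"
  expect_error(wildcard_iterate(d, hyp_all), "seed labels")
})

test_that("classification matrices: identities, perfect separation, permutation null", {
  d <- generate_morph_data(species_profiles()[c(7, 8), ], nests_per_species = 8,
                           workers_per_nest = 3, sd_scale = 0.3, seed = 15)
  cm <- classification_matrix(d, d$species, mode = "loocv")
  expect_equal(cm$overall, 1)                       # fully separated classes
  expect_equal(sum(cm$table), cm$n)
  expect_equal(sum(diag(cm$table)) / sum(cm$table), cm$overall)
  expect_equal(unname(rowSums(cm$table)), unname(as.vector(table(d$species))))

  # nest-level LOOCV holds out whole nests and stays perfect here
  cmn <- classification_matrix(d, d$species, mode = "loocv", level = "nest")
  expect_equal(cmn$overall, 1)
  expect_equal(cmn$n, length(unique(d$nest_id)))

  # shuffled labels, k classes: success ~ 1/k within binomial error
  set.seed(77)
  k <- 3
  dd <- generate_morph_data(species_profiles()[1:k, ], nests_per_species = 10,
                            workers_per_nest = 3, seed = 16)
  sh <- sample(rep(letters[1:k], length.out = nrow(dd)))
  cms <- classification_matrix(dd, sh, mode = "loocv")
  p0 <- 1 / k
  tol <- 4 * sqrt(p0 * (1 - p0) / nrow(dd))
  expect_lt(abs(cms$overall - p0), tol)
})

test_that("LOOCV success does not beat resubstitution in repeated noisy trials", {
  worse <- 0; trials <- 25
  for (s in seq_len(trials)) {
    df <- make_two_class(n = 18, gap = 2.2, sd = 1.6, seed = 100 + s)
    df$ML <- df$ML + rnorm(nrow(df), 0, 5)
    df$EL <- df$EL + rnorm(nrow(df), 0, 3)
    res <- classification_matrix(df, df$species, mode = "resubstitution",
                                 traits = c("SPST", "ML", "EL"))
    cv <- classification_matrix(df, df$species, mode = "loocv",
                                traits = c("SPST", "ML", "EL"))
    if (cv$overall <= res$overall + 1e-12) worse <- worse + 1
  }
  expect_gte(worse / trials, 0.95)
})

test_that("complex scores: axis count and centred symmetry of two-class means", {
  d <- generate_morph_data(species_profiles()[c(7, 8), ], nests_per_species = 5,
                           workers_per_nest = 3, seed = 19)
  m <- fit_lda(d, d$species)
  sc <- complex_scores(m, d)
  expect_equal(sum(grepl("^LD", names(sc))), 1)     # 2 classes -> 1 axis
  mu <- tapply(sc$LD1, d$species, mean)
  expect_lt(abs(mu[1] + mu[2]), 1e-9)               # symmetric about zero

  d4 <- generate_morph_data(species_profiles()[1:4, ], nests_per_species = 4,
                            workers_per_nest = 2, seed = 20)
  m4 <- fit_lda(d4, d4$species)
  expect_equal(sum(grepl("^LD", names(complex_scores(m4, d4)))), 3)

  m1 <- list(classes = "only", fit = NULL, traits = trait_names())
  class(m1) <- "morpho_lda"
  expect_error(complex_scores(m1, d), "single species")
})

test_that("reduced discriminant: single informative trait is found; means are symmetric", {
  df <- make_two_class(n = 40, gap = 12, sd = 1, seed = 6)
  fn <- reduce_discriminant(df, df$species, max_terms = 3)
  expect_equal(names(fn$coefficients), "SPST")
  expect_lt(abs(sum(fn$stats$mean)), 1e-9)
  expect_gt(attr(fn, "loocv"), 95)
  # sign rule consistent with the stored stats
  for (i in seq_len(nrow(fn$stats))) {
    side <- if (fn$stats$mean[i] < 0) fn$negative_classes else fn$positive_classes
    expect_true(fn$stats$class[i] %in% side)
  }
})

test_that("a three-term function separates the sibling-species profiles at > 95% LOOCV", {
  p <- two_species_profiles()        # SPST/CS means 0.346 vs 0.411
  d <- generate_morph_data(p, nests_per_species = 10, workers_per_nest = 3,
                           seed = 23)
  fn <- reduce_discriminant(d, d$species, max_terms = 3)
  expect_gte(attr(fn, "loocv"), 95)
  expect_lte(length(fn$coefficients), 3)
})
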