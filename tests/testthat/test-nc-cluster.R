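# nest-centroid clustering: standardization, agglomeration against oracles,
# ultrametricity, and the cross-linkage congruence hypothesis

test_that("centroid matrix is z-scored and constant columns are dropped with a warning", {
  n <- aggregate_nests(make_specimens(6, paste0("N", 1:6), jitter = 5))
  m <- nest_centroid_matrix(n)
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-9))

  # two nests: each column is {-s, +s}
  n2 <- n[1:2, ]
  m2 <- nest_centroid_matrix(n2)
  expect_true(all(abs(abs(m2) - sqrt(1 / 2)) < 1e-9))

  n$EL <- 150  # constant trait
  expect_warning(m3 <- nest_centroid_matrix(n), "EL")
  expect_false("EL" %in% colnames(m3))
  expect_equal(attr(m3, "dropped"), "EL")
})

test_that("two leaves merge once at their distance; the 1-D toy matches hand arithmetic", {
  d2 <- dist(c(a = 0, b = 5))
  t2 <- agglomerate(d2, "upgma")
  expect_equal(t2$height, 5)
  expect_equal(nrow(t2$merge), 1)

  # {0, 1, 3}: (A,B)@1 then (AB,C)@ mean(3,2) = 2.5
  t3 <- agglomerate(dist(c(0, 1, 3)), "upgma")
  expect_equal(t3$height, c(1, 2.5))
})

test_that("agglomeration agrees with the brute-force average-linkage oracle", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(n * 3), n)
    d <- dist(x)
    mine <- agglomerate(d, "upgma")
    oracle <- brute_upgma(d)
    expect_equal(mine$height, oracle$heights, tolerance = 1e-10)
    expect_equal(mine$merge, oracle$merges, ignore_attr = TRUE)
  }
})

test_that("both linkages reproduce hclust on larger instances", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40)
  d <- dist(x)
  expect_equal(agglomerate(d, "upgma")$height,
               hclust(d, "average")$height, tolerance = 1e-10)
  expect_equal(agglomerate(d, "ward")$height,
               hclust(d, "ward.D2")$height, tolerance = 1e-10)
  # and the cut partitions coincide
  for (k in c(2, 5, 9)) {
    a <- cut_dendrogram(agglomerate(d, "upgma"), k)
    b <- cutree(hclust(d, "average"), k)
    expect_equal(as.vector(table(a, b) > 0) |> sum(), k)
  }
})

test_that("ward heights are monotone and UPGMA cophenetic distances are ultrametric", {
  set.seed(17)
  for (rep in 1:10) {
    x <- matrix(rnorm(12 * 4), 12)
    tw <- agglomerate(dist(x), "ward")
    expect_true(all(diff(tw$height) >= -1e-12))
    tu <- agglomerate(dist(x), "upgma")
    cm <- as.matrix(cophenetic_dist(tu))
    n <- nrow(cm)
    # ultrametric inequality for every triple, vectorized over the middle leaf
    worst <- max(vapply(seq_len(n), function(l)
      max(cm - outer(cm[, l], cm[l, ], pmax)), 0))
    expect_lte(worst, 1e-10)
  }
})

test_that("leaf order permutation leaves the tree invariant up to relabeling", {
  set.seed(23)
  x <- matrix(rnorm(9 * 4), 9, dimnames = list(paste0("n", 1:9), NULL))
  d1 <- agglomerate(dist(x), "upgma")
  perm <- sample(9)
  d2 <- agglomerate(dist(x[perm, ]), "upgma")
  c1 <- as.matrix(cophenetic_dist(d1))
  c2 <- as.matrix(cophenetic_dist(d2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("NaN distances are fatal and newick export round-trips through ape", {
  dm <- matrix(c(0, 1, 1, 0), 2)
  dm[1, 2] <- NaN; dm[2, 1] <- NaN
  expect_error(agglomerate(dm), "NaN|NA")

  x <- matrix(rnorm(6 * 3), 6, dimnames = list(paste0("n", 1:6), NULL))
  dend <- agglomerate(dist(x), "upgma")
  nwk <- write_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, dend$labels)
})

test_that("congruent trees give zero wild-cards; disagreement marks exactly the moved nest", {
  set.seed(31)
  x <- matrix(c(rnorm(6, 0), rnorm(6, 10), rnorm(6, 20)), ncol = 2,
              dimnames = list(paste0("n", 1:9), NULL))
  du <- agglomerate(dist(x), "upgma")
  dw <- agglomerate(dist(x), "ward")
  hyp <- congruence_hypothesis(du, dw, 3)
  expect_equal(sum(hyp$label == "WILDCARD"), 0)

  # k = n: every nest its own group, still no wild-cards
  hyp_n <- congruence_hypothesis(du, dw, 9)
  expect_equal(sum(hyp_n$label == "WILDCARD"), 0)
  expect_equal(anyDuplicated(hyp_n$label), 0)

  # move one nest between groups in one tree only: brute-force toy
  ca <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 2, n5 = 2, n6 = 2)
  cb <- ca; cb["n4"] <- 1   # n4 swaps groups in tree b
  fake <- function(cl) {     # tiny helper: a dendrogram realizing partition cl
    pts <- ifelse(cl == 1, 0, 100) + seq_along(cl) * 0.01
    agglomerate(dist(setNames(pts, names(cl))), "upgma")
  }
  hyp2 <- congruence_hypothesis(fake(ca), fake(cb), 2)
  expect_equal(hyp2$label[hyp2$nest_id == "n4"], "WILDCARD")
  expect_equal(sum(hyp2$label == "WILDCARD"), 1)

  expect_error(congruence_hypothesis(du, dw, 10), "k must be")
})

test_that("silhouette support is highest at the true cluster count", {
  set.seed(41)
  x <- matrix(c(rnorm(8, 0), rnorm(8, 12), rnorm(8, 30)), ncol = 2,
              dimnames = list(paste0("n", 1:12), NULL))
  d <- dist(x)
  supp <- cluster_support(agglomerate(d, "upgma"), d, 2:6)
  expect_equal(supp$k[which.max(supp$mean_silhouette)], 3)
})
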