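# Nest-centroid clustering: z-scored nest means, agglomerative merge trees
# (UPGMA / Ward), and cross-linkage congruence hypotheses with wild-cards.

#' Standardized nest-centroid matrix
#'
#' Builds the matrix clustered by nest-centroid clustering: one row per
#' nest, each trait column z-scored to mean 0 / sd 1 across nests.
#' Standardization is isolated here on purpose (`scale_fun`) so that other
#' conventions can be plugged in.
#'
#' @param nests nest data frame ([aggregate_nests()]) or any data frame
#'   with `nest_id` plus trait columns.
#' @param traits trait columns to use (default: all 22 present).
#' @param scale_fun function(matrix) -> matrix; default z-scores columns.
#' @return numeric matrix (rownames = nest ids) with attribute
#'   `dropped` naming constant columns removed with a warning.
#' @export
nest_centroid_matrix <- function(nests, traits = NULL, scale_fun = NULL) {
  if (nrow(nests) < 2) stop("need at least 2 nests", call. = FALSE)
  if (is.null(traits)) traits <- intersect(trait_names(), names(nests))
  miss <- setdiff(traits, names(nests))
  if (length(miss)) stop("trait(s) absent from nests: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(nests[, traits, drop = FALSE])
  rownames(m) <- nests$nest_id
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant trait column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  m <- if (is.null(scale_fun)) scale(m) else scale_fun(m)
  attr(m, "dropped") <- dropped
  m
}

#' Agglomerative clustering of nest centroids
#'
#' Lance-Williams agglomeration of a Euclidean distance matrix under
#' average linkage (UPGMA) or Ward's criterion in the Ward.D2 convention
#' (squared distances inside the update, merge heights on the original
#' scale). Merge heights carry no halving. Ties are broken by the
#' smallest (row, column) pair in the current cluster ordering, so the
#' tree is deterministic.
#'
#' @param d a `dist` object or symmetric non-negative matrix.
#' @param linkage `"upgma"` or `"ward"`.
#' @return object of class `nc_dendrogram`: list with `merge`, `height`,
#'   `order`, `labels`, `linkage` (the `merge`/`height` layout of
#'   [stats::hclust()]).
#' @seealso [as.hclust.nc_dendrogram()], [write_newick()]
#' @export
#' @examples
#' x <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
#' agglomerate(dist(x), "upgma")$height   # 1, 2.5
agglomerate <- function(d, linkage = c("upgma", "ward")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  if (any(is.na(dm))) stop("NA/NaN in distance matrix", call. = FALSE)
  if (any(dm < 0)) stop("negative distances", call. = FALSE)
  n <- nrow(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)

  work <- if (linkage == "ward") dm^2 else dm
  active <- seq_len(n)            # current cluster slots
  id <- -seq_len(n)               # hclust coding: negative = singleton
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- work[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    pick <- cand[order(cand[, 1], cand[, 2])[1], ]   # smallest (row, col) on ties
    a <- pick[[1]]; b <- pick[[2]]
    ia <- active[a]; ib <- active[b]
    height[step] <- if (linkage == "ward") sqrt(m) else m
    merge[step, ] <- sort(c(id[ia], id[ib]))

    na_ <- size[ia]; nb <- size[ib]
    rest <- active[-c(a, b)]
    if (length(rest)) {
      nc_ <- size[rest]
      new <- if (linkage == "upgma") {
        (na_ * work[ia, rest] + nb * work[ib, rest]) / (na_ + nb)
      } else {
        ((na_ + nc_) * work[ia, rest] + (nb + nc_) * work[ib, rest] -
           nc_ * work[ia, ib]) / (na_ + nb + nc_)
      }
      work[ia, rest] <- work[rest, ia] <- new
    }
    size[ia] <- na_ + nb
    id[ia] <- step
    active <- active[-b]
  }
  ord <- .dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, linkage = linkage,
                 method = if (linkage == "upgma") "average" else "ward.D2",
                 dist.method = "euclidean"),
            class = "nc_dendrogram")
}

# leaf order by left-to-right traversal of the merge tree
.dendro_order <- function(merge, n) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1]), rec(merge[i, 2]))
  }
  rec(nrow(merge))
}

#' @export
as.hclust.nc_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$dist.method),
            class = "hclust")
}

#' @export
print.nc_dendrogram <- function(x, ...) {
  cat("Nest-centroid dendrogram (", toupper(x$linkage), " linkage)\n",
      "  leaves: ", length(x$labels),
      ", merge heights in [", format(min(x$height), digits = 4), ", ",
      format(max(x$height), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.nc_dendrogram <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
}

#' Cut a dendrogram into k groups
#'
#' @param dend `nc_dendrogram`.
#' @param k number of groups, `1 <= k <=` leaf count.
#' @return named integer vector of group memberships (names = leaf labels).
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  stats::cutree(stats::as.hclust(dend), k = k)
}

#' Cophenetic distances of a dendrogram
#'
#' @param dend `nc_dendrogram`.
#' @return `dist` of cophenetic (merge-height) distances.
#' @export
cophenetic_dist <- function(dend) {
  stats::cophenetic(stats::as.hclust(dend))
}

#' Export a dendrogram to Newick
#'
#' Writes the merge tree as a Newick string with merge heights as node
#' depths (branch lengths are height differences).
#'
#' @param dend `nc_dendrogram`.
#' @param path file path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Merge-table export
#'
#' @param dend `nc_dendrogram`.
#' @param path optional CSV path.
#' @return data frame with one row per merge (`left`, `right`, `height`,
#'   `size`), hclust coding (negative = leaf index).
#' @export
merge_table <- function(dend, path = NULL) {
  sizes <- integer(nrow(dend$merge))
  cnt <- function(i) if (i < 0) 1L else sizes[i]
  for (s in seq_along(sizes))
    sizes[s] <- cnt(dend$merge[s, 1]) + cnt(dend$merge[s, 2])
  df <- data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
                   height = dend$height, size = sizes)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Cross-linkage congruence hypothesis with wild-cards
#'
#' Cuts the UPGMA and Ward trees into `k` groups each, matches groups
#' across the two linkages by maximum overlap (greedy assignment with
#' deterministic tie-breaks), and assigns a cluster label to every nest
#' classified congruently by both linkages. Nests on which the linkages
#' disagree receive no hypothesis: the wild-card setting.
#'
#' @param dend_a,dend_b two `nc_dendrogram`s over the same nests
#'   (typically UPGMA and Ward).
#' @param k number of clusters to cut.
#' @return object of class `cluster_hypothesis`: data frame `nest_id`,
#'   `label` (`"cluster-<i>"` or `"WILDCARD"`), with attribute `k`.
#' @export
congruence_hypothesis <- function(dend_a, dend_b, k) {
  if (!setequal(dend_a$labels, dend_b$labels))
    stop("dendrograms cover different nests", call. = FALSE)
  ca <- cut_dendrogram(dend_a, k)
  cb <- cut_dendrogram(dend_b, k)[names(ca)]
  ov <- table(factor(ca, levels = seq_len(k)), factor(cb, levels = seq_len(k)))
  # greedy maximum-overlap matching, ties to the smallest (row, column)
  match_b <- rep(NA_integer_, k)
  taken_a <- taken_b <- rep(FALSE, k)
  for (step in seq_len(k)) {
    best <- c(-1L, 0L, 0L)
    for (i in seq_len(k)) if (!taken_a[i]) for (j in seq_len(k)) if (!taken_b[j]) {
      if (ov[i, j] > best[1]) best <- c(ov[i, j], i, j)
    }
    if (best[1] < 0) break
    match_b[best[2]] <- best[3]
    taken_a[best[2]] <- TRUE
    taken_b[best[3]] <- TRUE
  }
  agree <- cb == match_b[ca]
  label <- ifelse(agree, paste0("cluster-", ca), "WILDCARD")
  out <- data.frame(nest_id = names(ca), label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- k
  class(out) <- c("cluster_hypothesis", "data.frame")
  out
}

#' @export
print.cluster_hypothesis <- function(x, ...) {
  nw <- sum(x$label == "WILDCARD")
  cat("Cluster hypothesis: ", nrow(x), " nests, k = ", attr(x, "k"),
      ", wild-cards: ", nw, "\n", sep = "")
  invisible(x)
}

#' Silhouette-style support across a range of k
#'
#' Mean silhouette width of the partition obtained by cutting the tree at
#' each `k`, as descriptive support for choosing the cluster count (the
#' workflow inspects the dendrogram; no k is auto-selected).
#'
#' @param dend `nc_dendrogram`.
#' @param d the distance matrix the tree was built from.
#' @param k_range integer vector of cluster counts.
#' @return data frame `k`, `mean_silhouette`.
#' @export
cluster_support <- function(dend, d, k_range = 2:20) {
  dm <- as.matrix(d)
  res <- vapply(k_range, function(k) {
    cl <- cut_dendrogram(dend, k)[rownames(dm)]
    s <- vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      bs <- vapply(setdiff(unique(cl), cl[i]),
                   function(g) mean(dm[i, cl == g]), 0)
      b <- if (length(bs)) min(bs) else NA_real_
      if (is.na(b) || max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, 0)
    mean(s)
  }, 0)
  data.frame(k = k_range, mean_silhouette = res)
}
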