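# shared fixtures and independent oracles

# a syntactically valid trait vector (all orderings satisfied)
base_traits <- function(...) {
  tv <- c(CL = 640, CWb = 530, EL = 150, FRS = 210, ML = 700, MW = 360,
          NOdL = 120, NOH = 95, NOL = 140, PEH = 225, PEW = 150, PL = 245,
          PoOC = 235,
          PPH = 150, PPL = 165, PPW = 205, SL = 460, SPL = 95, SPBA = 160,
          SPST = 170, SPTI = 185, SPWI = 195)
  over <- c(...)
  tv[names(over)] <- over
  tv
}

# write a small specimen CSV (trait columns + metadata) and return its path
write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

make_specimens <- function(n, nest_ids, species = NULL, jitter = 0, seed = 1) {
  set.seed(seed)
  base <- base_traits()
  df <- as.data.frame(t(replicate(n, base + rnorm(length(base), 0, jitter))))
  df <- cbind(data.frame(specimen_id = paste0("s", seq_len(n)),
                         nest_id = rep_len(nest_ids, n),
                         stringsAsFactors = FALSE), df)
  if (!is.null(species)) df$species <- rep_len(species, n)
  df
}

# brute-force average-linkage (UPGMA) oracle: recompute every inter-cluster
# average from the original distances at each step
brute_upgma <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  ids <- -seq_len(n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      v <- mean(dm[clusters[[i]], clusters[[j]]])
      if (v < best[1] - 1e-12) best <- c(v, i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges[[length(merges) + 1]] <- sort(c(ids[i], ids[j]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- length(merges)
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(heights = heights, merges = do.call(rbind, merges))
}

# two-group Fisher direction oracle: w proportional to Sp^-1 (mu1 - mu2)
fisher_direction <- function(x, g) {
  g <- factor(g)
  mus <- rowsum(x, g) / as.vector(table(g))
  resid <- x - mus[g, ]
  Sp <- crossprod(resid) / (nrow(x) - 2)
  solve(Sp, mus[2, ] - mus[1, ])
}

# small well-separated two-species profile pair for LDA tests
two_species_profiles <- function(spst_means = c(0.346, 0.411)) {
  p <- species_profiles()
  p <- p[p$species %in% c("lichtensteini", "laconicus"), ]
  p$SPST_mean <- spst_means[match(c("lichtensteini", "laconicus"), p$species)]
  p
}
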