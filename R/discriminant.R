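# Linear discriminant functions on raw measurements: score = sum(coef * trait)
# + intercept, with a two-sided sign rule and published-style score bands.

#' Construct a discriminant function
#'
#' A named linear combination of raw measurements (coefficients per
#' micrometre) plus intercept. Negative scores assign to
#' `negative_classes`, positive to `positive_classes` (either side may be
#' a pool of taxa). `stats` carries per-taxon reference score
#' distributions: mean, min, max and 5-95% percentiles.
#'
#' @param id function identifier, e.g. `"D4_crassispinus_crasecundus"`.
#' @param coefficients named numeric vector (names are trait names).
#' @param intercept numeric.
#' @param negative_classes,positive_classes taxon label vectors.
#' @param stats optional data frame `class`, `mean`, `min`, `max`, `p5`,
#'   `p95`, `level`.
#' @param success optional named numeric of classification success rates
#'   (percent), e.g. `c(individual = 98.6)`.
#' @return object of class `discriminant_function`.
#' @export
discriminant_function <- function(id, coefficients, intercept,
                                  negative_classes, positive_classes,
                                  stats = NULL, success = NULL) {
  stopifnot(length(coefficients) >= 1, !is.null(names(coefficients)))
  names(coefficients) <- canonical_trait(names(coefficients))
  if (length(intersect(negative_classes, positive_classes)))
    stop("a taxon cannot sit on both sides of the sign rule", call. = FALSE)
  structure(list(id = id, coefficients = coefficients, intercept = intercept,
                 negative_classes = negative_classes,
                 positive_classes = positive_classes,
                 stats = stats, success = success),
            class = "discriminant_function")
}

#' @export
print.discriminant_function <- function(x, ...) {
  terms <- paste0(sprintf("%+g", x$coefficients), "*", names(x$coefficients),
                  collapse = " ")
  cat(x$id, ": score = ", terms, sprintf(" %+g", x$intercept), "\n",
      "  score < 0 -> ", paste(x$negative_classes, collapse = "/"),
      ";  score > 0 -> ", paste(x$positive_classes, collapse = "/"), "\n",
      sep = "")
  if (!is.null(x$success))
    cat("  success: ", paste(names(x$success), "=",
                             paste0(x$success, "%"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a discriminant function
#'
#' @param fn `discriminant_function` (or a registry id string, resolved
#'   via [printed_functions()]).
#' @param traits named vector / one-row data frame of measurements in
#'   micrometres.
#' @return the score (double). Vectorized over data-frame rows.
#' @export
#' @examples
#' evaluate_discriminant(printed_functions()[["D3_lichtensteini_laconicus"]],
#'                       c(PoOC = 0, FRS = 0, SPST = 0))  # intercept only
evaluate_discriminant <- function(fn, traits) {
  if (is.character(fn)) fn <- .resolve_printed(fn)
  if (is.numeric(traits)) traits <- as.data.frame(as.list(traits))
  names(traits) <- canonical_trait(names(traits))
  need <- names(fn$coefficients)
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop(fn$id, ": missing trait(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  as.numeric(as.matrix(traits[, need, drop = FALSE]) %*% fn$coefficients) +
    fn$intercept
}

#' Classify by a discriminant function's sign rule
#'
#' Scores the specimen, assigns by sign (negative score -> negative-side
#' taxa), and reports whether the score falls inside the assigned side's
#' reference 5-95% percentile band. A score outside every band is flagged
#' atypical; a score of exactly zero is a tie and gets no class.
#'
#' @inheritParams evaluate_discriminant
#' @return data frame `score`, `taxon` (NA on tie; pooled taxa joined by
#'   `"/"`), `band` (`"inside"`, `"outside"`, `"ambiguous/atypical"` or NA
#'   when no reference stats), `tie`.
#' @export
classify_by_function <- function(fn, traits) {
  if (is.character(fn)) fn <- .resolve_printed(fn)
  sc <- evaluate_discriminant(fn, traits)
  out <- data.frame(score = sc, taxon = NA_character_, band = NA_character_,
                    tie = sc == 0, stringsAsFactors = FALSE)
  for (i in seq_along(sc)) {
    if (sc[i] == 0) next
    side <- if (sc[i] < 0) fn$negative_classes else fn$positive_classes
    out$taxon[i] <- paste(side, collapse = "/")
    if (!is.null(fn$stats)) {
      st <- fn$stats[fn$stats$class %in% side & !is.na(fn$stats$p5), , drop = FALSE]
      if (nrow(st)) {
        inside <- any(sc[i] >= st$p5 & sc[i] <= st$p95)
        all_bands <- fn$stats[!is.na(fn$stats$p5), , drop = FALSE]
        inside_any <- any(sc[i] >= all_bands$p5 & sc[i] <= all_bands$p95)
        out$band[i] <- if (inside) "inside"
          else if (inside_any) "outside"
          else "ambiguous/atypical"
      }
    }
  }
  out
}

#' Reduced discriminant function by forward selection
#'
#' Greedy forward search for the shortest linear function of raw
#' measurements separating two groups with high leave-one-out success:
#' at each step the trait whose addition maximizes LOOCV success joins the
#' function; the search stops at `max_terms` or when the best gain falls
#' below `min_gain` percentage points. Coefficients come from the
#' two-group LDA on the selected traits (within-group unit variance
#' scaling); the intercept centres the two group score means symmetrically
#' about zero, so they print as the +/- pairs used in diagnoses.
#'
#' @param records specimen data frame.
#' @param labels class labels (2-4 classes; with more than two,
#'   `positive_class` names the taxon to separate from the pooled rest).
#' @param positive_class taxon given positive scores (default: second of
#'   the two class labels in sort order).
#' @param max_terms maximum number of traits (default 4).
#' @param min_gain minimum LOOCV gain (percentage points) to keep adding.
#' @param traits candidate trait pool.
#' @return `discriminant_function` with data-derived reference stats and
#'   attribute `loocv` (percent success of the selected function).
#' @export
reduce_discriminant <- function(records, labels, positive_class = NULL,
                                max_terms = 4, min_gain = 0.5,
                                traits = trait_names()) {
  labels <- as.character(labels)
  keep <- !is.na(labels)
  records <- records[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2 || length(classes) > 4)
    stop("reduce_discriminant expects 2-4 classes", call. = FALSE)
  if (is.null(positive_class))
    positive_class <- if (length(classes) == 2) classes[2] else
      stop("positive_class must be named when pooling > 2 classes", call. = FALSE)
  pos <- labels == positive_class
  g <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  x <- .trait_matrix(records, traits)

  loocv_pct <- function(cols) {
    cv <- tryCatch(
      suppressWarnings(MASS::lda(x[, cols, drop = FALSE], grouping = g,
                                 prior = c(0.5, 0.5), CV = TRUE)),
      error = function(e) NULL)       # e.g. a constant candidate trait
    if (is.null(cv)) return(-Inf)
    100 * mean(as.character(cv$class) == as.character(g), na.rm = TRUE)
  }
  chosen <- character(0)
  best_rate <- -Inf
  repeat {
    cand <- setdiff(traits, chosen)
    if (!length(cand) || length(chosen) >= max_terms) break
    rates <- vapply(cand, function(tr) loocv_pct(c(chosen, tr)), 0)
    top <- which.max(rates)
    if (rates[top] - best_rate < min_gain && length(chosen)) break
    chosen <- c(chosen, cand[top])
    best_rate <- unname(rates[top])
  }
  if (best_rate <= 50)
    stop("no function above 50% cross-validated success", call. = FALSE)

  fit <- MASS::lda(x[, chosen, drop = FALSE], grouping = g, prior = c(0.5, 0.5))
  w <- fit$scaling[, 1]
  raw <- x[, chosen, drop = FALSE] %*% w
  m_neg <- mean(raw[!pos]); m_pos <- mean(raw[pos])
  if (m_pos < m_neg) { w <- -w; raw <- -raw; tmp <- m_neg; m_neg <- -m_pos; m_pos <- -tmp }
  b <- -(mean(raw[!pos]) + mean(raw[pos])) / 2
  sc <- as.numeric(raw) + b
  stats <- do.call(rbind, lapply(classes, function(cl) {
    s <- sc[labels == cl]
    data.frame(class = cl, mean = mean(s), min = min(s), max = max(s),
               p5 = unname(stats::quantile(s, 0.05)),
               p95 = unname(stats::quantile(s, 0.95)),
               level = "individual", stringsAsFactors = FALSE)
  }))
  fn <- discriminant_function(
    id = paste0("D", length(chosen), "_", paste(classes, collapse = "_")),
    coefficients = stats::setNames(as.numeric(w), chosen), intercept = b,
    negative_classes = setdiff(classes, positive_class),
    positive_classes = positive_class,
    stats = stats, success = c(loocv = best_rate))
  attr(fn, "loocv") <- best_rate
  fn
}
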