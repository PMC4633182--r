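# Confirmatory LDA: individual-level fits, nest-mean posteriors, iterative
# wild-card reclassification, LOOCV classification matrices, per-complex
# discriminant scores and reduced discriminant functions.

.trait_matrix <- function(records, traits) {
  miss <- setdiff(traits, names(records))
  if (length(miss)) stop("trait(s) absent: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  as.matrix(records[, traits, drop = FALSE])
}

#' Fit a linear discriminant model on individual workers
#'
#' Classical (pooled within-class covariance) LDA on raw measurements.
#' Class priors are equal by default — the convention adopted throughout
#' this workflow — with proportional priors behind a flag. The sign of
#' each discriminant axis is fixed so that its first nonzero coefficient
#' is positive, making fits reproducible.
#'
#' @param records specimen data frame with trait columns.
#' @param labels class (species) label per record.
#' @param traits traits to use; default all 22.
#' @param prior `"equal"` (default) or `"proportional"`.
#' @param ridge ridge regularization fraction added to the pooled
#'   covariance diagonal when it is singular (`lambda = ridge * trace/p`);
#'   `0` disables and singular fits are an error.
#' @return object of class `morpho_lda` wrapping the fit, with `classes`,
#'   `prior`, `scaling` (trait-by-axis coefficients), `means`.
#' @export
fit_lda <- function(records, labels, traits = trait_names(),
                    prior = c("equal", "proportional"), ridge = 0) {
  prior <- match.arg(prior)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  x <- .trait_matrix(records[keep, , drop = FALSE], traits)
  g <- factor(labels[keep])
  tab <- table(g)
  if (length(tab) < 2) stop("need >= 2 labeled classes", call. = FALSE)
  if (any(tab < 2)) stop("class(es) with < 2 specimens: ",
                         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  pr <- if (prior == "equal") rep(1 / length(tab), length(tab)) else as.numeric(tab / sum(tab))
  transform <- NULL
  fit <- tryCatch(
    MASS::lda(x, grouping = g, prior = pr),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (ridge <= 0)
      stop("singular pooled covariance; reduce traits or set ridge > 0",
           call. = FALSE)
    # whiten with a ridge-regularized pooled covariance, then plain LDA
    resid <- x - rowsum(x, g)[g, ] / as.vector(tab[g])
    S <- crossprod(resid) / (nrow(x) - length(tab))
    lam <- ridge * sum(diag(S)) / ncol(S)
    transform <- solve(chol(S + lam * diag(ncol(S))))
    fit <- MASS::lda(x %*% transform, grouping = g, prior = pr)
  }
  # deterministic axis signs: first nonzero coefficient positive
  for (j in seq_len(ncol(fit$scaling))) {
    nz <- fit$scaling[, j][fit$scaling[, j] != 0]
    if (length(nz) && nz[1] < 0) fit$scaling[, j] <- -fit$scaling[, j]
  }
  structure(list(fit = fit, traits = traits, classes = levels(g),
                 prior = pr, scaling = fit$scaling, means = fit$means,
                 transform = transform),
            class = "morpho_lda")
}

#' @export
print.morpho_lda <- function(x, ...) {
  cat("Linear discriminant model: ", length(x$classes), " classes, ",
      ncol(x$scaling), " axes, traits: ", length(x$traits), "\n", sep = "")
  invisible(x)
}

#' Posterior class probabilities, with nest means
#'
#' Gaussian-LDA posteriors per specimen; when `nest_id` is present the
#' nest-level arithmetic means of the member posteriors — the quantity on
#' which final classifications rest — are attached.
#'
#' @param model `morpho_lda`.
#' @param records specimen data frame.
#' @return object of class `posterior_table`: data frame of specimen
#'   posteriors (`specimen_id`, one column per class, `predicted`), with
#'   attribute `nest_posteriors` (same layout per nest).
#' @export
predict_posteriors <- function(model, records) {
  x <- .trait_matrix(records, model$traits)
  if (!is.null(model$transform)) x <- x %*% model$transform
  p <- stats::predict(model$fit, x)
  post <- as.data.frame(p$posterior, check.names = FALSE)
  post <- cbind(specimen_id = records$specimen_id %||% rownames(post), post,
                stringsAsFactors = FALSE)
  post$predicted <- model$classes[max.col(p$posterior, ties.method = "first")]
  if ("nest_id" %in% names(records)) {
    agg <- stats::aggregate(p$posterior, by = list(nest_id = records$nest_id), FUN = mean)
    agg$predicted <- model$classes[max.col(as.matrix(agg[, model$classes]),
                                           ties.method = "first")]
    attr(post, "nest_posteriors") <- agg
  }
  class(post) <- c("posterior_table", "data.frame")
  post
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nest-level posterior means
#' @param posteriors result of [predict_posteriors()].
#' @return per-nest mean posterior data frame.
#' @export
nest_posteriors <- function(posteriors) attr(posteriors, "nest_posteriors")

#' Iterative wild-card reclassification
#'
#' The confirmatory step: starting from a [congruence_hypothesis()] (or
#' any nest -> label map with `"WILDCARD"` entries), repeatedly (i) fit an
#' individual-level LDA on workers of currently labeled nests, (ii)
#' assign every wild-card nest to the class with the highest nest-mean
#' posterior, until assignments are stable or `max_iter` is reached. No
#' nest keeps an ambiguous position once converged.
#'
#' @param records specimen data frame (`nest_id` + traits).
#' @param hypothesis `cluster_hypothesis` or data frame `nest_id`,`label`.
#' @param traits traits used in the fits.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param ... passed to [fit_lda()].
#' @return object of class `wildcard_lda`: list with `labels` (final
#'   nest -> class), `model` (final fit), `iterations`, `converged`,
#'   `trace` (per-iteration wild-card assignments).
#' @export
wildcard_iterate <- function(records, hypothesis, traits = trait_names(),
                             max_iter = 20, ...) {
  lab <- stats::setNames(hypothesis$label, hypothesis$nest_id)
  if (all(lab == "WILDCARD")) stop("all nests are wild-cards: no seed labels",
                                   call. = FALSE)
  wc <- names(lab)[lab == "WILDCARD"]
  trace <- list()
  converged <- length(wc) == 0
  it <- 0L
  model <- NULL
  repeat {
    it <- it + 1L
    rec_lab <- lab[records$nest_id]
    rec_lab[rec_lab == "WILDCARD"] <- NA
    model <- fit_lda(records, rec_lab, traits = traits, ...)
    if (!length(wc)) { converged <- TRUE; trace[[it]] <- character(0); break }
    post <- predict_posteriors(model, records[records$nest_id %in% wc, , drop = FALSE])
    np <- nest_posteriors(post)
    new <- stats::setNames(np$predicted, np$nest_id)
    trace[[it]] <- new
    prev <- lab[names(new)]
    lab[names(new)] <- new
    if (all(prev == new)) { converged <- TRUE }
    if (converged || it >= max_iter) break
  }
  if (converged && length(wc)) {
    # one confirmatory refit on the stabilized labels
    model <- fit_lda(records, lab[records$nest_id], traits = traits, ...)
  }
  structure(list(labels = lab, model = model, iterations = it,
                 converged = converged, trace = trace),
            class = "wildcard_lda")
}

#' @export
print.wildcard_lda <- function(x, ...) {
  cat("Wild-card LDA: ", length(x$labels), " nests, ",
      length(unique(x$labels)), " classes, ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Classification matrix (resubstitution or LOOCV)
#'
#' Confusion counts and success rates at the individual or nest level.
#' Nest-level cross validation removes the entire nest before refitting,
#' so no worker of the held-out nest leaks into the training set.
#'
#' @param records specimen data frame.
#' @param labels species label per record.
#' @param mode `"loocv"` or `"resubstitution"`.
#' @param level `"individual"` or `"nest"` (nest-mean posteriors decide).
#' @param traits,... passed to [fit_lda()].
#' @return object of class `classification_matrix`: list with `table`
#'   (true x predicted counts), `per_class` and `overall` success rates,
#'   `skipped` (units unscorable because holdout emptied a class).
#' @export
classification_matrix <- function(records, labels,
                                  mode = c("loocv", "resubstitution"),
                                  level = c("individual", "nest"),
                                  traits = trait_names(), ...) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  records <- records[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  skipped <- character(0)

  if (level == "individual") {
    if (mode == "resubstitution") {
      model <- fit_lda(records, labels, traits = traits, ...)
      pred <- predict_posteriors(model, records)$predicted
      truth <- labels
    } else {
      x <- .trait_matrix(records, traits)
      g <- factor(labels)
      pr <- rep(1 / nlevels(g), nlevels(g))
      cv <- MASS::lda(x, grouping = g, prior = pr, CV = TRUE)
      pred <- as.character(cv$class)
      truth <- labels
      ok <- !is.na(pred)
      skipped <- records$specimen_id[!ok] %||% character(0)
      pred <- pred[ok]; truth <- truth[ok]
    }
  } else {
    nests <- unique(records$nest_id)
    truth <- pred <- character(0)
    if (mode == "resubstitution") {
      model <- fit_lda(records, labels, traits = traits, ...)
      np <- nest_posteriors(predict_posteriors(model, records))
      nest_lab <- vapply(nests, function(nid)
        unique(labels[records$nest_id == nid])[1], "")
      truth <- nest_lab
      pred <- np$predicted[match(nests, np$nest_id)]
    } else {
      for (nid in nests) {
        hold <- records$nest_id == nid
        tr_lab <- labels[!hold]
        if (any(table(tr_lab) < 2) || length(unique(tr_lab)) < 2) {
          skipped <- c(skipped, nid); next
        }
        model <- fit_lda(records[!hold, , drop = FALSE], tr_lab,
                         traits = traits, ...)
        np <- nest_posteriors(predict_posteriors(model, records[hold, , drop = FALSE]))
        truth <- c(truth, unique(labels[hold])[1])
        pred <- c(pred, np$predicted[1])
      }
    }
  }
  tab <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  per_class <- ifelse(rowSums(tab) > 0, diag(tab) / rowSums(tab), NA_real_)
  structure(list(table = tab,
                 per_class = per_class,
                 overall = sum(diag(tab)) / sum(tab),
                 n = sum(tab), mode = mode, level = level,
                 skipped = skipped),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, digits = 1, ...) {
  cat("Classification matrix (", x$mode, ", ", x$level, " level): ",
      x$n, " units, overall success ",
      format(100 * x$overall, digits = digits + 2), "%\n", sep = "")
  if (length(x$skipped)) cat("  skipped (unscorable): ", length(x$skipped), "\n", sep = "")
  invisible(x)
}

#' Discriminant scores within a species complex
#'
#' Specimen coordinates on the first (up to three) discriminant axes of a
#' complex-level model, ordered by decreasing eigenvalue, for scatterplot
#' visualization of the species of one complex.
#'
#' @param model `morpho_lda` fitted on one complex (>= 2 species).
#' @param records specimen data frame.
#' @param axes how many axes to return (capped at classes - 1).
#' @return data frame `specimen_id`, `LD1`..`LDk`, `predicted`.
#' @export
complex_scores <- function(model, records, axes = 3) {
  k <- length(model$classes)
  if (k < 2) stop("complex has a single species: no discriminant axes", call. = FALSE)
  x <- .trait_matrix(records, model$traits)
  if (!is.null(model$transform)) x <- x %*% model$transform
  p <- stats::predict(model$fit, x)
  na <- min(axes, k - 1, ncol(p$x))
  out <- data.frame(specimen_id = records$specimen_id %||% seq_len(nrow(records)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(na)) out[[paste0("LD", j)]] <- unname(p$x[, j])
  out$predicted <- as.character(p$class)
  out
}
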