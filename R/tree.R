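# Cross-validated decision-tree key induction: CART (Gini, binary splits)
# on nest-mean ratios via rpart, conversion to the couplet structure the
# key engine traverses, leave-one-nest-out validation and node t-tests.

.safe_name <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Induce a decision-tree identification key
#'
#' Fits a classification tree (Gini impurity, binary splits) to labeled
#' nest-mean ratio data and converts it into a dichotomous key. Continuous
#' thresholds fall midway between adjacent observed values (the CART
#' convention); categorical features such as `region` may be offered to
#' the splitter alongside ratios, mirroring the published key where two
#' morphometric nodes were replaced by geographic distribution.
#'
#' @param nests nest data frame (one row per nest).
#' @param labels species label per nest.
#' @param features feature columns: ratio names (computed from the trait
#'   means via [compute_ratios()] when absent) and/or categorical columns
#'   present in `nests`.
#' @param min_leaf minimum nests per leaf (default 3).
#' @param max_depth maximum tree depth.
#' @param cp complexity penalty (rpart `cp`).
#' @return object of class `induced_tree`: list with `key`
#'   ([morpho_key()] form, couplets numbered in preorder), `rpart` (the
#'   underlying fit), `nodes` (per-node split feature, threshold, class
#'   counts, resubstitution success, per-branch feature mean/min/max),
#'   `features`, `data`.
#' @export
build_tree <- function(nests, labels, features = NULL, min_leaf = 3,
                       max_depth = 30, cp = 0.001) {
  labels <- as.character(labels)
  keep <- !is.na(labels)
  nests <- nests[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  small <- names(which(table(labels) < min_leaf))
  if (length(small))
    warning("class(es) with fewer nests than min_leaf may go unrepresented: ",
            paste(small, collapse = ", "), call. = FALSE)
  if (is.null(features)) {
    features <- setdiff(known_ratios(), "CWb/CS")
    if ("region" %in% names(nests)) features <- c(features, "region")
  }
  df <- .tree_frame(nests, features)
  if (length(classes) == 1) {        # pure input: a single leaf, no fit
    key <- structure(list(couplets = list(), nest_mean_key = TRUE,
                          single_leaf = classes),
                     class = "morpho_key")
    return(structure(list(key = key, rpart = NULL, nodes = NULL,
                          features = features, data = df, labels = labels,
                          classes = classes),
                     class = "induced_tree"))
  }
  dat <- cbind(.class = factor(labels, levels = classes), df)
  fit <- rpart::rpart(
    .class ~ ., data = dat, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(minsplit = 2 * min_leaf,
                                   minbucket = min_leaf, cp = cp,
                                   maxdepth = max_depth, xval = 0,
                                   maxsurrogate = 0, maxcompete = 0))
  conv <- .rpart_to_key(fit, df, labels)
  structure(list(key = conv$key, rpart = fit, nodes = conv$nodes,
                 features = features, data = df, labels = labels,
                 classes = classes),
            class = "induced_tree")
}

# assemble the feature frame: ratio features computed from trait means,
# categorical features passed through as factors; safe column names with a
# map back to the display names.
.tree_frame <- function(nests, features) {
  out <- list()
  for (f in features) {
    if (f %in% names(nests)) {
      v <- nests[[f]]
      out[[f]] <- if (is.character(v)) factor(v) else v
    } else if (f %in% known_ratios()) {
      out[[f]] <- compute_ratios(nests, f)[[f]]
    } else stop("feature '", f, "' is neither a column nor a known ratio",
                call. = FALSE)
  }
  df <- as.data.frame(out, check.names = FALSE)
  names(df) <- .safe_name(names(df))
  attr(df, "display") <- stats::setNames(features, .safe_name(features))
  df
}

.rpart_to_key <- function(fit, df, labels) {
  frame <- fit$frame
  display <- attr(df, "display")
  node_nums <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  classes <- attr(fit, "ylevels")

  # primary split per internal node (no competitors/surrogates were kept)
  split_info <- list()
  si <- 1
  for (i in seq_len(nrow(frame))) {
    if (is_leaf[i]) next
    s <- fit$splits[si, , drop = TRUE]
    vn <- rownames(fit$splits)[si]
    info <- list(var = vn, ncat = s[["ncat"]], index = s[["index"]])
    if (s[["ncat"]] > 1) {    # categorical: csplit row
      cs <- fit$csplit[s[["index"]], ]
      lv <- levels(df[[vn]])
      info$left_set <- lv[cs == 1L]
      info$right_set <- lv[cs == 3L]
    }
    split_info[[as.character(node_nums[i])]] <- info
    si <- si + 1
  }

  # route every training row, recording membership per rpart node
  membership <- list("1" = seq_len(nrow(df)))
  route_children <- function(num) {
    info <- split_info[[as.character(num)]]
    if (is.null(info)) return()
    rows <- membership[[as.character(num)]]
    x <- df[rows, info$var]
    goes_left <- if (info$ncat > 1) x %in% info$left_set
      else if (info$ncat == -1) x < info$index else x >= info$index
    membership[[as.character(2 * num)]] <<- rows[goes_left]
    membership[[as.character(2 * num + 1)]] <<- rows[!goes_left]
    route_children(2 * num)
    route_children(2 * num + 1)
  }
  route_children(1)

  pred_leaf <- classes[frame$yval][match(fit$where, seq_len(nrow(frame)))]
  correct <- pred_leaf == labels

  # preorder couplet numbering over internal nodes
  internal <- node_nums[!is_leaf]
  cid <- stats::setNames(seq_along(internal),
                         as.character(internal[order(match(internal, node_nums))]))
  leaf_class <- stats::setNames(classes[frame$yval[is_leaf]],
                                as.character(node_nums[is_leaf]))
  couplets <- list()
  nodes <- list()
  for (num in internal) {
    info <- split_info[[as.character(num)]]
    rows <- membership[[as.character(num)]]
    lrows <- membership[[as.character(2 * num)]]
    rrows <- membership[[as.character(2 * num + 1)]]
    tgt <- function(child) {
      if (as.character(child) %in% names(cid))
        paste0("#", cid[[as.character(child)]])
      else leaf_class[[as.character(child)]]
    }
    feat <- display[[info$var]] %||% info$var
    if (info$ncat > 1) {
      cpl <- .couplet(cid[[as.character(num)]], type = "region", feature = feat,
                      yes = tgt(2 * num), no = tgt(2 * num + 1),
                      yes_set = info$left_set, no_set = info$right_set)
      rng_l <- rng_r <- NULL
    } else {
      op <- if (info$ncat == -1) "<" else ">"
      thr <- info$index
      x <- df[[info$var]]
      rng_l <- c(min(x[lrows]), max(x[lrows]))
      rng_r <- c(min(x[rrows]), max(x[rrows]))
      cpl <- .couplet(cid[[as.character(num)]], type = "ratio", feature = feat,
                      op = op, threshold = thr,
                      yes = tgt(2 * num), no = tgt(2 * num + 1),
                      range_yes = rng_l, range_no = rng_r)
    }
    couplets[[length(couplets) + 1L]] <- cpl
    nodes[[length(nodes) + 1L]] <- data.frame(
      couplet = cid[[as.character(num)]], rpart_node = num, feature = feat,
      threshold = if (info$ncat > 1) NA_real_ else info$index,
      n = length(rows), success = mean(correct[rows]),
      yes_mean = if (is.null(rng_l)) NA_real_ else mean(df[lrows, info$var]),
      yes_min = if (is.null(rng_l)) NA_real_ else rng_l[1],
      yes_max = if (is.null(rng_l)) NA_real_ else rng_l[2],
      no_mean = if (is.null(rng_r)) NA_real_ else mean(df[rrows, info$var]),
      no_min = if (is.null(rng_r)) NA_real_ else rng_r[1],
      no_max = if (is.null(rng_r)) NA_real_ else rng_r[2],
      stringsAsFactors = FALSE)
  }
  if (!length(couplets)) {   # single-leaf tree
    key <- structure(list(couplets = list(), nest_mean_key = TRUE,
                          single_leaf = leaf_class[["1"]]),
                     class = "morpho_key")
    return(list(key = key, nodes = NULL))
  }
  list(key = morpho_key(couplets),
       nodes = do.call(rbind, nodes))
}

#' @export
print.induced_tree <- function(x, ...) {
  cat("Induced identification key (", length(x$classes), " taxa, ",
      length(x$key$couplets), " couplets)\n", sep = "")
  cat(render_key(x), sep = "\n")
  invisible(x)
}

#' @export
predict.induced_tree <- function(object, newdata = NULL, ...) {
  if (is.null(object$rpart)) {       # single-leaf tree
    n <- if (is.null(newdata)) nrow(object$data) else nrow(newdata)
    return(rep(object$classes, n))
  }
  if (is.null(newdata)) {
    classes <- attr(object$rpart, "ylevels")
    return(classes[object$rpart$frame$yval[object$rpart$where]])
  }
  df <- .tree_frame(newdata, object$features)
  for (cn in names(df))                      # align factor levels to training
    if (is.factor(df[[cn]]) && is.factor(object$data[[cn]]))
      df[[cn]] <- factor(as.character(df[[cn]]), levels = levels(object$data[[cn]]))
  as.character(stats::predict(object$rpart, df, type = "class"))
}

#' Render an induced tree as a numbered text key
#'
#' @param tree `induced_tree` (or a `morpho_key`).
#' @return character vector of couplet lines; a single-leaf tree renders
#'   as one line naming the taxon.
#' @export
render_key <- function(tree) {
  key <- if (inherits(tree, "induced_tree")) tree$key else tree
  if (!length(key$couplets))
    return(paste0("single taxon: ...", key$single_leaf))
  format_key(key)
}

#' Leave-one-nest-out validation of an induced tree
#'
#' Refits the tree with each nest held out in turn and predicts the
#' held-out nest; reports the overall success rate, the confusion table,
#' and the per-node resubstitution success of the full-data tree (the
#' percentages bracketed under each node of the published key figure).
#'
#' @param nests,labels,features,... as in [build_tree()].
#' @return list with `overall` (proportion correct), `table`, `per_node`
#'   (node summary of the full-data tree), `unscorable` (nests of
#'   single-nest classes, reported but not scored).
#' @export
loocv_tree <- function(nests, labels, features = NULL, ...) {
  labels <- as.character(labels)
  keep <- !is.na(labels)
  nests <- nests[keep, , drop = FALSE]
  labels <- labels[keep]
  full <- build_tree(nests, labels, features = features, ...)
  classes <- sort(unique(labels))
  n <- nrow(nests)
  pred <- rep(NA_character_, n)
  unscorable <- character(0)
  for (i in seq_len(n)) {
    if (sum(labels[-i] == labels[i]) == 0) {
      unscorable <- c(unscorable, nests$nest_id[i] %||% as.character(i))
      next
    }
    fit_i <- suppressWarnings(
      build_tree(nests[-i, , drop = FALSE], labels[-i],
                 features = full$features, ...))
    pred[i] <- predict(fit_i, nests[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  tab <- table(factor(labels[ok], levels = classes),
               factor(pred[ok], levels = classes))
  list(overall = sum(diag(tab)) / sum(tab), table = tab,
       per_node = full$nodes, unscorable = unscorable)
}

#' Welch t-test of a split feature between a node's branches
#'
#' The manual reliability check of a key node: a two-sample Welch t-test
#' of the node's split feature between the nests routed to its two
#' branches.
#'
#' @param tree `induced_tree`.
#' @param couplet couplet number (default: all internal nodes, with
#'   Holm-adjusted p-values alongside the raw ones).
#' @return data frame `couplet`, `feature`, `t`, `df`, `p`, `p_holm`.
#' @export
node_ttest <- function(tree, couplet = NULL) {
  nodes <- tree$nodes
  if (is.null(nodes)) stop("single-leaf tree has no nodes", call. = FALSE)
  if (!is.null(couplet)) nodes <- nodes[nodes$couplet %in% couplet, , drop = FALSE]
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    nd <- nodes[i, ]
    if (is.na(nd$threshold))
      return(data.frame(couplet = nd$couplet, feature = nd$feature,
                        t = NA_real_, df = NA_real_, p = NA_real_))
    cpl <- tree$key$couplets[[paste0("#", nd$couplet)]]
    x <- tree$data[[.safe_name(nd$feature)]]
    rows <- .route_rows(tree, nd$couplet)
    a <- x[rows$yes]; b <- x[rows$no]
    if (length(a) < 2 || length(b) < 2)
      stop("couplet ", nd$couplet, ": both branches need >= 2 nests", call. = FALSE)
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(data.frame(couplet = nd$couplet, feature = nd$feature, t = 0,
                        df = length(a) + length(b) - 2, p = 1))
    tt <- stats::t.test(a, b)
    data.frame(couplet = nd$couplet, feature = nd$feature,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, "holm")
  out
}

# rows of tree$data reaching each branch of a couplet, by key traversal
.route_rows <- function(tree, couplet) {
  df <- tree$data
  display <- attr(df, "display")
  reach <- function(rows, at) {
    cpl <- tree$key$couplets[[at]]
    x <- df[rows, .safe_name(cpl$feature)]
    goes_yes <- if (cpl$type %in% c("categorical", "region")) x %in% cpl$yes_set
      else if (cpl$op == "<") x < cpl$threshold else x > cpl$threshold
    list(yes = rows[goes_yes], no = rows[!goes_yes])
  }
  # walk from root accumulating membership
  memb <- list(`#1` = seq_len(nrow(df)))
  for (cpl in tree$key$couplets) {
    at <- paste0("#", cpl$id)
    if (is.null(memb[[at]])) next
    br <- reach(memb[[at]], at)
    for (side in c("yes", "no")) {
      t_ <- cpl[[side]]
      if (startsWith(t_, "#")) memb[[t_]] <- br[[side]]
    }
    if (cpl$id == couplet) return(br)
  }
  stop("couplet ", couplet, " not found", call. = FALSE)
}

#' Replace a couplet of a key
#'
#' Post-hoc node replacement, e.g. swapping a morphometric test for a
#' geographic one as done at two nodes of the published key.
#'
#' @param key `morpho_key` (or `induced_tree`, whose key is modified).
#' @param id couplet number to replace.
#' @param couplet replacement node built like the entries of
#'   [nylanderi_key()]; its `yes`/`no` targets must point at existing
#'   couplets or taxa.
#' @return the modified object.
#' @export
replace_couplet <- function(key, id, couplet) {
  if (inherits(key, "induced_tree")) {
    key$key <- replace_couplet(key$key, id, couplet)
    return(key)
  }
  at <- paste0("#", id)
  if (is.null(key$couplets[[at]])) stop("no couplet ", id, call. = FALSE)
  couplet$id <- id
  key$couplets[[at]] <- couplet
  key
}
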