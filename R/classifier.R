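feature_set_levels <- c("topo", "topo_sent", "topo_sent_topic", "enriched")

#' Assemble edge feature matrices for the four evaluated configurations
#'
#' Builds, for every edge of `deg_twitter`, one of the four nested feature
#' sets: `"topo"` (Twitter-side topological features plus the two edge
#' weights), `"topo_sent"` (+ sentiment tuple), `"topo_sent_topic"` (+ the
#' 2k-vector concatenating the drug and effect topic contexts) and
#' `"enriched"` (+ the reference-graph topological block). Enrichment of an
#' edge with an endpoint absent from `deg_sider` uses an all-zero block with
#' `missing_sider_flag = 1`.
#'
#' @param deg_twitter A labeled [deg] from [build_twitter_deg()].
#' @param feature_set One of `"topo"`, `"topo_sent"`, `"topo_sent_topic"`,
#'   `"enriched"`.
#' @param deg_sider Reference [deg]; required for `"enriched"`.
#' @param sentiment Data frame `drug_id`, `effect_id`, `s_drug`, `s_effect`
#'   (e.g. from [semantic_context()]); required beyond `"topo"`.
#' @param topic List with matrices `drug` and `effect` (rows named by entity
#'   id, k columns); required beyond `"topo_sent"`.
#' @return Data frame: `drug_id`, `effect_id`, `label`, then the feature
#'   columns in fixed order.
#' @export
edge_feature_matrix <- function(deg_twitter, feature_set = "topo",
                                deg_sider = NULL, sentiment = NULL,
                                topic = NULL) {
  feature_set <- match.arg(feature_set, feature_set_levels)
  edges <- deg_twitter$edges
  pairs <- edges[, c("drug_id", "effect_id"), drop = FALSE]
  out <- featurize_edges(deg_twitter, pairs, insert = FALSE)
  out$temporal_weight <- ifelse(is.na(edges$temporal_weight), 0,
                                edges$temporal_weight)
  out$frequency_weight <- ifelse(is.na(edges$frequency_weight), 0,
                                 edges$frequency_weight)
  key <- pair_key(edges$drug_id, edges$effect_id)
  if (feature_set %in% c("topo_sent", "topo_sent_topic", "enriched")) {
    if (is.null(sentiment)) {
      stop("feature set `", feature_set, "` needs the sentiment context",
           call. = FALSE)
    }
    skey <- pair_key(sentiment$drug_id, sentiment$effect_id)
    idx <- match(key, skey)
    if (anyNA(idx)) stop("sentiment context missing for some edges", call. = FALSE)
    out$s_drug <- sentiment$s_drug[idx]
    out$s_effect <- sentiment$s_effect[idx]
  }
  if (feature_set %in% c("topo_sent_topic", "enriched")) {
    if (is.null(topic)) {
      stop("feature set `", feature_set, "` needs the topic context",
           call. = FALSE)
    }
    k <- ncol(topic$drug)
    miss_d <- setdiff(edges$drug_id, rownames(topic$drug))
    miss_e <- setdiff(edges$effect_id, rownames(topic$effect))
    if (length(miss_d) || length(miss_e)) {
      stop("topic context missing for endpoint(s): ",
           paste(c(miss_d, miss_e), collapse = ", "), call. = FALSE)
    }
    td <- topic$drug[edges$drug_id, , drop = FALSE]
    te <- topic$effect[edges$effect_id, , drop = FALSE]
    colnames(td) <- paste0("topic_drug_", seq_len(k))
    colnames(te) <- paste0("topic_effect_", seq_len(k))
    out <- cbind(out, as.data.frame(td, row.names = NULL),
                 as.data.frame(te, row.names = NULL))
  }
  if (feature_set == "enriched") {
    if (is.null(deg_sider)) {
      stop("feature set `enriched` needs `deg_sider`", call. = FALSE)
    }
    present <- edges$drug_id %in% deg_sider$drugs$id &
      edges$effect_id %in% deg_sider$effects$id
    sider_cols <- paste0("sider_", c("degree_d", "degree_e", "common_neighbors",
                                     "jaccard", "adamic_adar", "pref_attach"))
    block <- matrix(0, nrow = nrow(edges), ncol = 6L,
                    dimnames = list(NULL, sider_cols))
    if (any(present)) {
      f <- featurize_edges(deg_sider, pairs[present, , drop = FALSE],
                           insert = FALSE)
      block[present, ] <- as.matrix(f[, 3:8])
    }
    out <- cbind(out, as.data.frame(block))
    out$missing_sider_flag <- as.numeric(!present)
  }
  out$label <- edges$label
  lead <- c("drug_id", "effect_id", "label")
  out[, c(lead, setdiff(names(out), lead))]
}

feature_columns <- function(features) {
  setdiff(names(features), c("drug_id", "effect_id", "label"))
}

as_feature_matrix <- function(features, cols = NULL) {
  if (is.matrix(features)) return(features)
  cols <- cols %||% feature_columns(features)
  as.matrix(features[, cols, drop = FALSE])
}

#' Train the adverse-edge classifier
#'
#' A 10-tree random forest separating adverse from pseudo-non-adverse edges.
#' The positive class is `"adverse"` (or the factor's last level for other
#' labelings). Reproducible from `seed`.
#'
#' @param features Feature data frame (id/label columns are dropped
#'   automatically) or numeric matrix.
#' @param labels Edge labels; character, factor or binary vector.
#' @param seed Integer seed.
#' @param n_trees Ensemble size (default 10).
#' @return An object of class `"edge_classifier"`.
#' @export
train_edge_classifier <- function(features, labels, seed, n_trees = 10L) {
  x <- as_feature_matrix(features)
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("labels contain a single class; need both classes to train",
         call. = FALSE)
  }
  y <- droplevels(y)
  positive <- if ("adverse" %in% levels(y)) "adverse" else levels(y)[length(levels(y))]
  model <- local_seed(seed, randomForest::randomForest(x = x, y = y, ntree = n_trees))
  structure(list(model = model, feature_names = colnames(x),
                 positive = positive, n_trees = n_trees),
            class = "edge_classifier")
}

#' @export
print.edge_classifier <- function(x, ...) {
  cat(sprintf("<edge_classifier> %d trees over %d features (positive class: %s)\n",
              x$n_trees, length(x$feature_names), x$positive))
  invisible(x)
}

#' Predict with an edge classifier
#'
#' @param object An `"edge_classifier"`.
#' @param features Feature data frame or matrix with the training columns.
#' @param type `"label"` for hard class predictions (0.5 vote-fraction
#'   threshold), `"score"` for the positive-class vote fraction.
#' @param ... Unused.
#' @return Character vector of labels or numeric scores in \[0, 1\].
#' @export
predict.edge_classifier <- function(object, features, type = c("label", "score"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(features, intersect(colnames(as_feature_matrix(features)),
                                             object$feature_names))
  missing_cols <- setdiff(object$feature_names, colnames(x))
  if (length(missing_cols)) {
    stop("features lack training column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, object$feature_names, drop = FALSE]
  votes <- stats::predict(object$model, x, type = "prob")
  score <- votes[, object$positive]
  if (type == "score") return(unname(score))
  lv <- levels(object$model$y)
  negative <- setdiff(lv, object$positive)[1L]
  unname(ifelse(score >= 0.5, object$positive, negative))
}

#' Precision, recall and F1 of predicted edge labels
#'
#' `precision = TP / (TP + FP)` (0 by convention when there are no positive
#' predictions), `recall = TP / (TP + FN)` (0 when there are no positive
#' cases) and `f1` their harmonic mean (0 when both are 0).
#'
#' @param predicted,truth Label vectors of equal length.
#' @param positive The positive-class label (default `"adverse"`).
#' @return Named numeric vector `c(precision =, recall =, f1 =)`.
#' @export
evaluate_predictions <- function(predicted, truth, positive = "adverse") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# Shared stratified k-fold CV engine (also used by the tweet filter).
cv_metrics <- function(x, y, folds, n_trees, positive) {
  y <- droplevels(as.factor(y))
  stopifnot(folds >= 2L)
  fold_of <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  per_fold <- matrix(NA_real_, nrow = folds, ncol = 3L,
                     dimnames = list(NULL, c("precision", "recall", "f1")))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    if (nlevels(droplevels(y[tr])) < 2L || !any(te)) {
      warning("fold ", f, " has a single class; metrics set to 0", call. = FALSE)
      per_fold[f, ] <- 0
      next
    }
    m <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                    ntree = n_trees)
    pred <- stats::predict(m, x[te, , drop = FALSE])
    per_fold[f, ] <- evaluate_predictions(pred, y[te], positive = positive)
  }
  list(mean = colMeans(per_fold), sd = apply(per_fold, 2L, stats::sd),
       folds = as.data.frame(per_fold))
}

#' Stratified k-fold cross-validation of the edge classifier
#'
#' Folds are stratified by label and the assignment is reproducible from
#' `seed`. A fold whose training part degenerates to one class scores 0 with a
#' warning.
#'
#' @inheritParams train_edge_classifier
#' @param folds Number of folds (default 10, must be >= 2).
#' @return List with `mean` and `sd` (named vectors over precision, recall,
#'   f1) and `folds` (per-fold metric data frame).
#' @export
cross_validate <- function(features, labels, folds = 10L, seed, n_trees = 10L) {
  x <- as_feature_matrix(features)
  y <- droplevels(as.factor(labels))
  positive <- if ("adverse" %in% levels(y)) "adverse" else levels(y)[length(levels(y))]
  local_seed(seed, cv_metrics(x, y, folds = folds, n_trees = n_trees,
                              positive = positive))
}

#' Random train/test split
#'
#' Disjoint and exhaustive: every index lands in exactly one side.
#' Reproducible from `seed`.
#'
#' @param n Number of items (or a data frame / vector whose length is used).
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, fraction = 0.5, seed) {
  if (is.data.frame(n)) n <- nrow(n) else if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  stopifnot(fraction > 0, fraction < 1)
  train <- local_seed(seed, sort(sample.int(n, round(fraction * n))))
  list(train = train, test = setdiff(seq_len(n), train))
}
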