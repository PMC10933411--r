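#' Default random-forest hyperparameter grid
#'
#' @return Data frame of configurations (`num_trees`, `max_depth`; depth 0
#'   means unlimited).
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100L, 500L), max_depth = c(0L, 10L, 20L))
}

## Assign groups to folds, shuffled, balancing member counts greedily.
group_folds <- function(groups, folds, seed = NULL) {
  tab <- table(groups)
  gnames <- with_seed(seed, sample(names(tab)))
  sizes <- as.integer(tab[gnames])
  fold_of_group <- integer(length(gnames))
  load <- numeric(folds)
  for (g in order(-sizes)) {
    f <- which.min(load)
    fold_of_group[g] <- f
    load[f] <- load[f] + sizes[g]
  }
  setNames(fold_of_group, gnames)[as.character(groups)]
}

#' Train a grouped, grid-searched random forest
#'
#' Splits pairs into 80/20 train/hold-out sets and runs group five-fold
#' cross-validation on the training set, where grouping is by paralogous
#' family (`family_group`): no family ever appears on both sides of the
#' split or of any fold, preventing leakage between related pairs. The grid
#' configuration maximizing mean cross-validated AUC-PR is refit on the full
#' training set. Forests use balanced class weights.
#'
#' @param features Numeric feature matrix, rows = pairs (rownames used as
#'   pair ids).
#' @param labels Binary labels (1 = positive), one per row.
#' @param family_group Family-group id per row.
#' @param train_frac Training fraction (default 0.8).
#' @param folds Cross-validation folds (default 5).
#' @param grid Hyperparameter data frame (default [default_rf_grid()]).
#' @param seed Integer seed controlling the split, folds and forests.
#' @return A `coev_rf` object: the fitted `ranger` model, the chosen
#'   configuration, the per-fold CV report, and train/test row indices.
#' @export
train_rf <- function(features, labels, family_group, train_frac = 0.8,
                     folds = 5, grid = default_rf_grid(), seed = 1L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n || length(family_group) != n)
    coev_stop("labels and family_group must match feature rows")
  if (length(unique(family_group)) < folds)
    coev_stop(sprintf("need at least %d distinct family groups for %d-fold CV",
                      folds, folds))
  seeds <- child_seeds(seed, 3L)
  ## group-aware 80/20 split: add shuffled groups until the train quota fills
  gshuf <- with_seed(seeds[1], sample(unique(family_group)))
  gsize <- table(family_group)[gshuf]
  n_train_target <- train_frac * n
  in_train_group <- cumsum(as.integer(gsize)) <= n_train_target
  if (!any(in_train_group)) in_train_group[1] <- TRUE
  train_groups <- gshuf[in_train_group]
  train_idx <- which(family_group %in% train_groups)
  test_idx <- setdiff(seq_len(n), train_idx)
  fg_train <- family_group[train_idx]
  if (length(unique(fg_train)) < folds)
    coev_stop("training set has fewer family groups than folds")
  fold_id <- group_folds(fg_train, folds, seed = seeds[2])
  cv <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- train_idx[fold_id != f]
      va <- train_idx[fold_id == f]
      if (sum(labels[va] == 1L) == 0L || length(unique(labels[tr])) < 2L)
        return(NA_real_)
      fit <- fit_ranger(features[tr, , drop = FALSE], labels[tr],
                        grid$num_trees[g], grid$max_depth[g], seeds[3])
      p <- predict_ranger(fit, features[va, , drop = FALSE])
      pr_curve(p, labels[va])$auc_pr
    }, numeric(1))
    data.frame(num_trees = grid$num_trees[g], max_depth = grid$max_depth[g],
               fold = seq_len(folds), auc_pr = aucs)
  }))
  mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
    m <- cv$num_trees == grid$num_trees[g] & cv$max_depth == grid$max_depth[g]
    mean(cv$auc_pr[m], na.rm = TRUE)
  }, numeric(1))
  best <- if (all(is.nan(mean_auc))) 1L else which.max(mean_auc)
  model <- fit_ranger(features[train_idx, , drop = FALSE], labels[train_idx],
                      grid$num_trees[best], grid$max_depth[best], seeds[3])
  structure(
    list(version = 1L, model = model, best = grid[best, , drop = FALSE],
         cv = cv, mean_cv_auc = mean_auc,
         train_idx = train_idx, test_idx = test_idx, fold_id = fold_id,
         feature_names = colnames(features)),
    class = "coev_rf")
}

fit_ranger <- function(X, y, num_trees, max_depth, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  tab <- table(yf)
  cw <- as.numeric(sum(tab) / (2 * pmax(tab, 1L)))
  df <- data.frame(X)
  df$.label <- yf
  ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = num_trees, max.depth = max_depth,
    class.weights = cw, seed = seed, num.threads = 1L,
    respect.unordered.factors = "order", verbose = FALSE)
}

predict_ranger <- function(fit, X) {
  p <- predict(fit, data = data.frame(X), num.threads = 1L)$predictions
  unname(p[, "1"])
}

#' @export
print.coev_rf <- function(x, ...) {
  cat(sprintf("<coev_rf> %d trees, max depth %s, CV AUC-PR %.3f (%d train / %d test)\n",
              x$best$num_trees,
              ifelse(x$best$max_depth == 0, "unlimited", x$best$max_depth),
              max(x$mean_cv_auc, na.rm = TRUE),
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Rank pairs with a fitted classifier
#'
#' @param fit A `coev_rf` from [train_rf()].
#' @param features Feature matrix with the training feature layout.
#' @param pair_id Pair identifiers (default rownames).
#' @param method Method tag recorded in the output.
#' @return Data frame (`pair_id`, `method`, `score`, `rank`) sorted by score
#'   descending, ties stable by pair id.
#' @export
predict_interactions <- function(fit, features, pair_id = rownames(features),
                                 method = "rf_integrated") {
  features <- as.matrix(features)
  if (ncol(features) != length(fit$feature_names))
    coev_stop(sprintf("feature length %d does not match training length %d",
                      ncol(features), length(fit$feature_names)))
  colnames(features) <- fit$feature_names
  p <- predict_ranger(fit$model, features)
  ranked_predictions(pair_id %||% as.character(seq_len(nrow(features))),
                     p, method = method)
}

#' Hold-out AUC-PR of a fitted classifier
#'
#' @param fit A `coev_rf`.
#' @param features,labels The full feature matrix and labels the fit was
#'   trained from (its stored test indices are used).
#' @return The [pr_curve()] result on the hold-out set.
#' @export
evaluate_holdout <- function(fit, features, labels) {
  idx <- fit$test_idx
  X <- as.matrix(features)[idx, , drop = FALSE]
  colnames(X) <- fit$feature_names
  p <- predict_ranger(fit$model, X)
  pr_curve(p, as.integer(labels)[idx])
}

#' Presence/absence transform of a feature matrix
#'
#' Replaces every observed DCA score by +1, keeping missing-clade entries at
#' -1, so the only signal left is the pattern of missing data.
#'
#' @param features Clade-blocked feature matrix.
#' @param fill Missing-value code (default -1).
#' @return Transformed matrix.
#' @export
presence_absence <- function(features, fill = -1) {
  out <- ifelse(features == fill, fill, 1)
  dimnames(out) <- dimnames(features)
  out
}
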