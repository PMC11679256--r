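#' Random-forest feature voting
#'
#' Ranks features of a two-group table by impurity (mean decrease in Gini)
#' importance from a seeded forest fit on the full sub-dataset, then selects
#' either every feature with importance at or above the mean importance
#' (default policy) or the top `k`.
#'
#' @param table Two-group feature table (`group` column + feature columns).
#' @param policy `"mean"` or `"topk"`.
#' @param k Number of features for `policy = "topk"`.
#' @param seed Integer seed (forest fitting is stochastic).
#' @param ntree Trees in the voting forest.
#' @return List with `ranking` (data.frame `feature`, `importance`, sorted
#'   decreasing) and `selected` (character vector, ranking order). At least
#'   two features are always selected.
#' @export
rf_feature_vote <- function(table, policy = c("mean", "topk"), k = NULL,
                            seed = 1L, ntree = 500L) {
  policy <- match.arg(policy)
  y <- factor(table$group)
  if (nlevels(y) < 2) stop("single-class input")
  feats <- setdiff(names(table), c("subject_id", "group"))
  if (length(feats) < 2) stop("need >= 2 features")
  x <- as.matrix(table[, feats])
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = ntree, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(imp, decreasing = TRUE)
  ranking <- data.frame(feature = feats[ord], importance = unname(imp[ord]),
                        stringsAsFactors = FALSE)
  selected <- if (policy == "mean") {
    ranking$feature[ranking$importance >= mean(ranking$importance)]
  } else {
    if (is.null(k)) stop("policy 'topk' needs k")
    ranking$feature[seq_len(min(k, nrow(ranking)))]
  }
  if (length(selected) < 2) selected <- ranking$feature[1:2]
  list(ranking = ranking, selected = selected)
}

#' Stratified train/test split
#'
#' Splits by class so the test set holds `round(n_class * test_fraction)` of
#' each class; train and test are disjoint and exhaustive.
#'
#' @param table Table with a `group` column.
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames (and `test_idx`, the row
#'   indices of the test set in `table`).
#' @export
split_train_test <- function(table, test_fraction = 0.3, seed = 1L) {
  y <- table$group
  if (any(table(y) < 2)) stop("class too small to stratify")
  set.seed(seed)
  test_idx <- integer()
  for (cl in unique(y)) {
    rows <- which(y == cl)
    n_test <- round(length(rows) * test_fraction)
    if (n_test < 1 || n_test >= length(rows))
      stop("degenerate split: test_fraction leaves an empty train or test set")
    test_idx <- c(test_idx, sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       test_idx = test_idx)
}

#' Default hyperparameter grids
#'
#' Small exhaustive grids per model family, containing the configurations the
#' workflow is tuned around: logistic regression `C` in 0.1/1.0 (ridge
#' penalty, up to 100 optimizer iterations), random forest with 75 or 100
#' trees at depth 3 (`maxnodes = 8`) and minimum leaf sizes 2-4, and an RBF
#' support vector classifier with `C` in 1/10 and `gamma` in 0.01/0.1.
#'
#' @return Named list of data.frame grids for families `lr`, `rf`, `svc`.
#' @export
default_grids <- function() {
  list(
    lr = data.frame(C = c(0.1, 1.0)),
    rf = expand.grid(ntree = c(75L, 100L), maxnodes = 8L,
                     nodesize = c(2L, 4L)),
    svc = expand.grid(cost = c(1, 10), gamma = c(0.01, 0.1)))
}

# Fit one (family, params) configuration; returns an object whose
# probabilities are exposed by predict_binary_prob(). y levels are kept in
# task order; the second level is the positive class.
fit_family <- function(family, params, x, y) {
  lev <- levels(y)
  model <- switch(family,
    lr = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (params$C * nrow(x)), maxit = 100L,
                        standardize = TRUE),
    rf = randomForest::randomForest(x, y, ntree = params$ntree,
                                    maxnodes = params$maxnodes,
                                    nodesize = params$nodesize),
    svc = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = TRUE),
    stop("unknown model family: ", family))
  structure(list(family = family, params = params, model = model,
                 levels = lev, features = colnames(x)),
            class = "binary_fit")
}

#' Class probabilities from a fitted binary model
#'
#' Returns the n x 2 probability matrix of a `binary_fit` (as produced by
#' [grid_search_fit()]), columns in task level order. This is the interface
#' the ensemble consumes.
#'
#' @param fit A `binary_fit`.
#' @param newx Data containing the fit's feature columns.
#' @return Numeric matrix, one column per class.
#' @export
predict_binary_prob <- function(fit, newx) {
  newx <- as.matrix(newx[, fit$features, drop = FALSE])
  p <- switch(fit$family,
    lr = {
      p2 <- as.vector(stats::predict(fit$model, newx, type = "response"))
      cbind(1 - p2, p2)  # glmnet models P(second level)
    },
    rf = unname(stats::predict(fit$model, newx,
                               type = "prob")[, fit$levels, drop = FALSE]),
    svc = {
      pr <- attr(stats::predict(fit$model, newx, probability = TRUE),
                 "probabilities")
      unname(pr[, fit$levels, drop = FALSE])
    })
  colnames(p) <- fit$levels
  p
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    rows <- sample(which(y == cl))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Grid search with stratified cross-validation
#'
#' Exhaustive search over a family's grid, scored by stratified k-fold CV
#' accuracy on the training data; ties are broken by first-in-grid order. If
#' a fold would contain a single class, `k` is reduced with a warning. The
#' winning configuration is refit on the full training set.
#'
#' @param family `"lr"`, `"rf"` or `"svc"`.
#' @param train Training table (`group` + feature columns).
#' @param features Feature columns to use.
#' @param grid data.frame of configurations (default: the family's
#'   [default_grids()] entry).
#' @param cv_folds Folds (default 5).
#' @param seed Integer seed (folds and stochastic fits).
#' @return A `binary_fit` with extra fields `cv_accuracy` (of the winner) and
#'   `cv_table` (accuracy per grid row).
#' @export
grid_search_fit <- function(family, train, features,
                            grid = default_grids()[[family]],
                            cv_folds = 5L, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("grid must be non-empty")
  y <- factor(train$group, levels = unique(train$group))
  if (nlevels(y) < 2) stop("train has a single class")
  x <- as.matrix(train[, features, drop = FALSE])
  k <- min(cv_folds, min(table(y)))
  if (k < cv_folds)
    warning("reducing cv folds to ", k, " (smallest class size)")
  fold <- stratified_folds(y, k, seed)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      set.seed(seed + 1000L * gi + f)
      fit <- fit_family(family, grid[gi, , drop = FALSE],
                        x[tr, , drop = FALSE], droplevels(y[tr]))
      p <- predict_binary_prob(fit, x[te, , drop = FALSE])
      pred <- fit$levels[max.col(p, ties.method = "first")]
      correct <- correct + sum(pred == as.character(y[te]))
    }
    acc[gi] <- correct / length(y)
  }
  best <- which.max(acc)  # first maximum: first-in-grid tie-break
  set.seed(seed)
  fit <- fit_family(family, grid[best, , drop = FALSE], x, y)
  fit$cv_accuracy <- acc[best]
  fit$cv_table <- cbind(grid, cv_accuracy = acc)
  fit
}

roc_curve <- function(scores, actual, positive) {
  pos <- actual == positive
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # one point per distinct threshold
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(pos)); fpr <- c(0, fp[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate binary predictions
#'
#' Confusion counts, accuracy, support-weighted precision / recall / F1, and
#' (when probability scores are given) the ROC curve with trapezoid AUC for
#' the positive class.
#'
#' @param actual True class labels.
#' @param predicted Predicted class labels.
#' @param scores Optional probability of the positive class.
#' @param positive Positive class (default: second level of `actual`).
#' @return Object of class `model_report`: list with `confusion` (rows =
#'   actual), `accuracy`, `precision`, `recall`, `f1` (weighted), `per_class`
#'   and optionally `roc`, `auc`.
#' @export
evaluate_predictions <- function(actual, predicted, scores = NULL,
                                 positive = NULL) {
  if (length(actual) == 0) stop("empty test set")
  lev <- if (is.factor(actual)) levels(actual) else unique(actual)
  if (is.null(positive)) positive <- lev[length(lev)]
  actual <- factor(actual, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(actual = actual, predicted = predicted)
  support <- rowSums(cm)
  prec <- diag(cm) / colSums(cm); prec[is.nan(prec)] <- 0
  rec <- diag(cm) / support; rec[is.nan(rec)] <- 0
  f1 <- 2 * prec * rec / (prec + rec); f1[is.nan(f1)] <- 0
  w <- support / sum(support)
  rep <- list(confusion = cm,
              accuracy = sum(diag(cm)) / sum(cm),
              precision = sum(w * prec), recall = sum(w * rec),
              f1 = sum(w * f1),
              per_class = data.frame(class = lev, support = as.vector(support),
                                     precision = as.vector(prec),
                                     recall = as.vector(rec),
                                     f1 = as.vector(f1)),
              positive = positive)
  if (!is.null(scores)) {
    roc <- roc_curve(scores, as.character(actual), positive)
    rep$roc <- roc$points; rep$auc <- roc$auc
  } else {
    warning("no probability scores: ROC omitted")
  }
  class(rep) <- "model_report"
  rep
}

#' @exportS3Method print model_report
print.model_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f%s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  print(x$confusion)
  invisible(x)
}

#' Fit the staged three-task classification workflow
#'
#' The workflow's fitting front-end: for each of the three binary tasks
#' (control vs Parkinson's, control vs prodromal, Parkinson's vs prodromal)
#' it subsets the cohort to the two groups, votes features with a random
#' forest, makes a stratified 70/30 train/test split, grid-searches each
#' model family with stratified CV, evaluates every family on the held-out
#' test set, and retains the best family per task (highest test accuracy,
#' ties broken in family order) for the probability-summing ensemble exposed
#' through [predict.pd_stage()].
#'
#' @param features Feature table with all three groups.
#' @param families Model families to fit (subset of `lr`, `rf`, `svc`).
#' @param select Feature-selection policy, `"mean"` or `"topk"`.
#' @param k Top-k size when `select = "topk"`.
#' @param test_fraction Held-out fraction per class (default 0.3).
#' @param cv_folds CV folds in the grid search.
#' @param grids Named list of grids (default [default_grids()]).
#' @param seed Integer seed governing voting, splits and fits.
#' @return Object of class `pd_stage`: per-task selected features, fits,
#'   `model_report`s and best model, plus the class order used by the
#'   ensemble.
#' @export
pd_stage <- function(features,
                     families = c("lr", "rf", "svc"),
                     select = c("mean", "topk"), k = NULL,
                     test_fraction = 0.3, cv_folds = 5L,
                     grids = default_grids(), seed = 1L) {
  select <- match.arg(select)
  class_order <- intersect(c("CONTROL", "PRODROMAL", "PARKINSON"),
                           unique(features$group))
  if (length(class_order) != 3)
    stop("feature table must contain the three cohort groups")
  tasks <- list(c("CONTROL", "PARKINSON"),
                c("CONTROL", "PRODROMAL"),
                c("PARKINSON", "PRODROMAL"))
  names(tasks) <- vapply(tasks, pair_label, "")
  out <- list(tasks = list(), class_order = class_order, seed = seed)
  for (tn in names(tasks)) {
    pair <- tasks[[tn]]
    sub <- features[features$group %in% pair, , drop = FALSE]
    sub$group <- factor(as.character(sub$group), levels = pair)
    vote <- rf_feature_vote(sub, policy = select, k = k, seed = seed)
    spl <- split_train_test(sub, test_fraction = test_fraction, seed = seed)
    fits <- list(); reports <- list()
    for (fam in families) {
      fit <- grid_search_fit(fam, spl$train, vote$selected,
                             grid = grids[[fam]], cv_folds = cv_folds,
                             seed = seed)
      p <- predict_binary_prob(fit, spl$test)
      pred <- fit$levels[max.col(p, ties.method = "first")]
      reports[[fam]] <- evaluate_predictions(
        factor(spl$test$group, levels = pair), pred,
        scores = p[, pair[2]], positive = pair[2])
      fits[[fam]] <- fit
    }
    accs <- vapply(reports, function(r) r$accuracy, numeric(1))
    best <- names(reports)[which.max(accs)]
    out$tasks[[tn]] <- list(
      groups = pair, selected = vote$selected, ranking = vote$ranking,
      split = list(test_idx = spl$test_idx, n_train = nrow(spl$train),
                   n_test = nrow(spl$test)),
      fits = fits, reports = reports, best_family = best,
      best_fit = fits[[best]])
  }
  class(out) <- "pd_stage"
  out
}

#' @exportS3Method print pd_stage
print.pd_stage <- function(x, ...) {
  cat("Staged three-task classification workflow\n")
  for (tn in names(x$tasks)) {
    t <- x$tasks[[tn]]
    r <- t$reports[[t$best_family]]
    cat(sprintf("  %-6s %2d features, best %-3s: accuracy %.2f, AUC %.2f\n",
                tn, length(t$selected), t$best_family, r$accuracy,
                if (is.null(r$auc)) NA else r$auc))
  }
  invisible(x)
}

#' @exportS3Method summary pd_stage
summary.pd_stage <- function(object, ...) {
  rows <- list()
  for (tn in names(object$tasks)) {
    t <- object$tasks[[tn]]
    for (fam in names(t$reports)) {
      r <- t$reports[[fam]]
      rows[[paste(tn, fam)]] <- data.frame(
        task = tn, family = fam, n_features = length(t$selected),
        accuracy = r$accuracy, precision = r$precision, recall = r$recall,
        f1 = r$f1, auc = if (is.null(r$auc)) NA_real_ else r$auc,
        best = fam == t$best_family)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  class(out) <- c("summary.pd_stage", class(out))
  out
}

#' @exportS3Method print summary.pd_stage
print.summary.pd_stage <- function(x, ...) {
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pd_stage <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$tasks)), pty = "s")
  on.exit(graphics::par(op))
  for (tn in names(x$tasks)) {
    t <- x$tasks[[tn]]
    r <- t$reports[[t$best_family]]
    plot(r$roc$fpr, r$roc$tpr, type = "l", xlim = 0:1, ylim = 0:1,
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("%s (%s, AUC %.2f)", tn, t$best_family, r$auc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Probability-summing ensemble prediction
#'
#' Aggregates the three best binary models into a three-way prediction: for
#' each diagnostic class, the probabilities assigned to it by the two binary
#' models in which it participates are summed; the prediction is the argmax.
#' After normalizing the summed scores to 1, the margin between the top two
#' classes sets the confidence tier: high (>= 0.5), moderate (>= 0.25), low
#' (>= 0.1), else extremely low. An exact tie is broken by the fixed class
#' order (CONTROL, PRODROMAL, PARKINSON) and forces the extremely-low tier.
#'
#' @param object A fitted [pd_stage()] model.
#' @param newdata Feature table rows containing every selected feature.
#' @param ... Unused.
#' @return data.frame with per-class aggregated probabilities (raw sums),
#'   `predicted`, `margin` (normalized) and `tier`.
#' @export
predict.pd_stage <- function(object, newdata, ...) {
  prob_list <- list()
  for (tn in names(object$tasks)) {
    t <- object$tasks[[tn]]
    miss <- setdiff(t$best_fit$features, names(newdata))
    if (length(miss))
      stop("newdata lacks selected features: ", paste(miss, collapse = ", "))
    prob_list[[tn]] <- predict_binary_prob(t$best_fit, newdata)
  }
  ensemble_aggregate(prob_list, object$class_order)
}

#' Aggregate binary class probabilities into a three-way prediction
#'
#' The ensemble arithmetic behind [predict.pd_stage()], exposed for use with
#' externally produced probability matrices: per class, sum the
#' probabilities assigned by every binary model whose task involves it
#' (matrix columns name the task's two classes); predict the argmax;
#' normalize the sums to 1 and set the confidence tier from the top-two
#' margin. Raw sums total the number of contributing models per subject.
#'
#' @param prob_list List of n x 2 probability matrices, each with column
#'   names giving the task's class pair; rows must align across matrices.
#' @param classes Class order used for output columns and tie-breaking.
#' @return data.frame: one raw aggregated-probability column per class,
#'   `predicted`, `margin` (on normalized scores) and `tier`.
#' @export
ensemble_aggregate <- function(prob_list, classes) {
  n <- nrow(prob_list[[1]])
  agg <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (p in prob_list) {
    for (cl in intersect(colnames(p), classes)) agg[, cl] <- agg[, cl] + p[, cl]
  }
  norm <- agg / rowSums(agg)
  eps <- 1e-9
  predicted <- character(n); tier <- character(n); margin <- numeric(n)
  for (i in seq_len(n)) {
    v <- norm[i, ]
    top <- which(v >= max(v) - eps)
    predicted[i] <- classes[top[1]]
    srt <- sort(v, decreasing = TRUE)
    margin[i] <- srt[1] - srt[2]
    tier[i] <- if (length(top) > 1) "extremely low"
      else if (margin[i] >= 0.5 - eps) "high"
      else if (margin[i] >= 0.25 - eps) "moderate"
      else if (margin[i] >= 0.1 - eps) "low"
      else "extremely low"
  }
  out <- as.data.frame(agg)
  out$predicted <- predicted
  out$margin <- margin
  out$tier <- tier
  out
}
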