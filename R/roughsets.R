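#' Boundary-midpoint discretization cuts
#'
#' Candidate cuts are midpoints between consecutive distinct attribute values
#' whose adjacent observations are not class-pure for the same class; the
#' returned subset is chosen greedily to maximize the number of
#' class-discernible object pairs separated, until every pair is discerned or
#' the per-attribute budget is exhausted. Deterministic (first-candidate
#' tie-break). Constant attributes yield no cuts. Identical objects with
#' different classes cannot be discerned and are reported.
#'
#' @param x Numeric data.frame/matrix of attributes.
#' @param y Class labels.
#' @param max_cuts_per_attribute Budget per attribute.
#' @return List with `cuts` (data.frame `attr`, `threshold`),
#'   `inconsistent_pairs` (count of undiscernible different-class pairs
#'   given all candidates) and `undiscerned_pairs` (left after selection).
#' @export
discretize_cuts <- function(x, y, max_cuts_per_attribute = 4L) {
  x <- as.data.frame(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  n <- nrow(x)
  # candidate cuts
  cand <- list()
  for (attr in names(x)) {
    v <- x[[attr]]
    u <- sort(unique(v))
    if (length(u) < 2) next  # constant attribute: excluded
    for (j in seq_len(length(u) - 1)) {
      cl1 <- unique(y[v == u[j]]); cl2 <- unique(y[v == u[j + 1]])
      if (length(cl1) > 1 || length(cl2) > 1 || cl1[1] != cl2[1])
        cand[[length(cand) + 1]] <- data.frame(
          attr = attr, threshold = (u[j] + u[j + 1]) / 2)
    }
  }
  pairs <- which(outer(y, y, "!=") & upper.tri(matrix(0, n, n)),
                 arr.ind = TRUE)
  empty <- data.frame(attr = character(), threshold = numeric())
  if (length(cand) == 0 || nrow(pairs) == 0)
    return(list(cuts = empty, inconsistent_pairs = nrow(pairs),
                undiscerned_pairs = nrow(pairs)))
  cand <- do.call(rbind, cand)
  disc <- vapply(seq_len(nrow(cand)), function(ci) {
    m <- x[[cand$attr[ci]]] <= cand$threshold[ci]
    m[pairs[, 1]] != m[pairs[, 2]]
  }, logical(nrow(pairs)))
  disc <- matrix(disc, nrow = nrow(pairs))
  inconsistent <- sum(rowSums(disc) == 0)
  undisc <- rep(TRUE, nrow(pairs))
  used <- rep(FALSE, nrow(cand))
  budget <- stats::setNames(rep(max_cuts_per_attribute,
                                length(unique(cand$attr))),
                            unique(cand$attr))
  sel <- integer()
  repeat {
    avail <- !used & budget[cand$attr] > 0
    if (!any(avail) || !any(undisc)) break
    gains <- colSums(disc[undisc, , drop = FALSE]) * avail
    if (max(gains) == 0) break
    pick <- which.max(gains)
    sel <- c(sel, pick)
    used[pick] <- TRUE
    budget[cand$attr[pick]] <- budget[cand$attr[pick]] - 1L
    undisc <- undisc & !disc[, pick]
  }
  list(cuts = cand[sel, , drop = FALSE],
       inconsistent_pairs = inconsistent,
       undiscerned_pairs = sum(undisc))
}

rule_matches <- function(conds, x) {
  m <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(conds))) {
    v <- x[[conds$attr[i]]]
    m <- m & if (conds$op[i] == "<=") v <= conds$threshold[i]
             else v > conds$threshold[i]
  }
  m
}

format_rule <- function(rule) {
  conds <- paste(sprintf("%s %s %.6g", rule$conditions$attr,
                         ifelse(rule$conditions$op == "<=", "<", ">="),
                         rule$conditions$threshold),
                 collapse = " AND ")
  sprintf("IF %s THEN %s (support=%d, accuracy=%.2f)",
          conds, rule$decision, rule$support, rule$accuracy)
}

induce_rules_internal <- function(x, y, cuts, max_rule_len,
                                  min_support = 3L) {
  conds_all <- rbind(
    data.frame(attr = cuts$attr, op = "<=", threshold = cuts$threshold,
               stringsAsFactors = FALSE),
    data.frame(attr = cuts$attr, op = ">", threshold = cuts$threshold,
               stringsAsFactors = FALSE))
  rules <- list()
  for (cl in levels(y)) {
    uncovered <- which(y == cl)
    while (length(uncovered) > 0) {
      matching <- rep(TRUE, nrow(x))
      conds <- conds_all[0, ]
      repeat {
        pur <- mean(y[matching] == cl)
        if (pur == 1 && nrow(conds) >= 1) break
        if (nrow(conds) >= max_rule_len) break
        best <- NULL; best_score <- c(-1, -1)
        for (ci in seq_len(nrow(conds_all))) {
          m2 <- matching & rule_matches(conds_all[ci, , drop = FALSE], x)
          npos <- length(intersect(which(m2), uncovered))
          if (npos == 0 || sum(m2) == sum(matching)) next
          if (sum(m2) < min_support) next  # guard against overfit rules
          score <- c(mean(y[m2] == cl), npos)
          if (score[1] > best_score[1] ||
              (score[1] == best_score[1] && score[2] > best_score[2])) {
            best <- ci; best_score <- score
          }
        }
        if (is.null(best)) break
        conds <- rbind(conds, conds_all[best, ])
        matching <- matching & rule_matches(conds_all[best, , drop = FALSE], x)
      }
      if (nrow(conds) == 0) break  # no usable condition: stop this class
      covered_pos <- intersect(which(matching), uncovered)
      if (length(covered_pos) == 0) break
      rules[[length(rules) + 1]] <- list(
        conditions = conds, decision = cl,
        support = sum(matching),
        accuracy = mean(y[matching] == cl))
      uncovered <- setdiff(uncovered, covered_pos)
    }
  }
  rules
}

#' Pawlak-style rough-set rule classifier
#'
#' A minimal rough-set pipeline for interpretable validation of the binary
#' classification tasks: boundary-midpoint discretization with greedy
#' discernibility cut selection ([discretize_cuts()]), then sequential
#' covering that grows conjunctions of threshold conditions until each rule
#' is class-pure on the training data (or no condition improves it), records
#' the rule's support and accuracy, removes the covered objects and repeats.
#' Prediction lets all matching rules vote with weight support x accuracy;
#' no matching rule, or a tied vote, abstains.
#'
#' @param formula Model formula, e.g. `group ~ .`.
#' @param data Training data.
#' @param max_cuts_per_attribute Discretization budget per attribute.
#' @param max_rule_len Maximum conditions per rule.
#' @param min_support Smallest training support a grown rule may reach;
#'   conditions that would shrink a rule below it are not considered,
#'   which forbids near-singleton pure rules and raises generalization.
#'   Default: 12% of the training size, floored at 3.
#' @return Object of class `roughset`: `rules`, `cuts`, `classes`,
#'   `n_rules`, discernibility diagnostics, and the training call.
#' @export
roughset <- function(formula, data, max_cuts_per_attribute = 4L,
                     max_rule_len = 4L, min_support = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- factor(mf[[1]])
  x <- mf[, -1, drop = FALSE]
  if (nrow(x) == 0) stop("empty training set")
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  if (is.null(min_support))
    min_support <- max(3L, as.integer(ceiling(0.12 * nrow(x))))
  d <- discretize_cuts(x, y, max_cuts_per_attribute)
  rules <- induce_rules_internal(x, y, d$cuts, max_rule_len, min_support)
  structure(list(rules = rules, cuts = d$cuts, classes = levels(y),
                 n_rules = length(rules),
                 inconsistent_pairs = d$inconsistent_pairs,
                 undiscerned_pairs = d$undiscerned_pairs,
                 attributes = names(x), call = match.call()),
            class = "roughset")
}

#' @exportS3Method print roughset
print.roughset <- function(x, max_rules = 10L, ...) {
  cat("Rough-set rule classifier:", x$n_rules, "rules,",
      nrow(x$cuts), "cuts over", length(x$attributes), "attributes\n")
  for (r in utils::head(x$rules, max_rules)) cat(" ", format_rule(r), "\n")
  if (x$n_rules > max_rules) cat("  ...", x$n_rules - max_rules, "more\n")
  invisible(x)
}

#' Predict with a rough-set rule classifier
#'
#' @param object A [roughset()] model.
#' @param newdata Data containing the model's attributes.
#' @param type `"class"` (factor with `NA` = abstain) or `"votes"` (matrix
#'   of summed support x accuracy weights per class).
#' @param ... Unused.
#' @return Factor of predictions (with abstentions as `NA`) or vote matrix.
#' @export
predict.roughset <- function(object, newdata, type = c("class", "votes"),
                             ...) {
  type <- match.arg(type)
  if (length(object$rules) == 0) stop("ruleset is empty")
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (r in object$rules) {
    m <- rule_matches(r$conditions, newdata)
    votes[m, r$decision] <- votes[m, r$decision] + r$support * r$accuracy
  }
  if (type == "votes") return(votes)
  pred <- apply(votes, 1, function(v) {
    if (all(v == 0)) return(NA_character_)             # no matching rule
    top <- which(v == max(v))
    if (length(top) > 1) return(NA_character_)         # tie: abstain
    object$classes[top]
  })
  factor(pred, levels = object$classes)
}

#' Rough-set evaluation report
#'
#' Coverage (fraction of objects matched by at least one rule, i.e. not
#' abstained on), overall accuracy with abstentions counted as errors,
#' accuracy on the covered subset, and per-class true-positive rates.
#'
#' @param object A [roughset()] model.
#' @param newdata Evaluation data.
#' @param truth True class labels.
#' @return List with `coverage`, `accuracy`, `accuracy_covered`,
#'   `class_tpr`, `n_rules`.
#' @export
roughset_report <- function(object, newdata, truth) {
  pred <- predict(object, newdata)
  truth <- factor(truth, levels = object$classes)
  covered <- !is.na(pred)
  tpr <- vapply(object$classes, function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    mean(!is.na(pred[idx]) & pred[idx] == cl)
  }, numeric(1))
  list(coverage = mean(covered),
       accuracy = mean(!is.na(pred) & pred == truth),
       accuracy_covered = if (any(covered))
         mean(pred[covered] == truth[covered]) else NA_real_,
       class_tpr = tpr,
       n_rules = object$n_rules)
}

#' @exportS3Method summary roughset
summary.roughset <- function(object, ...) {
  cat("Rough-set classifier\n")
  cat("  rules:", object$n_rules, "\n")
  cat("  cuts :", nrow(object$cuts), "\n")
  cat("  inconsistent training pairs:", object$inconsistent_pairs, "\n")
  invisible(object)
}
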