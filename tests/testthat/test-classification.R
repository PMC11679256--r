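two_group_cohort <- function(seed = 1, effects = default_feature_effects(),
                             groups = c("CONTROL", "PARKINSON")) {
  fc <- generate_feature_cohort(cohort_config(feature_effects = effects,
                                              seed = seed))
  sub <- fc$features[fc$features$group %in% groups, ]
  sub$group <- factor(as.character(sub$group), levels = groups)
  sub
}

test_that("stratified split yields 17 + 17 test subjects from 56/56", {
  sub <- two_group_cohort(seed = 2)
  spl <- split_train_test(sub, test_fraction = 0.3, seed = 4)
  expect_equal(nrow(spl$test), 34)
  expect_equal(as.vector(table(spl$test$group)), c(17, 17))
  expect_equal(nrow(spl$train) + nrow(spl$test), 112)
  # partition: disjoint and exhaustive
  expect_length(intersect(spl$train$subject_id, spl$test$subject_id), 0)
  expect_setequal(c(spl$train$subject_id, spl$test$subject_id),
                  sub$subject_id)
  expect_error(split_train_test(sub, test_fraction = 0), "degenerate split")
  # determinism
  spl2 <- split_train_test(sub, seed = 4)
  expect_identical(spl$test_idx, spl2$test_idx)
  spl3 <- split_train_test(sub, seed = 5)
  expect_false(identical(spl$test_idx, spl3$test_idx))
})

test_that("feature voting ranks a strong single effect first almost always", {
  eff <- data.frame(column = "Left-Caudate_cosine", group = "PARKINSON",
                    d = 2.0)
  first <- 0
  for (i in 1:100) {
    sub <- two_group_cohort(seed = 400 + i, effects = eff)
    v <- rf_feature_vote(sub, seed = i, ntree = 300)
    if (v$ranking$feature[1] == "Left-Caudate_cosine") first <- first + 1
  }
  expect_gte(first, 95)
})

test_that("feature voting policies behave at the boundaries", {
  sub <- two_group_cohort(seed = 3)
  v <- rf_feature_vote(sub, policy = "topk", k = 1000, seed = 1)
  expect_identical(v$selected, v$ranking$feature)  # k >= n: all, ranked order
  v2 <- rf_feature_vote(sub, policy = "mean", seed = 1)
  expect_true(all(v2$selected %in% v2$ranking$feature))
  expect_gte(length(v2$selected), 2)
  onecls <- sub[sub$group == "CONTROL", ]
  expect_error(rf_feature_vote(onecls, seed = 1), "single-class")
  # deterministic under fixed seed
  expect_identical(rf_feature_vote(sub, seed = 9)$ranking,
                   rf_feature_vote(sub, seed = 9)$ranking)
})

test_that("grid search honors single-point grids and solves separable data", {
  set.seed(8)
  n <- 40
  sep <- data.frame(
    group = rep(c("A", "B"), each = n / 2),
    f1 = c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3)),
    f2 = rnorm(n))
  fit <- grid_search_fit("rf", sep, c("f1", "f2"),
                         grid = data.frame(ntree = 75L, maxnodes = 8L,
                                           nodesize = 2L), seed = 2)
  expect_equal(fit$params$ntree, 75L)
  for (fam in c("lr", "rf", "svc")) {
    f <- grid_search_fit(fam, sep, c("f1", "f2"), seed = 3)
    expect_equal(f$cv_accuracy, 1.0)
  }
  expect_error(grid_search_fit("lr", sep, c("f1", "f2"),
                               grid = data.frame()), "non-empty")
})

test_that("default grids contain the workflow's canonical configurations", {
  g <- default_grids()
  expect_true(all(c(0.1, 1.0) %in% g$lr$C))
  expect_true(any(g$rf$ntree == 75 & g$rf$maxnodes == 8 & g$rf$nodesize == 4))
  expect_true(any(g$rf$nodesize == 2))
  expect_true(any(g$svc$cost == 10 & g$svc$gamma == 0.01))
})

test_that("evaluation metrics agree with an independent formula oracle", {
  # perfect predictor
  act <- factor(rep(c("HC", "PD"), each = 5), levels = c("HC", "PD"))
  perfect <- evaluate_predictions(act, act, scores = c(rep(0, 5), rep(1, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_true(all(diag(perfect$confusion) == 5))

  # arbitrary confusion counts vs hand-computed weighted metrics
  cm <- matrix(c(14, 3, 2, 15), 2, byrow = TRUE)
  v <- confusion_to_vectors(cm, c("HC", "PD"))
  r <- suppressWarnings(evaluate_predictions(v$actual, v$predicted))
  prec <- c(14 / 16, 15 / 18); rec <- c(14 / 17, 15 / 17)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(r$accuracy, 29 / 34, tolerance = 1e-12)
  expect_equal(r$precision, mean(prec), tolerance = 1e-12)
  expect_equal(r$recall, mean(rec), tolerance = 1e-12)
  expect_equal(r$f1, mean(f1), tolerance = 1e-12)
  expect_warning(evaluate_predictions(v$actual, v$predicted), "ROC omitted")
})

test_that("ROC/AUC: random scores give ~0.5, monotone transforms change nothing", {
  set.seed(15)
  act <- factor(rep(c("A", "B"), each = 50))
  scores <- runif(100)
  r <- evaluate_predictions(act, factor(rep("A", 100), levels = c("A", "B")),
                            scores = scores)
  expect_equal(r$accuracy, 0.5)
  expect_lt(abs(r$auc - 0.5), 0.15)
  # AUC is invariant to monotone transformation of the scores
  r2 <- evaluate_predictions(act, factor(rep("A", 100), levels = c("A", "B")),
                             scores = exp(3 * scores))
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  # cross-check the trapezoid AUC against pROC
  skip_if_not_installed("pROC")
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(act, scores, levels = c("A", "B"),
                        direction = "<"))))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("the staged workflow runs all tasks and is seed-reproducible", {
  fc <- generate_feature_cohort(
    cohort_config(feature_effects = default_feature_effects(), seed = 42))
  m <- pd_stage(fc$features, seed = 5)
  expect_s3_class(m, "pd_stage")
  expect_named(m$tasks, c("HCvPD", "HCvPR", "PDvPR"))
  for (tn in names(m$tasks)) {
    t <- m$tasks[[tn]]
    expect_named(t$reports, c("lr", "rf", "svc"))
    expect_true(t$best_family %in% c("lr", "rf", "svc"))
    expect_equal(t$split$n_test, 34)
    for (r in t$reports) {
      expect_true(all(c(r$accuracy, r$precision, r$recall, r$f1) >= 0 &
                        c(r$accuracy, r$precision, r$recall, r$f1) <= 1))
      expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
    }
  }
  m2 <- pd_stage(fc$features, seed = 5)
  expect_equal(summary(m), summary(m2))
  s <- summary(m)
  expect_equal(nrow(s), 9)
  expect_output(print(m), "Staged three-task")
})

test_that("ensemble aggregation sums probabilities and tiers the margin", {
  classes <- c("CONTROL", "PRODROMAL", "PARKINSON")
  mk <- function(p, pair) {
    m <- cbind(p, 1 - p); colnames(m) <- pair; m
  }
  # both PD-involved models certain, third uninformative -> PD at high tier
  probs <- list(
    mk(0, c("CONTROL", "PARKINSON")),    # P(PD) = 1
    mk(0.5, c("CONTROL", "PRODROMAL")),
    mk(0, c("PRODROMAL", "PARKINSON")))  # P(PD) = 1
  out <- ensemble_aggregate(probs, classes)
  expect_equal(out$predicted, "PARKINSON")
  expect_equal(out$tier, "high")
  expect_equal(out$PARKINSON, 2)
  # conservation: raw sums total the number of contributing models
  expect_equal(out$CONTROL + out$PRODROMAL + out$PARKINSON, 3)

  # all models uniform -> exact three-way tie -> first class, extremely low
  probs0 <- list(mk(0.5, c("CONTROL", "PARKINSON")),
                 mk(0.5, c("CONTROL", "PRODROMAL")),
                 mk(0.5, c("PRODROMAL", "PARKINSON")))
  out0 <- ensemble_aggregate(probs0, classes)
  expect_equal(out0$predicted, "CONTROL")
  expect_equal(out0$tier, "extremely low")
  expect_equal(out0$margin, 0)

  # moderate and low margins
  probs1 <- list(mk(0.25, c("CONTROL", "PARKINSON")),
                 mk(0.60, c("CONTROL", "PRODROMAL")),
                 mk(0.45, c("PRODROMAL", "PARKINSON")))
  out1 <- ensemble_aggregate(probs1, classes)
  agg <- c(0.25 + 0.60, 0.40 + 0.45, 0.75 + 0.55)
  expect_equal(unlist(out1[1, classes]), setNames(agg, classes))
  expect_equal(out1$predicted, "PARKINSON")
})

test_that("ensemble predictions on held-out subjects beat three-way chance", {
  fc <- generate_feature_cohort(
    cohort_config(feature_effects = default_feature_effects(), seed = 19))
  # hold out 17 subjects per group before fitting
  set.seed(7)
  hold <- unlist(lapply(split(seq_len(168), fc$features$group),
                        sample, size = 17))
  m <- pd_stage(fc$features[-hold, ], seed = 3)
  pr <- predict(m, fc$features[hold, ])
  acc <- mean(pr$predicted == fc$features$group[hold])
  # binomial test against chance 1/3 at n = 51
  expect_lt(binom.test(sum(pr$predicted == fc$features$group[hold]),
                       length(hold), p = 1 / 3,
                       alternative = "greater")$p.value, 0.01)
  expect_true(all(pr$tier %in% c("high", "moderate", "low", "extremely low")))
  expect_error(predict(m, fc$features[hold, 1:4]), "lacks selected features")
})
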