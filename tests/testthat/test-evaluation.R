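# Metrics, threshold selection and patient-grouped folding.

test_that("roc_auc matches hand-derived values and tie convention", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0), c(0.4, 0.6)), 0)        # single discordant pair
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all tied
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "class")
})

test_that("average_precision matches the hand-enumerated example", {
  # labels (1,0,1) by descending score: precisions at recall 0.5 and 1.0 are
  # 1 and 2/3, so AP = 0.5*1 + 0.5*(2/3) = 5/6
  expect_equal(average_precision(c(1, 0, 1), c(0.9, 0.8, 0.7)), 5 / 6)
  expect_equal(average_precision(c(1, 1, 0), c(0.9, 0.8, 0.7)), 1)
  expect_error(average_precision(c(0, 0), c(0.1, 0.2)), "positive")
  # reversed separable scores: equals the brute-force minimum
  lab <- c(1, 1, 0, 0, 0)
  sc <- c(0.1, 0.2, 0.8, 0.9, 0.7)
  expect_equal(average_precision(lab, sc), brute_average_precision(lab, sc))
})

test_that("roc_auc and average_precision match exhaustive enumeration on random sets", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # ensure both classes
    scores <- round(runif(n), sample(1:3, 1)) # induce frequent ties
    expect_equal(roc_auc(labels, scores), brute_roc_auc(labels, scores))
    expect_equal(average_precision(labels, scores),
                 brute_average_precision(labels, scores))
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(5)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(8, 1, 0.4))
    scores <- runif(10)
    a <- roc_auc(labels, scores)
    expect_equal(roc_auc(labels, plogis(3 * scores - 1)), a)
    expect_equal(roc_auc(labels, scores^3), a)
  }
})

test_that("f1_optimal_threshold maximises F1 and breaks ties toward 0.5", {
  # labels (1,0,1), scores (0.9, 0.8, 0.7): predicting everything positive
  # gives the best F1 = 0.8, so any threshold <= 0.7 wins; nearest to 0.5 wins
  lab <- c(1, 0, 1); sc <- c(0.9, 0.8, 0.7)
  thr <- f1_optimal_threshold(lab, sc)
  expect_lte(thr, 0.7)
  f1_at <- function(t) {
    pred <- sc >= t
    2 * sum(pred & lab == 1) / (sum(pred) + 2)
  }
  expect_equal(f1_at(thr), brute_best_f1(lab, sc))
  expect_equal(f1_at(thr), 0.8)

  # scores equal to labels: perfect F1 at any interior threshold; returns 0.5
  expect_equal(f1_optimal_threshold(c(0, 1, 0, 1), c(0, 1, 0, 1)), 0.5)

  # duplicating a sample does not change the achieved optimum
  set.seed(9)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(6, 1, 0.5))
    scores <- round(runif(8), 2)
    t1 <- f1_optimal_threshold(labels, scores)
    t2 <- f1_optimal_threshold(c(labels, labels[3]), c(scores, scores[3]))
    f1 <- function(l, s, t) {
      pred <- s >= t
      tp <- sum(pred & l == 1)
      if (tp == 0) 0 else 2 * tp / (sum(pred) + sum(l == 1))
    }
    expect_equal(f1(labels, scores, t1), brute_best_f1(labels, scores))
    expect_equal(f1(c(labels, labels[3]), c(scores, scores[3]), t2),
                 brute_best_f1(c(labels, labels[3]), c(scores, scores[3])))
  }
})

test_that("confusion matrix arithmetic is consistent with accuracy", {
  lab <- c(0, 0, 0, 0, 1, 1, 1, 1)
  sc <- c(0.1, 0.2, 0.3, 0.6, 0.4, 0.7, 0.8, 0.9)
  ca <- confusion_and_accuracy(lab, sc, 0.5)
  expect_equal(ca$confusion["negative", "positive"], 1)
  expect_equal(ca$confusion["positive", "negative"], 1)
  expect_equal(ca$accuracy, 75)
  expect_equal(sum(ca$confusion), 8)
  expect_equal(confusion_and_accuracy(lab, lab, 0.5)$accuracy, 100)
  r <- eval_report(lab, sc)
  expect_equal(100 * sum(diag(r$confusion)) / sum(r$confusion), r$accuracy,
               tolerance = 1e-4)
})

test_that("patient folds are disjoint, covering and near-equal for all k", {
  ids <- sprintf("P%02d", 1:23)
  for (k in c(2, 5, 10, 23)) {
    plan <- make_patient_folds(ids, k = k, seed = 3)
    tests <- unlist(lapply(plan$folds, `[[`, "test"))
    expect_equal(sort(tests), sort(ids))           # coverage, no duplicates
    for (f in plan$folds) {
      expect_length(intersect(f$train, f$test), 0) # disjoint
      expect_equal(sort(c(f$train, f$test)), sort(ids))
      expect_lte(abs(length(f$test) - length(ids) / k), 1)
    }
  }
  expect_equal(make_patient_folds(ids[1:10], k = 10)$k, 10)
  plan <- make_patient_folds(ids, loocv = TRUE)
  expect_equal(plan$k, 23)
  expect_true(all(vapply(plan$folds, function(f) length(f$test), 0) == 1))
  expect_error(make_patient_folds(ids[1:5], k = 9), "exceeds")
})
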