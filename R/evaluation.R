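# Patient-grouped cross-validation, threshold selection, and the reported
# metrics: ROC AUC, average precision, F1-optimal-threshold accuracy and the
# 2x2 confusion matrix.

#' Patient-grouped cross-validation folds
#'
#' Every sample of a patient is assigned to the same fold, so a model never
#' sees another site of a test patient's forearms (nor their attributes)
#' during training.  Patients are shuffled by `seed` and split into `k`
#' near-equal groups; leave-one-out uses one patient per fold.
#'
#' @param patient_ids Character vector (duplicates allowed; unique ids are
#'   folded).
#' @param k Number of folds (>= 2), at most the number of patients.
#' @param seed Shuffle seed.
#' @param loocv If `TRUE`, `k` is set to the number of patients.
#' @return An object of class `"fold_plan"`: a list of folds, each with
#'   `train` and `test` patient-id vectors.
#' @export
make_patient_folds <- function(patient_ids, k = 10, seed = 1, loocv = FALSE) {
  ids <- unique(as.character(patient_ids))
  if (loocv) k <- length(ids)
  if (!is_count(k) || k < 2) stop_thermoprick("k must be >= 2")
  if (k > length(ids))
    stop_thermoprick("k = ", k, " exceeds the ", length(ids), " available patients")
  shuffled <- with_seed(seed, sample(ids))
  grp <- sort(rep_len(seq_len(k), length(ids)))
  folds <- lapply(seq_len(k), function(i)
    list(train = shuffled[grp != i], test = shuffled[grp == i]))
  structure(list(folds = folds, k = k, seed = seed, loocv = loocv),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d folds over %d patients%s>\n", x$k,
              length(unlist(lapply(x$folds, `[[`, "test"))),
              if (x$loocv) " (LOOCV)" else ""))
  invisible(x)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop_thermoprick("both classes must be present")
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_two_classes(labels)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (area-like summary of the precision-recall curve)
#'
#' Step-wise, non-interpolated: `sum over thresholds of
#' (recall_i - recall_{i-1}) * precision_i` with thresholds descending over
#' the unique scores (tied scores enter together).
#'
#' @inheritParams roc_auc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (sum(labels == 1) == 0) stop_thermoprick("average precision needs >= 1 positive")
  np <- sum(labels == 1)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)  # last index of each tie group
  tp <- cumsum(lab == 1)[keep]
  n_at <- seq_along(lab)[keep]
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Threshold maximising the F1 score
#'
#' Scans all midpoints between consecutive sorted unique scores plus the
#' endpoints 0 and 1 (prediction rule: `score >= threshold`); among
#' F1-maximising candidates the one closest to 0.5 is returned — in practice
#' the selected threshold is close to 0.5.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
f1_optimal_threshold <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- unique(c(0, (u[-length(u)] + u[-1]) / 2, u, 1))
  f1 <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    if (tp == 0) return(0)
    2 * tp / (sum(pred) + sum(labels == 1))
  }, 0)
  best <- which(f1 >= max(f1) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

#' Confusion matrix and accuracy at a threshold
#'
#' Predictions are `score >= threshold` (ties predicted positive).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold in `[0, 1]`.
#' @return A list with `confusion` (2 x 2 matrix, rows = true, cols =
#'   predicted), `accuracy` (percent) and `threshold`.
#' @export
confusion_and_accuracy <- function(labels, scores, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  cm <- matrix(c(sum(labels == 0 & pred == 0), sum(labels == 0 & pred == 1),
                 sum(labels == 1 & pred == 0), sum(labels == 1 & pred == 1)),
               2, 2, byrow = TRUE,
               dimnames = list(true = c("negative", "positive"),
                               predicted = c("negative", "positive")))
  list(confusion = cm, accuracy = 100 * sum(diag(cm)) / length(labels),
       threshold = threshold)
}

#' Full evaluation report for one score set
#'
#' ROC AUC, average precision, the F1-optimal threshold and the accuracy and
#' confusion matrix at that threshold.
#'
#' @inheritParams roc_auc
#' @return An object of class `"eval_report"`.
#' @export
eval_report <- function(labels, scores) {
  thr <- f1_optimal_threshold(labels, scores)
  ca <- confusion_and_accuracy(labels, scores, thr)
  structure(list(roc_auc = roc_auc(labels, scores),
                 average_precision = average_precision(labels, scores),
                 threshold = thr, accuracy = ca$accuracy,
                 confusion = ca$confusion, n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n %d, AUC %.3f, AP %.3f, acc %.2f%% @ thr %.3f>\n",
              x$n, x$roc_auc, x$average_precision, x$accuracy, x$threshold))
  print(x$confusion)
  invisible(x)
}

#' Patient-grouped cross-validation of the classifier
#'
#' For each fold, normalisation statistics are fitted and the classifier
#' trained on the training patients only, then the held-out patients'
#' samples are scored.  All held-out scores are pooled and a single
#' [eval_report()] computed on them (the F1 threshold is selected on the
#' pooled cross-validated scores, matching a single reported accuracy per
#' configuration).
#'
#' @param samples List of `"prick_sample"`s for the whole cohort.
#' @param config A [classifier_config()].
#' @param k Folds (ignored when `loocv`).
#' @param loocv Leave-one-patient-out.
#' @param seed Fold-shuffle seed; fold models derive their seeds from it.
#' @return A list with `report` (pooled [eval_report()]), `fold_reports`,
#'   `scores` (data frame: `patient_id`, `site_id`, `label`, `score`,
#'   `fold`) and `plan`.
#' @export
run_cross_validation <- function(samples, config = classifier_config(), k = 10,
                                 loocv = FALSE, seed = 1) {
  pid <- vapply(samples, `[[`, "", "patient_id")
  labs <- vapply(samples, `[[`, 0L, "label")
  plan <- make_patient_folds(pid, k = k, seed = seed, loocv = loocv)
  rows <- list()
  fold_reports <- vector("list", plan$k)
  for (i in seq_len(plan$k)) {
    fold <- plan$folds[[i]]
    tr <- samples[pid %in% fold$train]
    te <- samples[pid %in% fold$test]
    if (!length(te)) next
    cfg <- config
    cfg$seed <- derive_seed(seed, config$seed, i)
    model <- train_classifier(tr, cfg)
    sc <- predict_proba(model, te)
    rows[[i]] <- data.frame(patient_id = vapply(te, `[[`, "", "patient_id"),
                            site_id = vapply(te, `[[`, "", "site_id"),
                            label = vapply(te, `[[`, 0L, "label"),
                            score = sc, fold = i)
    fold_reports[[i]] <- tryCatch(eval_report(rows[[i]]$label, sc),
                                  error = function(e) NULL)  # single-class folds
  }
  scores <- do.call(rbind, rows)
  list(report = eval_report(scores$label, scores$score),
       fold_reports = fold_reports, scores = scores, plan = plan)
}

#' Input-spectra ablation grid
#'
#' Cross-validates the same cohort under each input mode (both spectra,
#' delta-thermal only, visible only) with identical folds, reproducing the
#' layout of a validation-results table: one row per input-spectra
#' configuration.
#'
#' @inheritParams run_cross_validation
#' @param modes Input modes to evaluate.
#' @return A list with `table` (data frame: mode, roc_auc,
#'   average_precision, accuracy) and `runs` (named list of
#'   [run_cross_validation()] results).
#' @export
run_input_ablation <- function(samples, config = classifier_config(), k = 10,
                               loocv = FALSE, seed = 1,
                               modes = c("both", "thermal_only", "visible_only")) {
  runs <- list()
  for (m in modes) {
    cfg <- config
    cfg$input_mode <- m
    runs[[m]] <- run_cross_validation(samples, cfg, k = k, loocv = loocv, seed = seed)
  }
  tab <- do.call(rbind, lapply(names(runs), function(m) {
    r <- runs[[m]]$report
    data.frame(mode = m, roc_auc = r$roc_auc, average_precision = r$average_precision,
               accuracy = r$accuracy)
  }))
  list(table = tab, runs = runs)
}
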