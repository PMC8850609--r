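# Independent brute-force oracles and small fixture builders shared across
# the suite.  The oracles deliberately use naive per-threshold loops so they
# share no code path with the package implementations they check.

# ROC AUC by trapezoidal integration over exhaustively enumerated thresholds
brute_roc_auc <- function(labels, scores) {
  ts <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(ts))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  for (i in seq_along(ts)) {
    pred <- scores >= ts[i]
    tpr[i] <- sum(pred & labels == 1) / np
    fpr[i] <- sum(pred & labels == 0) / nn
  }
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# step-wise AP by exhaustive threshold enumeration
brute_average_precision <- function(labels, scores) {
  ts <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (t in ts) {
    pred <- scores >= t
    prec <- sum(pred & labels == 1) / sum(pred)
    rec <- sum(pred & labels == 1) / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# best F1 over exhaustive thresholds (value, not the threshold)
brute_best_f1 <- function(labels, scores) {
  cand <- c(0, sort(unique(scores)), 1)
  best <- 0
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    f1 <- if (tp == 0) 0 else 2 * tp / (sum(pred) + sum(labels == 1))
    best <- max(best, f1)
  }
  best
}

# a tiny scene configuration that renders fast (quarter-ish scale)
tiny_scene <- function(...) scene_config(image_size = c(193, 256), ...)

# an ideal 2 x 4 grid of segments with given spacing and jitter
make_grid_segments <- function(rows = c(120, 260), cols = c(85, 195, 305, 415),
                               jitter = 0, bbox_side = 42) {
  segs <- list()
  for (ln in seq_along(rows)) for (p in seq_along(cols)) {
    ctr <- c(rows[ln], cols[p]) + runif(2, -1, 1) * jitter
    segs[[length(segs) + 1]] <-
      prick_segment(ctr, c(ctr[1] - bbox_side / 2, ctr[2] - bbox_side / 2,
                           bbox_side, bbox_side))
  }
  segs
}

centers_of <- function(segments) t(vapply(segments, `[[`, numeric(2), "center"))

# disc-uniform point noise with |displacement| <= rmax
disc_noise <- function(n, rmax) {
  r <- rmax * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(r * sin(a), r * cos(a))
}

# assemble classification samples for a rendered cohort using ground-truth
# (manual) segmentation and estimated alignment
cohort_samples_manual <- function(cohort, roi_size = 48, method = "homography") {
  out <- list()
  for (cs in cohort$cases) {
    sp <- segments_from_annotations(cs$annotations)
    sq <- segments_from_annotations(cs$annotations_post)
    ad <- align_and_delta(cs$pre$thermal, cs$post$thermal, sp, sq, method = method)
    out <- c(out, make_samples(cs$post$visible, ad$delta, sq, cs$patient,
                               cs$site_meta, roi_size = roi_size))
  }
  out
}
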