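# Independent oracles and generators used across the suite. The oracles are
# deliberately naive (explicit loops, no shared code with the implementation).

# One-vs-rest metrics by explicit per-sample counting.
oracle_metrics <- function(true_idx, pred_idx, M) {
  per <- data.frame(tp = integer(M), fp = integer(M), fn = integer(M),
                    precision = numeric(M), recall = numeric(M),
                    f1 = numeric(M))
  for (c in seq_len(M)) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(true_idx)) {
      if (pred_idx[i] == c && true_idx[i] == c) tp <- tp + 1L
      if (pred_idx[i] == c && true_idx[i] != c) fp <- fp + 1L
      if (pred_idx[i] != c && true_idx[i] == c) fn <- fn + 1L
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    per[c, ] <- list(tp, fp, fn, p, r,
                     if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  per
}

# Corner-coordinate IoU, written independently of box_iou().
oracle_iou <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ax2 <- a[1] + a[3] / 2
  ay1 <- a[2] - a[4] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; bx2 <- b[1] + b[3] / 2
  by1 <- b[2] - b[4] / 2; by2 <- b[2] + b[4] / 2
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Reference NMS: repeatedly pick the highest-confidence unsuppressed box
# (earliest row on ties), keep it, suppress its overlaps.
oracle_nms <- function(det, iou_thr, score_thr, class_aware) {
  det <- det[det$confidence >= score_thr, , drop = FALSE]
  state <- rep("open", nrow(det))
  cls <- sapply(det$scores, which.max)
  while (any(state == "open")) {
    open <- which(state == "open")
    best <- open[which.max(det$confidence[open])]
    # which.max returns the first maximum, i.e. lowest row index on ties
    state[best] <- "kept"
    for (j in which(state == "open")) {
      if (class_aware && cls[j] != cls[best]) next
      if (oracle_iou(as.numeric(det[best, c("cx", "cy", "w", "h")]),
                     as.numeric(det[j, c("cx", "cy", "w", "h")])) > iou_thr) {
        state[j] <- "suppressed"
      }
    }
  }
  kept <- det[state == "kept", , drop = FALSE]
  kept[order(-kept$confidence), , drop = FALSE]
}

# Hand evaluation of the two-view weight/fusion rule on explicit columns.
oracle_sdf <- function(P1, P2, A1, A2) {
  m1 <- which.max(P1); m2 <- which.max(P2)
  M <- length(P1)
  a1 <- A1[, m1]; a2sel <- A2[, m2]
  den1 <- A1[, m1] + A2[, m1]
  den2 <- A1[, m2] + A2[, m2]
  alpha1 <- numeric(M); alpha2 <- numeric(M)
  for (j in seq_len(M)) {
    alpha1[j] <- if (den1[j] > 0) a1[j] / den1[j] else 0
    alpha2[j] <- if (den2[j] > 0) a2sel[j] / den2[j] else 0
  }
  fused <- alpha1 * P1 + alpha2 * P2
  list(alpha1 = alpha1, alpha2 = alpha2, fused = fused,
       stage = which.max(fused))
}

random_scores <- function(M) {
  v <- stats::runif(M)
  if (all(v == 0)) v[1] <- 1
  v
}

# Random column-normalized confusion matrix; diag_boost > 0 makes every
# column attain its maximum on the diagonal.
random_confusion <- function(M, diag_boost = 0) {
  m <- matrix(stats::runif(M * M), M, M) + diag(M) * diag_boost
  m <- sweep(m, 2, colSums(m), "/")
  confusion_matrix(m, class_names = ripeness_stages(M))
}

# Per-view argmax stage calls from a long simulated sample table
# (rows ordered sample-major with stages cycling in class-name order).
argmax_calls <- function(samples, v, class_names = ripeness_stages()) {
  s <- samples[samples$view == v, ]
  M <- length(class_names)
  stopifnot(nrow(s) %% M == 0, all(s$stage[1:M] == class_names))
  sc <- matrix(s$score, ncol = M, byrow = TRUE)
  list(sample_id = s$sample_id[seq(1, nrow(s), M)],
       true_stage = s$true_stage[seq(1, nrow(s), M)],
       pred = class_names[max.col(sc, ties.method = "first")])
}
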