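#' Detector output tensor size
#'
#' A one-stage grid detector over an S x S cell grid with B boxes per cell and
#' M classes emits, per box, 4 coordinates + 1 objectness confidence + M class
#' scores, so the full output tensor holds `S * S * B * (5 + M)` numbers.
#'
#' @param S Grid side length (cells), `>= 1`.
#' @param B Boxes per cell, `>= 1`.
#' @param M Class count, `>= 0`.
#' @return Integer tensor size.
#' @examples
#' output_tensor_size(13, 3, 5)
#' @export
output_tensor_size <- function(S, B, M) {
  if (S < 1 || B < 1 || M < 0 ||
      S != round(S) || B != round(B) || M != round(M)) {
    abort_sdfuse("S >= 1, B >= 1, M >= 0 integers required.",
                 "sdfuse_validation_error")
  }
  as.integer(S * S * B * (5 + M))
}

#' Intersection over union of two boxes
#'
#' Boxes are center-format `c(cx, cy, w, h)`; IoU is computed on the derived
#' corner coordinates. Symmetric, bounded in \[0, 1\], and 0 for disjoint
#' boxes.
#'
#' @param a,b Numeric length-4 vectors `c(cx, cy, w, h)`.
#' @return IoU in \[0, 1\].
#' @examples
#' box_iou(c(1, 1, 2, 2), c(2, 1, 2, 2)) # 1/3
#' @export
box_iou <- function(a, b) {
  validate_box(a, "a"); validate_box(b, "b")
  ix <- max(0, min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
                 max(a[1] - a[3] / 2, b[1] - b[3] / 2))
  iy <- max(0, min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
                 max(a[2] - a[4] / 2, b[2] - b[4] / 2))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  inter / union
}

#' Greedy non-maximum suppression
#'
#' Detections below `score_threshold` are dropped; the remainder are processed
#' in descending confidence order, and each kept detection suppresses later
#' ones whose IoU with it exceeds `iou_threshold` (within the same argmax
#' class when `class_aware`). Ties in confidence are broken by input order
#' (earlier row wins), making the result deterministic.
#'
#' @param detections Detection tibble: columns `cx`, `cy`, `w`, `h`,
#'   `confidence`, list-column `scores`; other columns pass through.
#' @param iou_threshold Suppression IoU threshold in \[0, 1\].
#' @param score_threshold Minimum confidence in \[0, 1\].
#' @param class_aware Suppress only within the same argmax class.
#' @return The surviving rows, sorted by descending confidence.
#' @export
nms <- function(detections, iou_threshold = 0.45, score_threshold = 0.25,
                class_aware = TRUE) {
  if (iou_threshold < 0 || iou_threshold > 1 ||
      score_threshold < 0 || score_threshold > 1) {
    abort_sdfuse("Thresholds must lie in [0, 1].", "sdfuse_validation_error")
  }
  if (!nrow(detections)) return(detections)
  lens <- lengths(detections$scores)
  if (length(unique(lens)) != 1L) {
    abort_sdfuse("All detections must share one score-vector length M.",
                 "sdfuse_validation_error")
  }
  det <- detections[detections$confidence >= score_threshold, , drop = FALSE]
  if (!nrow(det)) return(det)
  # stable order: descending confidence, input order breaking ties
  ord <- order(-det$confidence, seq_len(nrow(det)))
  det <- det[ord, , drop = FALSE]
  cls <- vapply(det$scores, which.max, integer(1))
  boxes <- as.matrix(det[, c("cx", "cy", "w", "h")])
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(det)) break
    for (j in seq(i + 1L, nrow(det))) {
      if (!alive[j]) next
      if (class_aware && cls[j] != cls[i]) next
      if (box_iou(boxes[i, ], boxes[j, ]) > iou_threshold) alive[j] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' Detection loss weights
#'
#' @param lambda_bbox Weight on the localization loss; default 5.
#' @param lambda_nobj Weight on the no-object confidence term; default 0.1.
#' @return Named list of the two weights.
#' @export
loss_weights <- function(lambda_bbox = 5, lambda_nobj = 0.1) {
  list(lambda_bbox = lambda_bbox, lambda_nobj = lambda_nobj)
}

#' @noRd
check_mask <- function(mask, dims) {
  if (!is.matrix(mask$obj) || !identical(dim(mask$obj), dims)) {
    abort_sdfuse("Assignment mask shape does not match the grid.",
                 "sdfuse_validation_error")
  }
  if (!all(mask$obj %in% c(0, 1))) {
    abort_sdfuse("Assignment mask must be binary.", "sdfuse_validation_error")
  }
}

#' Assignment mask for grid losses
#'
#' @param obj Binary S^2 x B matrix: 1 where a ground-truth object is assigned
#'   to that cell/box slot. The no-object mask is its complement.
#' @return List with `obj` and `nobj` matrices.
#' @export
assignment_mask <- function(obj) {
  obj <- as.matrix(obj)
  if (!all(obj %in% c(0, 1))) {
    abort_sdfuse("`obj` must be binary.", "sdfuse_validation_error")
  }
  list(obj = obj, nobj = 1 - obj)
}

#' Localization loss on toy tensors
#'
#' Sum over assigned cell/box slots of the distance between the predicted and
#' ground-truth box 4-vectors, scaled by `lambda_bbox`. The distance is the
#' plain Euclidean norm of the difference; `squared = TRUE` switches to the
#' squared-error variant for comparison.
#'
#' @param pred_boxes,truth_boxes Arrays of dimension `c(S^2, B, 4)`.
#' @param mask [assignment_mask()] of dimension `S^2 x B`.
#' @param weights [loss_weights()].
#' @param squared Use squared Euclidean distance instead.
#' @return Non-negative scalar loss.
#' @export
bbox_loss <- function(pred_boxes, truth_boxes, mask,
                      weights = loss_weights(), squared = FALSE) {
  if (!identical(dim(pred_boxes), dim(truth_boxes)) ||
      length(dim(pred_boxes)) != 3L || dim(pred_boxes)[3] != 4L) {
    abort_sdfuse("Box tensors must be c(S^2, B, 4) arrays of equal shape.",
                 "sdfuse_validation_error")
  }
  check_mask(mask, dim(pred_boxes)[1:2])
  diff2 <- apply((pred_boxes - truth_boxes)^2, c(1, 2), sum)
  d <- if (squared) diff2 else sqrt(diff2)
  weights$lambda_bbox * sum(mask$obj * d)
}

#' Objectness confidence loss on toy tensors
#'
#' Absolute confidence error summed over assigned slots, plus `lambda_nobj`
#' times the same sum over unassigned slots.
#'
#' @param pred_conf,truth_conf `S^2 x B` matrices; truth entries in `{0, 1}`.
#' @inheritParams bbox_loss
#' @return Non-negative scalar loss.
#' @export
conf_loss <- function(pred_conf, truth_conf, mask,
                      weights = loss_weights(), squared = FALSE) {
  pred_conf <- as.matrix(pred_conf); truth_conf <- as.matrix(truth_conf)
  if (!identical(dim(pred_conf), dim(truth_conf))) {
    abort_sdfuse("Confidence tensors must have equal shape.",
                 "sdfuse_validation_error")
  }
  if (!all(truth_conf %in% c(0, 1))) {
    abort_sdfuse("Ground-truth confidences must be 0 or 1.",
                 "sdfuse_validation_error")
  }
  check_mask(mask, dim(pred_conf))
  d <- abs(pred_conf - truth_conf)
  if (squared) d <- d^2
  sum(mask$obj * d) + weights$lambda_nobj * sum(mask$nobj * d)
}

#' Multi-label classification loss on toy tensors
#'
#' Binary cross-entropy between predicted per-class scores and one-hot truth,
#' averaged over the M classes and summed over assigned slots. Scores are
#' clipped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param pred_scores,truth_onehot Arrays of dimension `c(S^2, B, M)`; truth
#'   entries in `{0, 1}`.
#' @param mask [assignment_mask()].
#' @return Non-negative scalar loss.
#' @export
cls_loss <- function(pred_scores, truth_onehot, mask) {
  if (!identical(dim(pred_scores), dim(truth_onehot)) ||
      length(dim(pred_scores)) != 3L) {
    abort_sdfuse("Score tensors must be c(S^2, B, M) arrays of equal shape.",
                 "sdfuse_validation_error")
  }
  if (!all(truth_onehot %in% c(0, 1))) {
    abort_sdfuse("Ground-truth labels must be 0 or 1.",
                 "sdfuse_validation_error")
  }
  check_mask(mask, dim(pred_scores)[1:2])
  M <- dim(pred_scores)[3]
  p <- pmin(pmax(pred_scores, 1e-12), 1 - 1e-12)
  ce <- -(truth_onehot * log(p) + (1 - truth_onehot) * log(1 - p))
  per_box <- apply(ce, c(1, 2), sum) / M
  sum(mask$obj * per_box)
}

#' Total detection loss
#'
#' Sum of the localization, confidence, and classification components, all
#' computed on the same grid and mask.
#'
#' @param l_bbox,l_conf,l_cls Component losses, each non-negative.
#' @return Their sum.
#' @export
total_loss <- function(l_bbox, l_conf, l_cls) {
  parts <- c(l_bbox, l_conf, l_cls)
  if (any(parts < 0)) {
    abort_sdfuse("Loss components are non-negative by construction.",
                 "sdfuse_validation_error")
  }
  sum(parts)
}
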