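#' One-vs-rest classification metrics
#'
#' Per-class TP/FP/FN counts treating each class in turn as positive, with
#' precision = TP/(TP+FP), recall = TP/(TP+FN) and F1 = 2PR/(P+R). Any 0/0 is
#' reported as 0 with a degenerate flag rather than dropped, so the macro
#' averages are always unweighted means over all M classes.
#'
#' @param true_stages,predicted_stages Equal-length vectors of stage names or
#'   1-based indices.
#' @param class_names Class names (defines M and row order).
#' @return A `metrics_report`: list with `per_class` tibble (`stage`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`, `degenerate`) and `macro`
#'   (named list of the three unweighted means).
#' @examples
#' classification_metrics(c(1, 1, 2), c(1, 2, 2), class_names = c("A", "B"))
#' @export
classification_metrics <- function(true_stages, predicted_stages,
                                   class_names = ripeness_stages()) {
  if (length(true_stages) != length(predicted_stages)) {
    abort_sdfuse("Label vectors must have equal length.",
                 "sdfuse_validation_error")
  }
  M <- length(class_names)
  ti <- stage_index(true_stages, class_names)
  pi <- stage_index(predicted_stages, class_names)
  per_class <- purrr::map_dfr(seq_len(M), function(c) {
    tp <- sum(ti == c & pi == c)
    fp <- sum(ti != c & pi == c)
    fn <- sum(ti == c & pi != c)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(stage = class_names[c], tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1,
                   degenerate = (tp + fp == 0) | (tp + fn == 0) |
                     (precision + recall == 0))
  })
  structure(
    list(per_class = per_class,
         macro = list(precision = mean(per_class$precision),
                      recall = mean(per_class$recall),
                      f1 = mean(per_class$f1)),
         n = length(ti)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %d samples, %d classes>\n",
              x$n, nrow(x$per_class)))
  print(x$per_class, ...)
  cat(sprintf("Macro: precision %.4f, recall %.4f, F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  invisible(x)
}

#' Tidy / summarize a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-class tibble. `glance()`: one row with macro
#'   precision, recall, F1 and sample count.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro$precision,
                 macro_recall = x$macro$recall,
                 macro_f1 = x$macro$f1,
                 n = x$n)
}

#' @rdname tidy.metrics_report
#' @param object A `metrics_report`.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  df$stage <- factor(df$stage, levels = object$per_class$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Stage", y = "Score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve for one class
#'
#' Sweeps a decision threshold over the distinct scores of class `class` from
#' high to low; at each threshold a sample is called positive when its score
#' is `>= threshold`. The area is the step sum `sum_i (R_i - R_{i-1}) * P_i`
#' over the sweep, anchored at recall 0 (average-precision-style; equals 1
#' for perfectly separating scores).
#'
#' @param scores Numeric vector of per-sample scores for the class, or a long
#'   sample tibble (`sample_id`, `stage`, `score`) from which the class
#'   column is extracted.
#' @param truth Logical vector: is each sample truly of the class? (Or stage
#'   names when `scores` is a tibble.)
#' @param class Class name, used when `scores` is a tibble.
#' @return A `pr_curve`: tibble of `threshold`, `recall`, `precision` points
#'   (plus the recall-0 anchor), with attributes `area` and `degenerate`
#'   (TRUE when no positive ground truth exists).
#' @examples
#' pr_curve(c(0.9, 0.8, 0.3, 0.2), c(TRUE, FALSE, TRUE, FALSE))
#' @export
pr_curve <- function(scores, truth, class = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(class)) {
      abort_sdfuse("`class` is required when `scores` is a table.",
                   "sdfuse_validation_error")
    }
    sub <- scores[scores$stage == class, , drop = FALSE]
    truth <- truth[match(sub$sample_id, names(truth) %||% sub$sample_id)]
    scores <- sub$score
  }
  if (!length(scores)) {
    abort_sdfuse("At least one sample is required.",
                 "sdfuse_validation_error")
  }
  truth <- as.logical(truth)
  if (length(truth) != length(scores)) {
    abort_sdfuse("`scores` and `truth` must have equal length.",
                 "sdfuse_validation_error")
  }
  n_pos <- sum(truth)
  if (n_pos == 0) {
    out <- tibble::tibble(threshold = double(), recall = double(),
                          precision = double())
    return(structure(out, area = NA_real_, degenerate = TRUE,
                     class = c("pr_curve", class(out))))
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thresholds, function(t) {
    called <- scores >= t
    tp <- sum(called & truth)
    tibble::tibble(threshold = t,
                   recall = tp / n_pos,
                   precision = tp / sum(called))
  })
  anchor <- tibble::tibble(threshold = Inf, recall = 0,
                           precision = pts$precision[1])
  out <- dplyr::bind_rows(anchor, pts)
  area <- sum(diff(out$recall) * out$precision[-1])
  structure(out, area = area, degenerate = FALSE,
            class = c("pr_curve", class(out)))
}

#' Area under a precision-recall curve
#'
#' @param x A `pr_curve`.
#' @return The stored area (NA for a degenerate curve).
#' @export
pr_area <- function(x) attr(x, "area")

#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot of the PR curve.
#' @rdname pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("Area = %.3f", pr_area(object))) +
    ggplot2::theme_minimal()
}

#' Seeded k-fold split
#'
#' Shuffles the ids with the given seed, then deals them into k folds whose
#' sizes differ by at most one. Test sets are disjoint and cover all ids;
#' train sets are the complements. With `stratify`, the deal is done within
#' each stratum so per-stage proportions are preserved.
#'
#' @param sample_ids Vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @param stratify Optional vector, parallel to `sample_ids`, of stratum
#'   labels (e.g. true stages).
#' @return Tibble with columns `fold`, `train`, `test` (list-columns of ids).
#' @export
kfold_split <- function(sample_ids, k = 5L, seed = 1L, stratify = NULL) {
  n <- length(sample_ids)
  if (k < 2L) {
    abort_sdfuse("k must be at least 2.", "sdfuse_validation_error")
  }
  if (n < k) {
    abort_sdfuse(sprintf("Need at least k = %d samples, got %d.", k, n),
                 "sdfuse_validation_error")
  }
  assign_folds <- function(idx, rng_offset = 0L) {
    shuffled <- idx[sample.int(length(idx))]
    fold_of <- rep(seq_len(k), length.out = length(idx))
    split(shuffled, fold_of)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(stratify)) {
    folds <- assign_folds(seq_len(n))
  } else {
    if (length(stratify) != n) {
      abort_sdfuse("`stratify` must be parallel to `sample_ids`.",
                   "sdfuse_validation_error")
    }
    per_stratum <- lapply(split(seq_len(n), stratify), assign_folds)
    folds <- lapply(seq_len(k), function(f) {
      unlist(lapply(per_stratum, function(s) s[[as.character(f)]] %||%
                      integer()), use.names = FALSE)
    })
    names(folds) <- seq_len(k)
  }
  tibble::tibble(
    fold = seq_len(k),
    train = purrr::map(seq_len(k),
                       function(f) sample_ids[-sort(folds[[as.character(f)]])]),
    test = purrr::map(seq_len(k),
                      function(f) sample_ids[sort(folds[[as.character(f)]])])
  )
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cross-validated fusion evaluation
#'
#' Runs the calibrate-then-fuse pipeline under seeded k-fold cross-validation:
#' on each fold the per-view confusion matrices are calibrated from the
#' training samples' argmax predictions, the held-out samples are fused with
#' the requested method, and one-vs-rest metrics are computed; fold macro
#' metrics are then averaged.
#'
#' @param samples Long labeled sample tibble (`sample_id`, `view`, `stage`,
#'   `score`, `true_stage`), e.g. from [simulate_views()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @param method `"sdf"` or `"equal"`.
#' @param stratify Stratify folds by true stage.
#' @return List with `per_fold` tibble (fold, macro metrics) and `mean`
#'   (named list of averaged macro metrics).
#' @export
crossval_fusion <- function(samples, k = 5L, seed = 1L,
                            method = c("sdf", "equal"), stratify = FALSE) {
  method <- match.arg(method)
  truth <- dplyr::distinct(samples, .data$sample_id, .data$true_stage)
  folds <- kfold_split(truth$sample_id, k = k, seed = seed,
                       stratify = if (stratify) truth$true_stage else NULL)
  class_names <- unique(samples$stage)
  views <- unique(samples$view)
  per_fold <- purrr::pmap_dfr(folds, function(fold, train, test) {
    train_df <- samples[samples$sample_id %in% train, , drop = FALSE]
    test_df <- samples[samples$sample_id %in% test, , drop = FALSE]
    confusions <- NULL
    if (method == "sdf") {
      confusions <- purrr::map(views, function(v) {
        sm <- score_matrices(train_df[train_df$view == v, ], class_names)
        pred <- class_names[apply(sm$arrays[[v]], 1, which.max)]
        tr <- truth$true_stage[match(sm$sample_ids, truth$sample_id)]
        calibrate_confusion(tr, pred, class_names)
      })
      names(confusions) <- views
    }
    dec <- fuse_decisions(test_df, confusions, method = method)
    tr <- truth$true_stage[match(dec$sample_id, truth$sample_id)]
    rep <- classification_metrics(tr, dec$stage_name, class_names)
    tibble::tibble(fold = fold,
                   macro_precision = rep$macro$precision,
                   macro_recall = rep$macro$recall,
                   macro_f1 = rep$macro$f1,
                   n_test = length(test))
  })
  list(per_fold = per_fold,
       mean = list(precision = mean(per_fold$macro_precision),
                   recall = mean(per_fold$macro_recall),
                   f1 = mean(per_fold$macro_f1)),
       method = method, k = k, seed = seed)
}
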