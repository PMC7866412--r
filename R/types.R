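#' Ripeness stage names
#'
#' The five ordinal USDA color classes used for tomato ripeness staging, in
#' ripening order. Stage indices used throughout the package are 1-based
#' positions in this vector; interchange files always carry the names.
#'
#' @param M Number of stages. Defaults to 5, the standard five-stage scheme;
#'   other values return generic `"stage_1"`, ... names for simulations with a
#'   different class count.
#' @return Character vector of length `M`.
#' @examples
#' ripeness_stages()
#' @export
ripeness_stages <- function(M = 5L) {
  if (M == 5L) {
    c("Turning", "Pink", "Light Red", "Red", "Deep Red")
  } else {
    paste0("stage_", seq_len(M))
  }
}

#' @noRd
abort_sdfuse <- function(message, class) {
  rlang::abort(message, class = c(class, "sdfuse_error"))
}

# Score vectors are plain numeric vectors: per-class outputs of independent
# logistic heads, non-negative, NOT constrained to sum to 1.
#' @noRd
validate_scores <- function(scores, M = NULL, arg = "scores") {
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    abort_sdfuse(sprintf("`%s` must be a finite numeric vector.", arg),
                 "sdfuse_validation_error")
  }
  if (any(scores < 0)) {
    abort_sdfuse(sprintf("`%s` must be non-negative.", arg),
                 "sdfuse_validation_error")
  }
  if (!is.null(M) && length(scores) != M) {
    abort_sdfuse(
      sprintf("`%s` has length %d, expected %d.", arg, length(scores), M),
      "sdfuse_validation_error"
    )
  }
  invisible(scores)
}

#' @noRd
validate_box <- function(box, arg = "box") {
  if (!is.numeric(box) || length(box) != 4 || any(!is.finite(box))) {
    abort_sdfuse(
      sprintf("`%s` must be a finite numeric vector (cx, cy, w, h).", arg),
      "sdfuse_validation_error"
    )
  }
  if (box[3] <= 0 || box[4] <= 0) {
    abort_sdfuse(sprintf("`%s` must have positive width and height.", arg),
                 "sdfuse_validation_error")
  }
  invisible(box)
}

#' Construct a column-normalized confusion matrix object
#'
#' Rows index the true class, columns the predicted class; each non-degenerate
#' column sums to 1 so that the diagonal entry of column m is the precision of
#' class m. Columns that are all zero (class never predicted during
#' calibration) are allowed and flagged degenerate.
#'
#' @param values Square numeric matrix, rows = true class, columns = predicted
#'   class.
#' @param class_names Optional character vector of class names; defaults to
#'   existing dimnames or [ripeness_stages()].
#' @param normalize If `TRUE`, treat `values` as raw counts and divide each
#'   column by its total first.
#' @return A `confusion_matrix`: the matrix with dimnames and a logical
#'   `degenerate` attribute marking all-zero columns.
#' @examples
#' cm <- confusion_matrix(diag(5))
#' attr(cm, "degenerate")
#' @export
confusion_matrix <- function(values, class_names = NULL, normalize = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort_sdfuse("Confusion matrix must be square.", "sdfuse_shape_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort_sdfuse("Confusion matrix entries must be finite.",
                 "sdfuse_validation_error")
  }
  if (any(values < 0)) {
    abort_sdfuse("Confusion matrix entries must be non-negative.",
                 "sdfuse_validation_error")
  }
  M <- ncol(values)
  if (is.null(class_names)) {
    class_names <- colnames(values) %||% ripeness_stages(M)
  }
  if (length(class_names) != M) {
    abort_sdfuse("`class_names` length must match the matrix dimension.",
                 "sdfuse_validation_error")
  }
  col_tot <- colSums(values)
  if (normalize) {
    nz <- col_tot > 0
    values[, nz] <- sweep(values[, nz, drop = FALSE], 2, col_tot[nz], "/")
    col_tot <- colSums(values)
  } else {
    bad <- which(col_tot > 0 & abs(col_tot - 1) > 1e-9)
    if (length(bad)) {
      abort_sdfuse(
        sprintf("Column%s %s must sum to 1 (got %s).",
                if (length(bad) > 1) "s" else "",
                paste(bad, collapse = ", "),
                paste(signif(col_tot[bad], 6), collapse = ", ")),
        "sdfuse_validation_error"
      )
    }
  }
  dimnames(values) <- list(true = class_names, predicted = class_names)
  structure(values,
            degenerate = stats::setNames(col_tot == 0, class_names),
            class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Column-normalized confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x)[, , drop = FALSE], ...)
  deg <- attr(x, "degenerate")
  if (any(deg)) {
    cat("Degenerate (never-predicted) columns:",
        paste(names(deg)[deg], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom rlang %||%
#' @noRd
validate_confusions <- function(confusions, M = NULL) {
  if (!is.list(confusions) || !length(confusions)) {
    abort_sdfuse("`confusions` must be a non-empty list of confusion matrices.",
                 "sdfuse_validation_error")
  }
  confusions <- lapply(confusions, function(cm) {
    if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
    cm
  })
  dims <- vapply(confusions, ncol, integer(1))
  if (length(unique(dims)) != 1L || (!is.null(M) && dims[1] != M)) {
    abort_sdfuse("All confusion matrices must share one class count M.",
                 "sdfuse_validation_error")
  }
  confusions
}

#' Tidy a confusion matrix into long format
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `true`, `predicted`, `proportion`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  cn <- colnames(x)
  tibble::tibble(
    true = factor(rep(rownames(x), times = ncol(x)), levels = rownames(x)),
    predicted = factor(rep(cn, each = nrow(x)), levels = cn),
    proportion = as.vector(unclass(x))
  )
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$true,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted stage", y = "True stage",
                  fill = "Column\nproportion") +
    ggplot2::theme_minimal()
}

# Map stage labels (names, factor, or 1-based indices) to 1-based indices.
#' @noRd
stage_index <- function(stages, class_names) {
  if (is.factor(stages)) stages <- as.character(stages)
  if (is.character(stages)) {
    idx <- match(stages, class_names)
    if (anyNA(idx)) {
      abort_sdfuse(
        sprintf("Unknown stage name(s): %s.",
                paste(unique(stages[is.na(idx)]), collapse = ", ")),
        "sdfuse_validation_error"
      )
    }
    return(idx)
  }
  idx <- as.integer(stages)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(class_names))) {
    abort_sdfuse("Stage indices must lie in 1..M.", "sdfuse_validation_error")
  }
  idx
}
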