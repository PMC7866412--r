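#' Calibrate a confusion matrix from labeled predictions
#'
#' Builds the raw count matrix (rows = true class, columns = predicted class)
#' and divides each column by its total, so that the diagonal entry of column
#' m is the precision of class m. Classes never predicted yield all-zero
#' columns, kept and flagged degenerate rather than dropped.
#'
#' @param true_stages,predicted_stages Equal-length vectors of stage names or
#'   1-based indices.
#' @param class_names Class names (defines M and the matrix order).
#' @return A [confusion_matrix()].
#' @examples
#' calibrate_confusion(c(1, 1, 2, 2), c(1, 2, 1, 2), class_names = c("A", "B"))
#' @export
calibrate_confusion <- function(true_stages, predicted_stages,
                                class_names = ripeness_stages()) {
  if (length(true_stages) != length(predicted_stages) ||
      !length(true_stages)) {
    abort_sdfuse("Label vectors must be non-empty and of equal length.",
                 "sdfuse_validation_error")
  }
  M <- length(class_names)
  ti <- stage_index(true_stages, class_names)
  pi <- stage_index(predicted_stages, class_names)
  counts <- matrix(0, M, M)
  for (k in seq_along(ti)) counts[ti[k], pi[k]] <- counts[ti[k], pi[k]] + 1
  confusion_matrix(counts, class_names = class_names, normalize = TRUE)
}

#' @noRd
new_fused_decision <- function(fused, per_view_stage, class_names,
                               method, weights = NULL) {
  nrm <- sqrt(sum(fused^2))
  degenerate <- nrm == 0
  scores <- if (degenerate) fused else fused / nrm
  structure(
    list(fused_scores = stats::setNames(scores, class_names),
         stage = if (degenerate) NA_integer_ else unname(which.max(scores)),
         stage_name = if (degenerate) NA_character_
                      else class_names[which.max(scores)],
         per_view_stages = per_view_stage,
         degenerate = degenerate,
         method = method,
         weights = weights),
    class = "fused_decision"
  )
}

#' @export
print.fused_decision <- function(x, ...) {
  cat(sprintf("<fused_decision: %s>\n", x$method))
  if (x$degenerate) {
    cat("Degenerate: all-zero fused vector, stage undefined\n")
  } else {
    cat(sprintf("Stage: %s (L2-normalized score %.4f)\n",
                x$stage_name, max(x$fused_scores)))
  }
  cat("Fused scores:", paste(signif(x$fused_scores, 6), collapse = " "), "\n")
  cat("Per-view stages:",
      paste(names(x$per_view_stages), x$per_view_stages, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fused decision
#'
#' @param x A `fused_decision`.
#' @param ... Unused.
#' @return One-row-per-class tibble of fused scores with the decided stage.
#' @export
tidy.fused_decision <- function(x, ...) {
  tibble::tibble(
    stage = names(x$fused_scores),
    fused_score = as.numeric(x$fused_scores),
    decided = !x$degenerate & seq_along(x$fused_scores) == (x$stage %||% 0L)
  )
}

#' @param x A `fused_decision`.
#' @param ... Unused.
#' @return One-row tibble: `stage_name`, `stage_score`, `degenerate`, `method`.
#' @rdname tidy.fused_decision
#' @export
glance.fused_decision <- function(x, ...) {
  tibble::tibble(
    stage_name = x$stage_name,
    stage_score = if (x$degenerate) NA_real_ else max(x$fused_scores),
    degenerate = x$degenerate,
    method = x$method
  )
}

#' Equal-weight decision fusion
#'
#' Averages the per-view multi-label score vectors with equal weight 1/N
#' (0.5 per view in the two-view setting), L2-normalizes the sum, and decides
#' the stage by argmax. Exact ties are resolved to the LOWEST class index,
#' i.e. the earliest ripeness stage — a conservative rule for sorting, where
#' under-calling ripeness is preferred to over-calling it.
#'
#' @param score_vectors List of >= 2 equal-length non-negative numeric score
#'   vectors, one per view; names identify the views.
#' @param class_names Class names; defaults to the standard five stages.
#' @return A `fused_decision`: L2-normalized `fused_scores`, decided `stage`
#'   and `stage_name`, per-view argmax stages, and a `degenerate` flag set
#'   when the fused vector is all zero.
#' @examples
#' equal_weight_fuse(list(stem = c(0.8, 0.1, 0.05, 0.025, 0.025),
#'                        flower = c(0.1, 0.8, 0.1, 0, 0)))
#' @export
equal_weight_fuse <- function(score_vectors,
                              class_names = ripeness_stages(
                                length(score_vectors[[1]]))) {
  score_vectors <- check_views(score_vectors, class_names)
  N <- length(score_vectors)
  fused <- Reduce(`+`, score_vectors) / N
  new_fused_decision(fused, per_view_argmax(score_vectors, class_names),
                     class_names, method = "equal")
}

#' @noRd
check_views <- function(score_vectors, class_names) {
  if (!is.list(score_vectors) || length(score_vectors) < 2L) {
    abort_sdfuse("At least two per-view score vectors are required.",
                 "sdfuse_validation_error")
  }
  M <- length(class_names)
  if (is.null(names(score_vectors))) {
    names(score_vectors) <- paste0("view_", seq_along(score_vectors))
  }
  purrr::iwalk(score_vectors, function(v, nm) validate_scores(v, M, nm))
  score_vectors
}

#' @noRd
per_view_argmax <- function(score_vectors, class_names) {
  vapply(score_vectors, function(v) {
    if (all(v == 0)) NA_character_ else class_names[which.max(v)]
  }, character(1))
}

#' Stochastic decision fusion weights
#'
#' For view n with winning class `m_n = argmax(P_n)`, column `m_n` is selected
#' from EVERY view's confusion matrix and view n's weight vector is the
#' element-wise ratio `a_{n, m_n} / sum_k a_{k, m_n}`. A view with high
#' precision for its own called class therefore retains more of its score
#' mass, coordinate by coordinate. Coordinates where every selected column is
#' zero carry no precision evidence from any view; by default they get weight
#' 0 (`zero_over_zero = "zero"`), or `1/N` with `"half"`.
#'
#' @param score_vectors List of per-view score vectors (as in
#'   [equal_weight_fuse()]).
#' @param confusions List of per-view [confusion_matrix()] objects, same
#'   order and length as `score_vectors`.
#' @param zero_over_zero Convention for 0/0 coordinates: `"zero"` (default)
#'   or `"half"` (= 1/N).
#' @param class_names Class names.
#' @return Named list of per-view weight vectors, with the selected column
#'   index per view attached as attribute `selected_column`.
#' @export
sdf_weights <- function(score_vectors, confusions,
                        zero_over_zero = c("zero", "half"),
                        class_names = ripeness_stages(
                          length(score_vectors[[1]]))) {
  zero_over_zero <- match.arg(zero_over_zero)
  score_vectors <- check_views(score_vectors, class_names)
  M <- length(class_names)
  confusions <- validate_confusions(confusions, M)
  if (length(confusions) != length(score_vectors)) {
    abort_sdfuse("One confusion matrix per view is required.",
                 "sdfuse_validation_error")
  }
  N <- length(score_vectors)
  m_n <- vapply(score_vectors, which.max, integer(1))
  weights <- purrr::imap(score_vectors, function(v, nm) {
    col <- m_n[[nm]]
    num <- unclass(confusions[[match(nm, names(score_vectors))]])[, col]
    den <- Reduce(`+`, lapply(confusions, function(cm) unclass(cm)[, col]))
    w <- ifelse(den > 0, num / den,
                if (zero_over_zero == "zero") 0 else 1 / N)
    stats::setNames(as.numeric(w), class_names)
  })
  attr(weights, "selected_column") <- m_n
  weights
}

#' Stochastic decision fusion
#'
#' The fused score vector is `sum_n alpha_n (x) P_n`, where `(x)` is
#' element-wise multiplication and the weight vectors `alpha_n` come from
#' [sdf_weights()] — each view's confusion-matrix column for its own winning
#' class, normalized element-wise across views. The sum is L2-normalized and
#' the stage decided by argmax with the lowest-index (earliest-stage)
#' tie-break.
#'
#' @inheritParams sdf_weights
#' @return A `fused_decision` (see [equal_weight_fuse()]); the per-view
#'   weight vectors are stored in `$weights`.
#' @examples
#' cms <- tomato_confusion_fixtures()
#' sdf_fuse(list(stem = c(0.8, 0.1, 0.05, 0.025, 0.025),
#'               flower = c(0.1, 0.8, 0.1, 0, 0)),
#'          confusions = cms)
#' @export
sdf_fuse <- function(score_vectors, confusions,
                     zero_over_zero = c("zero", "half"),
                     class_names = ripeness_stages(
                       length(score_vectors[[1]]))) {
  score_vectors <- check_views(score_vectors, class_names)
  alpha <- sdf_weights(score_vectors, confusions, zero_over_zero,
                       class_names)
  fused <- Reduce(`+`, purrr::map2(alpha, score_vectors, `*`))
  new_fused_decision(fused, per_view_argmax(score_vectors, class_names),
                     class_names, method = "sdf", weights = alpha)
}

#' Fuse decisions for a table of multi-view samples
#'
#' Applies [equal_weight_fuse()] or [sdf_fuse()] to every sample of a long
#' score table and returns one decision row per sample.
#'
#' @param samples Long tibble with columns `sample_id`, `view`, `stage`,
#'   `score` (one row per sample x view x class), e.g. from
#'   [simulate_views()] or [read_samples_json()].
#' @param confusions Named list of per-view confusion matrices (required for
#'   `method = "sdf"`; names must cover every view present).
#' @param method `"sdf"` or `"equal"`.
#' @param zero_over_zero Passed to [sdf_weights()].
#' @return Tibble with one row per sample: `sample_id`, `stage_name`,
#'   `stage_score` (max L2-normalized fused score), one `stage_<view>` column
#'   per view, and `degenerate`.
#' @export
fuse_decisions <- function(samples, confusions = NULL,
                           method = c("sdf", "equal"),
                           zero_over_zero = c("zero", "half")) {
  method <- match.arg(method)
  zero_over_zero <- match.arg(zero_over_zero)
  class_names <- unique(samples$stage)
  sm <- score_matrices(samples, class_names)
  if (method == "sdf") {
    if (is.null(confusions)) {
      abort_sdfuse("`method = \"sdf\"` requires one confusion matrix per view.",
                   "sdfuse_config_error")
    }
    missing_views <- setdiff(sm$views, names(confusions))
    if (length(missing_views)) {
      abort_sdfuse(
        sprintf("No confusion matrix supplied for view(s): %s.",
                paste(missing_views, collapse = ", ")),
        "sdfuse_config_error"
      )
    }
    confusions <- validate_confusions(confusions[sm$views],
                                      length(class_names))
    names(confusions) <- sm$views
  }
  rows <- purrr::map(seq_along(sm$sample_ids), function(i) {
    sv <- purrr::map(sm$arrays, function(a) a[i, ])
    dec <- if (method == "sdf") {
      sdf_fuse(sv, confusions, zero_over_zero, class_names)
    } else {
      equal_weight_fuse(sv, class_names)
    }
    out <- tibble::tibble(
      sample_id = sm$sample_ids[i],
      stage_name = dec$stage_name,
      stage_score = if (dec$degenerate) NA_real_ else max(dec$fused_scores),
      degenerate = dec$degenerate
    )
    for (v in sm$views) out[[paste0("stage_", v)]] <- dec$per_view_stages[[v]]
    out
  })
  dplyr::bind_rows(rows)
}

#' Built-in example confusion matrices
#'
#' The two-viewpoint (stem-end, flower-end) five-stage confusion matrices
#' shipped as package fixtures; columns sum to 1 and the diagonal entries are
#' per-class precisions.
#'
#' @return Named list of two [confusion_matrix()] objects, `stem` and
#'   `flower`.
#' @export
tomato_confusion_fixtures <- function() {
  dir <- system.file("extdata", package = "sdfuse")
  list(stem = read_confusion_csv(file.path(dir, "stem_end_confusion.csv")),
       flower = read_confusion_csv(file.path(dir, "flower_end_confusion.csv")))
}
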