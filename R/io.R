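#' Read a Darknet annotation file
#'
#' Parses the one-object-per-line annotation dialect
#' `<class> <cx> <cy> <w> <h>` with fractional center-format coordinates in
#' \[0, 1\]. Class ids are kept 0-based as they appear on disk.
#'
#' @param path Path to the annotation text file.
#' @param M Optional class count; when given, class ids `>= M` raise a
#'   validation error.
#' @return A tibble with columns `class_id`, `cx`, `cy`, `w`, `h`, one row per
#'   annotation line, in file order.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("0 0.5 0.5 0.2 0.3", f)
#' read_darknet_labels(f)
#' @export
read_darknet_labels <- function(path, M = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    return(tibble::tibble(class_id = integer(), cx = double(), cy = double(),
                          w = double(), h = double()))
  }
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 5L) {
      abort_sdfuse(
        sprintf("Line %d: expected 5 tokens (class cx cy w h), got %d.",
                i, length(tok)),
        "sdfuse_parse_error"
      )
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals) || vals[1] != round(vals[1])) {
      abort_sdfuse(sprintf("Line %d: malformed numeric field.", i),
                   "sdfuse_parse_error")
    }
    vals
  })
  m <- do.call(rbind, rows)
  if (!is.null(M) && any(m[, 1] >= M)) {
    abort_sdfuse(sprintf("Class id >= M = %d found.", M),
                 "sdfuse_validation_error")
  }
  tibble::tibble(class_id = as.integer(m[, 1]),
                 cx = m[, 2], cy = m[, 3], w = m[, 4], h = m[, 5])
}

#' Read a confusion matrix from CSV
#'
#' Expects a header row of M class names and M data rows of M reals, rows in
#' true-class order, columns in predicted-class order. By default the body is
#' validated against the column-sum invariant (each non-degenerate column sums
#' to 1); with `raw_counts = TRUE` the body is taken as counts and
#' column-normalized on load.
#'
#' @param path CSV path.
#' @param raw_counts Declare the raw-counts dialect.
#' @return A [confusion_matrix()].
#' @export
read_confusion_csv <- function(path, raw_counts = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    abort_sdfuse(
      sprintf("Confusion CSV body is %dx%d; a square matrix is required.",
              nrow(m), ncol(m)),
      "sdfuse_shape_error"
    )
  }
  storage.mode(m) <- "double"
  confusion_matrix(m, class_names = colnames(df), normalize = raw_counts)
}

#' Write a confusion matrix to CSV
#'
#' @param cm A [confusion_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- as.data.frame(unclass(cm))
  colnames(df) <- colnames(cm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ground-truth stage labels
#'
#' Labels CSV carries columns `sample_id,stage_name`; stage names, never
#' indices, are the interchange representation.
#'
#' @param path CSV path.
#' @return `read_labels_csv()`: a tibble with columns `sample_id`,
#'   `stage_name`.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character", "character"))
  if (!all(c("sample_id", "stage_name") %in% names(df))) {
    abort_sdfuse("Labels CSV must have columns sample_id, stage_name.",
                 "sdfuse_parse_error")
  }
  tibble::as_tibble(df[c("sample_id", "stage_name")])
}

#' @rdname read_labels_csv
#' @param labels Tibble with columns `sample_id`, `stage_name`.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[c("sample_id", "stage_name")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detections to JSON
#'
#' Serializes a detection table as a top-level JSON list of records
#' `{sample_id, view, box:{cx,cy,w,h}, confidence, scores:[...],
#' class_names:[...]}`. Round-trip stable with [read_detections_json()]:
#' floats are written at full precision.
#'
#' @param detections Detection tibble as produced by [simulate_boxes()]:
#'   columns `sample_id`, `view`, `cx`, `cy`, `w`, `h`, `confidence`, and a
#'   list-column `scores` of equal-length score vectors.
#' @param path Output path.
#' @param class_names Class names recorded in each record; length must equal
#'   the common score-vector length.
#' @return `path`, invisibly.
#' @export
write_detections_json <- function(detections, path,
                                  class_names = NULL) {
  n <- nrow(detections)
  lens <- if (n) lengths(detections$scores) else integer()
  if (n && length(unique(lens)) != 1L) {
    abort_sdfuse("All detections must share one score-vector length M.",
                 "sdfuse_validation_error")
  }
  M <- if (n) lens[1] else length(class_names %||% ripeness_stages())
  class_names <- class_names %||% ripeness_stages(M)
  if (length(class_names) != M) {
    abort_sdfuse("`class_names` length must equal the score-vector length.",
                 "sdfuse_validation_error")
  }
  recs <- purrr::pmap(detections, function(sample_id, view, cx, cy, w, h,
                                           confidence, scores, ...) {
    list(sample_id = sample_id, view = view,
         box = list(cx = cx, cy = cy, w = w, h = h),
         confidence = confidence,
         scores = as.numeric(scores),
         class_names = class_names)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from JSON
#'
#' @param path Path written by [write_detections_json()].
#' @return Detection tibble (see [write_detections_json()]); the class names
#'   are attached as attribute `class_names`.
#' @export
read_detections_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(recs)) {
    out <- tibble::tibble(sample_id = character(), view = character(),
                          cx = double(), cy = double(), w = double(),
                          h = double(), confidence = double(),
                          scores = list())
    return(out)
  }
  out <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(sample_id = r$sample_id, view = r$view,
                   cx = r$box$cx, cy = r$box$cy, w = r$box$w, h = r$box$h,
                   confidence = r$confidence,
                   scores = list(as.numeric(unlist(r$scores))))
  })
  attr(out, "class_names") <- as.character(unlist(recs[[1]]$class_names))
  out
}

#' Write / read multi-view sample scores as JSON
#'
#' The samples JSON is the interchange format between the simulator and the
#' fusion step: `{class_names:[...], samples:[{sample_id, true_stage?,
#' scores:{<view>:[...], ...}}, ...]}`.
#'
#' @param samples Long tibble with columns `sample_id`, `view`, `stage`,
#'   `score` and optionally `true_stage` (stage name), as produced by
#'   [simulate_views()].
#' @param path Output path.
#' @return `path` invisibly for the writer; the long tibble for the reader.
#' @export
write_samples_json <- function(samples, path) {
  class_names <- levels(factor(samples$stage,
                               levels = unique(samples$stage)))
  wide <- score_matrices(samples, class_names)
  has_truth <- "true_stage" %in% names(samples)
  truth <- if (has_truth) {
    samples |>
      dplyr::distinct(.data$sample_id, .data$true_stage)
  } else NULL
  recs <- purrr::map(wide$sample_ids, function(sid) {
    sc <- purrr::map(wide$views, function(v) {
      as.numeric(wide$arrays[[v]][match(sid, wide$sample_ids), ])
    })
    names(sc) <- wide$views
    rec <- list(sample_id = sid, scores = sc)
    if (has_truth) {
      rec$true_stage <- truth$true_stage[match(sid, truth$sample_id)]
    }
    rec
  })
  jsonlite::write_json(list(class_names = class_names, samples = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_samples_json
#' @export
read_samples_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  class_names <- as.character(unlist(obj$class_names))
  purrr::map_dfr(obj$samples, function(r) {
    purrr::imap_dfr(r$scores, function(sc, v) {
      out <- tibble::tibble(sample_id = r$sample_id, view = v,
                            stage = class_names,
                            score = as.numeric(unlist(sc)))
      if (!is.null(r$true_stage)) out$true_stage <- r$true_stage
      out
    })
  })
}

# Reshape a long (sample_id, view, stage, score) table into one
# samples x M score matrix per view, preserving first-appearance order.
#' @noRd
score_matrices <- function(samples, class_names) {
  sample_ids <- unique(samples$sample_id)
  views <- unique(samples$view)
  arrays <- lapply(views, function(v) {
    sub <- samples[samples$view == v, , drop = FALSE]
    m <- matrix(0, nrow = length(sample_ids), ncol = length(class_names),
                dimnames = list(sample_ids, class_names))
    m[cbind(match(sub$sample_id, sample_ids),
            match(sub$stage, class_names))] <- sub$score
    m
  })
  names(arrays) <- views
  list(sample_ids = sample_ids, views = views, class_names = class_names,
       arrays = arrays)
}
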