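#' Construct an ordinal view kernel
#'
#' A view kernel is a row-stochastic M x M matrix whose row c is the expected
#' score profile of a view when the true stage is c. Mass `accuracy` sits on
#' the diagonal, `spill` on each ordinal neighbor (stages c-1 and c+1 where
#' they exist), and the remainder is spread uniformly over the other classes
#' — mirroring how ripeness classifiers confuse adjacent color stages far more
#' often than distant ones.
#'
#' @param M Class count.
#' @param accuracy Diagonal mass per row, in \[0, 1\].
#' @param spill Mass per ordinal neighbor.
#' @return A numeric M x M row-stochastic matrix.
#' @examples
#' make_view_kernel(3, accuracy = 0.8, spill = 0.1)
#' @export
make_view_kernel <- function(M, accuracy, spill) {
  if (M < 1 || accuracy < 0 || accuracy > 1 || spill < 0) {
    abort_sdfuse("M >= 1, accuracy in [0, 1] and spill >= 0 required.",
                 "sdfuse_validation_error")
  }
  K <- matrix(0, M, M)
  for (c in seq_len(M)) {
    neighbors <- intersect(c(c - 1L, c + 1L), seq_len(M))
    others <- setdiff(seq_len(M), c(c, neighbors))
    remainder <- 1 - accuracy - length(neighbors) * spill
    if (remainder < -1e-12) {
      abort_sdfuse(
        sprintf(
          "Row %d infeasible: accuracy + %d * spill = %.3f exceeds 1.",
          c, length(neighbors), accuracy + length(neighbors) * spill),
        "sdfuse_validation_error"
      )
    }
    K[c, c] <- accuracy
    K[c, neighbors] <- spill
    if (length(others)) {
      K[c, others] <- max(remainder, 0) / length(others)
    } else if (remainder > 1e-12) {
      # no non-neighbor classes to absorb the remainder: rescale the row
      K[c, ] <- K[c, ] / (accuracy + length(neighbors) * spill + remainder)
    }
    K[c, ] <- K[c, ] / sum(K[c, ])
  }
  K
}

# Dirichlet draws via the gamma construction: X_i ~ Gamma(alpha_i, 1),
# normalized rows are Dirichlet(alpha).
#' @noRd
rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Simulate multi-view labeled score samples
#'
#' Emulates a multi-viewpoint classification stream: for each sample a true
#' stage c is drawn from `priors`, and each view v independently draws its
#' score vector from `Dirichlet(kappa * (K_v[c, ] + eps))` with smoothing
#' `eps = 1e-3` (so exact kernel zeros stay drawable). Larger `kappa`
#' concentrates draws around the (smoothed, renormalized) kernel row, which
#' is exactly the Dirichlet mean.
#'
#' @param n Number of samples.
#' @param kernels Named list of per-view kernels from [make_view_kernel()].
#' @param kappa Dirichlet concentration, `> 0`.
#' @param priors Length-M simplex of stage frequencies; uniform by default.
#' @param seed Integer seed; output is fully reproducible.
#' @param class_names Class names.
#' @return Long tibble with columns `sample_id`, `true_stage`, `view`,
#'   `stage`, `score` (one row per sample x view x class).
#' @examples
#' k <- make_view_kernel(3, 0.8, 0.1)
#' simulate_views(4, list(a = k, b = k), kappa = 20, seed = 1,
#'                class_names = c("u", "v", "w"))
#' @export
simulate_views <- function(n, kernels, kappa = 50, priors = NULL, seed = 1L,
                           class_names = ripeness_stages(ncol(kernels[[1]]))) {
  if (kappa <= 0) {
    abort_sdfuse("kappa must be positive.", "sdfuse_validation_error")
  }
  M <- length(class_names)
  kernels <- lapply(kernels, function(K) {
    K <- as.matrix(K)
    if (!identical(dim(K), c(M, M)) || any(K < 0) ||
        any(abs(rowSums(K) - 1) > 1e-9)) {
      abort_sdfuse("Each kernel must be a row-stochastic M x M matrix.",
                   "sdfuse_validation_error")
    }
    K
  })
  if (is.null(names(kernels))) {
    names(kernels) <- paste0("view_", seq_along(kernels))
  }
  if (is.null(priors)) priors <- rep(1 / M, M)
  if (length(priors) != M || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9) {
    abort_sdfuse("`priors` must be a length-M simplex vector.",
                 "sdfuse_validation_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sprintf("s%05d", seq_len(n))
  true_idx <- sample.int(M, n, replace = TRUE, prob = priors)
  eps <- 1e-3
  out <- purrr::imap_dfr(kernels, function(K, v) {
    scores <- matrix(0, n, M)
    for (c in seq_len(M)) {
      rows <- which(true_idx == c)
      if (!length(rows)) next
      scores[rows, ] <- rdirichlet_rows(length(rows),
                                        kappa * (K[c, ] + eps))
    }
    tibble::tibble(
      sample_id = rep(ids, each = M),
      true_stage = rep(class_names[true_idx], each = M),
      view = v,
      stage = rep(class_names, times = n),
      score = as.vector(t(scores))
    )
  })
  dplyr::arrange(out, .data$sample_id, .data$view)
}

#' Smoothed, renormalized kernel row
#'
#' The expected score profile of [simulate_views()] for true stage `c`:
#' `(K[c, ] + eps) / sum(K[c, ] + eps)` — the mean of the Dirichlet the
#' simulator draws from.
#'
#' @param kernel A view kernel.
#' @param c 1-based stage index.
#' @param eps Smoothing constant (must match the simulator's; default 1e-3).
#' @return Length-M numeric vector.
#' @export
kernel_row_mean <- function(kernel, c, eps = 1e-3) {
  row <- kernel[c, ] + eps
  row / sum(row)
}

#' Simulate detection boxes
#'
#' Random center-format boxes with random confidences and Dirichlet score
#' vectors, plus optional jittered duplicates to exercise suppression.
#'
#' @param n Number of base boxes.
#' @param M Class count for the score vectors.
#' @param duplicate_frac Fraction of boxes duplicated with jitter.
#' @param jitter_sd Standard deviation of the center/size jitter applied to
#'   duplicates (0 gives exact duplicates with IoU 1).
#' @param seed Integer seed.
#' @return Detection tibble: `sample_id`, `view`, `cx`, `cy`, `w`, `h`,
#'   `confidence`, list-column `scores`.
#' @export
simulate_boxes <- function(n, M = 5L, duplicate_frac = 0.5, jitter_sd = 0.01,
                           seed = 1L) {
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), view = character(),
                          cx = double(), cy = double(), w = double(),
                          h = double(), confidence = double(),
                          scores = list()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base <- tibble::tibble(
    sample_id = sprintf("b%04d", seq_len(n)),
    view = "sim",
    cx = stats::runif(n, 0.2, 0.8),
    cy = stats::runif(n, 0.2, 0.8),
    w = stats::runif(n, 0.05, 0.3),
    h = stats::runif(n, 0.05, 0.3),
    confidence = stats::runif(n),
    scores = purrr::map(seq_len(n),
                        function(i) as.numeric(rdirichlet_rows(1, rep(1, M))))
  )
  n_dup <- round(n * duplicate_frac)
  if (n_dup > 0) {
    dup <- base[seq_len(n_dup), , drop = FALSE]
    dup$sample_id <- paste0(dup$sample_id, "_dup")
    dup$cx <- dup$cx + stats::rnorm(n_dup, 0, jitter_sd)
    dup$cy <- dup$cy + stats::rnorm(n_dup, 0, jitter_sd)
    dup$w <- pmax(dup$w + stats::rnorm(n_dup, 0, jitter_sd), 1e-3)
    dup$h <- pmax(dup$h + stats::rnorm(n_dup, 0, jitter_sd), 1e-3)
    dup$confidence <- stats::runif(n_dup)
    base <- dplyr::bind_rows(base, dup)
  }
  base
}
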