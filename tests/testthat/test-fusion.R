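worked_example <- function() {
  list(P1 = c(0.8, 0.1, 0.05, 0.025, 0.025),
       P2 = c(0.1, 0.8, 0.1, 0, 0),
       cms = tomato_confusion_fixtures())
}

test_that("confusion calibration counts, column-normalizes, and flags dead columns", {
  cm <- calibrate_confusion(c(1, 1, 2, 2), c(1, 2, 1, 2),
                            class_names = c("A", "B"))
  expect_equal(unclass(cm), matrix(0.5, 2, 2), ignore_attr = TRUE)

  truths <- sample(ripeness_stages(), 30, replace = TRUE)
  cm <- calibrate_confusion(truths, truths)
  present <- ripeness_stages() %in% truths
  expect_equal(unname(diag(cm))[present], rep(1, sum(present)))

  cm <- calibrate_confusion(c(1, 2, 3), c(1, 2, 1),
                            class_names = c("a", "b", "c"))
  expect_equal(unname(cm[, 3]), c(0, 0, 0))
  expect_true(attr(cm, "degenerate")[["c"]])
  expect_false(attr(cm, "degenerate")[["a"]])

  expect_error(calibrate_confusion(1:3, 1:2, class_names = c("a", "b", "c")),
               class = "sdfuse_validation_error")
})

test_that("equal-weight fusion averages, L2-normalizes, and breaks ties to the earliest stage", {
  v <- c(0.2, 0.7, 0.05, 0.025, 0.025)
  d <- equal_weight_fuse(list(a = v, b = v))
  expect_equal(as.numeric(d$fused_scores), v / sqrt(sum(v^2)))
  expect_equal(d$stage_name, "Pink")

  we <- worked_example()
  d <- equal_weight_fuse(list(stem = we$P1, flower = we$P2))
  pre <- 0.5 * we$P1 + 0.5 * we$P2
  expect_equal(pre[1], 0.45)
  expect_equal(pre[2], 0.45)
  expect_equal(as.numeric(d$fused_scores), pre / sqrt(sum(pre^2)))
  # exact tie between Turning and Pink resolves to the earlier stage
  expect_equal(d$stage_name, "Turning")
  expect_equal(unname(d$per_view_stages), c("Turning", "Pink"))

  d <- equal_weight_fuse(list(a = c(1, 0), b = c(0, 1)),
                         class_names = c("x", "y"))
  expect_equal(d$stage, 1L)

  d <- equal_weight_fuse(list(a = c(0, 0), b = c(0, 0)),
                         class_names = c("x", "y"))
  expect_true(d$degenerate)
  expect_true(is.na(d$stage))
})

test_that("sdf weights reproduce the two-view worked example to 1e-6", {
  we <- worked_example()
  w <- sdf_weights(list(stem = we$P1, flower = we$P2), we$cms)
  expect_equal(as.numeric(w$stem), c(0.9 / 1.7, 0.1 / 0.25, 0, 0, 0),
               tolerance = 1e-6)
  expect_equal(as.numeric(w$flower),
               c(0.1 / 0.14, 0.8 / 1.72, 0.1 / 0.14, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(attr(w, "selected_column")), c(1L, 2L))
})

test_that("sdf weights handle symmetric and identity confusion structures", {
  cm <- random_confusion(4, diag_boost = 2)
  v <- c(0.1, 0.6, 0.2, 0.1)
  w <- sdf_weights(list(a = v, b = v), list(cm, cm),
                   class_names = ripeness_stages(4))
  nz <- unclass(cm)[, 2] > 0
  expect_equal(unname(w$a[nz]), rep(0.5, sum(nz)))
  expect_equal(w$a, w$b)

  id <- confusion_matrix(diag(3), class_names = c("a", "b", "c"))
  w <- sdf_weights(list(a = c(0.9, 0.1, 0), b = c(0, 0.1, 0.9)),
                   list(id, id), class_names = c("a", "b", "c"))
  expect_equal(unname(w$a), c(0.5, 0, 0))
  expect_equal(unname(w$b), c(0, 0, 0.5))

  # the 1/N convention can be chosen for no-evidence coordinates
  w <- sdf_weights(list(a = c(0.9, 0.1, 0), b = c(0, 0.1, 0.9)),
                   list(id, id), zero_over_zero = "half",
                   class_names = c("a", "b", "c"))
  expect_equal(unname(w$a), c(0.5, 0.5, 0.5))
})

test_that("sdf fusion reproduces the worked example decision", {
  we <- worked_example()
  d <- sdf_fuse(list(stem = we$P1, flower = we$P2), we$cms)
  ref <- oracle_sdf(we$P1, we$P2, unclass(we$cms$stem),
                    unclass(we$cms$flower))
  expect_equal(ref$fused, c(0.494958, 0.412093, 0.071429, 0, 0),
               tolerance = 1e-5)
  expect_equal(as.numeric(d$fused_scores),
               ref$fused / sqrt(sum(ref$fused^2)), tolerance = 1e-12)
  # the more precise stem-end call outweighs the flower-end's
  expect_equal(d$stage_name, "Turning")
  expect_equal(d$stage, ref$stage)
})

test_that("sdf fusion absorbs an all-zero view and flags all-zero results", {
  we <- worked_example()
  d <- sdf_fuse(list(stem = we$P1, flower = rep(0, 5)), we$cms)
  w1 <- sdf_weights(list(stem = we$P1, flower = rep(0, 5)), we$cms)$stem
  solo <- w1 * we$P1
  expect_equal(as.numeric(d$fused_scores),
               as.numeric(solo / sqrt(sum(solo^2))))
  expect_true(is.na(d$per_view_stages[["flower"]]))

  zero_cm <- calibrate_confusion(c(1, 2), c(2, 2),
                                 class_names = c("a", "b", "c"))
  # both views call class 1, but neither matrix has mass in column 1
  d <- sdf_fuse(list(a = c(1, 0, 0), b = c(1, 0, 0)),
                list(zero_cm, zero_cm), class_names = c("a", "b", "c"))
  expect_true(d$degenerate)
})

test_that("sdf agrees with the independent oracle on random two-view inputs", {
  withr::local_seed(31)
  for (rep in 1:200) {
    M <- sample(2:6, 1)
    P1 <- random_scores(M); P2 <- random_scores(M)
    A1 <- random_confusion(M); A2 <- random_confusion(M)
    d <- sdf_fuse(list(v1 = P1, v2 = P2), list(A1, A2),
                  class_names = ripeness_stages(M))
    ref <- oracle_sdf(P1, P2, unclass(A1), unclass(A2))
    expect_equal(as.numeric(d$fused_scores),
                 ref$fused / sqrt(sum(ref$fused^2)), tolerance = 1e-12)
    expect_equal(d$stage, ref$stage)
  }
})

test_that("fused vectors are unit-norm and view order does not change the decision", {
  withr::local_seed(17)
  for (rep in 1:200) {
    M <- sample(3:6, 1)
    N <- sample(2:4, 1)
    svs <- lapply(seq_len(N), function(i) random_scores(M))
    names(svs) <- paste0("v", seq_len(N))
    cms <- replicate(N, random_confusion(M), simplify = FALSE)
    d <- sdf_fuse(svs, cms, class_names = ripeness_stages(M))
    expect_equal(sqrt(sum(d$fused_scores^2)), 1, tolerance = 1e-12)

    perm <- sample(N)
    dp <- sdf_fuse(svs[perm], cms[perm], class_names = ripeness_stages(M))
    expect_equal(dp$fused_scores, d$fused_scores, tolerance = 1e-12)
    expect_equal(dp$stage, d$stage)
    expect_equal(dp$per_view_stages, d$per_view_stages[perm])

    de <- equal_weight_fuse(svs, class_names = ripeness_stages(M))
    dep <- equal_weight_fuse(svs[perm], class_names = ripeness_stages(M))
    expect_equal(sqrt(sum(de$fused_scores^2)), 1, tolerance = 1e-12)
    expect_equal(dep$fused_scores, de$fused_scores, tolerance = 1e-12)
  }
})

test_that("per-column weight normalization partitions unity across views", {
  # For any fixed selected column, the across-view weights at each coordinate
  # sum to 1 where any view has mass and to 0 where none does. (When views
  # select different columns their weight vectors are NOT complementary —
  # the worked example itself sums to ~1.24 at the first coordinate.)
  withr::local_seed(23)
  for (rep in 1:200) {
    M <- sample(2:6, 1)
    N <- sample(2:4, 1)
    cms <- replicate(N, {
      m <- matrix(runif(M * M) * rbinom(M * M, 1, 0.7), M, M)
      m[1, ] <- m[1, ] + 0.1 # keep no column fully zero
      confusion_matrix(m, ripeness_stages(M), normalize = TRUE)
    }, simplify = FALSE)
    col <- sample(M, 1)
    target <- rep(0.1, M); target[col] <- 1
    svs <- replicate(N, target, simplify = FALSE)
    names(svs) <- paste0("v", seq_len(N))
    w <- sdf_weights(svs, cms, class_names = ripeness_stages(M))
    sums <- Reduce(`+`, w)
    den <- Reduce(`+`, lapply(cms, function(cm) unclass(cm)[, col]))
    expect_equal(unname(sums[den > 0]), rep(1, sum(den > 0)),
                 tolerance = 1e-12)
    expect_equal(unname(sums[den == 0]), rep(0, sum(den == 0)))
  }
})

test_that("agreeing views with diagonally-dominant columns keep their stage", {
  withr::local_seed(41)
  for (rep in 1:200) {
    M <- sample(3:6, 1)
    N <- sample(2:3, 1)
    m <- sample(M, 1)
    cms <- replicate(N, random_confusion(M, diag_boost = 3),
                     simplify = FALSE)
    svs <- replicate(N, {
      v <- runif(M, 0, 0.5); v[m] <- runif(1, 0.6, 1); v
    }, simplify = FALSE)
    names(svs) <- paste0("v", seq_len(N))
    d <- sdf_fuse(svs, cms, class_names = ripeness_stages(M))
    expect_equal(unique(unname(d$per_view_stages)), ripeness_stages(M)[m])
    expect_equal(d$stage, m)
  }
})

test_that("with equal confusion matrices sdf and equal weighting pick the same stage", {
  withr::local_seed(53)
  n_checked <- 0
  for (rep in 1:1000) {
    M <- sample(2:6, 1)
    cm <- random_confusion(M)
    P1 <- random_scores(M); P2 <- random_scores(M)
    de <- equal_weight_fuse(list(a = P1, b = P2),
                            class_names = ripeness_stages(M))
    fe <- as.numeric(de$fused_scores)
    # skip exact ties, where the tie-break rather than the weights decides
    if (sum(fe == max(fe)) > 1) next
    ds <- sdf_fuse(list(a = P1, b = P2), list(cm, cm),
                   class_names = ripeness_stages(M))
    fs <- as.numeric(ds$fused_scores)
    if (sum(fs == max(fs)) > 1) next
    n_checked <- n_checked + 1
    expect_equal(ds$stage, de$stage)
  }
  expect_gte(n_checked, 900)
})

test_that("fuse_decisions applies either method across a sample table", {
  kern1 <- make_view_kernel(5, 0.9, 0.04)
  kern2 <- make_view_kernel(5, 0.78, 0.10)
  samples <- simulate_views(40, list(stem = kern1, flower = kern2),
                            kappa = 50, seed = 8)
  cms <- tomato_confusion_fixtures()
  dec <- fuse_decisions(samples, cms, method = "sdf")
  expect_equal(nrow(dec), 40L)
  expect_true(all(c("stage_name", "stage_score", "stage_stem",
                    "stage_flower", "degenerate") %in% names(dec)))
  expect_true(all(dec$stage_name %in% ripeness_stages()))
  expect_false(any(dec$degenerate))

  # row-by-row agreement with the single-sample path
  sm <- samples[samples$sample_id == dec$sample_id[1], ]
  svs <- list(stem = sm$score[sm$view == "stem"],
              flower = sm$score[sm$view == "flower"])
  names(svs$stem) <- sm$stage[sm$view == "stem"]
  one <- sdf_fuse(svs, cms, class_names = unique(samples$stage))
  expect_equal(dec$stage_name[1], one$stage_name)
  expect_equal(dec$stage_score[1], max(one$fused_scores))

  deq <- fuse_decisions(samples, method = "equal")
  expect_equal(nrow(deq), 40L)
  expect_error(fuse_decisions(samples, method = "sdf"),
               class = "sdfuse_config_error")
  expect_error(fuse_decisions(samples, cms["stem"], method = "sdf"),
               class = "sdfuse_config_error")
})
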