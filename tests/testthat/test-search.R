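test_that("combination counting is exact", {
  expect_equal(count_combinations(76, 5), 18474840)
  expect_equal(count_combinations(7, 0), 1)
  expect_equal(count_combinations(5, 2), 10)
  expect_error(count_combinations(3, 4), "<=")
})

test_that("the subset iterator enumerates every combination exactly once", {
  n <- 7; k <- 3
  idx <- seq_len(k)
  seen <- character(0)
  repeat {
    seen <- c(seen, paste(idx, collapse = "-"))
    idx <- metabolda:::next_combination(idx, n)
    if (is.null(idx)) break
  }
  expect_equal(length(seen), count_combinations(n, k))
  expect_false(anyDuplicated(seen) > 0)
})

test_that("search is exhaustive, deterministic, and skips singular subsets", {
  g <- gaussian_clouds(30, 25, p = 8, delta = 1.5, seed = 41)
  X <- cbind(g$X, f9 = g$X[, 1])  # exact duplicate: subsets {f1, f9, .} singular
  res <- search_panels(X, k = 2, candidates = colnames(X), labels = g$labels,
                       threshold = 0.5, top_n = 50)
  log_ <- attr(res, "run_log")
  expect_equal(log_$n_evaluated + log_$n_skipped,
               count_combinations(9, 2))
  expect_equal(log_$n_skipped, 1)  # only the {f1, f9} pair is singular

  # chunking must not affect the result
  res_small <- search_panels(X, k = 2, candidates = colnames(X),
                             labels = g$labels, threshold = 0.5, top_n = 50,
                             chunk_size = 3L)
  expect_equal(res, res_small, ignore_attr = TRUE)
})

test_that("search metrics agree with the direct per-panel route", {
  g <- gaussian_clouds(25, 20, p = 6, delta = 1.5, seed = 42)
  res <- search_panels(g$X, k = 3, candidates = colnames(g$X),
                       labels = g$labels, threshold = 0.58, top_n = 100,
                       loocv = TRUE)
  expect_equal(nrow(res), count_combinations(6, 3))
  for (i in c(1, 7, nrow(res))) {
    feats <- strsplit(res$features[i], "+", fixed = TRUE)[[1]]
    fit <- fit_lda(g$X, feats, g$labels)
    m <- evaluate_classification(
      classify(posterior_scores(fit, g$X), 0.58), g$labels)
    expect_equal(res$accuracy[i], m$accuracy, tolerance = 1e-12)
    expect_equal(res$sensitivity[i], m$sensitivity, tolerance = 1e-12)
    cv <- loocv_lda(g$X, feats, g$labels, 0.58)
    expect_equal(res$loocv_accuracy[i], cv$accuracy, tolerance = 1e-12)
    expect_equal(res$loocv_specificity[i], cv$specificity, tolerance = 1e-12)
  }
})

test_that("a planted panel with large effects ranks first among decoys", {
  set.seed(43)
  n1 <- 45; n0 <- 45; n <- n1 + n0
  panel <- paste0("hit", 1:4)
  decoys <- paste0("noise", 1:20)
  grp <- c(rep(1, n1), rep(0, n0))
  X <- cbind(
    sapply(panel, function(m) 0.8 * grp * sample(c(1, -1), 1) + rnorm(n, 0, 0.5)),
    sapply(decoys, function(m) rnorm(n)))
  rownames(X) <- sprintf("P%03d", 1:n)
  labels <- ifelse(grp == 1, "AD", "NC")
  res <- search_panels(X, k = 4, candidates = colnames(X), labels = labels,
                       threshold = 0.5, top_n = 3)
  expect_equal(res$features[1], paste(sort(panel), collapse = "+"))
  expect_equal(attr(res, "run_log")$n_combinations,
               count_combinations(24, 4))
})

test_that("a candidate set of size k returns exactly one record", {
  g <- gaussian_clouds(15, 15, p = 3, seed = 44)
  res <- search_panels(g$X, k = 3, candidates = colnames(g$X),
                       labels = g$labels, threshold = 0.5)
  expect_equal(nrow(res), 1)
  expect_equal(res$features, "f1+f2+f3")
})

test_that("augmentation reports honestly: duplicates skip, noise does not help", {
  g <- gaussian_clouds(40, 40, p = 5, delta = 2.5, seed = 45)
  res <- search_panels(g$X, k = 3, candidates = colnames(g$X)[1:4],
                       labels = g$labels, threshold = 0.5, top_n = 1,
                       loocv = TRUE)
  best <- res[1, ]
  dup <- augment_best(best, g$X, g$labels,
                      extra = strsplit(best$features, "+", fixed = TRUE)[[1]][1])
  expect_true(dup$skipped)
  expect_true(is.na(dup$accuracy))

  # pure-noise augmentation: mean LOOCV change over seeds is ~0 or worse
  deltas <- vapply(1:25, function(s) {
    gs <- gaussian_clouds(35, 35, p = 4, delta = 1.8, seed = 500 + s)
    Xs <- cbind(gs$X, pure_noise = rnorm(70))
    base <- loocv_lda(Xs, paste0("f", 1:3), gs$labels, 0.5)$accuracy
    aug <- loocv_lda(Xs, c(paste0("f", 1:3), "pure_noise"), gs$labels, 0.5)$accuracy
    aug - base
  }, 0)
  expect_lt(mean(deltas), 2 * stats::sd(deltas) / sqrt(length(deltas)) + 1e-9)

  # nesting at the optimal threshold: a superset's resubstitution accuracy
  # is at least a nested subset's, when each uses its own best threshold
  gs <- gaussian_clouds(30, 30, p = 4, delta = 1.5, seed = 46)
  grid <- seq(0.05, 0.95, 0.01)
  acc_at_best <- function(feats) {
    fit <- fit_lda(gs$X, feats, gs$labels)
    sc <- posterior_scores(fit, gs$X)
    best_t <- scan_thresholds(sc, gs$labels, grid)$best
    evaluate_classification(classify(sc, best_t), gs$labels)$accuracy
  }
  expect_gte(acc_at_best(paste0("f", 1:3)), acc_at_best(paste0("f", 1:2)))
})

test_that("panel tables group features into family columns with directions", {
  g <- gaussian_clouds(20, 20, p = 4, delta = 2, seed = 47)
  res <- search_panels(g$X, k = 2, candidates = colnames(g$X),
                       labels = g$labels, threshold = 0.5, top_n = 3)
  fmap <- c(f1 = "famA", f2 = "famA", f3 = "famB", f4 = "famB")
  contr <- data.frame(metabolite = paste0("f", 1:4),
                      direction = c("up_in_AD", "down_in_AD",
                                    "up_in_AD", "down_in_AD"))
  tab <- format_panel_table(res, fmap, contr)
  expect_true(all(c("famA", "famB", "accuracy") %in% names(tab)))
  expect_equal(nrow(tab), nrow(res))
  joined <- paste(tab$famA, tab$famB, collapse = " ")
  expect_match(joined, "\\(\\+\\)|\\(-\\)")
})
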