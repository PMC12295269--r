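test_that("LDA weights match the explicit pooled-covariance oracle", {
  g <- gaussian_clouds(10, 10, p = 4, delta = 2, seed = 11)
  fit <- fit_lda(g$X, colnames(g$X), g$labels)
  # independent route: explicit matrix inversion
  X1 <- g$X[g$labels == "AD", ]; X0 <- g$X[g$labels == "NC", ]
  Sp <- (cov(X1) * (nrow(X1) - 1) + cov(X0) * (nrow(X0) - 1)) /
    (nrow(g$X) - 2)
  a <- solve(Sp) %*% (colMeans(X1) - colMeans(X0))
  w <- a / sqrt(drop(t(a) %*% Sp %*% a))
  agree <- min(max(abs(fit$weights - drop(w))),
               max(abs(fit$weights + drop(w))))  # up to global sign
  expect_lt(agree, 1e-8)
  # stated convention: unit within-group variance
  expect_equal(drop(t(fit$weights) %*% fit$pooled_covariance %*% fit$weights),
               1, tolerance = 1e-10)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
})

test_that("LDA weights agree with an established implementation up to sign", {
  skip_if_not_installed("MASS")
  g <- gaussian_clouds(30, 20, p = 3, delta = 1.5, seed = 12)
  fit <- fit_lda(g$X, colnames(g$X), g$labels)
  mf <- MASS::lda(g$X, grouping = g$labels)
  expect_equal(abs(unname(fit$weights)), abs(unname(mf$scaling[, 1])),
               tolerance = 1e-8)
})

test_that("collinear features raise a named singularity error", {
  g <- gaussian_clouds(10, 10, p = 2, seed = 13)
  X <- cbind(g$X, f3 = g$X[, 1])
  expect_error(fit_lda(X, colnames(X), g$labels), "f1.*f3|collinear")
})

test_that("posterior scores equal the closed-form Gaussian posterior", {
  # 1-D, two samples per class, hand-computable
  X <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  lab <- c("NC", "NC", "AD", "AD")
  fit <- fit_lda(X, "f", lab)
  s2 <- fit$pooled_covariance[1, 1]
  xq <- matrix(c(-0.7, 0.3, 1.9), ncol = 1, dimnames = list(NULL, "f"))
  num <- 0.5 * dnorm(xq[, 1], 1.5, sqrt(s2))
  den <- num + 0.5 * dnorm(xq[, 1], -1.5, sqrt(s2))
  expect_equal(unname(posterior_scores(fit, xq)), num / den,
               tolerance = 1e-10)
  # symmetry: the midpoint of the class means scores exactly 0.5
  mid <- matrix(0, ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(unname(posterior_scores(fit, mid)), 0.5, tolerance = 1e-12)
  # monotone in the LD1 projection
  g <- gaussian_clouds(15, 15, p = 3, seed = 14)
  f2 <- fit_lda(g$X, colnames(g$X), g$labels)
  sc <- posterior_scores(f2, g$X)
  proj <- drop(g$X %*% f2$coef_raw)
  expect_equal(order(sc), order(proj))
})

test_that("classification is strict at the threshold", {
  s <- c(a = 0.58, b = 0.5800001, c = 0.1)
  expect_equal(unname(classify(s, 0.58)), c("NC", "AD", "NC"))
  expect_equal(unname(classify(c(0.001, 0.9), 0)), c("AD", "AD"))
  expect_equal(unname(classify(c(0.001, 0.9), 1)), c("NC", "NC"))
  expect_error(classify(0.5, 1.2), "\\[0, 1\\]")
})

test_that("confusion metrics follow their definitions", {
  m <- evaluate_classification(
    c(rep("AD", 60 + 12), rep("NC", 21 + 46)),
    c(rep("AD", 60), rep("NC", 12), rep("AD", 21), rep("NC", 46)))
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(60, 12, 21, 46))
  expect_equal(round(m$accuracy, 2), 0.76)
  expect_equal(round(m$sensitivity, 2), 0.74)
  expect_equal(round(m$specificity, 2), 0.79)

  perfect <- evaluate_classification(c("AD", "NC"), c("AD", "NC"))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  allnc <- evaluate_classification(rep("NC", 4), c("AD", "AD", "NC", "NC"))
  expect_equal(c(allnc$sensitivity, allnc$specificity), c(0, 1))
})

test_that("LOOCV separates well-separated clouds and stays honest on nulls", {
  g <- gaussian_clouds(30, 30, p = 3, delta = 6, seed = 20)
  cv <- loocv_lda(g$X, colnames(g$X), g$labels, threshold = 0.5)
  expect_equal(cv$accuracy, 1)

  # permuted labels: accuracy near the majority-class prior
  accs <- vapply(1:10, function(s) {
    g0 <- gaussian_clouds(35, 25, p = 3, delta = 2, seed = 100 + s)
    set.seed(200 + s)
    loocv_lda(g0$X, colnames(g0$X), sample(g0$labels), threshold = 0.5)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 35 / 60), 0.12)

  # optimism: LOOCV accuracy does not beat resubstitution on average
  diffs <- vapply(1:30, function(s) {
    g1 <- gaussian_clouds(20, 20, p = 4, delta = 1.5, seed = 300 + s)
    fit <- fit_lda(g1$X, colnames(g1$X), g1$labels)
    resub <- evaluate_classification(
      classify(posterior_scores(fit, g1$X), 0.5), g1$labels)$accuracy
    resub - loocv_lda(g1$X, colnames(g1$X), g1$labels, 0.5)$accuracy
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("metrics are invariant to sign flips and column shifts", {
  g <- gaussian_clouds(25, 20, p = 3, delta = 1.5, seed = 22)
  base <- loocv_lda(g$X, colnames(g$X), g$labels, 0.58)
  shifted <- g$X
  shifted[, 2] <- shifted[, 2] + 5  # constant offset, absorbed by the means
  cv2 <- loocv_lda(shifted, colnames(g$X), g$labels, 0.58)
  expect_equal(unclass(base)[c("accuracy", "sensitivity", "specificity")],
               unclass(cv2)[c("accuracy", "sensitivity", "specificity")])

  fit <- fit_lda(g$X, colnames(g$X), g$labels)
  flip <- fit
  flip$coef_raw <- -flip$coef_raw
  flip$class_means <- fit$class_means[c(1, 2)]
  names(flip$class_means) <- c("AD", "NC")
  flip$class_means$AD <- fit$class_means$NC
  flip$class_means$NC <- fit$class_means$AD
  flip$priors <- fit$priors[c("NC", "AD")]
  names(flip$priors) <- c("AD", "NC")
  # flipping the discriminant and relabelling the classes swaps posteriors
  expect_equal(unname(posterior_scores(flip, g$X)),
               unname(1 - posterior_scores(fit, g$X)), tolerance = 1e-12)
})

test_that("threshold scanning optimises accuracy with the stated tie-breaks", {
  scores <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  labels <- c("NC", "NC", "NC", "AD", "AD", "AD")
  res <- scan_thresholds(scores, labels, grid = seq(0.1, 0.9, 0.1))
  expect_equal(res$best, 0.3)  # every separating cut is perfect; lowest wins
  expect_true(all(res$table$accuracy[res$table$threshold == 0.3] == 1))

  single <- scan_thresholds(scores, labels, grid = 0.42)
  expect_equal(single$best, 0.42)

  # imbalanced synthetic scores: the optimum sits near the positive fraction
  set.seed(31)
  n1 <- 81; n0 <- 58
  g <- gaussian_clouds(n1, n0, p = 4, delta = 1.6, seed = 31)
  fit <- fit_lda(g$X, colnames(g$X), g$labels)
  sc <- posterior_scores(fit, g$X)
  fine <- scan_thresholds(sc, g$labels, grid = seq(0.3, 0.8, 0.01))
  expect_lt(abs(fine$best - n1 / (n1 + n0)), 0.15)
})
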