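# Extract an aligned (X, labels) pair over complete cases for a feature set.
lda_design <- function(residuals, features, labels = NULL) {
  if (inherits(residuals, "residual_matrix")) {
    if (is.null(labels)) labels <- unname(residuals$group[rownames(residuals$residuals)])
    residuals <- residuals$residuals
  }
  missing_feats <- setdiff(features, colnames(residuals))
  if (length(missing_feats)) {
    stop("feature(s) not in residual matrix: ", paste(missing_feats, collapse = ", "))
  }
  if (is.null(labels)) stop("labels are required when residuals is a plain matrix")
  X <- residuals[, features, drop = FALSE]
  keep <- stats::complete.cases(X) & !is.na(labels)
  list(X = X[keep, , drop = FALSE], labels = labels[keep])
}

#' Fit a two-class linear discriminant on residual features
#'
#' Gaussian LDA with a shared (unbiased pooled within-class) covariance.
#' The discriminant vector is proportional to
#' `S_pooled^-1 (mu_AD - mu_NC)` and is rescaled to unit within-group
#' variance (`w' S_pooled w = 1`), the convention under which published
#' LD1 coefficients are reported; its global sign is arbitrary, so
#' comparisons with external coefficient sets are made up to sign. Priors
#' are the empirical class fractions.
#'
#' @param residuals a `residual_matrix` (without-Group variant) or a plain
#'   samples x metabolites matrix
#' @param features metabolites to use (subset of the columns)
#' @param labels per-sample `"AD"` / `"NC"`; taken from the residual
#'   matrix when omitted
#' @param threshold posterior-probability cutoff stored with the fit
#'   (default 0.58)
#' @return an `lda_fit`: `features`, `class_means`, `pooled_covariance`,
#'   `priors`, `weights` (LD1, unit within-group variance), `coef_raw`
#'   (unscaled `S^-1` difference, used by the posterior), `threshold`
#' @export
fit_lda <- function(residuals, features, labels = NULL, threshold = 0.58) {
  d <- lda_design(residuals, features, labels)
  X <- d$X
  lab <- d$labels
  n1 <- sum(lab == "AD"); n0 <- sum(lab == "NC")
  if (n1 < 2 || n0 < 2) {
    stop("fit_lda: need >= 2 complete cases per class (AD: ", n1, ", NC: ", n0, ")")
  }
  X1 <- X[lab == "AD", , drop = FALSE]
  X0 <- X[lab == "NC", , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  Sp <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X0, 2, mu0))) /
    (n1 + n0 - 2)
  a <- tryCatch(solve(Sp, mu1 - mu0), error = function(e) {
    stop("fit_lda: singular pooled covariance; collinear feature set {",
         paste(features, collapse = ", "), "}", call. = FALSE)
  })
  d2 <- drop(crossprod(a, Sp %*% a))  # = Mahalanobis^2 between class means
  if (!is.finite(d2) || d2 <= 0) {
    stop("fit_lda: degenerate discriminant (zero between-class separation ",
         "or singular covariance) for {", paste(features, collapse = ", "), "}")
  }
  structure(
    list(features = features,
         class_means = list(AD = mu1, NC = mu0),
         pooled_covariance = Sp,
         priors = c(AD = n1 / (n1 + n0), NC = n0 / (n1 + n0)),
         weights = a / sqrt(d2),
         coef_raw = a,
         threshold = threshold,
         scaling_convention = "unit_within_group_variance",
         n = c(AD = n1, NC = n0)),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("<lda_fit> ", length(x$features), " feature(s): ",
      paste(x$features, collapse = ", "), "\n  LD1: ",
      paste(signif(x$weights, 5), collapse = ", "),
      "\n  priors AD/NC: ", signif(x$priors[1], 3), "/", signif(x$priors[2], 3),
      ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Posterior probability of AD for each sample
#'
#' `P(AD | x)` under the shared-covariance two-class Gaussian model with
#' the fitted priors: a logistic function of the discriminant projection,
#' so scores lie strictly inside (0, 1) and are monotone in LD1.
#'
#' @param fit an `lda_fit`
#' @param residuals a `residual_matrix` or plain matrix holding all the
#'   fit's features
#' @return named vector of posterior scores for the complete cases
#' @export
posterior_scores <- function(fit, residuals) {
  stopifnot(inherits(fit, "lda_fit"))
  if (inherits(residuals, "residual_matrix")) residuals <- residuals$residuals
  X <- residuals[, fit$features, drop = FALSE]
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  mid <- (fit$class_means$AD + fit$class_means$NC) / 2
  logodds <- drop(sweep(X, 2, mid) %*% fit$coef_raw) +
    log(fit$priors[["AD"]] / fit$priors[["NC"]])
  stats::setNames(stats::plogis(logodds), rownames(X))
}

#' Threshold posterior scores into class labels
#'
#' A sample is called AD iff its score is strictly above the threshold;
#' scores equal to the threshold are called control.
#'
#' @param scores posterior scores in `[0, 1]`
#' @param threshold cutoff in `[0, 1]`
#' @return character vector of `"AD"` / `"NC"`
#' @export
classify <- function(scores, threshold = 0.58) {
  if (threshold < 0 || threshold > 1) stop("classify: threshold must lie in [0, 1]")
  stats::setNames(ifelse(scores > threshold, "AD", "NC"), names(scores))
}

#' Confusion-matrix metrics with AD as the positive class
#'
#' @param predicted,truth character vectors of `"AD"` / `"NC"`, aligned
#' @return a `confusion_metrics` list: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`
#' @export
evaluate_classification <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("evaluate_classification: length mismatch")
  }
  tp <- sum(predicted == "AD" & truth == "AD")
  fp <- sum(predicted == "AD" & truth == "NC")
  tn <- sum(predicted == "NC" & truth == "NC")
  fn <- sum(predicted == "NC" & truth == "AD")
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / (tp + fp + tn + fn),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("accuracy ", round(x$accuracy, 3), ", sensitivity ",
      round(x$sensitivity, 3), ", specificity ", round(x$specificity, 3),
      "  (tp ", x$tp, ", fp ", x$fp, ", tn ", x$tn, ", fn ", x$fn, ")\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out cross-validation of the LDA step
#'
#' Each complete case is held out once, the discriminant refit on the
#' rest, and the held-out sample scored and thresholded; the pooled
#' held-out predictions give one confusion matrix. Only the LDA is refit:
#' the residuals stay as computed on the full cohort, matching a pipeline
#' that residualizes first and cross-validates classification afterwards
#' (the induced optimism is discussed in the vignette; re-residualize per
#' fold upstream if a strict protocol is required).
#'
#' @inheritParams fit_lda
#' @param threshold posterior cutoff applied to each held-out score
#' @return a `confusion_metrics` with attribute `scores` (held-out
#'   posterior per sample)
#' @export
loocv_lda <- function(residuals, features, labels = NULL, threshold = 0.58) {
  d <- lda_design(residuals, features, labels)
  n <- nrow(d$X)
  if (n < 4) stop("loocv_lda: need >= 4 complete cases")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      fit_lda(d$X[-i, , drop = FALSE], features, d$labels[-i],
              threshold = threshold),
      error = function(e) stop("loocv_lda: fold ", i, " (held-out sample ",
                               rownames(d$X)[i], "): ", conditionMessage(e),
                               call. = FALSE)
    )
    scores[i] <- posterior_scores(fit_i, d$X[i, , drop = FALSE])
  }
  names(scores) <- rownames(d$X)
  out <- evaluate_classification(classify(scores, threshold), d$labels)
  attr(out, "scores") <- scores
  out
}

#' Scan classification thresholds
#'
#' Evaluates a grid of posterior cutoffs and reports the optimum: highest
#' accuracy, ties broken by the smaller |sensitivity - specificity|, then
#' by the lower threshold.
#'
#' @param scores posterior scores
#' @param labels true `"AD"` / `"NC"` labels, aligned with `scores`
#' @param grid numeric vector of thresholds (default 0.1 ... 0.9)
#' @return list with `table` (one row per threshold) and `best` (the
#'   optimal threshold)
#' @export
scan_thresholds <- function(scores, labels, grid = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(grid, function(t) {
    m <- evaluate_classification(classify(scores, t), labels)
    data.frame(threshold = t, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity)
  })
  tab <- do.call(rbind, rows)
  balance <- abs(tab$sensitivity - tab$specificity)
  ord <- order(-tab$accuracy, balance, tab$threshold)
  list(table = tab, best = tab$threshold[ord[1]])
}
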