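#' Exact number of k-metabolite panels
#'
#' @param n_candidates candidate pool size
#' @param k panel size, `0 <= k <= n_candidates`
#' @return the binomial coefficient `C(n_candidates, k)`, exact
#' @export
count_combinations <- function(n_candidates, k) {
  if (k < 0 || k > n_candidates) stop("count_combinations: need 0 <= k <= n_candidates")
  round(choose(n_candidates, k))
}

# Lexicographic successor of a k-combination of 1..n; NULL when exhausted.
next_combination <- function(idx, n) {
  k <- length(idx)
  i <- k
  while (i >= 1 && idx[i] == n - k + i) i <- i - 1
  if (i == 0) return(NULL)
  idx[i] <- idx[i] + 1
  if (i < k) idx[(i + 1):k] <- idx[i] + seq_len(k - i)
  idx
}

# Precompute the class statistics every subset fit reuses: class means and
# centered Gram matrices over the complete cases of the full candidate set.
search_stats <- function(residuals, candidates, labels = NULL) {
  d <- lda_design(residuals, candidates, labels)
  X <- d$X
  y <- d$labels
  n1 <- sum(y == "AD"); n0 <- sum(y == "NC")
  if (n1 < 2 || n0 < 2) stop("search: need >= 2 complete cases per class")
  X1 <- X[y == "AD", , drop = FALSE]
  X0 <- X[y == "NC", , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  list(X = X, y = y, is_ad = y == "AD", n1 = n1, n0 = n0,
       mu1 = mu1, mu0 = mu0,
       C1 = crossprod(sweep(X1, 2, mu1)), C0 = crossprod(sweep(X0, 2, mu0)))
}

# Resubstitution metrics for one subset, from precomputed stats.
# Returns NULL when the pooled covariance is singular.
subset_resub <- function(st, S, threshold) {
  Tm <- st$C1[S, S, drop = FALSE] + st$C0[S, S, drop = FALSE]
  delta <- st$mu1[S] - st$mu0[S]
  n <- st$n1 + st$n0
  a <- tryCatch(solve(Tm, delta) * (n - 2), error = function(e) NULL)
  if (is.null(a) || !all(is.finite(a))) return(NULL)
  mid <- (st$mu1[S] + st$mu0[S]) / 2
  logodds <- drop(sweep(st$X[, S, drop = FALSE], 2, mid) %*% a) +
    log(st$n1 / st$n0)
  pred <- logodds > stats::qlogis(threshold)
  tp <- sum(pred & st$is_ad); fp <- sum(pred & !st$is_ad)
  fn <- sum(!pred & st$is_ad); tn <- sum(!pred & !st$is_ad)
  c(accuracy = (tp + tn) / n, sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# Leave-one-out metrics for one subset via rank-one downdates of the
# pooled Gram matrix (Sherman-Morrison), refitting means and priors per
# fold without re-inverting. Returns NULL on a singular full-data fit.
subset_loocv <- function(st, S, threshold) {
  Tm <- st$C1[S, S, drop = FALSE] + st$C0[S, S, drop = FALSE]
  Tinv <- tryCatch(solve(Tm), error = function(e) NULL)
  if (is.null(Tinv)) return(NULL)
  Xs <- st$X[, S, drop = FALSE]
  n <- st$n1 + st$n0
  delta <- st$mu1[S] - st$mu0[S]
  cut <- stats::qlogis(threshold)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n)) {
    xi <- Xs[i, ]
    if (st$is_ad[i]) {
      nk <- st$n1
      d <- xi - st$mu1[S]
      delta_i <- delta - d / (nk - 1)
      mid_i <- (st$mu1[S] + st$mu0[S]) / 2 - d / (2 * (nk - 1))
      prior_lo <- log((st$n1 - 1) / st$n0)
    } else {
      nk <- st$n0
      d <- xi - st$mu0[S]
      delta_i <- delta + d / (nk - 1)
      mid_i <- (st$mu1[S] + st$mu0[S]) / 2 - d / (2 * (nk - 1))
      prior_lo <- log(st$n1 / (st$n0 - 1))
    }
    r <- nk / (nk - 1)
    v <- Tinv %*% d
    denom <- 1 - r * drop(crossprod(d, v))
    if (!is.finite(denom) || abs(denom) < 1e-12) return(NULL)
    Tinv_i <- Tinv + (r / denom) * tcrossprod(v)
    a_i <- (n - 3) * drop(Tinv_i %*% delta_i)
    logodds <- drop(crossprod(a_i, xi - mid_i)) + prior_lo
    pred <- logodds > cut
    if (pred && st$is_ad[i]) tp <- tp + 1L
    else if (pred) fp <- fp + 1L
    else if (st$is_ad[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(accuracy = (tp + tn) / n, sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

#' Exhaustive search over k-metabolite panels
#'
#' Evaluates every k-subset of the candidate metabolites with a linear
#' discriminant on their residuals: posterior scores are thresholded and
#' summarized as accuracy / sensitivity / specificity, optionally also
#' under leave-one-out cross-validation. Evaluation streams through the
#' subsets with a bounded top-n buffer, so memory does not grow with
#' `C(n, k)`; per-subset fits reuse class means and centered Gram matrices
#' computed once over the candidate pool (complete cases across all
#' candidates, the merged-sample convention). Subsets with a singular
#' pooled covariance are skipped and counted, not fatal.
#'
#' Ranking: accuracy (descending), then sensitivity, then specificity,
#' then lexicographic feature names. With `loocv = TRUE` the ranking and
#' the `min_accuracy` filter use the cross-validated metrics.
#'
#' @param residuals a `residual_matrix` (without-Group variant) or matrix
#' @param k panel size (>= 1)
#' @param candidates candidate metabolites; defaults to every
#'   non-concomitant column
#' @param labels per-sample `"AD"`/`"NC"` if `residuals` is a plain matrix
#' @param threshold posterior cutoff (default 0.58)
#' @param min_accuracy report only panels at or above this accuracy
#' @param top_n number of panels to keep (default 10)
#' @param loocv also cross-validate each panel and rank by the LOOCV
#'   metrics?
#' @param chunk_size how many records to buffer before pruning to `top_n`
#' @return data.frame of the top panels (`features` is a `+`-joined,
#'   sorted name list) with resubstitution and, if requested, LOOCV
#'   metrics; attribute `run_log` records evaluated / skipped counts
#' @export
search_panels <- function(residuals, k, candidates = NULL, labels = NULL,
                          threshold = 0.58, min_accuracy = 0, top_n = 10,
                          loocv = FALSE, chunk_size = 20000L) {
  if (k < 1) stop("search_panels: k must be >= 1")
  if (is.null(candidates)) {
    if (!inherits(residuals, "residual_matrix")) {
      stop("search_panels: candidates are required for a plain matrix")
    }
    candidates <- colnames(residuals$residuals)
  }
  candidates <- sort(candidates)
  n_cand <- length(candidates)
  if (k > n_cand) stop("search_panels: k exceeds the number of candidates")
  st <- search_stats(residuals, candidates, labels)

  buf <- list()
  n_eval <- 0; n_skip <- 0
  prune <- function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(NULL)
    tab <- do.call(rbind, rows)
    ord <- order(-tab$rank_accuracy, -tab$rank_sensitivity,
                 -tab$rank_specificity, tab$features)
    tab <- tab[ord, , drop = FALSE]
    utils::head(tab, top_n)
  }
  pruned <- NULL

  idx <- seq_len(k)
  repeat {
    S <- idx
    rs <- subset_resub(st, candidates[S], threshold)
    cv <- if (!is.null(rs) && loocv) subset_loocv(st, candidates[S], threshold) else NULL
    if (is.null(rs) || (loocv && is.null(cv))) {
      n_skip <- n_skip + 1
    } else {
      n_eval <- n_eval + 1
      rank_m <- if (loocv) cv else rs
      if (rank_m[["accuracy"]] >= min_accuracy) {
        row <- data.frame(
          features = paste(candidates[S], collapse = "+"), k = k,
          threshold = threshold,
          accuracy = rs[["accuracy"]], sensitivity = rs[["sensitivity"]],
          specificity = rs[["specificity"]],
          rank_accuracy = rank_m[["accuracy"]],
          rank_sensitivity = rank_m[["sensitivity"]],
          rank_specificity = rank_m[["specificity"]],
          stringsAsFactors = FALSE)
        if (loocv) {
          row$loocv_accuracy <- cv[["accuracy"]]
          row$loocv_sensitivity <- cv[["sensitivity"]]
          row$loocv_specificity <- cv[["specificity"]]
        }
        buf[[length(buf) + 1]] <- row
        if (length(buf) >= chunk_size) {
          pruned <- prune(c(list(pruned), buf))
          buf <- list()
        }
      }
    }
    idx <- next_combination(idx, n_cand)
    if (is.null(idx)) break
  }
  out <- prune(c(list(pruned), buf))
  if (is.null(out)) {
    out <- data.frame(features = character(0), k = integer(0),
                      threshold = numeric(0), accuracy = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      rank_accuracy = numeric(0), rank_sensitivity = numeric(0),
                      rank_specificity = numeric(0), stringsAsFactors = FALSE)
    if (loocv) {
      out$loocv_accuracy <- out$loocv_sensitivity <-
        out$loocv_specificity <- numeric(0)
    }
  }
  out$validated <- rep(if (loocv) "loocv" else "resubstitution", nrow(out))
  rownames(out) <- NULL
  out$rank_accuracy <- out$rank_sensitivity <- out$rank_specificity <- NULL
  attr(out, "run_log") <- list(
    n_candidates = n_cand, k = k,
    n_combinations = count_combinations(n_cand, k),
    n_evaluated = n_eval, n_skipped = n_skip,
    threshold = threshold, loocv = loocv)
  out
}

#' Evaluate a panel augmented by one extra metabolite
#'
#' Refits the (k+1)-panel obtained by adding `extra` to an existing
#' record's features and reports its metrics next to the original — no
#' claim that augmentation improves anything; the caller compares. A
#' collinear addition (e.g. a duplicated feature) yields a skip: metrics
#' `NA` and `skipped = TRUE`.
#'
#' @param record one row of a [search_panels()] result
#' @param residuals,labels as in [search_panels()]
#' @param extra metabolite to add
#' @param loocv cross-validate the augmented panel too?
#' @return one-row data.frame in the record layout, plus `skipped`
#' @export
augment_best <- function(record, residuals, labels = NULL, extra,
                         loocv = FALSE) {
  feats <- sort(c(strsplit(record$features, "+", fixed = TRUE)[[1]], extra))
  threshold <- record$threshold
  st <- tryCatch(search_stats(residuals, feats, labels), error = function(e) NULL)
  rs <- if (!is.null(st)) subset_resub(st, feats, threshold) else NULL
  if (is.null(rs)) {
    return(data.frame(features = paste(feats, collapse = "+"),
                      k = length(feats), threshold = threshold,
                      accuracy = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_, skipped = TRUE,
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(features = paste(feats, collapse = "+"),
                    k = length(feats), threshold = threshold,
                    accuracy = rs[["accuracy"]],
                    sensitivity = rs[["sensitivity"]],
                    specificity = rs[["specificity"]], skipped = FALSE,
                    stringsAsFactors = FALSE)
  if (loocv) {
    cv <- subset_loocv(st, feats, threshold)
    out$loocv_accuracy <- if (is.null(cv)) NA_real_ else cv[["accuracy"]]
    out$loocv_sensitivity <- if (is.null(cv)) NA_real_ else cv[["sensitivity"]]
    out$loocv_specificity <- if (is.null(cv)) NA_real_ else cv[["specificity"]]
  }
  out
}

#' Lay a search result out as a family-column panel table
#'
#' One row per panel; one column per biochemical family listing that
#' panel's members of the family, each annotated with its direction of
#' change in AD (`(+)` up, `(-)` down) when a contrast table is given.
#'
#' @param records a [search_panels()] result
#' @param family_map named metabolite -> family vector
#' @param contrasts optional [group_contrasts()] table for the direction
#'   annotations
#' @return data.frame with one column per family plus the metric columns
#' @export
format_panel_table <- function(records, family_map, contrasts = NULL) {
  fams <- unique(unname(family_map))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    feats <- strsplit(records$features[i], "+", fixed = TRUE)[[1]]
    lab <- feats
    if (!is.null(contrasts)) {
      idx <- match(feats, contrasts$metabolite)
      lab <- paste0(feats, ifelse(is.na(idx), "", ifelse(
        contrasts$direction[idx] == "up_in_AD", " (+)", " (-)")))
    }
    cells <- vapply(fams, function(f) {
      paste(lab[family_map[feats] == f], collapse = ", ")
    }, "")
    as.data.frame(as.list(cells), check.names = FALSE,
                  stringsAsFactors = FALSE)
  })
  cbind(do.call(rbind, rows),
        records[, intersect(c("accuracy", "sensitivity", "specificity",
                              "loocv_accuracy", "loocv_sensitivity",
                              "loocv_specificity", "validated"),
                            names(records)), drop = FALSE])
}
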