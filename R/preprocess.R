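#' @name preprocessing
#' @title Cohort cleaning filters
#'
#' @description
#' Three filters applied in this order: named sample exclusion, below-LOD
#' missingness filtering, and per-family outlier-sample exclusion. The two
#' per-family filters do not drop a sample from the whole cohort: they mask
#' its entries within the offending family only (a sample may survive in
#' other families), which is how family-wise sample tallies like "152
#' samples, 14 metabolites" arise from one shared table. Each filter
#' returns the filtered cohort plus a `filter_report`.
NULL

new_filter_report <- function(step, removed_samples, removed_metabolites,
                              before, after) {
  structure(
    list(step = step,
         removed_samples = removed_samples,
         removed_metabolites = removed_metabolites,
         counts_before = before, counts_after = after),
    class = "filter_report"
  )
}

empty_removals <- function() {
  data.frame(sample_id = character(0), family = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

empty_met_removals <- function() {
  data.frame(metabolite = character(0), family = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report:", x$step, "> removed", nrow(x$removed_samples),
      "sample entries,", nrow(x$removed_metabolites), "metabolites\n")
  invisible(x)
}

#' Drop explicitly named samples
#'
#' Removes listed samples from the whole cohort (all families). Unknown
#' names are tolerated and reported with a warning, not an error.
#'
#' @param x a [cohort()]
#' @param names character vector of sample ids to drop (may be empty)
#' @return list with elements `cohort` and `report`
#' @export
exclude_named_samples <- function(x, names = character(0)) {
  stopifnot(inherits(x, "metab_cohort"))
  before <- family_counts(x)
  known <- intersect(names, x$samples$sample_id)
  unknown <- setdiff(names, known)
  if (length(unknown)) {
    warning("exclude_named_samples: unknown sample id(s) ignored: ",
            paste(unknown, collapse = ", "))
  }
  if (length(known)) {
    keep <- !(x$samples$sample_id %in% known)
    x <- cohort(x$samples[keep, , drop = FALSE],
                x$abundances[keep, , drop = FALSE],
                x$family_map)
  }
  removed <- if (length(known)) {
    data.frame(sample_id = known, family = "*", reason = "named_exclusion",
               stringsAsFactors = FALSE)
  } else empty_removals()
  list(cohort = x,
       report = new_filter_report("named_exclusion", removed,
                                  empty_met_removals(), before,
                                  family_counts(x)))
}

# samples still present in a family (>= 1 observed value there)
present_in_family <- function(x, cols) {
  rowSums(!is.na(x$abundances[, cols, drop = FALSE])) > 0L
}

#' Drop samples with excess below-LOD missingness, per family
#'
#' Within each family, a sample whose fraction of missing metabolite values
#' exceeds `max_missing_frac` is removed from that family (its entries
#' masked). Remaining missing entries are left as `NA` and handled
#' pairwise / per model fit downstream — no imputation. A sample already
#' fully masked in a family is treated as absent from it, which makes the
#' filter idempotent.
#'
#' @param x a [cohort()]
#' @param max_missing_frac tolerated missing fraction, in `[0, 1]`
#' @return list with elements `cohort` and `report`
#' @export
drop_low_quality <- function(x, max_missing_frac = 0.2) {
  stopifnot(inherits(x, "metab_cohort"))
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must lie in [0, 1]")
  }
  before <- family_counts(x)
  removed <- empty_removals()
  ab <- x$abundances
  for (f in unique(x$family_map)) {
    cols <- names(x$family_map)[x$family_map == f]
    present <- present_in_family(x, cols)
    frac <- rowMeans(is.na(ab[, cols, drop = FALSE]))
    drop <- present & frac > max_missing_frac
    if (any(drop)) {
      ab[drop, cols] <- NA_real_
      removed <- rbind(removed, data.frame(
        sample_id = x$samples$sample_id[drop], family = f,
        reason = "excess_missing", stringsAsFactors = FALSE))
    }
    if (!any(present & !drop)) {
      stop("drop_low_quality: family '", f, "' left without samples")
    }
  }
  x$abundances <- ab
  list(cohort = x,
       report = new_filter_report("low_quality", removed, empty_met_removals(),
                                  before, family_counts(x)))
}

#' Exclude samples with an excess of outlying metabolite values, per family
#'
#' A value is flagged as an outlier when it lies more than `sd_mult`
#' standard deviations from its metabolite's mean (computed among samples
#' present in the family). A sample is excluded from a family when its
#' flagged fraction of that family's metabolites is strictly greater than
#' `max_outlier_frac`. Metabolites with zero SD flag nothing (degenerate).
#'
#' @param x a [cohort()]
#' @param sd_mult flagging threshold in SD units (> 0)
#' @param max_outlier_frac tolerated flagged fraction (strict `>` rule)
#' @param scale `"log10"` (default; all downstream modeling is log10) or
#'   `"raw"` to compute z-scores on the raw abundance scale
#' @return list with elements `cohort` and `report`
#' @export
filter_outlier_samples <- function(x, sd_mult = 3, max_outlier_frac = 0.10,
                                   scale = c("log10", "raw")) {
  stopifnot(inherits(x, "metab_cohort"))
  if (sd_mult <= 0) stop("sd_mult must be > 0")
  scale <- match.arg(scale)
  before <- family_counts(x)
  removed <- empty_removals()
  ab <- x$abundances
  vals <- if (scale == "log10") log10(ab) else ab
  for (f in unique(x$family_map)) {
    cols <- names(x$family_map)[x$family_map == f]
    sub <- vals[, cols, drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 2, stats::sd, na.rm = TRUE)
    z <- sweep(sweep(sub, 2, mu, "-"), 2, sdv, "/")
    z[, !is.finite(sdv) | sdv == 0] <- 0  # zero-SD metabolites flag nothing
    flags <- rowSums(abs(z) > sd_mult, na.rm = TRUE)
    present <- present_in_family(x, cols)
    drop <- present & (flags / length(cols)) > max_outlier_frac
    if (any(drop)) {
      ab[drop, cols] <- NA_real_
      removed <- rbind(removed, data.frame(
        sample_id = x$samples$sample_id[drop], family = f,
        reason = "excess_outliers", stringsAsFactors = FALSE))
    }
  }
  x$abundances <- ab
  list(cohort = x,
       report = new_filter_report("outlier_filter", removed, empty_met_removals(),
                                  before, family_counts(x)))
}

#' Run the three cleaning filters in the standard order
#'
#' Named exclusion, then below-LOD missingness filtering, then per-family
#' outlier exclusion.
#'
#' @inheritParams exclude_named_samples
#' @inheritParams drop_low_quality
#' @inheritParams filter_outlier_samples
#' @return list with `cohort` and `reports` (one `filter_report` per step)
#' @export
preprocess_cohort <- function(x, names = character(0),
                              max_missing_frac = 0.2,
                              sd_mult = 3, max_outlier_frac = 0.10,
                              scale = "log10") {
  s1 <- exclude_named_samples(x, names)
  s2 <- drop_low_quality(s1$cohort, max_missing_frac)
  s3 <- filter_outlier_samples(s2$cohort, sd_mult, max_outlier_frac, scale)
  list(cohort = s3$cohort,
       reports = list(named = s1$report, low_quality = s2$report,
                      outliers = s3$report))
}

#' Serialize a filter report (or list of them) to JSON
#' @param report a `filter_report` or list of them
#' @param path output path
#' @return the path, invisibly
#' @export
write_filter_report <- function(report, path) {
  if (inherits(report, "filter_report")) report <- list(report)
  jsonlite::write_json(lapply(report, unclass), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
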