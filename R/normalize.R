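#' Fit the concomitant normalization model for one metabolite
#'
#' Ordinary least squares on the log10 abundance of `response` with design
#' `{1, Age, Sex, Age:Sex, Fasting_time, [Group], log10(concomitant)}`,
#' over complete cases. The Group term (0 = control, 1 = AD) is included
#' when `include_group = TRUE`; the without-Group variant is the one whose
#' residuals feed classification, so class information never leaks into
#' the features.
#'
#' @param x a [cohort()]
#' @param response metabolite to model
#' @param concomitant concomitant metabolite (same family, different
#'   metabolite)
#' @param include_group include the Group term?
#' @param min_cases minimum complete cases required (default 8)
#' @return a `norm_fit`: coefficients, adjusted R-squared, overall F-test
#'   p-value, per-term p-values, residuals (named by sample id), `n_used`
#' @export
fit_normalization_model <- function(x, response, concomitant,
                                    include_group = TRUE, min_cases = 8) {
  stopifnot(inherits(x, "metab_cohort"))
  if (response == concomitant) stop("response and concomitant must differ")
  fam_r <- x$family_map[[response]]
  fam_c <- x$family_map[[concomitant]]
  if (is.null(fam_r) || is.null(fam_c) || fam_r != fam_c) {
    stop("response '", response, "' and concomitant '", concomitant,
         "' must belong to the same family")
  }
  df <- covariate_frame(x)
  df$y <- log10(x$abundances[, response])
  df$log10_conc <- log10(x$abundances[, concomitant])
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  form <- if (include_group) {
    y ~ Age * Sex + Fasting_time + Group + log10_conc
  } else {
    y ~ Age * Sex + Fasting_time + log10_conc
  }
  p_terms <- if (include_group) 6L else 5L  # non-intercept df of the design
  if (nrow(df) < max(min_cases, p_terms + 2L)) {
    stop("fit_normalization_model: only ", nrow(df),
         " complete cases for '", response, "' (need >= ",
         max(min_cases, p_terms + 2L), ")")
  }
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  if (any(sm$aliased)) {
    stop("fit_normalization_model: rank-deficient design for '", response,
         "'; collinear term(s): ",
         paste(names(sm$aliased)[sm$aliased], collapse = ", "))
  }
  fstat <- sm$fstatistic
  res <- stats::setNames(stats::residuals(fit), rownames(df))
  structure(
    list(response = response, concomitant = concomitant, family = fam_r,
         include_group = include_group,
         terms = names(stats::coef(fit)),
         coefficients = stats::coef(fit),
         adj_r2 = sm$adj.r.squared,
         r2 = sm$r.squared,
         f_pvalue = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
         term_pvalues = sm$coefficients[, "Pr(>|t|)"],
         n_used = nrow(df),
         residuals = res,
         lm = fit),
    class = "norm_fit"
  )
}

#' @export
print.norm_fit <- function(x, ...) {
  cat("<norm_fit> log10(", x$response, ") ~ Age * Sex + Fasting_time",
      if (x$include_group) " + Group", " + log10(", x$concomitant, ")\n",
      "  adj R2 = ", signif(x$adj_r2, 3), ", F p = ", signif(x$f_pvalue, 3),
      ", n = ", x$n_used, "\n", sep = "")
  invisible(x)
}

#' Score concomitant candidates for one family
#'
#' For every candidate metabolite, fits the with-Group normalization model
#' to each other member of the family and averages the adjusted R-squared
#' and overall F-test p-value over those models. Candidates are ranked by
#' mean adjusted R-squared (descending), ties broken by smaller mean F
#' p-value, then lexicographic name. A member whose fit fails is skipped
#' with a warning and the candidate is scored over the remaining fits.
#'
#' @param x a [cohort()]
#' @param family family label (>= 3 metabolites)
#' @param include_group include the Group term in the scoring model?
#'   Default `TRUE` (the variant whose averages a selection table reports)
#' @return data.frame with `family`, `candidate`, `mean_adj_r2`,
#'   `mean_f_pvalue`, `n_models`, sorted best first
#' @export
score_concomitants <- function(x, family, include_group = TRUE) {
  members <- family_members(x, family)
  if (length(members) < 3) {
    stop("score_concomitants: family '", family, "' has fewer than 3 metabolites")
  }
  rows <- lapply(members, function(cand) {
    others <- setdiff(members, cand)
    fits <- lapply(others, function(m) {
      tryCatch(fit_normalization_model(x, m, cand, include_group = include_group),
               error = function(e) {
                 warning("score_concomitants: skipping ", m, " ~ ", cand,
                         ": ", conditionMessage(e))
                 NULL
               })
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    data.frame(family = family, candidate = cand,
               mean_adj_r2 = mean(vapply(fits, `[[`, 0, "adj_r2")),
               mean_f_pvalue = mean(vapply(fits, `[[`, 0, "f_pvalue")),
               n_models = length(fits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || !nrow(out)) {
    stop("score_concomitants: no candidate could be scored in family '", family, "'")
  }
  out[order(-out$mean_adj_r2, out$mean_f_pvalue, out$candidate), , drop = FALSE]
}

#' Choose one concomitant per family
#'
#' Takes the top-ranked candidate from each family's score table unless an
#' override names another member — the hook through which biological
#' relevance (which no statistic computes) enters the selection.
#'
#' @param scores a list of score tables from [score_concomitants()] (or one
#'   combined data.frame with a `family` column)
#' @param overrides named character vector, family -> metabolite
#' @return named character vector mapping family to its concomitant
#' @export
select_concomitants <- function(scores, overrides = NULL) {
  if (is.data.frame(scores)) scores <- split(scores, scores$family)
  out <- character(0)
  for (tab in scores) {
    if (is.null(tab) || !nrow(tab)) stop("select_concomitants: empty score table")
    fam <- tab$family[1]
    pick <- tab$candidate[which.max(tab$mean_adj_r2)]
    if (!is.null(overrides) && fam %in% names(overrides)) {
      ov <- overrides[[fam]]
      if (!ov %in% tab$candidate) {
        stop("select_concomitants: override '", ov,
             "' is not a scored member of family '", fam, "'")
      }
      pick <- ov
    }
    out[fam] <- pick
  }
  out
}

#' The conventional concomitant choices for the six retained families
#'
#' Symmetric dimethylarginine for the amino-acid-related group,
#' taurodeoxycholic acid for bile acids, spermine for biogenic amines,
#' 3-indoleacetic acid for indoles, succinic acid for carboxylic acids and
#' docosahexaenoic acid for fatty acids.
#'
#' @return named character vector, family -> metabolite
#' @export
study_concomitants <- function() {
  c("AA-related" = "SDMA", "Bile Acids" = "TDCA",
    "Biogenic Amines" = "Spermine", "Indoles" = "3-IAA",
    "Carboxylic Acids" = "Suc", "Fatty Acids" = "DHA")
}

#' Residualize every non-concomitant metabolite
#'
#' Fits the normalization model per metabolite (against its family's
#' concomitant) and returns the matrix of residuals
#' `e = log10(observed) - log10(predicted)` over each model's complete
#' cases (`NA` where inputs are missing). Concomitant metabolites are
#' excluded from the columns: they are the normalizers, not features.
#'
#' @param x a [cohort()]
#' @param concomitants named character vector family -> metabolite,
#'   covering every family with metabolites to residualize
#' @param include_group with-Group variant (for contrasts / correlation
#'   heatmaps) or without-Group variant (for classification)?
#' @return a `residual_matrix`: `residuals` (samples x metabolites),
#'   `model_variant`, `concomitants`, `family_map`, and `fits` (per
#'   metabolite `norm_fit`)
#' @export
compute_residuals <- function(x, concomitants, include_group = FALSE) {
  stopifnot(inherits(x, "metab_cohort"))
  fams <- unique(x$family_map)
  missing_fams <- setdiff(fams, names(concomitants))
  if (length(missing_fams)) {
    stop("compute_residuals: no concomitant for family(s): ",
         paste(missing_fams, collapse = ", "))
  }
  bad <- vapply(fams, function(f) !concomitants[[f]] %in% family_members(x, f), TRUE)
  if (any(bad)) {
    stop("compute_residuals: concomitant not a member of its family: ",
         paste(concomitants[fams[bad]], collapse = ", "))
  }
  targets <- setdiff(colnames(x$abundances), unname(concomitants[fams]))
  res <- matrix(NA_real_, nrow(x$samples), length(targets),
                dimnames = list(x$samples$sample_id, targets))
  fits <- vector("list", length(targets))
  names(fits) <- targets
  for (m in targets) {
    fam <- x$family_map[[m]]
    fit <- tryCatch(
      fit_normalization_model(x, m, concomitants[[fam]],
                              include_group = include_group),
      error = function(e) stop("compute_residuals: '", m, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    res[names(fit$residuals), m] <- fit$residuals
    fit$lm <- NULL  # keep the matrix light; refit if a model is needed
    fits[[m]] <- fit
  }
  structure(
    list(residuals = res,
         model_variant = if (include_group) "with_group" else "without_group",
         concomitants = concomitants[fams],
         family_map = x$family_map[targets],
         group = stats::setNames(x$samples$group, x$samples$sample_id),
         fits = fits),
    class = "residual_matrix"
  )
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat("<residual_matrix> ", nrow(x$residuals), " samples x ",
      ncol(x$residuals), " metabolites (", x$model_variant, " model)\n",
      sep = "")
  invisible(x)
}

#' Selection report in the layout of a concomitant table
#'
#' One row per family: the model formula, the mean adjusted R-squared and
#' mean F-test p-value of the selected concomitant's models.
#'
#' @param scores list of score tables from [score_concomitants()]
#' @param concomitants selection from [select_concomitants()]
#' @return data.frame with `family`, `model`, `mean_adj_r2`, `mean_f_pvalue`
#' @export
concomitant_report <- function(scores, concomitants) {
  if (is.data.frame(scores)) scores <- split(scores, scores$family)
  rows <- lapply(scores, function(tab) {
    fam <- tab$family[1]
    sel <- tab[tab$candidate == concomitants[[fam]], , drop = FALSE]
    if (!nrow(sel)) stop("concomitant_report: '", concomitants[[fam]],
                         "' not scored in family '", fam, "'")
    data.frame(
      family = fam,
      model = paste0("log10(metabolite) ~ Group + Age * Sex + Fasting_time + log10(",
                     sel$candidate, ")"),
      mean_adj_r2 = sel$mean_adj_r2, mean_f_pvalue = sel$mean_f_pvalue,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
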