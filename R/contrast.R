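#' Direction and significance of the disease effect for one metabolite
#'
#' Reads the Group coefficient off a with-Group normalization fit: the
#' metabolite tends up in AD iff the coefficient is strictly positive (an
#' exactly-zero coefficient is reported as down, by the strict rule), and
#' the group p-value is the coefficient's two-sided t-test p.
#'
#' @param fit a `norm_fit` fitted with `include_group = TRUE`
#' @return one-row data.frame: `metabolite`, `family`, `direction`,
#'   `group_coef`, `group_pvalue`
#' @export
contrast_metabolite <- function(fit) {
  stopifnot(inherits(fit, "norm_fit"))
  if (!"Group" %in% fit$terms) {
    stop("contrast_metabolite: fit has no Group term (without-Group variant?)")
  }
  co <- fit$coefficients[["Group"]]
  data.frame(
    metabolite = fit$response, family = fit$family,
    direction = if (co > 0) "up_in_AD" else "down_in_AD",
    group_coef = co,
    group_pvalue = unname(fit$term_pvalues[["Group"]]),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement); output order matches input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`
#' @param method only `"BH"` is offered
#' @return adjusted p-values, same length and order
#' @export
adjust_pvalues <- function(pvalues, method = "BH") {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("adjust_pvalues: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = method)
}

#' Per-metabolite group contrasts across the cohort
#'
#' Builds the with-Group residualization fits for every non-concomitant
#' metabolite, extracts direction of change and group p-value, and adds a
#' BH-adjusted p plus a significance tier (`none`, `nominal` for p < 0.05,
#' `adjusted` for adjusted p < 0.05). Adjustment is applied within each
#' family by default — significance is framed within a family's heatmap —
#' or globally over all metabolites.
#'
#' @param x a [cohort()]
#' @param concomitants named family -> metabolite vector
#' @param scope `"per_family"` (default) or `"global"` BH scope
#' @param alpha significance threshold for the tiers (default 0.05)
#' @return data.frame, one row per metabolite, with `direction`,
#'   `group_pvalue`, `group_p_adjusted`, `significance_tier`
#' @export
group_contrasts <- function(x, concomitants, scope = c("per_family", "global"),
                            alpha = 0.05) {
  scope <- match.arg(scope)
  rm <- compute_residuals(x, concomitants, include_group = TRUE)
  tab <- do.call(rbind, lapply(rm$fits, contrast_metabolite))
  rownames(tab) <- NULL
  tab$group_p_adjusted <- NA_real_
  if (scope == "per_family") {
    for (f in unique(tab$family)) {
      i <- tab$family == f
      tab$group_p_adjusted[i] <- adjust_pvalues(tab$group_pvalue[i])
    }
  } else {
    tab$group_p_adjusted <- adjust_pvalues(tab$group_pvalue)
  }
  tab$significance_tier <- ifelse(
    tab$group_p_adjusted < alpha, "adjusted",
    ifelse(tab$group_pvalue < alpha, "nominal", "none"))
  tab
}

#' Residual Pearson correlation matrix for one family
#'
#' Pairwise-complete Pearson correlations between the residuals of a
#' family's metabolites (the concomitant is already excluded from the
#' residual matrix). The number of complete pairs behind each coefficient
#' is recorded.
#'
#' @param rm a `residual_matrix` (with-Group variant for the heatmaps)
#' @param family family label with >= 2 non-concomitant metabolites
#' @return a `correlation_matrix`: `family`, `r` (symmetric, unit
#'   diagonal), `n_pairs`
#' @export
residual_correlations <- function(rm, family) {
  stopifnot(inherits(rm, "residual_matrix"))
  cols <- names(rm$family_map)[rm$family_map == family]
  if (length(cols) < 2) {
    stop("residual_correlations: family '", family,
         "' has fewer than 2 non-concomitant metabolites")
  }
  sub <- rm$residuals[, cols, drop = FALSE]
  r <- stats::cor(sub, use = "pairwise.complete.obs")
  diag(r) <- 1
  structure(
    list(family = family, r = r, n_pairs = crossprod(!is.na(sub))),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> family '", x$family, "', ",
      ncol(x$r), " metabolites\n", sep = "")
  invisible(x)
}

#' Family heatmap of residual correlations
#'
#' Renders one family's residual correlation matrix on a diverging
#' blue-white-red scale over `[-1, 1]`. Row labels carry the direction of
#' change (up/down in AD) and the significance tier from a contrast table,
#' mirroring the label-color / dashed-vs-solid-frame convention of
#' residual-correlation heatmaps; rendering needs the pheatmap package.
#'
#' @param cm a `correlation_matrix`
#' @param contrasts optional [group_contrasts()] table used to annotate
#'   direction and significance
#' @param filename optional path (PNG/PDF); `NA` draws to the active device
#' @return the pheatmap object, invisibly
#' @export
plot_family_heatmap <- function(cm, contrasts = NULL, filename = NA) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_family_heatmap requires the pheatmap package")
  }
  labs <- colnames(cm$r)
  if (!is.null(contrasts)) {
    idx <- match(labs, contrasts$metabolite)
    mark <- ifelse(is.na(idx), "", ifelse(
      contrasts$significance_tier[idx] == "adjusted", " **",
      ifelse(contrasts$significance_tier[idx] == "nominal", " *", "")))
    arrow <- ifelse(is.na(idx), "", ifelse(
      contrasts$direction[idx] == "up_in_AD", " (+)", " (-)"))
    labs <- paste0(labs, arrow, mark)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  ph <- pheatmap::pheatmap(
    cm$r, color = pal, breaks = seq(-1, 1, length.out = 102),
    cluster_rows = FALSE, cluster_cols = FALSE,
    labels_row = labs, labels_col = colnames(cm$r),
    main = paste0("Residual correlations: ", cm$family),
    filename = filename, silent = !is.na(filename)
  )
  invisible(ph)
}
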