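#' Cohort container
#'
#' A `metab_cohort` bundles the three pieces every pipeline stage consumes:
#' per-sample metadata, a samples x metabolites abundance matrix, and the
#' metabolite -> biochemical-family map. Abundances are relative
#' (area-under-curve) values; entries below the limit of detection are `NA`.
#'
#' @param samples data.frame with columns `sample_id`, `group` (`"AD"` or
#'   `"NC"`), `age` (years), `sex` (0 = male, 1 = female), `fasting_time`
#'   (hours). One row per sample.
#' @param abundances numeric matrix, rows = samples (rownames are sample
#'   ids), columns = metabolites. Strictly positive where present; `NA`
#'   marks below-LOD / removed entries.
#' @param family_map named character vector mapping each metabolite column
#'   to its biochemical family.
#' @return An object of class `metab_cohort`.
#' @export
cohort <- function(samples, abundances, family_map) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "age", "sex", "fasting_time")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("samples is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique")
  }
  if (!all(samples$group %in% c("AD", "NC"))) {
    stop("group must be 'AD' or 'NC'")
  }
  if (!all(samples$sex %in% c(0, 1))) {
    stop("sex must be coded 0 (male) / 1 (female)")
  }
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (is.null(colnames(abundances))) stop("abundances must have metabolite column names")
  rownames(abundances) <- as.character(samples$sample_id)
  if (nrow(abundances) != nrow(samples)) {
    stop("abundances rows (", nrow(abundances), ") != samples rows (", nrow(samples), ")")
  }
  bad <- which(!is.na(abundances) & abundances <= 0)
  if (length(bad)) {
    stop("abundances must be strictly positive where present (log10 must be defined); ",
         length(bad), " non-positive entries found")
  }
  mets <- colnames(abundances)
  if (anyDuplicated(mets)) stop("metabolite names must be unique")
  unmapped <- setdiff(mets, names(family_map))
  if (length(unmapped)) {
    stop("metabolite(s) not in family_map: ", paste(utils::head(unmapped, 5), collapse = ", "))
  }
  family_map <- family_map[mets]

  structure(
    list(samples = samples, abundances = abundances,
         family_map = family_map),
    class = "metab_cohort"
  )
}

#' @export
print.metab_cohort <- function(x, ...) {
  cat("<metab_cohort> ", nrow(x$samples), " samples (",
      sum(x$samples$group == "AD"), " AD / ", sum(x$samples$group == "NC"),
      " NC), ", ncol(x$abundances), " metabolites in ",
      length(unique(x$family_map)), " families\n", sep = "")
  cat("missing entries:", sum(is.na(x$abundances)), "\n")
  invisible(x)
}

#' Metabolites of one family
#' @param x a `metab_cohort`
#' @param family family label
#' @return character vector of metabolite names
#' @export
family_members <- function(x, family) {
  stopifnot(inherits(x, "metab_cohort"))
  members <- names(x$family_map)[x$family_map == family]
  if (!length(members)) stop("unknown family: ", family)
  members
}

#' Per-family sample / metabolite tallies
#'
#' A sample counts as present in a family when at least one of the family's
#' metabolites is observed for it (per-family filters remove a sample from a
#' family by masking all of its entries there).
#'
#' @param x a `metab_cohort`
#' @return data.frame with `family`, `n_samples`, `n_metabolites`
#' @export
family_counts <- function(x) {
  stopifnot(inherits(x, "metab_cohort"))
  fams <- unique(x$family_map)
  out <- lapply(fams, function(f) {
    cols <- names(x$family_map)[x$family_map == f]
    sub <- x$abundances[, cols, drop = FALSE]
    data.frame(family = f,
               n_samples = sum(rowSums(!is.na(sub)) > 0L),
               n_metabolites = length(cols),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group / covariate design frame for model fitting
#'
#' @param x a `metab_cohort`
#' @return data.frame with Age, Sex, Fasting_time and Group (0 = NC, 1 = AD)
#' @keywords internal
covariate_frame <- function(x) {
  data.frame(
    Age = x$samples$age,
    Sex = x$samples$sex,
    Fasting_time = x$samples$fasting_time,
    Group = as.integer(x$samples$group == "AD"),
    row.names = x$samples$sample_id,
    stringsAsFactors = FALSE
  )
}

#' Write / read the cohort CSV dialect
#'
#' One row per sample: `Sample_ID, Group, Age, Sex, Fasting_time`, then one
#' column per metabolite; missing values are empty cells. The family map is
#' a two-column CSV (`metabolite, family`).
#'
#' @param x a `metab_cohort`
#' @param data_path path for the abundance + metadata CSV
#' @param family_path path for the family-map CSV
#' @return `write_cohort` invisibly returns the paths; `read_cohort` a
#'   `metab_cohort`.
#' @export
write_cohort <- function(x, data_path, family_path) {
  stopifnot(inherits(x, "metab_cohort"))
  tab <- data.frame(
    Sample_ID = x$samples$sample_id,
    Group = x$samples$group,
    Age = x$samples$age,
    Sex = x$samples$sex,
    Fasting_time = x$samples$fasting_time,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(x$abundances, check.names = FALSE))
  utils::write.csv(tab, data_path, row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(metabolite = names(x$family_map), family = unname(x$family_map),
               stringsAsFactors = FALSE),
    family_path, row.names = FALSE
  )
  invisible(c(data = data_path, family = family_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(data_path, family_path) {
  tab <- utils::read.csv(data_path, check.names = FALSE, stringsAsFactors = FALSE)
  fam <- utils::read.csv(family_path, stringsAsFactors = FALSE)
  meta_cols <- c("Sample_ID", "Group", "Age", "Sex", "Fasting_time")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss)) stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  mets <- setdiff(names(tab), meta_cols)
  ab <- as.matrix(tab[, mets, drop = FALSE])
  cohort(
    samples = data.frame(sample_id = as.character(tab$Sample_ID), group = tab$Group,
                         age = tab$Age, sex = tab$Sex,
                         fasting_time = tab$Fasting_time,
                         stringsAsFactors = FALSE),
    abundances = ab,
    family_map = stats::setNames(fam$family, fam$metabolite)
  )
}
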