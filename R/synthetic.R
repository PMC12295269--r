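#' Specify one synthetic biochemical family
#'
#' A family is a set of metabolites driven by a shared latent concomitant
#' metabolite: on the log10 scale every member is an affine function of the
#' concomitant's log10 value, the demographic covariates (Age, Sex, their
#' interaction, fasting time), a signed disease shift, and Gaussian noise.
#'
#' Per-member arguments (`beta_c` through `noise_sd`) are recycled to
#' `n_members`; the entry aligned with the concomitant itself is ignored
#' (the concomitant is drawn, not regressed).
#'
#' @param name family label
#' @param concomitant name of the driving metabolite (a member)
#' @param n_members number of metabolites in the family (>= 2)
#' @param member_names optional metabolite names; defaults to the
#'   concomitant followed by `<name>_m2 ...`
#' @param beta_c slope on log10(concomitant)
#' @param intercept member intercept on the log10 scale
#' @param beta_age,beta_sex,beta_agesex,beta_fasting covariate coefficients
#'   (log10 units per year / per category / per year / per hour)
#' @param group_delta signed log10 shift in AD (0 = null metabolite)
#' @param noise_sd residual SD on the log10 scale (> 0)
#' @param conc_mu,conc_sd mean and SD of the concomitant's log10 value
#' @return a `family_spec` list
#' @export
family_spec <- function(name, concomitant, n_members,
                        member_names = NULL,
                        beta_c = 0.5, intercept = 0.5,
                        beta_age = 0.002, beta_sex = 0.05,
                        beta_agesex = 0.001, beta_fasting = 0.005,
                        group_delta = 0, noise_sd = 0.15,
                        conc_mu = 3, conc_sd = 0.3) {
  if (n_members < 2) stop("family_spec: n_members must be >= 2 (field n_members)")
  if (any(noise_sd <= 0)) stop("family_spec: noise_sd must be > 0 (field noise_sd)")
  if (is.null(member_names)) {
    member_names <- c(concomitant, paste0(name, "_m", seq_len(n_members)[-1]))
  }
  if (length(member_names) != n_members) {
    stop("family_spec: member_names length != n_members (field member_names)")
  }
  if (!concomitant %in% member_names) {
    stop("family_spec: concomitant must be a member of the family (field concomitant)")
  }
  rec <- function(v) rep_len(v, n_members)
  structure(
    list(name = name, concomitant = concomitant, n_members = n_members,
         member_names = member_names,
         beta_c = rec(beta_c), intercept = rec(intercept),
         beta_age = rec(beta_age), beta_sex = rec(beta_sex),
         beta_agesex = rec(beta_agesex), beta_fasting = rec(beta_fasting),
         group_delta = rec(group_delta), noise_sd = rec(noise_sd),
         conc_mu = conc_mu, conc_sd = conc_sd),
    class = "family_spec"
  )
}

#' Specify a synthetic cohort
#'
#' Defaults describe a cohort of the size and covariate ranges typical of
#' plasma metabolomics studies of Alzheimer's disease in elderly
#' populations: 94 AD cases and 64 controls aged 55-90, roughly balanced
#' sexes, fasting times of a few hours, a small below-LOD censoring rate
#' and rare gross outliers.
#'
#' @param n_ad,n_control class sizes (each >= 2)
#' @param families list of [family_spec()] objects with globally unique
#'   metabolite names
#' @param age_range,fasting_range numeric length-2 ranges (years / hours)
#' @param sex_balance fraction female in `[0, 1]`
#' @param lod_censor_rate expected fraction of entries censored as below
#'   the limit of detection, in `[0, 1)`
#' @param outlier_rate expected fraction of entries replaced by gross
#'   outliers (>= 4 SD from the metabolite mean), in `[0, 1)`
#' @param seed integer seed; the generator is fully reproducible from it
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_ad = 94, n_control = 64,
                           families = study_like_families(),
                           age_range = c(55, 90), sex_balance = 0.5,
                           fasting_range = c(2, 14),
                           lod_censor_rate = 0.02, outlier_rate = 0.005,
                           seed = 1L) {
  if (n_ad < 2) stop("synthetic_spec: n_ad must be >= 2 (field n_ad)")
  if (n_control < 2) stop("synthetic_spec: n_control must be >= 2 (field n_control)")
  for (r in c(lod_censor_rate = lod_censor_rate, outlier_rate = outlier_rate)) {
    if (r < 0 || r >= 1) {
      stop("synthetic_spec: censor/outlier rates must lie in [0, 1) ",
           "(fields lod_censor_rate, outlier_rate)")
    }
  }
  if (sex_balance < 0 || sex_balance > 1) {
    stop("synthetic_spec: sex_balance must lie in [0, 1] (field sex_balance)")
  }
  if (!length(families)) stop("synthetic_spec: families must be non-empty (field families)")
  all_names <- unlist(lapply(families, `[[`, "member_names"))
  if (anyDuplicated(all_names)) {
    stop("synthetic_spec: metabolite names must be unique across families ",
         "(field families): ", all_names[duplicated(all_names)][1])
  }
  structure(
    list(n_ad = n_ad, n_control = n_control, families = families,
         age_range = age_range, sex_balance = sex_balance,
         fasting_range = fasting_range,
         lod_censor_rate = lod_censor_rate, outlier_rate = outlier_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Study-like family layout
#'
#' Six families with the member counts of the retained biochemical groups
#' of a Biocrates small-molecule panel (30 amino-acid-related, 14 bile
#' acids, 14 biogenic amines, 4 indoles, 8 carboxylic acids, 12 fatty
#' acids) and their conventional concomitant metabolites. Group shifts
#' cycle through up / down / null so every family carries effects of both
#' signs.
#'
#' @param group_delta magnitude of the non-null per-metabolite shifts
#'   (log10 units)
#' @param noise_sd residual SD shared by all members
#' @return list of [family_spec()] objects
#' @export
study_like_families <- function(group_delta = 0.12, noise_sd = 0.15) {
  layout <- data.frame(
    name = c("AA-related", "Bile Acids", "Biogenic Amines", "Indoles",
             "Carboxylic Acids", "Fatty Acids"),
    concomitant = c("SDMA", "TDCA", "Spermine", "3-IAA", "Suc", "DHA"),
    n = c(30L, 14L, 14L, 4L, 8L, 12L),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(layout)), function(i) {
    n <- layout$n[i]
    family_spec(
      name = layout$name[i], concomitant = layout$concomitant[i],
      n_members = n,
      beta_c = 0.5,
      group_delta = rep_len(c(group_delta, -group_delta, 0, 0), n),
      noise_sd = noise_sd
    )
  })
}

# Deterministic substream seed: family i gets its own stream so adding a
# family leaves the others' draws untouched. Kept below 2^31 - 1.
substream_seed <- function(seed, i) {
  as.integer((abs(as.double(seed)) * 1009 + 7919 * (i + 1)) %% 2147483629) + 1L
}

#' Generate a synthetic cohort
#'
#' Draws covariates and, per family, a log-normal concomitant plus members
#' satisfying (before censoring and outlier injection)
#' `log10(m) = b0 + bc*log10(m_c) + ba*Age + bs*Sex + bas*Age*Sex +
#' bf*Fasting + delta*Group + eps`, `eps ~ N(0, noise_sd)`. A Binomial
#' number of entries per metabolite is censored at the low end (below-LOD),
#' and a Binomial number of entries per family is replaced by additive
#' shifts of 4-6 SD so a three-SD outlier rule detects them by
#' construction. All draws flow from `spec$seed` through per-family
#' substreams.
#'
#' @param spec a [synthetic_spec()]
#' @return a [cohort()] with attribute `generation_log`: per-family counts
#'   of censored and outlier entries and the planted truth (concomitant,
#'   coefficients, deltas)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_ad + spec$n_control

  set.seed(substream_seed(spec$seed, 0))
  samples <- data.frame(
    sample_id = sprintf("PX%03d", seq_len(n)),
    group = c(rep("AD", spec$n_ad), rep("NC", spec$n_control)),
    age = round(stats::runif(n, spec$age_range[1], spec$age_range[2]), 1),
    sex = stats::rbinom(n, 1, spec$sex_balance),
    fasting_time = round(stats::runif(n, spec$fasting_range[1], spec$fasting_range[2]), 1),
    stringsAsFactors = FALSE
  )
  grp <- as.integer(samples$group == "AD")

  blocks <- vector("list", length(spec$families))
  fam_map <- character(0)
  log_entries <- vector("list", length(spec$families))

  for (i in seq_along(spec$families)) {
    fs <- spec$families[[i]]
    set.seed(substream_seed(spec$seed, i))
    lc <- stats::rnorm(n, fs$conc_mu, fs$conc_sd)
    logm <- matrix(NA_real_, n, fs$n_members,
                   dimnames = list(samples$sample_id, fs$member_names))
    ci <- match(fs$concomitant, fs$member_names)
    logm[, ci] <- lc
    for (j in seq_len(fs$n_members)) {
      if (j == ci) next
      mu <- fs$intercept[j] + fs$beta_c[j] * lc +
        fs$beta_age[j] * samples$age + fs$beta_sex[j] * samples$sex +
        fs$beta_agesex[j] * samples$age * samples$sex +
        fs$beta_fasting[j] * samples$fasting_time +
        fs$group_delta[j] * grp
      logm[, j] <- mu + stats::rnorm(n, 0, fs$noise_sd[j])
    }

    # gross outliers: additive +/- k*SD (k in [4,6]) on the log10 scale
    n_entries <- length(logm)
    n_out <- stats::rbinom(1, n_entries, spec$outlier_rate)
    if (n_out > 0) {
      pos <- sample.int(n_entries, n_out)
      sds <- apply(logm, 2, stats::sd)
      col_of <- (pos - 1L) %/% n + 1L
      shift <- sample(c(-1, 1), n_out, replace = TRUE) *
        stats::runif(n_out, 4, 6) * sds[col_of]
      logm[pos] <- logm[pos] + shift
    }

    # below-LOD censoring: Binomial count per metabolite, lowest values masked
    n_cens <- 0L
    if (spec$lod_censor_rate > 0) {
      for (j in seq_len(fs$n_members)) {
        k <- stats::rbinom(1, n, spec$lod_censor_rate)
        if (k > 0) {
          logm[order(logm[, j])[seq_len(k)], j] <- NA_real_
          n_cens <- n_cens + k
        }
      }
    }

    blocks[[i]] <- 10^logm
    fam_map <- c(fam_map, stats::setNames(rep(fs$name, fs$n_members), fs$member_names))
    log_entries[[i]] <- list(
      family = fs$name, concomitant = fs$concomitant,
      n_censored = n_cens, n_outliers = n_out,
      truth = fs[c("member_names", "beta_c", "intercept", "beta_age",
                   "beta_sex", "beta_agesex", "beta_fasting",
                   "group_delta", "noise_sd")]
    )
  }

  out <- cohort(samples = samples, abundances = do.call(cbind, blocks),
                family_map = fam_map)
  attr(out, "generation_log") <- log_entries
  out
}

#' Write the generating spec alongside a cohort for provenance
#'
#' @param spec a [synthetic_spec()]
#' @param path YAML file path
#' @return the path, invisibly
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  plain <- unclass(spec)
  plain$families <- lapply(plain$families, unclass)
  yaml::write_yaml(plain, path)
  invisible(path)
}
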