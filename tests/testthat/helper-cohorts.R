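# Builders for the synthetic fixtures the tests share. Everything is
# generated in code; no fixture files.

# One-family synthetic cohort, thin wrapper over the generator.
one_family_cohort <- function(n_ad = 40, n_control = 30, n_members = 6,
                              beta_c = 0.5, group_delta = 0,
                              noise_sd = 0.15, seed = 1,
                              lod_censor_rate = 0, outlier_rate = 0,
                              name = "Fam", concomitant = "Conc", ...) {
  fam <- family_spec(name = name, concomitant = concomitant,
                     n_members = n_members, beta_c = beta_c,
                     group_delta = group_delta, noise_sd = noise_sd, ...)
  generate_cohort(synthetic_spec(
    n_ad = n_ad, n_control = n_control, families = list(fam),
    lod_censor_rate = lod_censor_rate, outlier_rate = outlier_rate,
    seed = seed))
}

# Hand-built cohort for the preprocessing fixtures: deterministic values,
# no generator involved. Two families: "twelve" (12 metabolites) and
# "ten" (10 metabolites), 20 samples.
handmade_cohort <- function() {
  n <- 20
  mets12 <- sprintf("t%02d", 1:12)
  mets10 <- sprintf("u%02d", 1:10)
  ab <- matrix(rep(seq(99, 101, length.out = n), 22), nrow = n,
               dimnames = list(NULL, c(mets12, mets10)))
  # sample 1: gross outliers in exactly 2/12 of family "twelve" (> 10%)
  ab[1, c("t01", "t02")] <- 1e6
  # sample 2: gross outlier in exactly 1/10 of family "ten" (= 10%, retained)
  ab[2, "u01"] <- 1e6
  samples <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    group = rep(c("AD", "NC"), each = n / 2),
    age = seq(55, 90, length.out = n),
    sex = rep(c(0, 1), n / 2),
    fasting_time = seq(2, 14, length.out = n),
    stringsAsFactors = FALSE
  )
  cohort(samples, ab,
         c(stats::setNames(rep("twelve", 12), mets12),
           stats::setNames(rep("ten", 10), mets10)))
}

# Deterministic 10-sample single-metabolite-pair fixture for OLS oracles.
ols_fixture <- function() {
  set.seed(321)
  n <- 10
  samples <- data.frame(
    sample_id = sprintf("F%02d", 1:n),
    group = rep(c("AD", "NC"), 5),
    age = round(runif(n, 55, 90), 1),
    sex = rep(c(0, 1), each = 5),
    fasting_time = round(runif(n, 2, 14), 1),
    stringsAsFactors = FALSE
  )
  conc <- 10^rnorm(n, 3, 0.3)
  resp <- 10^(0.4 + 0.6 * log10(conc) + 0.01 * samples$age + rnorm(n, 0, 0.2))
  ab <- cbind(M = resp, C = conc)
  rownames(ab) <- samples$sample_id
  cohort(samples, ab, c(M = "fam", C = "fam"))
}

# Two Gaussian clouds with identity covariance at Mahalanobis distance
# `delta`, as a plain residual-style matrix plus labels.
gaussian_clouds <- function(n1, n0, p = 4, delta = 2, seed = 1) {
  set.seed(seed)
  shift <- rep(delta / sqrt(p), p)
  X <- rbind(
    matrix(rnorm(n1 * p), n1, p) + rep(shift, each = n1),
    matrix(rnorm(n0 * p), n0, p)
  )
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- sprintf("G%03d", seq_len(n1 + n0))
  list(X = X, labels = c(rep("AD", n1), rep("NC", n0)))
}

# Covariate frame rebuilt independently of the package internals.
covariate_frame_for_tests <- function(x) {
  data.frame(Age = x$samples$age, Sex = x$samples$sex,
             Fasting_time = x$samples$fasting_time,
             Group = as.integer(x$samples$group == "AD"),
             row.names = x$samples$sample_id)
}

# Independent-route BH step-up oracle (used to check adjust_pvalues).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
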