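test_that("the normalization fit matches a normal-equations oracle", {
  x <- ols_fixture()
  fit <- fit_normalization_model(x, "M", "C", include_group = TRUE)
  # independent route: closed-form least squares on the explicit design
  g <- as.integer(x$samples$group == "AD")
  X <- cbind(1, x$samples$age, x$samples$sex, x$samples$fasting_time, g,
             log10(x$abundances[, "C"]), x$samples$age * x$samples$sex)
  y <- log10(x$abundances[, "M"])
  beta <- solve(crossprod(X), crossprod(X, y))
  got <- fit$coefficients[c("(Intercept)", "Age", "Sex", "Fasting_time",
                            "Group", "log10_conc", "Age:Sex")]
  expect_equal(unname(got), unname(drop(beta)), tolerance = 1e-10)
  # adjusted R2 from its definition
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  n <- length(y); p <- ncol(X) - 1
  expect_equal(fit$adj_r2, 1 - (1 - r2) * (n - 1) / (n - p - 1),
               tolerance = 1e-10)
  expect_equal(fit$r2, r2, tolerance = 1e-10)
})

test_that("fit preconditions are enforced", {
  x <- ols_fixture()
  expect_error(fit_normalization_model(x, "M", "M"), "differ")
  expect_error(fit_normalization_model(x, "M", "C", min_cases = 11),
               "complete cases")
  # rank deficiency: constant covariate column duplicated through sex = 0
  y <- one_family_cohort(n_ad = 10, n_control = 10, seed = 1)
  y$samples$sex <- 0  # Age:Sex and Sex collapse -> aliased terms
  expect_error(fit_normalization_model(y, "Fam_m2", "Conc"), "collinear")
})

test_that("permuted responses give uniform overall F p-values", {
  x <- one_family_cohort(n_ad = 30, n_control = 30, seed = 10)
  base <- covariate_frame_for_tests(x)
  set.seed(77)
  pvals <- replicate(500, {
    xp <- x
    perm <- sample(nrow(xp$abundances))
    xp$abundances[, "Fam_m2"] <- xp$abundances[perm, "Fam_m2"]
    fit_normalization_model(xp, "Fam_m2", "Conc")$f_pvalue
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted concomitant drivers are recovered; null families are unstable", {
  # planted structure: the concomitant generates every other member
  x <- one_family_cohort(n_ad = 40, n_control = 40, n_members = 6,
                         beta_c = 0.8, noise_sd = 0.1, seed = 4)
  sc <- score_concomitants(x, "Fam")
  expect_equal(sc$candidate[1], "Conc")
  expect_equal(sc$n_models, rep(5L, 6))
  expect_true(all(diff(sc$mean_adj_r2) <= 1e-12))

  # null structure: three iid members; no candidate should dominate
  wins <- character(100)
  for (s in seq_len(100)) {
    y <- one_family_cohort(n_ad = 20, n_control = 20, n_members = 3,
                           beta_c = 0, noise_sd = 0.2, seed = 1000 + s)
    tab <- score_concomitants(y, "Fam")
    wins[s] <- tab$candidate[1]
    if (s == 1) expect_lt(max(tab$mean_adj_r2), 0.2)
  }
  expect_lt(max(table(wins)) / 100, 0.7)
})

test_that("concomitant selection honours ranking, overrides and presets", {
  sc <- data.frame(family = "f", candidate = c("a", "b", "c"),
                   mean_adj_r2 = c(0.3, 0.5, 0.2),
                   mean_f_pvalue = c(0.1, 0.05, 0.2), n_models = 2)
  expect_equal(select_concomitants(list(sc)), c(f = "b"))
  expect_equal(select_concomitants(list(sc), overrides = c(f = "c")),
               c(f = "c"))
  expect_error(select_concomitants(list(sc), overrides = c(f = "zzz")),
               "zzz")
  expect_error(select_concomitants(list(sc[0, ])), "empty")
  preset <- study_concomitants()
  expect_equal(unname(preset["Bile Acids"]), "TDCA")
  expect_length(preset, 6)
})

test_that("residual matrices satisfy the OLS identities", {
  x <- generate_cohort(synthetic_spec(
    n_ad = 40, n_control = 30, families = study_like_families()[c(2, 4)],
    lod_censor_rate = 0.03, seed = 6))
  conc <- c("Bile Acids" = "TDCA", "Indoles" = "3-IAA")
  rm_ <- compute_residuals(x, conc, include_group = TRUE)
  expect_false(any(unname(conc) %in% colnames(rm_$residuals)))
  # residuals sum to ~0 and are orthogonal to the design columns
  cv <- covariate_frame_for_tests(x)
  for (m in colnames(rm_$residuals)[1:5]) {
    e <- rm_$residuals[, m]
    used <- !is.na(e)
    expect_lt(abs(sum(e[used])), 1e-8)
    fam <- rm_$family_map[[m]]
    des <- cbind(cv$Age, cv$Sex, cv$Age * cv$Sex, cv$Fasting_time, cv$Group,
                 log10(x$abundances[, conc[[fam]]]))[used, ]
    expect_lt(max(abs(crossprod(des, e[used]))), 1e-8)
  }
  # adjusted R2 never exceeds R2; dropping the concomitant never raises R2
  for (m in colnames(rm_$residuals)[1:5]) {
    f <- rm_$fits[[m]]
    expect_lte(f$adj_r2, f$r2)
  }
})

test_that("group variants of the residuals behave as constructed", {
  delta <- 0.4
  x <- one_family_cohort(n_ad = 60, n_control = 60, n_members = 5,
                         group_delta = delta, noise_sd = 0.05, seed = 9)
  grp <- x$samples$group
  conc <- c(Fam = "Conc")
  with_g <- compute_residuals(x, conc, include_group = TRUE)$residuals
  no_g <- compute_residuals(x, conc, include_group = FALSE)$residuals
  m <- "Fam_m2"
  d_with <- mean(with_g[grp == "AD", m]) - mean(with_g[grp == "NC", m])
  d_no <- mean(no_g[grp == "AD", m]) - mean(no_g[grp == "NC", m])
  expect_lt(abs(d_with), 0.02)
  expect_equal(d_no, delta, tolerance = 0.15)

  # noiseless limit: all residuals vanish
  z <- one_family_cohort(n_ad = 20, n_control = 20, n_members = 4,
                         noise_sd = 1e-9, seed = 2)
  rz <- compute_residuals(z, conc, include_group = TRUE)$residuals
  expect_lt(max(abs(rz)), 1e-6)
})
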