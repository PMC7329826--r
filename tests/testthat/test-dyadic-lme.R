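test_that("with no member variance the fit reduces to ordinary least squares", {
  # data generated with sigma2_u = 0: the random effect should vanish and
  # the fixed effects agree with lm() to numerical precision
  dd <- make_dyad_data(20, beta1 = 0.5, s2u = 0, s2e = 1, seed = 42)
  f <- dyad_lme(similarity ~ distance, dd$data)
  ols <- lm(similarity ~ distance, dd$data)
  expect_true(f$singular)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f$sigma2_u, 0)
  expect_lt(abs(coef(f)["distance"] - 0.5) / f$se["distance"], 2)
})

test_that("REML optimum beats the dense-matrix criterion on a grid", {
  dd <- make_dyad_data(12, beta1 = 0.4, s2u = 0.5, s2e = 0.8, seed = 7)
  f <- dyad_lme(similarity ~ distance, dd$data)
  y <- dd$data$similarity
  crit_fit <- bf_dyad_reml_crit(f$sigma2_u, f$sigma2_e, y, dd$X, dd$Z)
  grid <- expand.grid(s2u = seq(0.02, 1.5, length.out = 40),
                      s2e = seq(0.2, 1.6, length.out = 40))
  crit_grid <- mapply(bf_dyad_reml_crit, grid$s2u, grid$s2e,
                      MoreArgs = list(y = y, X = dd$X, Z = dd$Z))
  expect_lte(crit_fit, min(crit_grid) + 1e-6)
  # and beats the OLS corner (optimizer sanity invariant)
  s2e_ols <- sum(residuals(lm(similarity ~ distance, dd$data))^2) /
    (nrow(dd$data) - 2)
  expect_lte(crit_fit, bf_dyad_reml_crit(0, s2e_ols, y, dd$X, dd$Z) + 1e-8)
})

test_that("estimates are exchangeable under dyad member relabelling", {
  dd <- make_dyad_data(10, s2u = 0.4, seed = 9)
  d2 <- dd$data
  d2$i <- dd$data$j
  d2$j <- dd$data$i
  f1 <- dyad_lme(similarity ~ distance, dd$data)
  f2 <- dyad_lme(similarity ~ distance, d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$sigma2_u, f2$sigma2_u, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("permuted outcomes reject at the nominal rate", {
  dd <- make_dyad_data(20, beta1 = 0, s2u = 0.3, s2e = 0.7, seed = 3)
  base <- dd$data
  pvals <- vapply(1:200, function(r) {
    d <- base
    d$similarity <- with_seed(child_seed(55, paste0("perm", r)),
                              sample(base$similarity))
    dyad_lme(similarity ~ distance, d)$p_value["distance"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("parameters of the exact model are recovered without bias", {
  R <- 200
  est <- t(vapply(seq_len(R), function(r) {
    dd <- make_dyad_data(30, beta0 = 0.1, beta1 = 0.3, s2u = 0.4, s2e = 0.6,
                         seed = 1000 + r)
    f <- dyad_lme(similarity ~ distance, dd$data)
    c(coef(f)["distance"], f$sigma2_u, f$sigma2_e)
  }, numeric(3)))
  mc_se <- sd(est[, 1]) / sqrt(R)
  expect_lt(abs(mean(est[, 1]) - 0.3), 2 * mc_se)
  expect_lt(abs(mean(est[, 2]) - 0.4), 3 * sd(est[, 2]) / sqrt(R))
  expect_lt(abs(mean(est[, 3]) - 0.6), 3 * sd(est[, 3]) / sqrt(R))
})

test_that("model methods are coherent", {
  dd <- make_dyad_data(12, s2u = 0.5, seed = 21)
  f <- dyad_lme(similarity ~ distance, dd$data)
  expect_equal(fitted(f) + residuals(f), f$y)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, dd$data[1:5, ]), fitted(f)[1:5])
  u <- ranef(f)
  expect_equal(length(u), 12)
  expect_equal(residuals(f, "conditional"), f$y - fitted(f) - drop(f$Z %*% u))
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(66, 3))
  expect_s3_class(summary(f), "summary.dyad_lme")
  expect_output(print(summary(f)), "crossed random member")
  expect_equal(nobs(f), 66)
  # Satterthwaite df are finite and the p-value is close to the z-based one
  fs <- dyad_lme(similarity ~ distance, dd$data, df = "satterthwaite")
  expect_true(all(is.finite(fs$df)))
  expect_true(all(fs$df > 1))
  expect_equal(fs$p_value["distance"], f$p_value["distance"], tolerance = 0.05)
})

test_that("unreachable dyads are dropped with a recorded count", {
  dd <- make_dyad_data(8, seed = 31)
  d <- dd$data
  d$distance[c(2, 5)] <- Inf
  f <- dyad_lme(similarity ~ distance, d)
  expect_equal(f$n_dropped, 2)
  expect_equal(f$n_dyads, nrow(d) - 2)
})

test_that("fit_dyadic_lme selects predictor and covariates from the table", {
  cfg <- sim_config(n_students = 14, n_parcels = 10, n_timepoints = 40,
                    theta = 0.3, eta = 0.3, seed = 23)
  sim <- simulate_cohort(cfg)
  g <- build_social_graph(sim$roster, 4)
  tab <- build_dyad_table(
    similarity_matrix(lapply(sim$series, function(ts) fisher_z(correlation_matrix(ts)))),
    social_distance(g), detect_communities(g, seed = 1, restarts = 10),
    covariates = sim$covariates, cohort = "c")
  f1 <- fit_dyadic_lme(tab, "distance")
  expect_true("distance" %in% names(coef(f1)))
  f2 <- fit_dyadic_lme(tab, "community")
  expect_true("same_community" %in% names(coef(f2)))
  f3 <- fit_dyadic_lme(tab, "distance", covariates = TRUE)
  expect_true(all(c("ethnicity_match", "boarding_match", "motion_abs_mean")
                  %in% names(coef(f3))))
})

test_that("meta-analysis pools cohorts with the standard estimators", {
  # homogeneous case: tau2 = 0, pooled SE = SE / sqrt(k)
  hom <- data.frame(beta = rep(0.2, 3), se = rep(0.1, 3))
  m <- meta_analyze(hom)
  expect_equal(m$estimate, 0.2, tolerance = 1e-10)
  expect_equal(m$tau2, 0, tolerance = 1e-10)
  expect_equal(m$se, 0.1 / sqrt(3), tolerance = 1e-10)
  expect_true(m$ci_lower <= m$estimate && m$estimate <= m$ci_upper)
  expect_equal(sum(m$weights), 1)

  # fixed-effect closed form
  fe <- meta_analyze(data.frame(beta = c(0, 1), se = c(1, 1)), method = "FE")
  expect_equal(fe$estimate, 0.5)

  # heterogeneous: REML tau2 matches an independent grid-search maximiser
  het <- data.frame(beta = c(-0.5, 0.1, 0.6, -0.2, 0.4),
                    se = c(0.15, 0.2, 0.1, 0.25, 0.12))
  mh <- meta_analyze(het)
  expect_equal(mh$tau2, bf_meta_tau2(het$beta, het$se), tolerance = 1e-6)
  # pooled estimate inside the cohort range
  expect_gte(mh$estimate, min(het$beta))
  expect_lte(mh$estimate, max(het$beta))

  expect_error(meta_analyze(data.frame(beta = 1, se = 1)), "at least 2")
})

test_that("meta-analysis of dyadic fits pools the requested coefficient", {
  fits <- lapply(1:3, function(k) {
    dd <- make_dyad_data(12, beta1 = -0.2, s2u = 0.3, seed = 40 + k)
    dyad_lme(similarity ~ distance, dd$data)
  })
  m <- meta_analyze(fits, "distance")
  expect_equal(m$k, 3)
  betas <- vapply(fits, function(f) unname(coef(f)["distance"]), numeric(1))
  expect_gte(m$estimate, min(betas))
  expect_lte(m$estimate, max(betas))
  ft <- forest_table(setNames(fits, paste0("c", 1:3)), m, "distance")
  expect_equal(nrow(ft), 4)
  expect_equal(ft$cohort[4], "pooled")
})
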