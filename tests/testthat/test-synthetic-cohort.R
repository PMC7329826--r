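test_that("sim_config validates probabilities, weights and counts", {
  expect_error(sim_config(theta = 0.7, eta = 0.5), "theta \\+ eta")
  expect_error(sim_config(p_in = 1.2), "p_in")
  expect_error(sim_config(n_students = 1), "n_students")
  expect_error(sim_config(n_groups = 30, n_students = 10), "n_groups")
  cfg <- sim_config(n_students = 10, n_parcels = 8, seed = 3)
  expect_s3_class(cfg, "sim_config")
})

test_that("degenerate tie probabilities give a deterministic roster", {
  cfg <- sim_config(n_students = 12, n_parcels = 4, p_in = 1, p_out = 0,
                    likert_noise = 0, n_groups = 3, seed = 5)
  r <- simulate_social_roster(cfg)
  groups <- attr(r, "groups")
  same <- outer(groups, groups, "==")
  off <- row(r) != col(r)
  expect_true(all(r[same & off] == 5))
  expect_true(all(r[!same & off] == 1))
})

test_that("roster has the right shape and rating range", {
  cfg <- sim_config(n_students = 59, n_parcels = 4, seed = 2)
  r <- simulate_social_roster(cfg)
  expect_equal(dim(r), c(59, 59))
  expect_equal(sum(!is.na(r)), 59 * 58)
  expect_true(all(r[!is.na(r)] %in% 1:5))
  expect_true(all(is.na(diag(r))))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_students = 10, n_parcels = 12, n_timepoints = 30,
                    theta = 0.2, eta = 0.3, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$series, b$series)
  # different seed changes output
  cfg2 <- sim_config(n_students = 10, n_parcels = 12, n_timepoints = 30,
                     theta = 0.2, eta = 0.3, seed = 78)
  expect_false(identical(simulate_cohort(cfg2)$roster, a$roster))
})

test_that("connectome templates and realizations are valid correlation matrices", {
  cfg <- sim_config(n_students = 8, n_parcels = 15, theta = 0.3, eta = 0.3, seed = 4)
  groups <- simulate_groups(cfg)
  out <- simulate_subject_connectomes(groups, cfg)
  for (m in c(list(out$truth$template_global), out$truth$template_groups,
              out$matrices[1:3])) {
    expect_equal(unname(diag(m)), rep(1, 15))
    expect_equal(m, t(m))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("theta = 1 makes same-group connectomes identical", {
  cfg <- sim_config(n_students = 8, n_parcels = 10, theta = 1, eta = 0,
                    n_groups = 2, seed = 11)
  groups <- simulate_groups(cfg)
  out <- simulate_subject_connectomes(groups, cfg)
  g1 <- names(groups)[groups == 1]
  expect_equal(out$matrices[[g1[1]]], out$matrices[[g1[2]]])
  z <- lapply(out$matrices[g1[1:2]], fisher_z)
  expect_equal(intersubject_similarity(z[[1]], z[[2]]), 1, tolerance = 1e-12)
})

test_that("planted homophily separates within- from between-group similarity", {
  # theta = 0.3: within > between in nearly all replicate seeds;
  # theta = 0: no systematic separation
  sep <- function(theta, seed) {
    cfg <- sim_config(n_students = 12, n_parcels = 20, theta = theta, eta = 0.3,
                      n_groups = 3, seed = seed)
    groups <- simulate_groups(cfg)
    out <- simulate_subject_connectomes(groups, cfg)
    z <- lapply(out$matrices, fisher_z)
    s <- similarity_matrix(z)
    same <- outer(groups, groups, "==")
    ut <- upper.tri(s)
    mean(s[ut & same]) - mean(s[ut & !same])
  }
  seps <- vapply(1:50, function(s) sep(0.3, s), numeric(1))
  expect_gte(mean(seps > 0), 0.95)
  null_seps <- vapply(1:50, function(s) sep(0, s + 500), numeric(1))
  expect_lt(abs(mean(null_seps)), 3 * sd(null_seps) / sqrt(50))
})

test_that("simulate_bold reproduces the target correlation at large T", {
  r <- simulate_bold(diag(6), 10000, seed = 9)
  cm <- cor(r)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  target <- matrix(c(1, 0.8, 0.8, 1), 2)
  r2 <- simulate_bold(target, 5000, seed = 10)
  expect_lt(abs(cor(r2)[1, 2] - 0.8), 0.03)
  expect_identical(simulate_bold(target, 100, seed = 3),
                   simulate_bold(target, 100, seed = 3))
})

test_that("simulate_bold rejects indefinite matrices naming the eigenvalue", {
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_bold(bad, 10, seed = 1), "eigenvalue")
})

test_that("nearest_correlation is a fixed point on valid input", {
  m <- random_correlation(10, seed = 21)
  out <- nearest_correlation(m)
  expect_lt(sqrt(sum((out - m)^2)), 1e-8)
})

test_that("nearest_correlation repairs a slightly indefinite matrix", {
  m <- random_correlation(8, seed = 22)
  e <- eigen(m, symmetric = TRUE)
  v <- e$values
  v[length(v)] <- -0.01
  bad <- e$vectors %*% (v * t(e$vectors))
  diag(bad) <- 1
  bad <- (bad + t(bad)) / 2
  out <- nearest_correlation(bad)
  expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_equal(unname(diag(out)), rep(1, 8))
})

test_that("nearest_correlation clips an out-of-range 2x2 toward the closed form", {
  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  # brute-force 2x2: nearest correlation matrix has off-diagonal
  # argmin_{|rho|<=1} (rho - 1.2)^2 = 1
  rho_grid <- seq(-1, 1, by = 1e-4)
  rho_best <- rho_grid[which.min((rho_grid - 1.2)^2)]
  out <- nearest_correlation(m)
  expect_gte(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_lt(abs(out[1, 2]) - 1, 1e-7)
  expect_equal(out[1, 2], rho_best, tolerance = 1e-3)
  expect_error(nearest_correlation(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})
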