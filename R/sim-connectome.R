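#' Random correlation matrix from factor loadings
#'
#' Draws a P x k loading matrix with standard normal entries, adds uniform
#' unique variances and converts the resulting covariance `LL' + diag(u)` to
#' a correlation matrix. Low-rank-plus-diagonal structure gives templates
#' with realistic large-scale covariance blocks rather than white noise.
#'
#' @param p dimension.
#' @param k number of factors (default 5).
#' @param seed integer seed.
#' @return A valid p x p correlation matrix (symmetric, unit diagonal, PSD).
#' @export
random_correlation <- function(p, k = 5, seed = 1) {
  with_seed(seed, {
    L <- matrix(stats::rnorm(p * k), p, k)
    u <- stats::runif(p, 0.2, 1)
  })
  S <- tcrossprod(L) + diag(u, p)
  stats::cov2cor(S)
}

#' Nearest correlation matrix
#'
#' Projects a symmetric matrix onto the set of correlation matrices (unit
#' diagonal, positive semi-definite) under the Frobenius norm, using
#' Higham's alternating-projection scheme as implemented in
#' [Matrix::nearPD()] with `corr = TRUE`.
#'
#' @param m symmetric numeric matrix.
#' @param tol convergence tolerance (default 1e-8).
#' @param maxit maximum alternating projections.
#' @return The nearest correlation matrix, with attribute `iterations`.
#' @export
nearest_correlation <- function(m, tol = 1e-8, maxit = 200) {
  m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("nearest_correlation requires a symmetric matrix")
  m <- (m + t(m)) / 2
  # fast path: already a valid correlation matrix
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (all(abs(diag(m) - 1) < 1e-12) && ev_min >= -1e-12 && max(abs(m)) <= 1 + 1e-12) {
    attr(m, "iterations") <- 0L
    return(m)
  }
  res <- Matrix::nearPD(m, corr = TRUE, conv.tol = tol, maxit = maxit,
                        do2eigen = TRUE, eig.tol = 1e-10, posd.tol = 1e-10)
  if (!res$converged)
    stop("nearest-correlation projection did not converge after ",
         res$iterations, " iterations")
  out <- as.matrix(res$mat)
  dimnames(out) <- dimnames(m)
  attr(out, "iterations") <- res$iterations
  out
}

#' Simulate per-subject connectomes with planted homophily
#'
#' Subject s in group g receives the correlation matrix nearest (in
#' Frobenius norm) to the convex mixture
#' `eta * C_global + theta * C_g + (1 - eta - theta) * E_s`,
#' where `C_global` is a cohort-wide template, `C_g` a group template and
#' `E_s` subject-unique noise, all random factor-structure correlation
#' matrices. Because a convex combination of correlation matrices is itself
#' a correlation matrix, the projection is the identity here; it guards
#' against numerical drift.
#'
#' @param partition integer/character group label per student (named by
#'   student ID, as from [simulate_groups()]).
#' @param config a [sim_config()]; `theta`, `eta` and `n_parcels` are used.
#' @return List with `matrices` (named list of P x P correlation matrices)
#'   and `truth` (class `ground_truth`: groups, global and per-group
#'   templates, theta, eta, seed).
#' @export
simulate_subject_connectomes <- function(partition, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(partition)
  if (n != config$n_students)
    stop("partition must have one label per student")
  p <- config$n_parcels
  labels <- parcel_labels(p)
  grp_levels <- sort(unique(partition))
  C_global <- random_correlation(p, seed = child_seed(config$seed, "template/global"))
  C_group <- lapply(grp_levels, function(g)
    random_correlation(p, seed = child_seed(config$seed, paste0("template/group", g))))
  names(C_group) <- as.character(grp_levels)
  ids <- names(partition)
  if (is.null(ids)) ids <- student_ids(n)
  w_noise <- 1 - config$theta - config$eta
  mats <- lapply(seq_len(n), function(s) {
    E_s <- if (w_noise > 0)
      random_correlation(p, seed = child_seed(config$seed, paste0("noise/", ids[s])))
    else matrix(0, p, p)
    R <- config$eta * C_global + config$theta * C_group[[as.character(partition[s])]] +
      w_noise * E_s
    R <- nearest_correlation(R)
    dimnames(R) <- list(labels, labels)
    R
  })
  names(mats) <- ids
  truth <- structure(list(groups = partition, template_global = C_global,
                          template_groups = C_group, theta = config$theta,
                          eta = config$eta, seed = config$seed),
                     class = "ground_truth")
  list(matrices = mats, truth = truth)
}

parcel_labels <- function(p) sprintf("parcel%03d", seq_len(p))

#' Simulate parcellated BOLD time series from a target correlation matrix
#'
#' Draws T rows from a zero-mean multivariate normal whose correlation is
#' the given matrix, via its symmetric eigen factorization.
#'
#' @param matrix P x P correlation matrix.
#' @param T_len number of time points (T > P recommended).
#' @param seed integer seed.
#' @return T x P numeric matrix with parcel labels as column names.
#' @export
simulate_bold <- function(matrix, T_len, seed) {
  m <- as.matrix(matrix)
  p <- ncol(m)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("correlation matrix is not positive semi-definite (smallest eigenvalue ",
         format(min(e$values)), ")")
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Z <- with_seed(seed, stats::rnorm(T_len * p))
  X <- matrix(Z, T_len, p) %*% A
  colnames(X) <- colnames(m)
  if (is.null(colnames(X))) colnames(X) <- parcel_labels(p)
  X
}

#' Simulate a complete synthetic cohort
#'
#' Bundles [simulate_groups()], [simulate_social_roster()],
#' [simulate_subject_connectomes()], [simulate_bold()] and
#' [simulate_covariates()] into one reproducible study object.
#'
#' @param config a [sim_config()].
#' @param bold if `FALSE`, skip the time-series stage and carry the
#'   correlation matrices forward directly.
#' @return List of class `synthetic_cohort`: roster, groups, matrices
#'   (ground-truth correlation), series (if `bold`), covariates, truth,
#'   config.
#' @export
simulate_cohort <- function(config, bold = TRUE) {
  groups <- simulate_groups(config)
  roster <- simulate_social_roster(config, groups)
  conn <- simulate_subject_connectomes(groups, config)
  series <- NULL
  if (bold) {
    series <- lapply(names(conn$matrices), function(id)
      simulate_bold(conn$matrices[[id]], config$n_timepoints,
                    child_seed(config$seed, paste0("bold/", id))))
    names(series) <- names(conn$matrices)
  }
  structure(list(roster = roster, groups = groups, matrices = conn$matrices,
                 series = series, covariates = simulate_covariates(config),
                 truth = conn$truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_students, "students,",
      x$config$n_groups, "planted groups, P =", x$config$n_parcels, "\n")
  cat("  theta =", x$config$theta, "(homophily), eta =", x$config$eta,
      ", seed =", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the roster CSV, one tab-separated T x P time-series file per
#' subject, a ground-truth JSON (group labels, theta, eta, seed) and a
#' manifest CSV mapping subject IDs to file paths.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(cohort$roster, file.path(dir, "roster.csv"))
  ids <- names(cohort$matrices)
  paths <- character(0)
  if (!is.null(cohort$series)) {
    paths <- vapply(ids, function(id) {
      p <- file.path(dir, paste0(id, "_timeseries.tsv"))
      utils::write.table(format(cohort$series[[id]], digits = 17),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }, character(1))
    utils::write.csv(data.frame(id = ids, path = paths),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(groups = as.list(cohort$groups), theta = cohort$config$theta,
         eta = cohort$config$eta, seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}
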