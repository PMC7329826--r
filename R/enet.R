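#' Edgewise similarity features for social-distance prediction
#'
#' For each dyad (i, j) and each node pair (p, q), the feature is the local
#' similarity of that connection between the two subjects. The default is
#' the negative absolute Fisher-z difference `-|z_i(p,q) - z_j(p,q)|`
#' (0 = maximally similar, more negative = less similar); alternatives are
#' the edgewise product and the edgewise mean. All variants are symmetric
#' in the dyad members.
#'
#' @param z_list named list of [fisher_z()] matrices over a common parcel
#'   set (P parcels give `P(P-1)/2` features).
#' @param distances [social_distance()] matrix supplying the target.
#' @param pairs optional 2-column matrix of subject IDs; defaults to every
#'   unordered pair in `z_list` with finite social distance.
#' @param method `"negabs"` (default), `"product"` or `"zmean"`.
#' @return List of class `feature_table`: `features` (dyads x edges),
#'   `target` (social distance), `members` (2-column ID matrix), `method`.
#' @export
edgewise_similarity_features <- function(z_list, distances, pairs = NULL,
                                         method = c("negabs", "product", "zmean")) {
  method <- match.arg(method)
  ids <- names(z_list)
  labs <- lapply(z_list, colnames)
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    stop("all subjects must share one parcel set")
  if (is.null(pairs)) {
    n <- length(ids)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    pairs <- cbind(ids[idx[, 1]], ids[idx[, 2]])
    d <- distances[pairs]
    pairs <- pairs[is.finite(d), , drop = FALSE]
  }
  V <- vapply(z_list, utri_vector, numeric(length(utri_vector(z_list[[1]]))))
  vi <- t(V[, pairs[, 1], drop = FALSE])
  vj <- t(V[, pairs[, 2], drop = FALSE])
  feats <- switch(method,
                  negabs = -abs(vi - vj),
                  product = vi * vj,
                  zmean = (vi + vj) / 2)
  p <- ncol(z_list[[1]])
  plabs <- colnames(z_list[[1]]) %||% parcel_labels(p)
  en <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  en <- en[order(en[, 1], en[, 2]), , drop = FALSE]
  colnames(feats) <- paste0(plabs[en[, 1]], "|", plabs[en[, 2]])
  structure(list(features = feats, target = unname(distances[pairs]),
                 members = pairs, method = method),
            class = "feature_table")
}

# deterministic grouped fold assignment: subjects -> folds
assign_subject_folds <- function(subjects, k, seed) {
  subjects <- sort(unique(subjects))
  k <- min(k, length(subjects))
  f <- with_seed(seed, sample(rep_len(seq_len(k), length(subjects))))
  stats::setNames(f, subjects)
}

#' Grouped nested cross-validated elastic net
#'
#' Predicts social distance from edgewise similarity features with elastic
#' net regression, using subject-grouped nested cross-validation: outer
#' test folds contain only dyads whose two members are both held out, and
#' training folds only dyads touching no held-out subject, so no subject
#' leaks between training and test. Inner (also subject-grouped) folds
#' select the mixing parameter alpha and penalty lambda by mean squared
#' error; features are standardized with training-fold statistics only.
#'
#' @param ft a [edgewise_similarity_features()] feature table (>= 20 dyads).
#' @param n_outer,n_inner numbers of outer/inner folds.
#' @param alphas mixing-parameter grid.
#' @param nlambda,lambda_min_ratio glmnet penalty path controls (about 4
#'   decades below the all-zero lambda by default).
#' @param lambda_path optional fixed lambda path overriding the glmnet one.
#' @param seed integer seed controlling fold assignment.
#' @return Object of class `enet_result`: out-of-fold `predictions`,
#'   `cor` and `mse` scores, per-fold chosen `(alpha, lambda)`, `nonzero`
#'   coefficient count of the final full-data fit, fold bookkeeping
#'   (including training-fold feature means for leakage audits), `seed`.
#' @export
fit_elastic_net <- function(ft, n_outer = 4, n_inner = 4,
                            alphas = c(0.1, 0.25, 0.5, 0.75, 1),
                            nlambda = 50, lambda_min_ratio = 1e-4,
                            lambda_path = NULL, seed = 1) {
  stopifnot(inherits(ft, "feature_table"))
  y <- ft$target
  if (length(y) < 20) stop("need at least 20 dyads, got ", length(y))
  if (length(unique(y)) < 2) stop("degenerate target: a single distance value")
  X <- ft$features
  subj <- ft$members
  folds <- assign_subject_folds(c(subj), n_outer, child_seed(seed, "outer"))
  oof_pred <- rep(NA_real_, length(y))
  chosen <- list(); fold_means <- list()
  for (f in seq_len(max(folds))) {
    held <- names(folds)[folds == f]
    test_idx <- which(subj[, 1] %in% held & subj[, 2] %in% held)
    train_idx <- which(!(subj[, 1] %in% held) & !(subj[, 2] %in% held))
    if (length(test_idx) == 0 || length(train_idx) < 10 ||
        stats::sd(y[train_idx]) == 0) next
    sel <- select_and_fit(X[train_idx, , drop = FALSE], y[train_idx],
                          subj[train_idx, , drop = FALSE], n_inner, alphas,
                          nlambda, lambda_min_ratio, lambda_path,
                          child_seed(seed, paste0("inner/", f)))
    Xte <- scale_with(X[test_idx, , drop = FALSE], sel$center, sel$scale)
    oof_pred[test_idx] <- drop(stats::predict(sel$fit, Xte, s = sel$lambda))
    chosen[[f]] <- data.frame(fold = f, alpha = sel$alpha, lambda = sel$lambda)
    fold_means[[f]] <- sel$center
  }
  scored <- !is.na(oof_pred)
  r <- if (sum(scored) >= 3 && stats::sd(oof_pred[scored]) > 0 &&
           stats::sd(y[scored]) > 0)
    stats::cor(oof_pred[scored], y[scored]) else 0
  final <- select_and_fit(X, y, subj, n_inner, alphas, nlambda,
                          lambda_min_ratio, lambda_path,
                          child_seed(seed, "final"))
  cf <- stats::coef(final$fit, s = final$lambda)
  structure(list(predictions = oof_pred, target = y, cor = r,
                 mse = mean((oof_pred[scored] - y[scored])^2),
                 n_scored = sum(scored),
                 chosen = do.call(rbind, chosen),
                 alpha = final$alpha, lambda = final$lambda,
                 nonzero = sum(cf[-1] != 0),
                 coefficients = cf,
                 fold_means = fold_means, folds = folds, seed = seed),
            class = "enet_result")
}

scale_with <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

# inner-CV (alpha, lambda) selection + fit on the given training data
select_and_fit <- function(X, y, subj, n_inner, alphas, nlambda,
                           lambda_min_ratio, lambda_path, seed) {
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Xs <- scale_with(X, center, scl)
  inner <- assign_subject_folds(c(subj), n_inner, seed)
  best <- NULL
  for (a in alphas) {
    full <- glmnet::glmnet(Xs, y, alpha = a, nlambda = nlambda,
                           lambda.min.ratio = lambda_min_ratio,
                           lambda = lambda_path, standardize = FALSE)
    lams <- full$lambda
    err <- matrix(NA_real_, max(inner), length(lams))
    for (g in seq_len(max(inner))) {
      held <- names(inner)[inner == g]
      va <- which(subj[, 1] %in% held & subj[, 2] %in% held)
      tr <- which(!(subj[, 1] %in% held) & !(subj[, 2] %in% held))
      if (length(va) == 0 || length(tr) < 5 || stats::sd(y[tr]) == 0) next
      fg <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], alpha = a,
                           lambda = lams, standardize = FALSE)
      pr <- stats::predict(fg, Xs[va, , drop = FALSE], s = lams)
      err[g, ] <- colMeans((pr - y[va])^2)
    }
    mse <- colMeans(err, na.rm = TRUE)
    j <- which.min(mse)
    if (length(j) == 0) {        # no inner fold usable: mid-path fallback
      j <- ceiling(length(lams) / 2)
      mse[j] <- Inf
    }
    if (is.null(best) || !is.finite(best$mse) || mse[j] < best$mse)
      best <- list(alpha = a, lambda = lams[j], mse = mse[j], fit = full)
  }
  c(best, list(center = center, scale = scl))
}

#' @export
print.enet_result <- function(x, digits = 3, ...) {
  cat("Grouped nested-CV elastic net\n")
  cat("  out-of-fold cor =", round(x$cor, digits), ", MSE =",
      round(x$mse, digits), "over", x$n_scored, "dyads\n")
  cat("  final fit: alpha =", x$alpha, ", lambda =", signif(x$lambda, digits),
      ",", x$nonzero, "nonzero coefficients\n")
  invisible(x)
}

#' Permutation test of elastic-net predictability
#'
#' Permutes the social-distance target across dyads (the subject-grouped
#' fold structure is preserved) and compares the observed out-of-fold
#' prediction correlation with the permutation distribution:
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`. A large p means the
#' connectome features carry no detectable distance signal.
#'
#' @param ft a [edgewise_similarity_features()] feature table.
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed (fit folds and permutations all derive from it).
#' @param ... passed to [fit_elastic_net()].
#' @return List of class `enet_permutation`: `p_value`, `observed`,
#'   `perm_scores`, `n_perm`, `seed`.
#' @export
permutation_test <- function(ft, n_perm = 99, seed = 1, ...) {
  if (n_perm < 19) stop("n_perm must be at least 19")
  obs <- fit_elastic_net(ft, seed = child_seed(seed, "observed"), ...)
  perm_scores <- vapply(seq_len(n_perm), function(b) {
    ftb <- ft
    ftb$target <- with_seed(child_seed(seed, paste0("perm/", b)),
                            sample(ft$target))
    fit_elastic_net(ftb, seed = child_seed(seed, "observed"), ...)$cor
  }, numeric(1))
  structure(list(p_value = (1 + sum(perm_scores >= obs$cor)) / (1 + n_perm),
                 observed = obs$cor, perm_scores = perm_scores,
                 n_perm = n_perm, seed = seed, fit = obs),
            class = "enet_permutation")
}

#' @export
print.enet_permutation <- function(x, digits = 3, ...) {
  cat("Permutation test of distance predictability:\n")
  cat("  observed out-of-fold cor =", round(x$observed, digits),
      ", p =", round(x$p_value, digits), "(", x$n_perm, "permutations )\n")
  invisible(x)
}
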