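#' Crossed-random-effects linear mixed model for dyadic outcomes
#'
#' Fits the dyadic model
#' \deqn{y_{ij} = x_{ij}' \beta + u_i + u_j + \epsilon_{ij},}
#' where every subject contributes a random intercept `u ~ N(0, sigma2_u)`
#' to each dyad it belongs to (crossed membership) and
#' `eps ~ N(0, sigma2_e)`. Because dyads are unordered, the two member
#' effects share a single variance component (exchangeable dyads); using
#' ordinary least squares on such data ignores the dependence created by
#' each subject appearing in many dyads and inflates type-I error.
#'
#' Estimation is restricted maximum likelihood: with
#' `lambda = sigma2_u / sigma2_e` the covariance is
#' `V = sigma2_e (I + lambda Z Z')` for the dyad-membership matrix Z, and
#' the one-dimensional REML profile in `lambda` is minimised exactly via a
#' thin eigendecomposition of `Z'Z`. `lambda = 0` (the OLS boundary) is
#' always evaluated and the fit is flagged singular when it wins.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `similarity ~ distance`; variables are looked up in `data`.
#' @param data a data.frame (typically a [build_dyad_table()] result).
#' @param members length-2 character vector naming the columns of `data`
#'   holding the two member IDs of each dyad.
#' @param df `"normal"` (Wald z tests, default) or `"satterthwaite"`
#'   (t tests with Satterthwaite degrees of freedom).
#' @return An object of class `dyad_lme`. Components include
#'   `coefficients`, `se`, `statistic`, `df`, `p_value`, `vcov`,
#'   `sigma2_u`, `sigma2_e`, `converged`, `singular`, `n_dyads`,
#'   `n_subjects`, `n_dropped` (rows removed for non-finite model
#'   variables, e.g. unreachable dyads).
#' @seealso [fit_dyadic_lme()] for the dyad-table front end,
#'   [meta_analyze()] for pooling cohorts.
#' @export
dyad_lme <- function(formula, data, members = c("i", "j"),
                     df = c("normal", "satterthwaite")) {
  df <- match.arg(df)
  stopifnot(is.data.frame(data), all(members %in% names(data)))
  vars <- all.vars(formula)
  if (!all(vars %in% names(data)))
    stop("variables not in data: ", paste(setdiff(vars, names(data)), collapse = ", "))
  finite <- rowSums(!is.finite(as.matrix(
    data.frame(lapply(data[vars], as.numeric))))) == 0
  n_dropped <- sum(!finite)
  d <- data[finite, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (ncol(X) > 1) {
    const <- apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2,
                   function(v) stats::sd(v) == 0)
    if (any(const))
      stop("predictor has no variance across dyads: ",
           paste(names(const)[const], collapse = ", "))
  }
  subj <- sort(unique(c(as.character(d[[members[1]]]), as.character(d[[members[2]]]))))
  if (length(subj) < 3) stop("need at least 3 subjects")
  n <- length(y); p <- ncol(X)
  Z <- matrix(0, n, length(subj))
  Z[cbind(seq_len(n), match(as.character(d[[members[1]]]), subj))] <- 1
  Z[cbind(seq_len(n), match(as.character(d[[members[2]]]), subj))] <- Z[
    cbind(seq_len(n), match(as.character(d[[members[2]]]), subj))] + 1

  # thin spectral decomposition of ZZ' through Z'Z
  ee <- eigen(crossprod(Z), symmetric = TRUE)
  keep <- ee$values > 1e-10
  s2 <- ee$values[keep]
  U <- Z %*% ee$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(s2), sum(keep))

  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  UX <- crossprod(U, X); Uy <- crossprod(U, y)

  gls <- function(lambda) {
    g <- lambda * s2 / (1 + lambda * s2)
    XtWX <- XtX - crossprod(UX, g * UX)
    XtWy <- Xty - crossprod(UX, g * Uy)
    ytWy <- yty - sum(g * Uy^2)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- max(ytWy - sum(beta * XtWy), 1e-300)
    list(beta = drop(beta), rss = rss, XtWX = XtWX, logdetA = 2 * sum(log(diag(ch))),
         logdetV = sum(log1p(lambda * s2)))
  }
  crit <- function(lambda) {
    f <- gls(lambda)
    if (is.null(f)) return(Inf)
    (n - p) * log(f$rss / (n - p)) + f$logdetV + f$logdetA
  }
  opt <- stats::optimize(function(t) crit(exp(t)), c(-15, 10), tol = 1e-10)
  lambda <- exp(opt$minimum)
  c0 <- crit(0)
  singular <- c0 <= opt$objective + 1e-8
  if (singular) lambda <- 0
  fit <- gls(lambda)
  if (is.null(fit)) stop("fixed-effects design is rank deficient")
  sigma2_e <- fit$rss / (n - p)
  sigma2_u <- lambda * sigma2_e
  vc <- sigma2_e * solve(fit$XtWX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- fit$beta; names(beta) <- colnames(X)
  se <- sqrt(diag(vc))
  reml2 <- crit(lambda) + (n - p) * (1 + log(2 * pi))

  dfs <- rep(Inf, p)
  if (df == "satterthwaite") dfs <- satterthwaite_df(sigma2_u, sigma2_e, n, p,
                                                     s2, XtX, UX, Xty, Uy, yty)
  stat <- beta / se
  pv <- 2 * stats::pt(-abs(stat), df = dfs)

  structure(list(
    coefficients = beta, se = se, statistic = stat, df = dfs, p_value = pv,
    vcov = vc, sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = lambda,
    reml_criterion = reml2, logLik = -reml2 / 2,
    converged = TRUE, singular = singular,
    n_dyads = n, n_subjects = length(subj), n_dropped = n_dropped,
    formula = formula, df_method = df,
    subjects = subj, X = X, y = y, Z = Z, members = members,
    fitted = drop(X %*% beta), call = match.call()
  ), class = "dyad_lme")
}

# Satterthwaite df for each coefficient: df_j = 2 v_j^2 / Var(v_j) with
# v_j = vcov_jj(sigma2_u, sigma2_e), Var via the inverse REML information,
# both obtained by central finite differences.
satterthwaite_df <- function(sigma2_u, sigma2_e, n, p, s2, XtX, UX, Xty, Uy, yty) {
  vcov_diag <- function(su, se2) {
    lam <- su / se2
    g <- lam * s2 / (1 + lam * s2)
    XtWX <- XtX - crossprod(UX, g * UX)
    se2 * diag(solve(XtWX))
  }
  m2ll <- function(su, se2) {
    lam <- su / se2
    g <- lam * s2 / (1 + lam * s2)
    XtWX <- XtX - crossprod(UX, g * UX)
    XtWy <- Xty - crossprod(UX, g * Uy)
    ytWy <- yty - sum(g * Uy^2)
    beta <- solve(XtWX, XtWy)
    rss <- ytWy - sum(beta * XtWy)
    n * log(se2) + sum(log1p(lam * s2)) + rss / se2 +
      determinant(XtWX / se2)$modulus[1]
  }
  h <- c(max(sigma2_u, 1e-4) * 1e-3, sigma2_e * 1e-3)
  th <- c(sigma2_u, sigma2_e)
  H <- matrix(0, 2, 2)
  f0 <- m2ll(th[1], th[2])
  for (a in 1:2) for (b in a:2) {
    ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
    if (a == b) {
      tp <- pmax(th + ea, c(0, 1e-12)); tm <- pmax(th - ea, c(0, 1e-12))
      H[a, a] <- (m2ll(tp[1], tp[2]) - 2 * f0 + m2ll(tm[1], tm[2])) / h[a]^2
    } else {
      pp <- pmax(th + ea + eb, c(0, 1e-12)); pm <- pmax(th + ea - eb, c(0, 1e-12))
      mp <- pmax(th - ea + eb, c(0, 1e-12)); mm <- pmax(th - ea - eb, c(0, 1e-12))
      H[a, b] <- H[b, a] <- (m2ll(pp[1], pp[2]) - m2ll(pm[1], pm[2]) -
                               m2ll(mp[1], mp[2]) + m2ll(mm[1], mm[2])) /
        (4 * h[a] * h[b])
    }
  }
  Iinv <- tryCatch(solve(H / 2), error = function(e) NULL)
  if (is.null(Iinv)) return(rep(Inf, p))
  grads <- vapply(1:2, function(a) {
    ea <- c(0, 0); ea[a] <- h[a]
    tp <- pmax(th + ea, c(0, 1e-12)); tm <- pmax(th - ea, c(0, 1e-12))
    (vcov_diag(tp[1], tp[2]) - vcov_diag(tm[1], tm[2])) / (tp[a] - tm[a])
  }, numeric(p))
  v <- vcov_diag(th[1], th[2])
  dfs <- vapply(seq_len(p), function(j) {
    varv <- drop(grads[j, , drop = FALSE] %*% Iinv %*% t(grads[j, , drop = FALSE]))
    if (varv <= 0) return(Inf)
    2 * v[j]^2 / varv
  }, numeric(1))
  pmax(dfs, 1)
}

#' Fit the dyadic model to a dyad table
#'
#' Front end to [dyad_lme()] matching the analysis pipeline: the outcome is
#' the standardized similarity, the predictor is either geodesic social
#' distance (continuous) or binary community co-membership, and the
#' covariate model adds ethnicity match, boarding match and head-motion
#' terms as fixed effects. Dyads with non-finite distance (unreachable
#' pairs) are dropped with a recorded count.
#'
#' @param table a [build_dyad_table()] result.
#' @param predictor `"distance"` or `"community"`.
#' @param covariates add the demographic and motion fixed effects?
#' @param df test type, see [dyad_lme()].
#' @return A `dyad_lme` fit; the predictor's coefficient is named
#'   `"distance"` or `"same_community"`.
#' @export
fit_dyadic_lme <- function(table, predictor = c("distance", "community"),
                           covariates = FALSE, df = c("normal", "satterthwaite")) {
  predictor <- match.arg(predictor)
  xvar <- if (predictor == "distance") "distance" else "same_community"
  rhs <- xvar
  if (covariates) {
    extra <- intersect(c("ethnicity_match", "boarding_match", "motion_abs_mean",
                         "motion_abs_diff", "motion_rel_mean", "motion_rel_diff"),
                       names(table))
    rhs <- paste(c(xvar, extra), collapse = " + ")
  }
  f <- stats::as.formula(paste("similarity ~", rhs))
  dyad_lme(f, table, members = c("i", "j"), df = df)
}

#' @export
print.dyad_lme <- function(x, digits = 4, ...) {
  cat("Dyadic LME with crossed random member effects (REML)\n")
  cat("  ", x$n_dyads, " dyads, ", x$n_subjects, " subjects",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " dyads dropped)"), "\n", sep = "")
  print(round(x$coefficients, digits))
  cat("sigma2_u =", signif(x$sigma2_u, digits),
      " sigma2_e =", signif(x$sigma2_e, digits),
      if (x$singular) " (singular: member variance at 0)", "\n")
  invisible(x)
}

#' @export
summary.dyad_lme <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$statistic, df = object$df,
               `Pr(>|t|)` = object$p_value)
  structure(list(coefficients = tab, sigma2_u = object$sigma2_u,
                 sigma2_e = object$sigma2_e, singular = object$singular,
                 n_dyads = object$n_dyads, n_subjects = object$n_subjects,
                 n_dropped = object$n_dropped, formula = object$formula,
                 df_method = object$df_method, logLik = object$logLik),
            class = "summary.dyad_lme")
}

#' @export
print.summary.dyad_lme <- function(x, digits = 4, ...) {
  cat("Dyadic linear mixed model (REML), crossed random member intercepts\n")
  cat("Formula:", deparse(x$formula), "\n")
  cat(x$n_dyads, "dyads,", x$n_subjects, "subjects")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " unreachable/incomplete dyads dropped)", sep = "")
  cat("\n\nFixed effects (", if (x$df_method == "normal") "Wald z" else "Satterthwaite t",
      " tests):\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nVariance components: member sigma2_u =", signif(x$sigma2_u, digits),
      ", residual sigma2_e =", signif(x$sigma2_e, digits), "\n")
  if (x$singular) cat("Note: singular fit, member variance estimated at zero\n")
  invisible(x)
}

#' @export
coef.dyad_lme <- function(object, ...) object$coefficients

#' @export
vcov.dyad_lme <- function(object, ...) object$vcov

#' @export
logLik.dyad_lme <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            nobs = object$n_dyads, class = "logLik")
}

#' @export
nobs.dyad_lme <- function(object, ...) object$n_dyads

#' Random-effect predictions (BLUPs) of the member intercepts
#'
#' @param object a `dyad_lme` fit.
#' @param ... unused.
#' @return Named numeric vector of subject-level BLUPs.
#' @export
ranef.dyad_lme <- function(object, ...) {
  e <- object$y - object$fitted
  lam <- object$lambda
  if (lam == 0) {
    u <- rep(0, object$n_subjects)
  } else {
    Z <- object$Z
    Vinv_e <- solve(diag(object$n_dyads) + lam * tcrossprod(Z), e)
    u <- lam * drop(crossprod(Z, Vinv_e))
  }
  names(u) <- object$subjects
  u
}

#' @rdname ranef.dyad_lme
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
fitted.dyad_lme <- function(object, ...) object$fitted

#' @export
residuals.dyad_lme <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "conditional")
    r <- r - drop(object$Z %*% ranef(object))
  r
}

#' @export
predict.dyad_lme <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$coefficients[colnames(X)])
}

#' @export
plot.dyad_lme <- function(x, ...) {
  graphics::plot(x$fitted, residuals(x), xlab = "Fitted similarity",
                 ylab = "Marginal residual",
                 main = "Dyadic LME: residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
simulate.dyad_lme <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_dyads
  out <- replicate(nsim, {
    u <- stats::rnorm(object$n_subjects, 0, sqrt(object$sigma2_u))
    object$fitted + drop(object$Z %*% u) +
      stats::rnorm(n, 0, sqrt(object$sigma2_e))
  })
  as.data.frame(out)
}
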