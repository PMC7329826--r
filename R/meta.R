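#' Random-effects meta-analysis of per-cohort dyadic fits
#'
#' Pools one named coefficient across independent cohort fits with a
#' random-effects model: cohort effects are `beta_k ~ N(beta_pooled,
#' tau2 + SE_k^2)`, the between-cohort variance `tau2` estimated by
#' restricted maximum likelihood (default), DerSimonian-Laird (`"DL"`), or
#' fixed at zero (`"FE"`). Pooling uses inverse-variance weights
#' `1 / (SE_k^2 + tau2)` and a normal 95% confidence interval. Backed by
#' [metafor::rma.uni()].
#'
#' @param fits list of [dyad_lme()] objects, or a data.frame with columns
#'   `beta` and `se` (one row per cohort).
#' @param coefficient name of the coefficient to pool (ignored for the
#'   data.frame form).
#' @param method `"REML"` (default), `"DL"` or `"FE"`.
#' @return Object of class `dyad_meta`: `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `tau2`, `zval`, `pval`, `weights` (normalised to sum 1),
#'   `k`, `per_cohort` (data.frame of inputs), `method`.
#' @export
meta_analyze <- function(fits, coefficient = "distance",
                         method = c("REML", "DL", "FE")) {
  method <- match.arg(method)
  if (is.data.frame(fits)) {
    stopifnot(all(c("beta", "se") %in% names(fits)))
    betas <- fits$beta; ses <- fits$se
  } else {
    betas <- vapply(fits, function(f) unname(stats::coef(f)[coefficient]), numeric(1))
    ses <- vapply(fits, function(f) unname(f$se[coefficient]), numeric(1))
  }
  if (length(betas) < 2) stop("meta-analysis needs at least 2 cohorts, got ",
                              length(betas))
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all standard errors must be finite and positive")
  rma <- metafor::rma.uni(yi = betas, sei = ses, method = method,
                          control = list(threshold = 1e-10, maxiter = 1000))
  w <- stats::weights(rma); w <- w / sum(w)
  structure(list(estimate = as.numeric(rma$b), se = rma$se,
                 ci_lower = rma$ci.lb, ci_upper = rma$ci.ub,
                 tau2 = rma$tau2, zval = rma$zval, pval = rma$pval,
                 weights = as.numeric(w), k = rma$k,
                 per_cohort = data.frame(beta = betas, se = ses),
                 coefficient = coefficient, method = method),
            class = "dyad_meta")
}

#' @export
print.dyad_meta <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis (", x$method, "), k = ", x$k,
      " cohorts, coefficient '", x$coefficient, "'\n", sep = "")
  cat(sprintf("  pooled beta = %.*g  SE = %.*g  95%% CI [%.*g, %.*g]\n",
              digits, x$estimate, digits, x$se, digits, x$ci_lower,
              digits, x$ci_upper))
  cat(sprintf("  tau2 = %.*g, z = %.*g, p = %.*g\n", digits, x$tau2,
              digits, x$zval, digits, x$pval))
  invisible(x)
}

#' @export
summary.dyad_meta <- function(object, ...) object

#' @export
plot.dyad_meta <- function(x, ...) {
  k <- x$k
  b <- c(x$per_cohort$beta, x$estimate)
  lo <- c(x$per_cohort$beta - 1.96 * x$per_cohort$se, x$ci_lower)
  hi <- c(x$per_cohort$beta + 1.96 * x$per_cohort$se, x$ci_upper)
  ypos <- rev(seq_len(k + 1))
  graphics::plot(b, ypos, xlim = range(lo, hi, 0), yaxt = "n",
                 xlab = paste("Effect of", x$coefficient), ylab = "",
                 pch = c(rep(19, k), 17),
                 main = "Random-effects meta-analysis", ...)
  graphics::segments(lo, ypos, hi, ypos)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = ypos, labels = c(paste0("cohort", seq_len(k)), "pooled"),
                 las = 1)
  invisible(x)
}

#' @export
coef.dyad_meta <- function(object, ...) {
  stats::setNames(object$estimate, object$coefficient)
}

#' Forest-plot-ready table of cohort and pooled estimates
#'
#' @param fits named list of `dyad_lme` fits (names = cohort labels).
#' @param meta matching [meta_analyze()] result.
#' @param coefficient coefficient name.
#' @param scope scope label to record.
#' @return data.frame with columns cohort, scope, beta, lo, hi (95% CI).
#' @export
forest_table <- function(fits, meta, coefficient = "distance",
                         scope = "whole-brain") {
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    b <- unname(stats::coef(f)[coefficient]); s <- unname(f$se[coefficient])
    data.frame(cohort = names(fits)[k] %||% paste0("cohort", k), scope = scope,
               beta = b, lo = b - 1.96 * s, hi = b + 1.96 * s)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(cohort = "pooled", scope = scope, beta = meta$estimate,
                        lo = meta$ci_lower, hi = meta$ci_upper))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
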