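#' Simulate a multi-cohort study and build its dyad tables
#'
#' Runs the full synthetic pipeline for each cohort: roster with planted
#' groups, reciprocal threshold-4 social graph, geodesic distances and
#' Louvain communities, per-subject connectomes (optionally realized as
#' BOLD time series and re-estimated), Fisher-z inter-subject similarity,
#' and a standardized dyad table.
#'
#' @param cohort_sizes integer vector of cohort sizes.
#' @param seed root seed; cohorts use derived child seeds.
#' @param theta,eta connectome mixture weights, see [sim_config()].
#' @param n_parcels,n_timepoints parcellation size and scan length.
#' @param n_groups,p_in,p_out,likert_noise roster parameters.
#' @param bold if `TRUE` (default) connectomes are realized as multivariate
#'   normal time series and re-estimated with [correlation_matrix()]; if
#'   `FALSE` the ground-truth matrices are used directly.
#' @param covariates include simulated dyad covariates in the tables?
#' @param louvain_restarts restarts for community detection.
#' @return List of class `dyad_study`: `tables` (one `dyad_table` per
#'   cohort), `cohorts` (the `synthetic_cohort` objects), `seed`.
#' @export
simulate_study <- function(cohort_sizes = c(23, 17, 28), seed = 1, theta = 0,
                           eta = 0.3, n_parcels = 40, n_timepoints = 250,
                           n_groups = 4, p_in = 0.85, p_out = 0.25,
                           likert_noise = 0.1, bold = TRUE, covariates = TRUE,
                           louvain_restarts = 25) {
  tables <- vector("list", length(cohort_sizes))
  cohorts <- vector("list", length(cohort_sizes))
  for (k in seq_along(cohort_sizes)) {
    label <- paste0("cohort", k)
    cfg <- sim_config(n_students = cohort_sizes[k], n_parcels = n_parcels,
                      n_timepoints = n_timepoints, p_in = p_in, p_out = p_out,
                      n_groups = n_groups, theta = theta, eta = eta,
                      likert_noise = likert_noise,
                      seed = child_seed(seed, label))
    sim <- simulate_cohort(cfg, bold = bold)
    graph <- build_social_graph(sim$roster, threshold = 4, mode = "reciprocal")
    dist <- social_distance(graph)
    part <- detect_communities(graph, seed = child_seed(cfg$seed, "communities"),
                               restarts = louvain_restarts)
    z <- if (bold)
      lapply(sim$series, function(ts) fisher_z(correlation_matrix(ts)))
    else lapply(sim$matrices, fisher_z)
    sims <- similarity_matrix(z)
    tables[[k]] <- build_dyad_table(
      sims, dist, part,
      covariates = if (covariates) sim$covariates else NULL,
      cohort = label)
    cohorts[[k]] <- sim
  }
  names(tables) <- names(cohorts) <- paste0("cohort", seq_along(cohort_sizes))
  structure(list(tables = tables, cohorts = cohorts, seed = seed),
            class = "dyad_study")
}

#' Fit all cohorts of a study and pool them
#'
#' @param study a [simulate_study()] result or a named list of dyad tables.
#' @param predictor `"distance"` or `"community"`.
#' @param covariates forwarded to [fit_dyadic_lme()].
#' @return List with `fits` (per-cohort `dyad_lme`) and `meta`
#'   ([meta_analyze()] over them).
#' @export
fit_study <- function(study, predictor = c("distance", "community"),
                      covariates = FALSE) {
  predictor <- match.arg(predictor)
  tables <- if (inherits(study, "dyad_study")) study$tables else study
  fits <- lapply(tables, fit_dyadic_lme, predictor = predictor,
                 covariates = covariates)
  coefname <- if (predictor == "distance") "distance" else "same_community"
  meta <- if (length(fits) >= 2) meta_analyze(fits, coefname) else NULL
  list(fits = fits, meta = meta)
}

#' Power and type-I error simulation for the dyadic pipeline
#'
#' For every cell of the `theta` x `cohort_sizes` grid, simulates `R`
#' replicate studies end-to-end (roster, graph, connectomes, similarity,
#' per-cohort dyadic LME, random-effects meta-analysis) and records how
#' often the pooled social-distance effect rejects H0 at level `alpha`.
#' With `theta = 0` this measures type-I error of the full pipeline; with
#' `theta > 0` it measures power against the planted homophily effect.
#'
#' @param theta numeric vector of homophily effect sizes.
#' @param cohort_sizes list of integer vectors (one study design per entry).
#' @param R replicates per cell.
#' @param alpha nominal level.
#' @param seed root seed; each cell and replicate has its own derived stream,
#'   so enlarging `R` never perturbs earlier replicates.
#' @param n_parcels,n_timepoints,eta,bold forwarded to [simulate_study()].
#' @param predictor forwarded to [fit_study()].
#' @return data.frame of class `power_table`: theta, design, R, alpha,
#'   rejection_rate, mc_se (binomial Monte-Carlo SE), n_failed, plus the
#'   mean pooled estimate per cell.
#' @export
power_simulation <- function(theta = c(0, 0.3), cohort_sizes = list(c(23, 17, 28)),
                             R = 200, alpha = 0.05, seed = 1, n_parcels = 40,
                             n_timepoints = 250, eta = 0.3, bold = TRUE,
                             predictor = "distance") {
  cells <- expand.grid(theta = theta, design = seq_along(cohort_sizes))
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    th <- cells$theta[ci]
    sizes <- cohort_sizes[[cells$design[ci]]]
    cell_lab <- paste0("cell/theta=", format(th), "/design=", cells$design[ci])
    pvals <- numeric(R); est <- numeric(R); failed <- 0L
    for (r in seq_len(R)) {
      res <- tryCatch({
        st <- simulate_study(sizes, seed = child_seed(seed, paste0(cell_lab, "/rep", r)),
                             theta = th, eta = eta, n_parcels = n_parcels,
                             n_timepoints = n_timepoints, covariates = FALSE)
        fs <- fit_study(st, predictor = predictor)
        if (is.null(fs$meta)) {
          f <- fs$fits[[1]]
          j <- if (predictor == "distance") "distance" else "same_community"
          list(p = unname(f$p_value[j]), b = unname(stats::coef(f)[j]))
        } else list(p = fs$meta$pval, b = fs$meta$estimate)
      }, error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; pvals[r] <- NA; est[r] <- NA }
      else { pvals[r] <- res$p; est[r] <- res$b }
    }
    ok <- !is.na(pvals)
    rate <- mean(pvals[ok] < alpha)
    data.frame(theta = th, design = paste(sizes, collapse = "+"), R = R,
               alpha = alpha, rejection_rate = rate,
               mc_se = sqrt(rate * (1 - rate) / sum(ok)),
               mean_estimate = mean(est[ok]), n_failed = failed)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("power_table", "data.frame")
  out
}
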