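#' Block network mask for a synthetic parcellation
#'
#' Assigns contiguous blocks of parcels to the four resting-state networks
#' (DMN, salience, lFPN, rFPN), each covering ~15% of parcels, leaving the
#' remainder unassigned — mimicking the shape of a real atlas-overlap mask
#' table without any voxel-level computation. Labelled synthetic.
#'
#' @param n_parcels number of parcels.
#' @return data.frame with columns `parcel`, `network`.
#' @export
synthetic_network_mask <- function(n_parcels) {
  labs <- parcel_labels(n_parcels)
  k <- max(2L, floor(n_parcels * 0.15))
  nets <- c("DMN", "salience", "lFPN", "rFPN")
  idx <- unlist(lapply(seq_along(nets), function(i) seq_len(k) + (i - 1L) * k))
  idx <- idx[idx <= n_parcels]
  data.frame(parcel = labs[idx],
             network = rep(nets, each = k)[seq_along(idx)],
             stringsAsFactors = FALSE)
}

#' Read a per-subject time-series manifest
#'
#' @param path manifest CSV with columns `id`, `path` (paths relative to
#'   the manifest's directory or absolute).
#' @return Named list of T x P matrices.
#' @export
load_time_series <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "path") %in% names(man)))
  base <- dirname(path)
  out <- lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, basename(p))
    as.matrix(utils::read.table(p, header = TRUE, sep = "\t",
                                check.names = FALSE))
  })
  names(out) <- man$id
  out
}

#' Pipeline run configuration
#'
#' @param cohorts named list; each element a list with either `sim` (a
#'   [simulate_cohort()] object) or paths `roster`, `manifest`,
#'   `covariates`.
#' @param threshold,mode social-graph construction settings.
#' @param scopes network scopes to analyse (subset of `"whole-brain"`,
#'   `"DMN"`, `"salience"`, `"lFPN"`, `"rFPN"`).
#' @param predictors subset of `"distance"`, `"community"`.
#' @param mask network mask data.frame (`parcel`, `network`) or path to one;
#'   `NULL` restricts scopes to whole-brain.
#' @param covariates include the dyad covariate fixed effects?
#' @param seed root seed.
#' @param out_dir output directory for artifacts (`NULL` = don't write).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(cohorts, threshold = 4, mode = "reciprocal",
                       scopes = "whole-brain", predictors = c("distance", "community"),
                       mask = NULL, covariates = FALSE, seed = 1, out_dir = NULL) {
  known <- c("whole-brain", "DMN", "salience", "lFPN", "rFPN")
  if (!all(scopes %in% known))
    stop("unknown scope(s): ", paste(setdiff(scopes, known), collapse = ", "))
  stopifnot(all(predictors %in% c("distance", "community")))
  if (is.character(mask)) mask <- utils::read.csv(mask, stringsAsFactors = FALSE)
  if (is.null(mask) && any(scopes != "whole-brain"))
    stop("network scopes requested but no mask supplied")
  structure(list(cohorts = cohorts, threshold = threshold, mode = mode,
                 scopes = scopes, predictors = predictors, mask = mask,
                 covariates = covariates, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file mirroring the [run_config()] arguments, with
#'   per-cohort `roster`/`manifest`/`covariates` paths (relative paths are
#'   resolved against the YAML's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  fix <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
  cohorts <- lapply(cfg$cohorts, function(co)
    list(roster = fix(co$roster), manifest = fix(co$manifest),
         covariates = fix(co$covariates)))
  run_config(cohorts,
             threshold = cfg$threshold %||% 4,
             mode = cfg$mode %||% "reciprocal",
             scopes = cfg$scopes %||% "whole-brain",
             predictors = cfg$predictors %||% c("distance", "community"),
             mask = fix(cfg$mask),
             covariates = isTRUE(cfg$covariates),
             seed = cfg$seed %||% 1,
             out_dir = fix(cfg$out_dir))
}

#' Run the full dyadic-similarity pipeline
#'
#' Per cohort: build the social graph, geodesic distances and Louvain
#' communities; compute per-subject connectomes and Fisher-z matrices;
#' for each network scope, compute inter-subject similarity and the
#' standardized dyad table; fit the dyadic LME for each predictor; then
#' pool each predictor x scope across cohorts by random-effects
#' meta-analysis. Artifacts (dyad tables, fit JSONs, forest CSV) are
#' written under `out_dir` together with a manifest listing content hashes.
#'
#' @param config a [run_config()].
#' @return List of class `pipeline_result`: `fits` (cohort x predictor x
#'   scope), `metas` (predictor x scope), `tables`, `summaries`
#'   (per-cohort [network_summary()]), `manifest` (data.frame, when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(cohort, what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed for ", cohort, ": ",
           conditionMessage(e), call. = FALSE))
  }
  tables <- list(); summaries <- list()
  for (nm in names(config$cohorts)) {
    co <- config$cohorts[[nm]]
    if (!is.null(co$sim)) {
      roster <- co$sim$roster
      series <- co$sim$series
      covar <- co$sim$covariates
    } else {
      roster <- stage(nm, "roster", load_roster(co$roster, cohort = nm))
      series <- stage(nm, "time series", load_time_series(co$manifest))
      covar <- if (!is.null(co$covariates))
        utils::read.csv(co$covariates, stringsAsFactors = FALSE) else NULL
    }
    graph <- stage(nm, "social graph",
                   build_social_graph(roster, config$threshold, "reciprocal"))
    dgraph <- build_social_graph(roster, config$threshold, "directed")
    dist <- stage(nm, "distances", social_distance(graph))
    part <- stage(nm, "communities",
                  detect_communities(graph, seed = child_seed(config$seed, nm)))
    summaries[[nm]] <- stage(nm, "summary",
                             network_summary(graph, dgraph,
                                             seed = child_seed(config$seed, nm)))
    z <- stage(nm, "connectomes",
               lapply(series, function(ts) fisher_z(correlation_matrix(ts))))
    message("INFO [", nm, "] ", length(z), " subjects, ",
            igraph::ecount(graph$graph), " edges, ",
            attr(dist, "n_unreachable"), " unreachable dyads, ",
            count_dyads(length(z)), " scanned dyads")
    for (sc in config$scopes) {
      zs <- if (sc == "whole-brain") z
      else lapply(z, subset_network, mask = config$mask, name = sc)
      sims <- stage(nm, paste0("similarity/", sc), similarity_matrix(zs))
      tables[[paste(nm, sc, sep = "/")]] <- stage(
        nm, paste0("dyad table/", sc),
        build_dyad_table(sims, dist, part, covariates = covar,
                         cohort = nm, scope = sc))
    }
  }
  fits <- list(); metas <- list()
  for (pred in config$predictors) {
    coefname <- if (pred == "distance") "distance" else "same_community"
    for (sc in config$scopes) {
      key <- paste(pred, sc, sep = "/")
      scope_fits <- list()
      for (nm in names(config$cohorts)) {
        tb <- tables[[paste(nm, sc, sep = "/")]]
        scope_fits[[nm]] <- stage(nm, paste0("lme/", key),
                                  fit_dyadic_lme(tb, predictor = pred,
                                                 covariates = config$covariates))
        fits[[paste(nm, key, sep = "/")]] <- scope_fits[[nm]]
      }
      if (length(scope_fits) >= 2)
        metas[[key]] <- stage("all", paste0("meta/", key),
                              meta_analyze(scope_fits, coefname))
    }
  }
  manifest <- NULL
  if (!is.null(config$out_dir))
    manifest <- write_pipeline_outputs(config, tables, fits, metas)
  structure(list(fits = fits, metas = metas, tables = tables,
                 summaries = summaries, manifest = manifest,
                 seed = config$seed),
            class = "pipeline_result")
}

fit_as_list <- function(f) {
  list(coefficients = as.list(f$coefficients), se = as.list(f$se),
       statistic = as.list(f$statistic), p_value = as.list(f$p_value),
       sigma2_u = f$sigma2_u, sigma2_e = f$sigma2_e,
       singular = f$singular, converged = f$converged,
       n_dyads = f$n_dyads, n_subjects = f$n_subjects,
       n_dropped = f$n_dropped)
}

write_pipeline_outputs <- function(config, tables, fits, metas) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta_info <- list(seed = config$seed,
                    version = as.character(utils::packageVersion("dyadconn")))
  paths <- character(0)
  for (key in names(tables)) {
    p <- file.path(config$out_dir, paste0("dyads_", gsub("/", "_", key), ".csv"))
    df <- tables[[key]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  res <- list(metadata = meta_info,
              fits = lapply(fits, fit_as_list),
              meta_analyses = lapply(metas, function(m)
                list(estimate = m$estimate, se = m$se, ci = c(m$ci_lower, m$ci_upper),
                     tau2 = m$tau2, pval = m$pval, k = m$k, weights = m$weights)))
  p <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  forest <- do.call(rbind, lapply(names(metas), function(key) {
    parts <- strsplit(key, "/")[[1]]
    coefname <- if (parts[1] == "distance") "distance" else "same_community"
    scope_fits <- fits[grep(paste0("/", key, "$"), names(fits))]
    names(scope_fits) <- sub("/.*", "", names(scope_fits))
    ft <- forest_table(scope_fits, metas[[key]], coefname, scope = parts[2])
    ft$predictor <- parts[1]
    ft
  }))
  if (!is.null(forest)) {
    p <- file.path(config$out_dir, "forest.csv")
    utils::write.csv(forest, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(metadata = meta_info, artifacts = manifest),
                       mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$fits), "LME fits,",
      length(x$metas), "meta-analyses,", length(x$tables), "dyad tables\n")
  invisible(x)
}
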