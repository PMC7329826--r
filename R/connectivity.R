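#' Subject-level functional connectivity matrix
#'
#' Pearson correlation between every pair of parcel time series, the
#' standard weighted undirected functional connectome.
#'
#' @param series T x P numeric matrix (rows = time points, columns =
#'   labelled parcels), T >= 3, no missing values, no constant column.
#' @return P x P correlation matrix of class `connectivity_matrix`
#'   (symmetric, unit diagonal).
#' @export
correlation_matrix <- function(series) {
  m <- as.matrix(series)
  if (nrow(m) < 3) stop("need at least 3 time points, got ", nrow(m))
  if (anyNA(m)) stop("time series contain missing values")
  if (is.null(colnames(m))) colnames(m) <- parcel_labels(ncol(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time series for parcel ", colnames(m)[which(sds == 0)[1]])
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  class(r) <- c("connectivity_matrix", "matrix", "array")
  r
}

#' Fisher z transform of a connectivity matrix
#'
#' `z = atanh(r)` variance-stabilises the correlations before inter-subject
#' comparison. Correlations are clipped to +/-(1 - 1e-7) so duplicated or
#' degenerate series never produce infinities, and the self-self diagonal is
#' masked (set to `NA`).
#'
#' @param matrix a [correlation_matrix()] result (or any correlation matrix).
#' @return P x P matrix of class `fisher_z` with `NA` diagonal.
#' @export
fisher_z <- function(matrix) {
  r <- as.matrix(matrix)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- NA
  class(z) <- c("fisher_z", "matrix", "array")
  z
}

#' Subset a Fisher-z matrix to one resting-state network
#'
#' The mask assigns parcel labels to named resting-state networks (DMN,
#' salience, lFPN, rFPN); parcels may be unassigned. Selection is keyed by
#' label, not position, and preserves the matrix's own label order. The
#' sentinel name `"whole-brain"` returns the input unchanged.
#'
#' @param z a [fisher_z()] matrix with parcel labels as dimnames.
#' @param mask data.frame with columns `parcel` and `network`.
#' @param name network name present in the mask, or `"whole-brain"`.
#' @return The submatrix over that network's parcels, still of class
#'   `fisher_z`.
#' @export
subset_network <- function(z, mask, name) {
  if (identical(name, "whole-brain")) return(z)
  stopifnot(is.data.frame(mask), all(c("parcel", "network") %in% names(mask)))
  if (!name %in% mask$network)
    stop("unknown network '", name, "'; mask defines: ",
         paste(unique(mask$network), collapse = ", "))
  wanted <- mask$parcel[mask$network == name]
  keep <- colnames(z)[colnames(z) %in% wanted]
  if (length(keep) < 2)
    stop("network '", name, "' selects fewer than 2 parcels from this matrix")
  out <- unclass(z)[keep, keep]
  class(out) <- class(z)
  out
}

# upper-triangle vector in fixed row-major (p < q) order
utri_vector <- function(m) {
  m <- unclass(m)
  t(m)[lower.tri(m)]
}

#' Inter-subject connectome similarity
#'
#' Vectorises each subject's Fisher-z matrix over the upper triangle
#' (diagonal excluded, fixed row-major order) and returns the Pearson
#' correlation of the two vectors: one number summarising how similar the
#' two connectomes are.
#'
#' @param z_i,z_j [fisher_z()] matrices over the identical parcel set.
#' @return Scalar correlation `r_ij`.
#' @export
intersubject_similarity <- function(z_i, z_j) {
  if (!identical(colnames(z_i), colnames(z_j)))
    stop("parcel labels differ between subjects")
  if (ncol(z_i) < 3)
    stop("need at least 3 parcels (2 distinct parcel pairs) to correlate")
  stats::cor(utri_vector(z_i), utri_vector(z_j))
}

#' All-pairs inter-subject similarity matrix
#'
#' @param z_list named list of [fisher_z()] matrices, one per subject.
#' @return Symmetric matrix of pairwise similarities with unit diagonal.
#' @export
similarity_matrix <- function(z_list) {
  if (ncol(z_list[[1]]) < 3)
    stop("need at least 3 parcels (2 distinct parcel pairs) to correlate")
  v <- vapply(z_list, utri_vector, numeric(length(utri_vector(z_list[[1]]))))
  s <- stats::cor(v)
  dimnames(s) <- list(names(z_list), names(z_list))
  s
}

#' Assemble the dyad table for one cohort and scope
#'
#' One row per unordered pair of scanned subjects, holding the standardized
#' similarity outcome, the pair's social distance and community match, and
#' optional dyad covariates. Standardisation (mean 0, SD 1) is applied
#' within the cohort, separately for every network scope.
#'
#' @param similarities square similarity matrix over scanned subject IDs
#'   (from [similarity_matrix()]).
#' @param distances [social_distance()] matrix over the full cohort
#'   (must contain all scanned subjects).
#' @param partition [detect_communities()] result for the full cohort.
#' @param covariates optional data.frame with columns `id`, `ethnicity`,
#'   `boarding`, `motion_abs`, `motion_rel`.
#' @param cohort cohort label.
#' @param scope network scope label recorded in the table.
#' @return data.frame of class `dyad_table` with `n (n - 1) / 2` rows:
#'   columns cohort, scope, i, j, similarity (standardized),
#'   similarity_raw, distance, same_community and, when covariates are
#'   given, ethnicity_match, boarding_match, motion_abs_mean,
#'   motion_abs_diff, motion_rel_mean, motion_rel_diff.
#' @export
build_dyad_table <- function(similarities, distances, partition,
                             covariates = NULL, cohort = "cohort",
                             scope = "whole-brain") {
  ids <- rownames(similarities)
  if (is.null(ids)) stop("similarity matrix must carry subject IDs")
  missing_ids <- setdiff(ids, rownames(distances))
  if (length(missing_ids))
    stop("subjects missing from distance matrix: ",
         paste(missing_ids, collapse = ", "))
  stopifnot(inherits(partition, "community_partition"))
  n <- length(ids)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # row-major (i < j) ordering for stable output files
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  i <- ids[pr[, 1]]; j <- ids[pr[, 2]]
  raw <- similarities[cbind(i, j)]
  sd_raw <- stats::sd(raw)
  if (!is.finite(sd_raw) || sd_raw == 0)
    stop("similarity outcome has zero variance in cohort '", cohort,
         "'; cannot standardize")
  memb <- partition$membership
  out <- data.frame(
    cohort = cohort, scope = scope, i = i, j = j,
    similarity = (raw - mean(raw)) / sd_raw,
    similarity_raw = raw,
    distance = distances[cbind(i, j)],
    same_community = as.integer(memb[i] == memb[j]),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$id), ]
    ci <- match(i, cv$id); cj <- match(j, cv$id)
    out$ethnicity_match <- as.integer(cv$ethnicity[ci] == cv$ethnicity[cj])
    out$boarding_match <- as.integer(cv$boarding[ci] == cv$boarding[cj])
    out$motion_abs_mean <- (cv$motion_abs[ci] + cv$motion_abs[cj]) / 2
    out$motion_abs_diff <- abs(cv$motion_abs[ci] - cv$motion_abs[cj])
    out$motion_rel_mean <- (cv$motion_rel[ci] + cv$motion_rel[cj]) / 2
    out$motion_rel_diff <- abs(cv$motion_rel[ci] - cv$motion_rel[cj])
  }
  class(out) <- c("dyad_table", "data.frame")
  out
}
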