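#' Planted group assignment for a synthetic cohort
#'
#' Students are assigned to `n_groups` friendship groups as evenly as
#' possible, in a seeded random order.
#'
#' @param config a [sim_config()].
#' @return Integer vector of group labels, named by student ID.
#' @export
simulate_groups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- student_ids(config$n_students)
  base <- rep_len(seq_len(config$n_groups), config$n_students)
  g <- with_seed(child_seed(config$seed, "groups"), sample(base))
  names(g) <- ids
  g
}

student_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate a roster-and-rating survey with planted groups
#'
#' Each directed rating is drawn independently (reciprocity is emergent, not
#' imposed): a within-group rating is "high" with probability `p_in` and a
#' between-group rating with probability `p_out`. High ratings are 5
#' ("Most"), low ratings 1 ("None"); with probability `likert_noise` a
#' rating is then jittered by one Likert step (clamped to 1..5), which
#' spreads mass onto the intermediate anchors.
#'
#' @param config a [sim_config()].
#' @param groups optional planted group labels; defaults to
#'   [simulate_groups()] under the config's seed.
#' @return A [roster_rating()] with the planted groups attached as attribute
#'   `groups`.
#' @export
simulate_social_roster <- function(config, groups = simulate_groups(config)) {
  stopifnot(inherits(config, "sim_config"), length(groups) == config$n_students)
  n <- config$n_students
  same <- outer(groups, groups, "==")
  with_seed(child_seed(config$seed, "roster"), {
    p_high <- ifelse(same, config$p_in, config$p_out)
    high <- matrix(stats::runif(n * n) < p_high, n, n)
    r <- ifelse(high, 5L, 1L)
    jitter <- matrix(stats::runif(n * n) < config$likert_noise, n, n)
    step <- matrix(sample(c(-1L, 1L), n * n, replace = TRUE), n, n)
    r <- pmin(pmax(r + ifelse(jitter, step, 0L), 1L), 5L)
  })
  diag(r) <- NA
  out <- roster_rating(r, ids = names(groups), cohort = "synthetic")
  attr(out, "groups") <- groups
  out
}

#' Simulate per-subject demographic and motion covariates
#'
#' Ethnicity is categorical with majority-class proportions typical of the
#' study population, boarding status Bernoulli, and mean absolute/relative
#' head motion log-normal (mm scale).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns id, ethnicity, boarding, motion_abs,
#'   motion_rel.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_students
  with_seed(child_seed(config$seed, "covariates"), {
    data.frame(
      id = student_ids(n),
      ethnicity = sample(c("White", "Asian", "Black", "Mixed"), n,
                         replace = TRUE, prob = c(0.8, 0.08, 0.07, 0.05)),
      boarding = stats::rbinom(n, 1, 0.3),
      motion_abs = exp(stats::rnorm(n, log(0.3), 0.4)),
      motion_rel = exp(stats::rnorm(n, log(0.1), 0.4)),
      stringsAsFactors = FALSE
    )
  })
}
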