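#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: a cohort of students split into
#' planted friendship groups, a Likert roster whose within-group ratings are
#' high, and per-subject functional connectomes built as a convex mixture of
#' a global template (weight `eta`), a group template (weight `theta`, the
#' planted homophily effect) and subject-unique noise (weight
#' `1 - theta - eta`).
#'
#' @param n_students number of students in the cohort (>= 2).
#' @param n_parcels number of brain parcels P (>= 2). The study parcellation
#'   has 272 parcels; simulation studies in this package use a reduced
#'   parcellation by passing a smaller value (tests use 40).
#' @param n_timepoints BOLD samples T per subject. Default 250, roughly a
#'   10-minute resting scan; only large-sample correlation stability matters
#'   downstream.
#' @param p_in probability that a within-group directed rating is drawn high.
#' @param p_out probability that a between-group directed rating is drawn high.
#' @param n_groups number of planted friendship groups.
#' @param theta homophily effect size in `[0, 1]`: weight of the shared-group
#'   connectome template. `theta = 0` is the null.
#' @param eta weight of the global connectome template in `[0, 1]`;
#'   `theta + eta <= 1`.
#' @param likert_noise probability that a rating is jittered by one Likert step.
#' @param seed integer root seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_students = 24, n_parcels = 272, n_timepoints = 250,
                       p_in = 0.85, p_out = 0.25, n_groups = 4,
                       theta = 0, eta = 0.3, likert_noise = 0.1, seed = 1) {
  cfg <- list(n_students = as.integer(n_students), n_parcels = as.integer(n_parcels),
              n_timepoints = as.integer(n_timepoints), p_in = p_in, p_out = p_out,
              n_groups = as.integer(n_groups), theta = theta, eta = eta,
              likert_noise = likert_noise, seed = as.integer(seed))
  for (nm in c("p_in", "p_out", "theta", "eta", "likert_noise")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability/weight in [0, 1], got ", v)
  }
  if (cfg$theta + cfg$eta > 1 + 1e-12)
    stop("theta + eta must not exceed 1 (got ", cfg$theta + cfg$eta, ")")
  for (nm in c("n_students", "n_parcels", "n_groups"))
    if (cfg[[nm]] < 2L) stop(nm, " must be at least 2, got ", cfg[[nm]])
  if (cfg$n_timepoints < 3L) stop("n_timepoints must be at least 3")
  if (cfg$n_groups > cfg$n_students) stop("n_groups cannot exceed n_students")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort config: n =", x$n_students, "students,",
      x$n_groups, "groups, P =", x$n_parcels, ", T =", x$n_timepoints, "\n")
  cat("  ties: p_in =", x$p_in, ", p_out =", x$p_out,
      "; connectome weights: theta =", x$theta, ", eta =", x$eta, "\n")
  cat("  likert_noise =", x$likert_noise, ", seed =", x$seed, "\n")
  invisible(x)
}
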