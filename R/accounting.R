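#' Survey inclusion rate
#'
#' Percentage of the year-group pool that enrolled in the social-network
#' survey, rounded to whole percent as conventionally reported.
#'
#' @param pool year-group pool size(s).
#' @param enrolled number(s) enrolled.
#' @return Rounded percentage(s).
#' @examples
#' inclusion_rate(c(62, 53, 75), c(59, 51, 65))  # 95 96 87
#' @export
inclusion_rate <- function(pool, enrolled) {
  stopifnot(length(pool) == length(enrolled), all(enrolled <= pool), all(pool > 0))
  round(100 * enrolled / pool)
}

#' Usable scanned-cohort sizes after exclusions
#'
#' @param recruited number recruited into the imaging arm per cohort.
#' @param excluded number excluded (e.g. artefacts) per cohort.
#' @return Integer vector of usable cohort sizes.
#' @examples
#' usable_fmri_n(c(28, 17, 34), c(5, 0, 6))  # 23 17 28, sum 68
#' @export
usable_fmri_n <- function(recruited, excluded) {
  stopifnot(length(recruited) == length(excluded), all(excluded >= 0),
            all(excluded <= recruited))
  as.integer(recruited - excluded)
}
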