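#' Roster-and-rating sociometric matrix
#'
#' A roster-and-rating instrument asks every student to rate every peer in
#' their year group on a five-point Likert scale ("None", "A rare amount",
#' "Some", "More than some", "Most", coded 1..5) in answer to "How much time
#' do you spend interacting with this student?". The result is a square,
#' generally asymmetric integer matrix with a missing diagonal.
#'
#' @param ratings square integer matrix; entry `(i, j)` is student i's rating
#'   of student j in `1:5`, or `NA`. The diagonal must be `NA`.
#' @param ids character vector of student identifiers (defaults to the
#'   dimnames of `ratings`).
#' @param cohort single character cohort label.
#' @return An object of class `roster_rating`: the validated rating matrix
#'   with `ids` as dimnames and a `cohort` attribute.
#' @seealso [load_roster()], [build_social_graph()]
#' @export
roster_rating <- function(ratings, ids = rownames(ratings), cohort = "cohort") {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != ncol(ratings))
    stop("roster must be square, got ", nrow(ratings), "x", ncol(ratings))
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(ratings)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate student IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(ratings) <- list(ids, ids)
  diag_vals <- diag(ratings)
  if (any(!is.na(diag_vals)))
    stop("diagonal (self-ratings) must be missing; found value at ",
         ids[which(!is.na(diag_vals))[1]])
  off <- ratings[row(ratings) != col(ratings)]
  bad <- which(!is.na(off) & (off < 1 | off > 5 | off != round(off)))
  if (length(bad)) {
    idx <- which(row(ratings) != col(ratings))[bad[1]]
    stop("rating out of 1..5 at cell (", ids[row(ratings)[idx]], ", ",
         ids[col(ratings)[idx]], "): ", ratings[idx])
  }
  storage.mode(ratings) <- "integer"
  structure(ratings, cohort = cohort, class = c("roster_rating", "matrix", "array"))
}

#' Read a roster-and-rating CSV
#'
#' The CSV has a header row and a first column of student IDs; cells hold
#' integer ratings 1..5 and the diagonal is empty. Students who did not take
#' part in the survey (an entirely missing row or column) are dropped, so
#' that outgoing or incoming ties with non-participants never enter the
#' social graph.
#'
#' @param path path to the CSV file.
#' @param cohort cohort label attached to the result.
#' @return A [roster_rating()] object. The number of dropped non-participants
#'   is attached as attribute `n_dropped`.
#' @export
load_roster <- function(path, cohort = basename(path)) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("roster CSV is not square: ", nrow(m), " rows vs ", ncol(m), " columns")
  if (!setequal(rownames(m), colnames(m)))
    stop("row and column ID sets differ in ", path)
  m <- m[, rownames(m), drop = FALSE]
  # non-participants: rated nobody (empty row) or were rated by nobody (empty column)
  n <- nrow(m)
  offdiag_row <- rowSums(!is.na(m))  # diagonal is NA already in valid files
  offdiag_col <- colSums(!is.na(m))
  keep <- offdiag_row > 0L | n == 1L
  keep <- keep & (offdiag_col > 0L)
  dropped <- sum(!keep)
  m <- m[keep, keep, drop = FALSE]
  diag(m) <- NA
  out <- roster_rating(m, cohort = cohort)
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a roster to CSV
#'
#' Inverse of [load_roster()]: header row/column of student IDs, integer
#' cells, empty diagonal.
#'
#' @param roster a [roster_rating()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  df <- as.data.frame(unclass(roster))
  utils::write.csv(df, path, na = "")
  invisible(path)
}

#' @export
print.roster_rating <- function(x, ...) {
  cat("Roster-and-rating matrix: ", nrow(x), " students, cohort '",
      attr(x, "cohort"), "'\n", sep = "")
  cat("  ", sum(!is.na(x)), " ratings, ", count_dyads(nrow(x)),
      " unordered dyads\n", sep = "")
  invisible(x)
}
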