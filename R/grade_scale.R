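#' Modified MRC grade scale
#'
#' The modified Medical Research Council (MRC) scale grades muscle strength on
#' integers 1..9 (9 = normal power). Cohorts of acute stroke patients seen in
#' a drift test typically occupy only a subset of grades; the default observed
#' subset is \{5, 7, 8, 9\}. A `grade_scale` fixes the bijection between the
#' observed grades and consecutive class indices 1..M used by the ordinal cost
#' matrices and the classifier. Index 1 is the lowest (most severe) grade.
#'
#' @param grades integer vector of admissible grades, strictly increasing
#'   after sorting, all in 1..9.
#' @return An object of class `grade_scale`: a list with `grades` (sorted
#'   ascending) and `M`, the number of classes.
#' @examples
#' sc <- grade_scale()
#' grade_to_index(sc, c(9, 5))   # c(4, 1)
#' index_to_grade(sc, 1:4)       # c(5, 7, 8, 9)
#' @export
grade_scale <- function(grades = c(5L, 7L, 8L, 9L)) {
  grades <- as.integer(grades)
  if (length(grades) < 1 || anyNA(grades)) {
    stop("'grades' must be a non-empty integer vector")
  }
  if (any(grades < 1L | grades > 9L)) {
    stop("all grades must lie in 1..9")
  }
  grades <- sort(unique(grades))
  structure(list(grades = grades, M = length(grades)), class = "grade_scale")
}

#' @describeIn grade_scale Map grades to class indices 1..M (1 = most severe).
#' @param scale a `grade_scale`.
#' @param x grades (for `grade_to_index`) or class indices (for
#'   `index_to_grade`).
#' @export
grade_to_index <- function(scale, x) {
  stopifnot(inherits(scale, "grade_scale"))
  idx <- match(as.integer(x), scale$grades)
  if (anyNA(idx)) {
    stop("grade(s) ", paste(unique(x[is.na(idx)]), collapse = ", "),
         " not in scale {", paste(scale$grades, collapse = ", "), "}")
  }
  idx
}

#' @describeIn grade_scale Inverse map, class index to grade.
#' @export
index_to_grade <- function(scale, x) {
  stopifnot(inherits(scale, "grade_scale"))
  x <- as.integer(x)
  if (any(x < 1L | x > scale$M)) stop("class index out of range 1..M")
  scale$grades[x]
}

#' @export
print.grade_scale <- function(x, ...) {
  cat("<grade_scale> M =", x$M, "classes; grades:",
      paste(x$grades, collapse = " < "), "\n")
  invisible(x)
}
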