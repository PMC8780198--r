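#' Ordinal misclassification cost matrices
#'
#' `linear_cost_matrix()` builds the linear-weight cost matrix over class
#' indices 1..M: the penalty for predicting class i when the truth is class j
#' is the ordinal distance, `c_ij = |j - i|` (zero diagonal, symmetric).
#'
#' `imbalance_cost_matrix()` additionally scales every row by a per-class
#' imbalance factor computed from the balanced-training-set class counts:
#' `c_ij = (sum_{k != i} n(SBT_k) / n(SBT_i)) * |j - i|`, i.e. predictions
#' into rare classes are policed more heavily. With equal counts the factor
#' is the constant `M - 1`-to-1 ratio, so the matrix is a positive scalar
#' multiple of the linear one and minimum-expected-cost decisions coincide.
#'
#' By default distances are on consecutive class indices (grades 5 and 7 of
#' the observed scale are adjacent classes); pass `grade_values` to use raw
#' grade distances instead.
#'
#' @param M number of classes (>= 2).
#' @param grade_values optional numeric vector of length M: compute
#'   `|grade_j - grade_i|` instead of index distance.
#' @return An M x M `cost_matrix` (numeric matrix with attribute
#'   `"grade_values"` when supplied).
#' @examples
#' linear_cost_matrix(3)
#' imbalance_cost_matrix(c(300, 100, 100, 100))
#' @export
linear_cost_matrix <- function(M, grade_values = NULL) {
  if (M < 2) stop("a cost matrix needs M >= 2 classes")
  v <- if (is.null(grade_values)) seq_len(M) else {
    if (length(grade_values) != M) stop("grade_values must have length M")
    as.numeric(grade_values)
  }
  C <- abs(outer(v, v, "-"))
  dimnames(C) <- list(predicted = seq_len(M), true = seq_len(M))
  attr(C, "grade_values") <- grade_values
  class(C) <- c("cost_matrix", class(C))
  C
}

#' @rdname linear_cost_matrix
#' @param sbt_counts per-class instance counts of the balanced training set,
#'   ordered by class index; all must be >= 1.
#' @export
imbalance_cost_matrix <- function(sbt_counts, M = length(sbt_counts),
                                  grade_values = NULL) {
  sbt_counts <- as.numeric(sbt_counts)
  if (length(sbt_counts) != M) stop("length(sbt_counts) must equal M")
  if (any(sbt_counts < 1)) stop("every class count must be >= 1")
  base <- linear_cost_matrix(M, grade_values)
  factor_i <- vapply(seq_len(M),
                     function(i) sum(sbt_counts[-i]) / sbt_counts[i],
                     numeric(1))
  C <- unclass(base) * factor_i      # row i scaled by its imbalance factor
  dimnames(C) <- dimnames(base)
  attr(C, "grade_values") <- grade_values
  attr(C, "imbalance_factors") <- factor_i
  class(C) <- c("cost_matrix", "matrix", "array")
  C
}

#' Zero-one cost matrix (plain accuracy)
#'
#' `c_ij = 1(i != j)`; minimum expected cost reduces to argmax posterior.
#'
#' @inheritParams linear_cost_matrix
#' @export
zero_one_cost_matrix <- function(M) {
  if (M < 2) stop("a cost matrix needs M >= 2 classes")
  C <- 1 - diag(M)
  dimnames(C) <- list(predicted = seq_len(M), true = seq_len(M))
  class(C) <- c("cost_matrix", class(C))
  C
}

#' Serialise a cost matrix to / from JSON
#'
#' The JSON object stores the penalty matrix row by row together with the
#' class order (and grade values when attached), so a matrix round-trips
#' exactly.
#'
#' @param cost a `cost_matrix`.
#' @param path file path; when `NULL`, `cost_to_json()` returns the JSON
#'   string.
#' @export
cost_to_json <- function(cost, path = NULL) {
  obj <- list(classes = seq_len(nrow(cost)),
              grade_values = attr(cost, "grade_values"),
              matrix = unname(apply(unclass(cost), 1, as.numeric,
                                    simplify = FALSE)))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}

#' @rdname cost_to_json
#' @param json JSON string or file path.
#' @export
cost_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  C <- obj$matrix                    # numeric matrix for equal-length rows
  if (is.list(C)) C <- do.call(rbind, C)
  C <- unname(as.matrix(C))
  dimnames(C) <- list(predicted = seq_len(nrow(C)), true = seq_len(ncol(C)))
  gv <- obj$grade_values
  attr(C, "grade_values") <- if (is.null(gv) || all(is.na(gv))) NULL else gv
  class(C) <- c("cost_matrix", class(C))
  C
}
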