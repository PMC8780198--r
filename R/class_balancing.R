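#' Boosting factors for class balancing
#'
#' For original per-class counts `n(T_i)` and a balanced target of `N`
#' instances over `M` classes, the boosting factor of class i is
#' \deqn{SBF_i = (N/M - n(T_i)) / n(T_i),}
#' and the number of synthetic instances to generate is
#' `n(SB_i) = n(T_i) * SBF_i = N/M - n(T_i)` (exact because `N` must be
#' divisible by `M`). A class already above `N/M` gets a negative factor,
#' which is clamped to 0 with a warning: the scheme over-samples minorities
#' and never under-samples.
#'
#' @param counts integer vector of original per-class counts, ordered by
#'   class index; every count must be >= 1.
#' @param N balanced training-set target size; must be divisible by `M`.
#' @param M number of classes (default `length(counts)`).
#' @return list with `sbf` (per-class factors, clamped), `n_synthetic`
#'   (per-class synthetic counts), `target_per_class` (= N/M).
#' @examples
#' boosting_factors(c(5, 22, 39, 78), N = 600)  # 145,128,111,72 synthetics
#' @export
boosting_factors <- function(counts, N, M = length(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) != M) stop("length(counts) must equal M")
  if (any(counts < 1)) {
    stop("every class needs at least one original instance (boosting factor ",
         "undefined for empty classes)")
  }
  if (N %% M != 0) {
    stop("N = ", N, " is not divisible by M = ", M,
         ": per-class target N/M would not be integral")
  }
  target <- N / M
  sbf <- (target - counts) / counts
  if (any(sbf < 0)) {
    warning("class(es) ", paste(which(sbf < 0), collapse = ", "),
            " exceed N/M = ", target,
            "; boosting factor clamped to 0 (no undersampling)")
    sbf <- pmax(sbf, 0)
  }
  list(sbf = sbf, n_synthetic = as.integer(round(counts * sbf)),
       target_per_class = target)
}

#' SMOTE-style synthetic over-sampling
#'
#' Creates synthetic minority instances by convex interpolation between an
#' original instance and one of its k nearest same-class neighbours
#' (Euclidean distance on z-scored features):
#' `x_new = x + u (x_nn - x)`, `u ~ Uniform(0, 1)`.
#'
#' `k` is silently reduced to `n_class - 1` when a class has fewer than
#' `k + 1` members. A singleton class cannot be interpolated; it falls back
#' to jitter duplication (Gaussian noise, SD = 1% of each feature's scale)
#' with a warning.
#'
#' @param x numeric matrix or data.frame of original feature vectors.
#' @param class_idx integer class index per row of `x`.
#' @param n_synthetic integer vector: synthetics to generate per class index
#'   (position i = class i).
#' @param k neighbour count (default 5).
#' @param seed integer seed.
#' @return data.frame of synthetic instances with columns of `x` plus
#'   `class_idx` and `origin = "synthetic"`; zero rows when no synthetics are
#'   requested.
#' @export
smote_augment <- function(x, class_idx, n_synthetic, k = 5, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  x <- as.data.frame(x)
  feat_names <- colnames(x)
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("features must be numeric")
  class_idx <- as.integer(class_idx)
  if (length(class_idx) != nrow(xm)) stop("class_idx length mismatch")

  # z-score on the originals for the neighbour metric only; interpolation is
  # in the raw feature space (affine-equivalent).
  mu <- colMeans(xm)
  sdv <- apply(xm, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  xs <- sweep(sweep(xm, 2, mu), 2, sdv, "/")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  out <- list()
  for (ci in seq_along(n_synthetic)) {
    n_syn <- n_synthetic[ci]
    if (n_syn <= 0) next
    members <- which(class_idx == ci)
    nm <- length(members)
    if (nm == 0) stop("class ", ci, " has no original instances")
    if (nm == 1) {
      warning("class ", ci, " is a singleton; falling back to jitter ",
              "duplication instead of SMOTE interpolation")
      base <- xm[rep(members, n_syn), , drop = FALSE]
      jit <- matrix(stats::rnorm(n_syn * ncol(xm), 0, 1), n_syn) *
        rep(0.01 * sdv, each = n_syn)
      syn <- base + jit
    } else {
      k_eff <- min(k, nm - 1)
      d <- as.matrix(stats::dist(xs[members, , drop = FALSE]))
      diag(d) <- Inf
      nn_idx <- apply(d, 1, function(row) order(row)[seq_len(k_eff)])
      nn <- if (k_eff == 1) matrix(nn_idx, ncol = 1) else t(nn_idx)
      base_pick <- sample.int(nm, n_syn, replace = TRUE)
      nb_pick <- if (k_eff == 1) rep(1L, n_syn) else
        sample.int(k_eff, n_syn, replace = TRUE)
      u <- stats::runif(n_syn)
      xb <- xm[members[base_pick], , drop = FALSE]
      xn <- xm[members[nn[cbind(base_pick, nb_pick)]], , drop = FALSE]
      syn <- xb + u * (xn - xb)
    }
    syn <- as.data.frame(syn)
    colnames(syn) <- feat_names
    syn$class_idx <- ci
    out[[length(out) + 1]] <- syn
  }
  if (length(out) == 0) {
    empty <- as.data.frame(xm[0, , drop = FALSE])
    empty$class_idx <- integer(0)
    empty$origin <- character(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  res$origin <- "synthetic"
  rownames(res) <- NULL
  res
}

#' Assemble the balanced training set
#'
#' Unions the original instances `T` with the synthetic instances `SB` and
#' shuffles the rows deterministically: the result is the balanced training
#' set `SBT` with `n(SBT_i) = n(T_i) + n(SB_i)` per class. Origin flags
#' ("original"/"synthetic") are preserved so that downstream cross-validation
#' can hold out originals only.
#'
#' @param originals data.frame of original instances with a `class_idx`
#'   column (an `origin` column is added/overwritten with "original").
#' @param synthetics data.frame from [smote_augment()] (may have zero rows).
#' @param seed shuffle seed.
#' @return data.frame of class `balanced_training_set`.
#' @export
build_balanced_set <- function(originals, synthetics, seed = 1L) {
  originals <- as.data.frame(originals)
  if (!"class_idx" %in% names(originals)) stop("originals need 'class_idx'")
  originals$origin <- "original"
  if (!is.null(synthetics) && nrow(synthetics) > 0) {
    keep <- intersect(names(originals), names(synthetics))
    if (!setequal(setdiff(names(originals), keep), character(0))) {
      originals <- originals[, keep, drop = FALSE]
    }
    sbt <- rbind(originals[, keep, drop = FALSE],
                 synthetics[, keep, drop = FALSE])
  } else {
    sbt <- originals
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sbt <- sbt[sample.int(nrow(sbt)), , drop = FALSE]
  rownames(sbt) <- NULL
  class(sbt) <- c("balanced_training_set", "data.frame")
  sbt
}

#' One-call balancing of a feature table
#'
#' Convenience wrapper: counts classes, computes [boosting_factors()], runs
#' [smote_augment()] on the numeric feature columns and returns the shuffled
#' union via [build_balanced_set()].
#'
#' @param features data.frame with a `class_idx` column; all other numeric
#'   columns are treated as features.
#' @param N balanced target size.
#' @param k SMOTE neighbour count.
#' @param seed integer seed.
#' @param feature_cols optional character vector naming the feature columns.
#' @return `balanced_training_set` with the feature columns, `class_idx` and
#'   `origin`.
#' @export
balance_training_set <- function(features, N, k = 5, seed = 1L,
                                 feature_cols = NULL) {
  stopifnot("class_idx" %in% names(features))
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, logical(1))
    feature_cols <- setdiff(names(features)[num], "class_idx")
  }
  M <- max(features$class_idx)
  counts <- tabulate(features$class_idx, nbins = M)
  bf <- boosting_factors(counts, N, M)
  syn <- smote_augment(features[, feature_cols, drop = FALSE],
                       features$class_idx, bf$n_synthetic, k = k, seed = seed)
  orig <- features[, c(feature_cols, "class_idx"), drop = FALSE]
  build_balanced_set(orig, syn, seed = seed + 1L)
}
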