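#' Percent agreement between two raters
#'
#' Fraction of subjects on which two raters give identical ratings, over
#' pairwise-complete cases. Not chance-corrected.
#'
#' @param a,b rating vectors of equal length (NA allowed; pairs with any NA
#'   are dropped).
#' @return fraction in \[0, 1\].
#' @export
percent_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("rating vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable (pairwise-complete) rating pairs")
  mean(a[ok] == b[ok])
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements `x` and `y` of the same quantity, computes the
#' differences `d = x - y`, their mean and sample SD (n - 1 denominator) and
#' the 95% limits of agreement `mean(d) +/- 1.96 sd(d)` (multiplier
#' configurable). The per-pair means and differences are returned as the
#' plotting payload.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param loa_multiplier LoA multiplier (default 1.96, the 95% normal
#'   quantile).
#' @return A `bland_altman` list: mean_diff, sd_diff, loa_low, loa_high, n,
#'   and data.frame `payload` (mean, diff).
#' @examples
#' bland_altman(c(1, 2, 3), c(1, 2, 3))   # all zero
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("Bland-Altman needs at least 2 complete pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - loa_multiplier * s,
                 loa_high = m + loa_multiplier * s,
                 n = length(d),
                 payload = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.4g, SD %.4g, LoA (%.4g, %.4g)\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random-effects, absolute-agreement, average-measures intraclass
#' correlation: every subject is measured by the same k raters, raters are a
#' random sample, and the reported reliability is that of the k-rater mean.
#' From the two-way ANOVA mean squares (rows = subjects, columns = raters),
#' \deqn{ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n).}
#' The 95% CI uses the McGraw-Wong F-based interval for the single-measure
#' coefficient stepped up by Spearman-Brown, and the p-value tests ICC = 0
#' via `F = MS_R / MS_E` on (n - 1, (n - 1)(k - 1)) df.
#'
#' @param table numeric matrix, subjects x raters, complete (no NA; perform
#'   listwise deletion upstream), >= 2 subjects and >= 2 raters.
#' @param conf_level confidence level (default 0.95). The F-based interval
#'   is defined for the positive-reliability regime; a negative point
#'   estimate gets NA bounds.
#' @return An `icc_result` list: icc, ci_low, ci_high, p_value, and the mean
#'   squares (ms_rows, ms_cols, ms_error), n, k.
#' @export
icc_2k <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (anyNA(x)) stop("icc_2k requires a complete matrix (listwise-delete upstream)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  SSR <- k * sum((rm_ - grand)^2)
  SSC <- n * sum((cm_ - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  if (SSR <= .Machine$double.eps * SST) {
    warning("zero between-subject variance; ICC reported as 0")
    return(structure(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, ms_rows = MSR, ms_cols = MSC,
                          ms_error = MSE, n = n, k = k),
                     class = "icc_result"))
  }

  denom_k <- MSR + (MSC - MSE) / n
  icc_ak <- (MSR - MSE) / denom_k
  icc_a1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha <- 1 - conf_level
  if (MSE <= 0 || 1 - icc_a1 < 1e-12) {
    ci <- c(icc_ak, icc_ak)   # degenerate noise-free table
    p <- 0
  } else if (icc_ak < 0) {
    # the F-based interval is derived for the positive-reliability regime;
    # for a negative point estimate it is not meaningful
    ci <- c(NA_real_, NA_real_)
    p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    a <- k * icc_a1 / (n * (1 - icc_a1))
    b <- 1 + k * icc_a1 * (n - 1) / (n * (1 - icc_a1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    L1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    U1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    sb <- function(r1) {
      # Spearman-Brown step-up; singular at r1 = -1/(k-1)
      if (r1 <= -1 / (k - 1)) return(-Inf)
      r1 * k / (1 + (k - 1) * r1)
    }
    ci <- c(sb(L1), sb(U1))
    p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc_ak, ci_low = min(ci), ci_high = max(ci),
                 p_value = p, ms_rows = MSR, ms_cols = MSC, ms_error = MSE,
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k) = %.3f, 95%% CI (%.3f, %.3f), p = %.3g  [n = %d, k = %d]\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$n, x$k))
  invisible(x)
}

#' Krippendorff's alpha
#'
#' Chance-adjusted inter-rater reliability from the coincidence matrix:
#' `alpha = 1 - D_o / D_e`, where the observed disagreement `D_o` sums the
#' squared metric differences over all ordered rating pairs within subjects
#' (each subject's pairs weighted by `1/(m_u - 1)` for `m_u` ratings) and
#' `D_e` is its expectation under random pairing of all pairable values.
#' Missing ratings are handled natively; subjects with fewer than 2 ratings
#' are dropped.
#'
#' Distance metrics: `"nominal"` (0/1), `"ordinal"` (squared rank-mass
#' distance on the coincidence marginals) and `"interval"` (squared value
#' difference).
#'
#' @param table subjects x raters matrix of ratings (numeric; NA = missing).
#' @param metric one of "nominal", "ordinal", "interval". The default
#'   nominal metric matches the common annotation-task convention.
#' @return alpha in \[-1, 1\].
#' @examples
#' m <- rbind(c(1, 2), c(2, 1))
#' krippendorff_alpha(m)   # -0.5
#' @export
krippendorff_alpha <- function(table,
                               metric = c("nominal", "ordinal", "interval")) {
  metric <- match.arg(metric)
  x <- as.matrix(table)
  keep <- rowSums(!is.na(x)) >= 2
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 1) stop("no subject has >= 2 ratings")
  vals <- sort(unique(as.numeric(x[!is.na(x)])))
  V <- length(vals)
  if (V < 2) stop("only one category observed: expected disagreement is 0 ",
                  "and alpha is undefined")
  o <- matrix(0, V, V)
  for (u in seq_len(nrow(x))) {
    r <- as.numeric(x[u, ])
    r <- r[!is.na(r)]
    m <- length(r)
    idx <- match(r, vals)
    tab <- tabulate(idx, nbins = V)
    # ordered within-unit pairs: n_c * n_k for c != k, n_c * (n_c - 1) on diag
    pair <- outer(tab, tab)
    diag(pair) <- tab * (tab - 1)
    o <- o + pair / (m - 1)
  }
  nc <- rowSums(o)
  n <- sum(nc)
  d2 <- switch(metric,
    nominal = 1 - diag(V),
    interval = outer(vals, vals, function(a, b) (a - b)^2),
    ordinal = {
      D <- matrix(0, V, V)
      for (c1 in seq_len(V)) for (c2 in seq_len(V)) {
        if (c1 == c2) next
        lo <- min(c1, c2); hi <- max(c1, c2)
        D[c1, c2] <- (sum(nc[lo:hi]) - (nc[c1] + nc[c2]) / 2)^2
      }
      D
    })
  Do <- sum(o * d2)
  De <- sum(outer(nc, nc) * d2) / (n - 1)
  if (De == 0) stop("expected disagreement is zero; alpha undefined")
  1 - Do / De
}

#' Fleiss' kappa
#'
#' Multi-rater chance-corrected agreement for categorical ratings: each of N
#' subjects must be rated by the same number of raters k (complete table).
#' With per-subject category counts `n_ij`,
#' `P_i = (sum_j n_ij^2 - k) / (k (k - 1))`, `Pbar = mean(P_i)`,
#' `Pe = sum_j p_j^2` with `p_j` the overall category proportions, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`.
#'
#' @param table subjects x raters matrix, complete (no NA).
#' @return kappa (scalar).
#' @export
fleiss_kappa <- function(table) {
  x <- as.matrix(table)
  if (anyNA(x)) stop("Fleiss' kappa requires a complete table (equal rater counts)")
  N <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need >= 2 raters")
  cats <- sort(unique(as.vector(x)))
  nij <- t(apply(x, 1, function(r) tabulate(match(r, cats),
                                            nbins = length(cats))))
  if (length(cats) == 1) nij <- matrix(k, N, 1)
  Pi <- (rowSums(nij^2) - k) / (k * (k - 1))
  Pbar <- mean(Pi)
  pj <- colSums(nij) / (N * k)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-15) {
    stop("expected agreement is 1 (single category); kappa undefined")
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Confusion matrix between two graders
#'
#' `counts[i, j]` = number of observations the test grader placed in class i
#' while the reference grader placed them in class j (classes per the grade
#' scale's index map). `sum(diag(.)) / sum(.)` equals the percent agreement.
#'
#' @param reference,test grade vectors of equal length, values in the scale.
#' @param scale a [grade_scale()].
#' @return M x M integer matrix with grade dimnames (test x reference).
#' @export
confusion_matrix <- function(reference, test, scale) {
  if (length(reference) != length(test)) stop("length mismatch")
  if (length(reference) == 0) stop("empty input")
  ti <- grade_to_index(scale, test)
  ri <- grade_to_index(scale, reference)
  m <- table(factor(ti, levels = seq_len(scale$M)),
             factor(ri, levels = seq_len(scale$M)))
  m <- matrix(as.integer(m), scale$M, scale$M,
              dimnames = list(test = scale$grades,
                              reference = scale$grades))
  m
}
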