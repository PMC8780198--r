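# Independent oracles used to cross-check the package's statistics. These are
# deliberately written against the defining formulas, not the package's code
# paths.

# Krippendorff alpha, route 1: explicit coincidence-matrix construction, one
# rating pair at a time.
oracle_alpha_coincidence <- function(mat, metric = "nominal") {
  keep <- rowSums(!is.na(mat)) >= 2
  mat <- mat[keep, , drop = FALSE]
  vals <- sort(unique(as.numeric(mat[!is.na(mat)])))
  V <- length(vals)
  o <- matrix(0, V, V)
  for (u in seq_len(nrow(mat))) {
    r <- as.numeric(mat[u, ]); r <- r[!is.na(r)]
    m <- length(r)
    for (p in seq_len(m)) for (q in seq_len(m)) {
      if (p == q) next
      o[match(r[p], vals), match(r[q], vals)] <-
        o[match(r[p], vals), match(r[q], vals)] + 1 / (m - 1)
    }
  }
  nc <- rowSums(o); n <- sum(nc)
  d2 <- matrix(0, V, V)
  for (a in seq_len(V)) for (b in seq_len(V)) {
    if (a == b) next
    d2[a, b] <- switch(metric,
      nominal = 1,
      interval = (vals[a] - vals[b])^2,
      ordinal = {
        lo <- min(a, b); hi <- max(a, b)
        (sum(nc[lo:hi]) - (nc[a] + nc[b]) / 2)^2
      })
  }
  Do <- sum(o * d2)
  De <- sum(outer(nc, nc) * d2) / (n - 1)
  1 - Do / De
}

# Krippendorff alpha, route 2: no coincidence matrix at all. D_o is the
# average squared metric difference over all ordered within-unit rating
# pairs (each unit weighted by 1/(m_u - 1)); D_e enumerates all ordered
# pairs of the pooled pairable values.
oracle_alpha_pairwise <- function(mat, metric = "nominal") {
  keep <- rowSums(!is.na(mat)) >= 2
  mat <- mat[keep, , drop = FALSE]
  pooled <- as.numeric(mat[!is.na(mat)])
  vals <- sort(unique(pooled))
  # rank-mass distances for the ordinal metric need the pooled frequencies
  # weighted exactly as coincidence marginals: each value of a unit with m_u
  # ratings appears (m_u - 1) times in pairs / (m_u - 1) weight = once.
  nc <- as.numeric(table(factor(pooled, levels = vals)))
  d2 <- function(a, b) {
    if (a == b) return(0)
    switch(metric,
      nominal = 1,
      interval = (a - b)^2,
      ordinal = {
        ia <- match(a, vals); ib <- match(b, vals)
        lo <- min(ia, ib); hi <- max(ia, ib)
        (sum(nc[lo:hi]) - (nc[ia] + nc[ib]) / 2)^2
      })
  }
  num <- 0; n_tot <- 0
  for (u in seq_len(nrow(mat))) {
    r <- as.numeric(mat[u, ]); r <- r[!is.na(r)]
    m <- length(r)
    n_tot <- n_tot + m
    for (p in seq_len(m)) for (q in seq_len(m)) {
      if (p != q) num <- num + d2(r[p], r[q]) / (m - 1)
    }
  }
  Do <- num / n_tot
  den <- 0
  for (a in pooled) for (b in pooled) den <- den + d2(a, b)
  De <- den / (n_tot * (n_tot - 1))
  1 - Do / De
}

# ICC(2,k) point estimate via base-R aov() variance decomposition.
oracle_icc2k_aov <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (MSC - MSE) / nrow(mat))
}

# Exhaustive-enumeration minimum-expected-cost rule.
oracle_min_cost <- function(p, C) {
  ec <- vapply(seq_len(nrow(C)), function(i) sum(C[i, ] * p), numeric(1))
  which(ec == min(ec))[1]
}

# random rating table with missing values
random_rating_table <- function(n_subj, n_rater, categories = 1:4,
                                p_missing = 0) {
  m <- matrix(sample(categories, n_subj * n_rater, replace = TRUE),
              n_subj, n_rater)
  if (p_missing > 0) {
    m[matrix(runif(length(m)) < p_missing, n_subj, n_rater)] <- NA
  }
  m
}

# tiny noise-free kinematics for closed-form checks
noiseless_kinematics <- function() {
  grade_kinematics(noise_sd_g = 0)
}

still_rater <- function(id = "R0") {
  rater_profile(id, confusion_spread = 0, session_noise_scale = 0)
}
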