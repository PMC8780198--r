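test_that("percent agreement counts exact matches over complete pairs", {
  expect_equal(percent_agreement(rep(9, 10), rep(9, 10)), 1)
  expect_equal(percent_agreement(c(9, 9, 8, 8), c(9, 8, 8, 9)), 0.5)
  expect_equal(percent_agreement(c(9, NA, 8), c(9, 7, NA)), 1)
  expect_error(percent_agreement(1:3, 1:4), "length")
  expect_error(percent_agreement(c(NA, 1), c(1, NA)), "no comparable")
})

test_that("Bland-Altman matches hand arithmetic", {
  r <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$mean_diff, r$sd_diff, r$loa_low, r$loa_high),
               c(0, 0, 0, 0))
  # d = (1, -1): mean 0, sd sqrt(2), LoA -/+ 1.96*sqrt(2)
  r2 <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(r2$mean_diff, 0)
  expect_equal(r2$sd_diff, sqrt(2))
  expect_equal(r2$loa_low, -2.7719, tolerance = 1e-4)
  expect_equal(r2$loa_high, 2.7719, tolerance = 1e-4)
  expect_true(r2$loa_low <= r2$mean_diff && r2$mean_diff <= r2$loa_high)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman is translation equivariant", {
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  base <- bland_altman(x, y)
  for (cst in c(-3.2, 0.5, 10)) {
    sh <- bland_altman(x + cst, y)
    expect_equal(sh$mean_diff, base$mean_diff + cst, tolerance = 1e-12)
    expect_equal(sh$loa_low, base$loa_low + cst, tolerance = 1e-12)
    expect_equal(sh$loa_high, base$loa_high + cst, tolerance = 1e-12)
    expect_equal(sh$sd_diff, base$sd_diff, tolerance = 1e-12)
  }
})

test_that("ICC(2,k) is exact on noise-free additive tables", {
  # identical rater columns with subject variance -> 1
  m <- cbind(1:6, 1:6, 1:6)
  r <- icc_2k(m)
  expect_equal(r$icc, 1)
  # subject effect + rater offsets, no residual noise: the absolute-agreement
  # coefficient charges the offset variance, so the closed form is
  # MSR / (MSR + MSC/n), < 1 for nonzero offsets
  subj <- c(2, 5, 9, 1)
  off <- c(0, 0.5, -0.3)
  m2 <- outer(subj, rep(1, 3)) + outer(rep(1, 4), off)
  n <- 4; k <- 3
  MSR <- k * sum((subj - mean(subj))^2) / (n - 1)
  MSC <- n * sum((off - mean(off))^2) / (k - 1)
  r2 <- icc_2k(m2)
  expect_equal(r2$icc, MSR / (MSR + MSC / n), tolerance = 1e-9)
  # with no offsets it is exactly 1
  expect_equal(icc_2k(outer(subj, rep(1, 3)))$icc, 1, tolerance = 1e-12)
})

test_that("ICC(2,k) matches the aov variance-decomposition oracle", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(5:12, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = 2), n, k) + rnorm(n)  # subject effect
    r <- icc_2k(m)
    expect_equal(r$icc, oracle_icc2k_aov(m), tolerance = 1e-10)
    expect_lte(r$icc, 1)
    if (!is.na(r$ci_low)) {
      expect_true(r$ci_low <= r$icc + 1e-12 && r$icc <= r$ci_high + 1e-12)
    } else {
      expect_lt(r$icc, 0)   # NA bounds only in the negative regime
    }
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("ICC handles degenerate tables as documented", {
  expect_error(icc_2k(cbind(c(1, NA), c(2, 3))), "complete")
  expect_error(icc_2k(matrix(1:3, ncol = 1)), ">= 2")
  expect_warning(r <- icc_2k(cbind(c(1, 1, 1), c(2, 2, 2))),
                 "zero between-subject")
  expect_equal(r$icc, 0)
})

test_that("Krippendorff alpha matches the hand-worked and limit cases", {
  # perfect agreement, any metric
  m <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 1))
  for (met in c("nominal", "ordinal", "interval")) {
    expect_equal(krippendorff_alpha(m, met), 1)
  }
  # two raters, two items, (1,2) vs (2,1): -0.5 nominal
  expect_equal(krippendorff_alpha(rbind(c(1, 2), c(2, 1))), -0.5)
  # a completely missing rater column changes nothing
  m3 <- cbind(c(1, 2, 2, 1), c(1, 2, 1, 1), NA)
  expect_equal(krippendorff_alpha(m3), krippendorff_alpha(m3[, 1:2]))
  # subjects with < 2 ratings are dropped
  m4 <- rbind(c(1, 2), c(2, 1), c(3, NA))
  expect_equal(krippendorff_alpha(m4), krippendorff_alpha(m4[1:2, ]))
  expect_error(krippendorff_alpha(cbind(c(1, 1), c(1, 1))), "one category")
})

test_that("alpha agrees with two independent oracles on random tables", {
  set.seed(3)
  for (i in 1:50) {
    m <- random_rating_table(sample(5:10, 1), sample(2:4, 1),
                             p_missing = runif(1, 0, 0.2))
    if (length(unique(stats::na.omit(as.vector(m)))) < 2) next
    met <- sample(c("nominal", "ordinal", "interval"), 1)
    a <- krippendorff_alpha(m, met)
    expect_equal(a, oracle_alpha_coincidence(m, met), tolerance = 1e-9)
    expect_equal(a, oracle_alpha_pairwise(m, met), tolerance = 1e-9)
    expect_gte(a, -1 - 1e-9)
    expect_lte(a, 1 + 1e-9)
  }
})

test_that("alpha and kappa vanish for independent uniform raters", {
  set.seed(4)
  m <- random_rating_table(10000, 2, categories = 1:4)
  expect_lt(abs(krippendorff_alpha(m)), 0.03)
  expect_lt(abs(fleiss_kappa(m)), 0.03)
})

test_that("ordinal alpha is at least nominal alpha when disagreements are adjacent", {
  set.seed(5)
  for (i in 1:10) {
    truth <- sample(1:4, 30, replace = TRUE)
    r2 <- pmin(pmax(truth + sample(c(-1, 0, 1), 30, replace = TRUE,
                                   prob = c(0.2, 0.6, 0.2)), 1), 4)
    m <- cbind(truth, r2)
    if (length(unique(as.vector(m))) < 2) next
    expect_gte(krippendorff_alpha(m, "ordinal") + 1e-9,
               krippendorff_alpha(m, "nominal"))
  }
})

test_that("Fleiss kappa matches its defining formula", {
  # all raters identical, two categories used
  m <- cbind(c(1, 2, 1), c(1, 2, 1), c(1, 2, 1))
  expect_equal(fleiss_kappa(m), 1)
  # 2 subjects x 2 raters, (1,2) and (2,1): Pbar = 0, Pe = 0.5 -> -1
  expect_equal(fleiss_kappa(rbind(c(1, 2), c(2, 1))), -1)
  # invariance to category relabeling (nominal statistic)
  set.seed(6)
  m2 <- random_rating_table(20, 3, categories = 1:4)
  relab <- matrix(c(40, 10, 30, 20)[m2], nrow(m2), ncol(m2))
  expect_equal(fleiss_kappa(relab), fleiss_kappa(m2))
  # general random tables vs direct formula evaluation
  for (i in 1:20) {
    mt <- random_rating_table(sample(4:10, 1), sample(2:5, 1))
    k <- ncol(mt)
    cats <- sort(unique(as.vector(mt)))
    nij <- t(apply(mt, 1, function(r) tabulate(match(r, cats),
                                               nbins = length(cats))))
    Pbar <- mean((rowSums(nij^2) - k) / (k * (k - 1)))
    pj <- colSums(nij) / sum(nij)
    Pe <- sum(pj^2)
    if (abs(1 - Pe) < 1e-12) next
    expect_equal(fleiss_kappa(mt), (Pbar - Pe) / (1 - Pe), tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(cbind(c(1, NA), c(1, 1))), "complete")
  expect_error(fleiss_kappa(cbind(c(1, 1), c(1, 1))), "undefined")
})

test_that("confusion matrix counts and ties to percent agreement", {
  sc <- grade_scale()
  ref <- c(9, 9, 8, 5)
  cm <- confusion_matrix(ref, ref, sc)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_equal(sum(diag(cm)), 4)
  expect_error(confusion_matrix(c(9, 6), c(9, 9), sc), "not in scale")
  expect_error(confusion_matrix(integer(0), integer(0), sc), "empty")
  # trace/total identity on random tables
  set.seed(7)
  for (i in 1:100) {
    a <- sample(sc$grades, 25, replace = TRUE)
    b <- sample(sc$grades, 25, replace = TRUE)
    cm <- confusion_matrix(a, b, sc)
    expect_equal(sum(diag(cm)) / sum(cm), percent_agreement(a, b))
  }
})
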