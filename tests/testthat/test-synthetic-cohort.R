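test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 3, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL, version = 2),
                   serialize(b, NULL, version = 2))
  # and a different seed changes the cohort
  c2 <- generate_cohort(cohort_config(n_patients = 3, seed = 43))
  expect_false(identical(a$observations$true_grade,
                         c2$observations$true_grade) &&
               identical(a$ratings$rating, c2$ratings$rating))
})

test_that("adding a rater leaves existing raters' draws untouched", {
  cfg <- cohort_config(n_patients = 3, seed = 11)
  two <- generate_cohort(cfg, raters = default_raters()[1:2])
  three <- generate_cohort(cfg, raters = default_raters())
  expect_identical(two$traces[["GS"]], three$traces[["GS"]])
  expect_identical(two$traces[["TS1"]], three$traces[["TS1"]])
  expect_identical(two$ratings[two$ratings$rater_id == "TS1", "rating"],
                   three$ratings[three$ratings$rater_id == "TS1", "rating"])
})

test_that("degenerate grade distribution yields a constant cohort", {
  cfg <- cohort_config(n_patients = 3, grade_probs = c("9" = 1), seed = 5)
  co <- generate_cohort(cfg, sessions = FALSE)
  expect_true(all(co$observations$true_grade == 9L))
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(grade_probs = c("9" = 0.7, "8" = 0.2)),
               "sum to 1")
  expect_error(cohort_config(grade_probs = c(0.5, 0.5)), "named")
  expect_error(cohort_config(window_s = 0), "positive")
  expect_error(generate_cohort(cohort_config(), raters = list()),
               "at least one rater")
  expect_error(generate_cohort(cohort_config(),
                               raters = list(still_rater("A"),
                                             still_rater("A"))),
               "distinct")
})

test_that("empirical composition matches the configured probabilities", {
  # n = 144 with default probabilities; expected counts (5.0, 21.9, 39.0,
  # 78.0) for grades 5,7,8,9. Chi-square GoF at alpha = 0.01 should pass in
  # >= 95 of 100 seeds.
  probs <- c("9" = 0.542, "8" = 0.271, "7" = 0.152, "5" = 0.035)
  expected <- 144 * probs[c("5", "7", "8", "9")]
  expect_equal(unname(expected), c(5.04, 21.888, 39.024, 78.048))
  pass <- 0L
  for (s in 1:100) {
    co <- generate_cohort(cohort_config(n_patients = 36, seed = s),
                          sessions = FALSE)
    counts <- table(factor(co$observations$true_grade, levels = c(5, 7, 8, 9)))
    stat <- sum((counts - expected)^2 / expected)
    if (stat <= qchisq(0.99, df = 3)) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("grade-9 count lands in the exact multinomial 99% interval", {
  co <- generate_cohort(cohort_config(n_patients = 36, seed = 7),
                        sessions = FALSE)
  n9 <- sum(co$observations$true_grade == 9L)
  lo <- qbinom(0.005, 144, 0.542)
  hi <- qbinom(0.995, 144, 0.542)
  expect_gte(n9, lo)
  expect_lte(n9, hi)
})

test_that("exact-count quota assignment reproduces the requested composition", {
  cfg <- cohort_config(n_patients = 36,
                       grade_counts = c("9" = 78, "8" = 39, "7" = 22,
                                        "5" = 5),
                       seed = 3)
  co <- generate_cohort(cfg, sessions = FALSE)
  counts <- table(co$observations$true_grade)
  expect_equal(unname(counts[as.character(c(5, 7, 8, 9))]),
               array(c(5L, 22L, 39L, 78L)), ignore_attr = TRUE)
})

test_that("noise-free traces follow the closed-form drift model", {
  kin <- grade_kinematics(grades = 5, drift_rate_deg_s = 0.7,
                          osc_amp_deg = 0, osc_freq_hz = 0.3,
                          noise_sd_g = 0)
  tr <- simulate_trace(5, kin, still_rater(), window_s = 20,
                       sample_rate_hz = 50, seed = 1)
  traj <- to_drift_trajectory(tr, reference = c(0, 0, 1))
  # recovered final drift angle = r * T within 1e-6 deg
  expect_equal(traj$drift_deg[length(traj$drift_deg)],
               0.7 * tr$time_s[length(tr$time_s)], tolerance = 1e-6)
  # full trajectory matches r*t + a*sin(2 pi f t)
  kin2 <- grade_kinematics(grades = 5, drift_rate_deg_s = 0.5,
                           osc_amp_deg = 2, osc_freq_hz = 0.4,
                           noise_sd_g = 0)
  tr2 <- simulate_trace(5, kin2, still_rater(), seed = 2)
  traj2 <- to_drift_trajectory(tr2, reference = c(0, 0, 1))
  analytic <- abs(0.5 * tr2$time_s + 2 * sin(2 * pi * 0.4 * tr2$time_s))
  expect_lt(max(abs(traj2$drift_deg - analytic)), 1e-6)
})

test_that("no-motion grade produces a constant gravity trace", {
  kin <- grade_kinematics(grades = 9, drift_rate_deg_s = 0, osc_amp_deg = 0,
                          osc_freq_hz = 1, noise_sd_g = 0)
  tr <- simulate_trace(9, kin, still_rater(), seed = 1)
  expect_true(all(abs(tr$acc_g[, 1]) < 1e-12))
  expect_true(all(abs(tr$acc_g[, 3] - 1) < 1e-12))
  expect_equal(nrow(tr$acc_g), round(20 * 50))
})

test_that("severer grades drift more (monotone severity)", {
  kin <- noiseless_kinematics()
  md <- vapply(c(5, 7, 8, 9), function(g) {
    tr <- simulate_trace(g, kin, still_rater(), seed = 99)
    mean(to_drift_trajectory(tr, reference = c(0, 0, 1))$drift_deg)
  }, numeric(1))
  expect_true(all(diff(md) < 0))
  # MaxDrift ordering too
  mx <- vapply(c(5, 9), function(g) {
    tr <- simulate_trace(g, kin, still_rater(), seed = 99)
    max(to_drift_trajectory(tr, reference = c(0, 0, 1))$drift_deg)
  }, numeric(1))
  expect_gt(mx[1], mx[2])
})

test_that("unknown grade is rejected by the trace simulator", {
  expect_error(simulate_trace(6, grade_kinematics(), still_rater()),
               "unknown")
})

test_that("manual ratings follow the confusion kernel", {
  sc <- grade_scale()
  # spread 0: ratings equal truth with probability 1
  r0 <- vapply(1:50, function(s)
    simulate_manual_rating(7, still_rater(), sc, seed = s), numeric(1))
  expect_true(all(r0 == 7))
  # spread Inf: uniform kernel rows
  K <- confusion_kernel(sc, Inf)
  expect_true(all(abs(K - 0.25) < 1e-12))
  # kernel rows are probability vectors decaying with ordinal distance
  K2 <- confusion_kernel(sc, 0.9)
  expect_equal(unname(rowSums(K2)), rep(1, 4))
  for (i in 1:4) {
    d <- abs(seq_len(4) - i)
    expect_true(all(diff(K2[i, order(d)]) <= 1e-12))
  }
  # empirical kernel vs analytic within 3 sd of binomial error, 10,000 draws
  spread <- 0.8
  rt <- rater_profile("X", confusion_spread = spread)
  draws <- vapply(1:10000, function(s)
    simulate_manual_rating(8, rt, sc, seed = s), numeric(1))
  emp <- table(factor(draws, levels = sc$grades)) / 10000
  ana <- confusion_kernel(sc, spread)[grade_to_index(sc, 8), ]
  se <- sqrt(ana * (1 - ana) / 10000)
  expect_true(all(abs(emp - ana) <= 3 * se))
})

test_that("cohort round-trips through the plain-text writer", {
  co <- generate_cohort(cohort_config(n_patients = 1, seed = 2))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$observations$true_grade, co$observations$true_grade)
  expect_equal(nrow(back$ratings), nrow(co$ratings))
  tr0 <- co$traces[["GS"]][[1]]$acc_g
  tr1 <- back$traces[["GS"]][[1]]$acc_g
  expect_equal(unname(tr1), unname(tr0), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
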