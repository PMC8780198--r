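#' Configuration of a synthetic drift-test cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: number of
#' patients (four limb observations each), the skewed grade composition over
#' the observed MRC grades, the age distribution, and the 20 s / 50 Hz
#' accelerometer recording protocol.
#'
#' Defaults reflect an acute-stroke drift-test cohort: 36 patients x 4 limbs
#' = 144 observations, grade probabilities 0.542 / 0.271 / 0.152 / 0.035 for
#' grades 9 / 8 / 7 / 5, age 65.4 +/- 16.02 years, and a 20 s observation
#' window sampled at 50 Hz.
#'
#' @param n_patients number of patients.
#' @param limbs_per_patient limb observations per patient (default 4).
#' @param grade_probs named numeric vector of per-grade probabilities; names
#'   are grades. Must sum to 1 (tolerance 1e-9) with nonnegative entries.
#' @param grade_counts optional named integer vector of exact per-grade
#'   observation counts (names are grades, must sum to
#'   `n_patients * limbs_per_patient`). When supplied, grades are assigned by
#'   exact quota instead of multinomial sampling; `grade_probs` is ignored.
#' @param age_mean,age_sd mean and SD of patient age in years.
#' @param window_s observation window in seconds.
#' @param sample_rate_hz accelerometer sampling rate in Hz.
#' @param seed master integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 36L,
                          limbs_per_patient = 4L,
                          grade_probs = c("9" = 0.542, "8" = 0.271,
                                          "7" = 0.152, "5" = 0.035),
                          grade_counts = NULL,
                          age_mean = 65.4,
                          age_sd = 16.02,
                          window_s = 20,
                          sample_rate_hz = 50,
                          seed = 1L) {
  if (is.null(names(grade_probs))) {
    stop("'grade_probs' must be named by grade")
  }
  if (any(grade_probs < 0)) stop("grade_probs entries must be >= 0")
  if (abs(sum(grade_probs) - 1) > 1e-9) {
    stop("grade_probs must sum to 1 (got ", format(sum(grade_probs)), ")")
  }
  if (window_s <= 0 || sample_rate_hz <= 0) {
    stop("window_s and sample_rate_hz must be positive")
  }
  n_obs <- as.integer(n_patients) * as.integer(limbs_per_patient)
  if (!is.null(grade_counts)) {
    if (is.null(names(grade_counts)) || sum(grade_counts) != n_obs) {
      stop("'grade_counts' must be named by grade and sum to n_patients * limbs_per_patient")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 limbs_per_patient = as.integer(limbs_per_patient),
                 grade_probs = grade_probs,
                 grade_counts = grade_counts,
                 age_mean = age_mean, age_sd = age_sd,
                 window_s = window_s, sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Grade-dependent limb kinematics
#'
#' Forward model linking a true MRC grade to limb movement during the drift
#' test. The tilt angle of the limb relative to its held reference
#' orientation follows
#' \deqn{\theta(t) = r\,t + a \sin(2\pi f t)}
#' in degrees, where the drift rate `r` (deg/s), oscillation amplitude `a`
#' (deg) and frequency `f` (Hz) depend on the grade; 3-axis accelerometer
#' samples are the gravity projection of that tilt plus Gaussian sensor noise.
#' Severer weakness (lower grade) drifts and oscillates more: both `r` and
#' `a` are non-increasing in grade.
#'
#' Defaults are calibrated so that, under the default cohort composition, the
#' cohort-level MeanDrift / MaxDrift / SumOsc are a few degrees, ~8 degrees,
#' and tens of degrees respectively over a 20 s window.
#'
#' @param grades grades the model covers.
#' @param drift_rate_deg_s per-grade drift rate, degrees/second.
#' @param osc_amp_deg per-grade oscillation amplitude, degrees.
#' @param osc_freq_hz per-grade oscillation frequency, Hz.
#' @param noise_sd_g sensor noise SD per axis, in g (post-filtering noise
#'   floor of a MEMS accelerometer).
#' @return A list of class `grade_kinematics` with one row per grade.
#' @export
grade_kinematics <- function(grades = c(5, 7, 8, 9),
                             drift_rate_deg_s = c(1.6, 0.8, 0.35, 0.10),
                             osc_amp_deg = c(4.0, 2.5, 1.5, 0.6),
                             osc_freq_hz = c(0.40, 0.30, 0.25, 0.20),
                             noise_sd_g = 2e-4) {
  stopifnot(length(grades) == length(drift_rate_deg_s),
            length(grades) == length(osc_amp_deg),
            length(grades) == length(osc_freq_hz))
  ord <- order(grades)
  grades <- grades[ord]
  r <- drift_rate_deg_s[ord]; a <- osc_amp_deg[ord]; f <- osc_freq_hz[ord]
  if (is.unsorted(rev(r)) || is.unsorted(rev(a))) {
    stop("drift rate and oscillation amplitude must be non-increasing in grade")
  }
  if (any(r < 0) || any(a < 0) || any(f <= 0) || noise_sd_g < 0) {
    stop("kinematic parameters must be nonnegative (frequencies positive)")
  }
  structure(list(grades = as.integer(grades), drift_rate_deg_s = r,
                 osc_amp_deg = a, osc_freq_hz = f, noise_sd_g = noise_sd_g),
            class = "grade_kinematics")
}

#' Rater profile
#'
#' A rater is characterised by `confusion_spread`, which controls how the
#' probability of a manual rating decays with ordinal distance from the true
#' grade (0 means perfectly accurate ratings), and `session_noise_scale`,
#' which scales the session-to-session variability of the patient's movement
#' during that rater's test relative to the grade-typical kinematics.
#'
#' @param rater_id label, e.g. "GS", "TS1".
#' @param confusion_spread nonnegative; scale of the exponential confusion
#'   kernel `exp(-|index distance| / spread)` (Inf gives uniform ratings).
#' @param session_noise_scale nonnegative multiplier on the log-normal
#'   session jitter of drift rate and oscillation amplitude.
#' @return A list of class `rater_profile`.
#' @export
rater_profile <- function(rater_id, confusion_spread = 0.5,
                          session_noise_scale = 1) {
  if (confusion_spread < 0) stop("confusion_spread must be >= 0")
  if (session_noise_scale < 0) stop("session_noise_scale must be >= 0")
  structure(list(rater_id = as.character(rater_id),
                 confusion_spread = confusion_spread,
                 session_noise_scale = session_noise_scale),
            class = "rater_profile")
}

#' @describeIn rater_profile Default three-rater panel: one expert gold
#'   standard (GS, small confusion spread) and two non-expert testers
#'   (TS1/TS2, larger spread and session variability).
#' @export
default_raters <- function() {
  list(rater_profile("GS",  confusion_spread = 0.35, session_noise_scale = 1.0),
       rater_profile("TS1", confusion_spread = 0.90, session_noise_scale = 1.2),
       rater_profile("TS2", confusion_spread = 0.90, session_noise_scale = 1.2))
}

#' Rater confusion kernel
#'
#' Row-stochastic M x M matrix `P(rated grade | true grade)` with mass
#' decaying exponentially in ordinal (class-index) distance:
#' `P(j | i) ~ exp(-|j - i| / spread)`. `spread = 0` is the identity;
#' `spread = Inf` is uniform.
#'
#' @param scale a [grade_scale()].
#' @param spread nonnegative confusion spread.
#' @return M x M matrix, rows = true grade, columns = rated grade, dimnames
#'   are grades.
#' @export
confusion_kernel <- function(scale, spread) {
  stopifnot(inherits(scale, "grade_scale"), spread >= 0)
  M <- scale$M
  d <- abs(outer(seq_len(M), seq_len(M), "-"))
  if (spread == 0) {
    K <- diag(M)
  } else if (is.infinite(spread)) {
    K <- matrix(1 / M, M, M)
  } else {
    K <- exp(-d / spread)
    K <- K / rowSums(K)
  }
  dimnames(K) <- list(true = scale$grades, rated = scale$grades)
  K
}

# Deterministic sub-seed for the (observation, rater) stream `which`.
# Streams are split per (observation, rater) so adding a rater leaves the
# draws of existing raters untouched. Kept below 2^31 - 1.
.sub_seed <- function(seed, obs, rater, which = 0L) {
  p <- 2147483647
  s <- (as.double(seed) %% p)
  s <- (s * 48271 + as.double(obs) * 7919) %% p
  s <- (s * 48271 + as.double(rater) * 104729) %% p
  s <- (s * 48271 + as.double(which) * 15485863) %% p
  as.integer(s %% 2147483646) + 1L
}

#' Simulate one accelerometer trace
#'
#' Generates the 3-axis accelerometer recording of a single drift-test
#' session: the limb tilts in a vertical plane following
#' `theta(t) = r t + a sin(2 pi f t)` (degrees), so the measured acceleration
#' is the gravity vector rotated by `theta`, i.e.
#' `(sin theta, 0, cos theta)` in g, plus i.i.d. Gaussian sensor noise per
#' axis. The session's effective rate and amplitude are jittered
#' log-normally, with log-SD `0.15 * session_noise_scale`, to emulate
#' within-patient variability between test sessions.
#'
#' @param true_grade the observation's true MRC grade.
#' @param kinematics a [grade_kinematics()] model covering `true_grade`.
#' @param rater a [rater_profile()].
#' @param window_s,sample_rate_hz recording window (s) and rate (Hz).
#' @param seed integer seed for this session's stream.
#' @return A `drift_trace`: list with `time_s`, `acc_g` (n x 3 matrix),
#'   `sample_rate_hz`, `reference` (the true gravity unit vector, c(0,0,1))
#'   and `meta`.
#' @export
simulate_trace <- function(true_grade, kinematics, rater,
                           window_s = 20, sample_rate_hz = 50, seed = 1L) {
  stopifnot(inherits(kinematics, "grade_kinematics"),
            inherits(rater, "rater_profile"))
  gi <- match(as.integer(true_grade), kinematics$grades)
  if (is.na(gi)) stop("grade ", true_grade, " unknown to the kinematics model")
  if (window_s <= 0 || sample_rate_hz <= 0) {
    stop("window_s and sample_rate_hz must be positive")
  }
  n <- round(window_s * sample_rate_hz)
  t <- seq(0, by = 1 / sample_rate_hz, length.out = n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jit_sd <- 0.15 * rater$session_noise_scale
  rate <- kinematics$drift_rate_deg_s[gi] * exp(stats::rnorm(1, 0, jit_sd))
  amp  <- kinematics$osc_amp_deg[gi] * exp(stats::rnorm(1, 0, jit_sd))
  freq <- kinematics$osc_freq_hz[gi]

  theta <- (rate * t + amp * sin(2 * pi * freq * t)) * pi / 180
  acc <- cbind(ax_g = sin(theta), ay_g = 0, az_g = cos(theta))
  if (kinematics$noise_sd_g > 0) {
    acc <- acc + matrix(stats::rnorm(3 * n, 0, kinematics$noise_sd_g), n, 3)
  }
  structure(list(time_s = t, acc_g = acc, sample_rate_hz = sample_rate_hz,
                 reference = c(0, 0, 1),
                 meta = list(rater_id = rater$rater_id,
                             true_grade = as.integer(true_grade),
                             drift_rate_deg_s = rate, osc_amp_deg = amp,
                             osc_freq_hz = freq)),
            class = "drift_trace")
}

#' Simulate one manual rating
#'
#' Draws a rating from the rater's confusion-kernel row for the true grade
#' (see [confusion_kernel()]).
#'
#' @inheritParams simulate_trace
#' @param scale the [grade_scale()] of admissible grades.
#' @return A single grade (integer).
#' @export
simulate_manual_rating <- function(true_grade, rater, scale, seed = 1L) {
  stopifnot(inherits(rater, "rater_profile"))
  i <- grade_to_index(scale, true_grade)
  K <- confusion_kernel(scale, rater$confusion_spread)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  scale$grades[sample.int(scale$M, 1L, prob = K[i, ])]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic drift-test cohort
#'
#' Draws patients (age, gender), assigns true grades to each limb observation
#' from the configured composition, then for every (observation, rater) pair
#' simulates one accelerometer trace and one manual rating. Random streams
#' are split per (observation, rater), so the cohort is bitwise reproducible
#' given `config$seed` and unchanged by appending additional raters.
#'
#' @param config a [cohort_config()].
#' @param kinematics a [grade_kinematics()] model.
#' @param raters list of [rater_profile()]s (at least one, distinct ids).
#' @param sessions simulate the per-rater traces and manual ratings
#'   (default). `FALSE` returns the demographics and true grades only —
#'   handy when only the composition is of interest.
#' @return An object of class `mrc_cohort`: list with
#'   * `observations`: data.frame (obs_id, patient_id, limb, true_grade, age,
#'     gender),
#'   * `ratings`: long data.frame (obs_id, rater_id, rating),
#'   * `traces`: nested list `traces[[rater_id]][[obs_id]]` of `drift_trace`,
#'   * `scale`: the [grade_scale()] spanned by the configured grades,
#'   * `config`, `kinematics`, `raters`.
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 4, seed = 7))
#' table(co$observations$true_grade)
#' @export
generate_cohort <- function(config, kinematics = grade_kinematics(),
                            raters = default_raters(), sessions = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(raters) < 1) stop("at least one rater is required")
  ids <- vapply(raters, function(r) r$rater_id, character(1))
  if (anyDuplicated(ids)) stop("rater ids must be distinct")

  grades_cfg <- as.integer(names(config$grade_probs))
  if (!is.null(config$grade_counts)) {
    grades_cfg <- union(grades_cfg, as.integer(names(config$grade_counts)))
  }
  scale <- grade_scale(grades_cfg)
  n_obs <- config$n_patients * config$limbs_per_patient

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.sub_seed(config$seed, 0L, 0L, 1L))
  age <- round(stats::rnorm(config$n_patients, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, 18), 100)
  gender <- sample(c("F", "M"), config$n_patients, replace = TRUE)

  set.seed(.sub_seed(config$seed, 0L, 0L, 2L))
  if (!is.null(config$grade_counts)) {
    true_grade <- rep(as.integer(names(config$grade_counts)),
                      times = config$grade_counts)
    true_grade <- sample(true_grade)      # shuffle assignment to observations
  } else {
    pool <- as.integer(names(config$grade_probs))
    true_grade <- if (length(pool) == 1) rep(pool, n_obs) else
      sample(pool, n_obs, replace = TRUE, prob = config$grade_probs)
  }

  obs <- data.frame(
    obs_id = seq_len(n_obs),
    patient_id = rep(seq_len(config$n_patients),
                     each = config$limbs_per_patient),
    limb = rep(c("left_arm", "right_arm", "left_leg",
                 "right_leg")[seq_len(config$limbs_per_patient)],
               times = config$n_patients),
    true_grade = true_grade,
    age = rep(age, each = config$limbs_per_patient),
    gender = rep(gender, each = config$limbs_per_patient),
    stringsAsFactors = FALSE
  )

  traces <- stats::setNames(vector("list", length(raters)), ids)
  ratings <- vector("list", length(raters))
  if (sessions) for (r in seq_along(raters)) {
    tr <- vector("list", n_obs)
    rated <- integer(n_obs)
    for (o in seq_len(n_obs)) {
      tr[[o]] <- simulate_trace(obs$true_grade[o], kinematics, raters[[r]],
                                config$window_s, config$sample_rate_hz,
                                seed = .sub_seed(config$seed, o, r, 3L))
      tr[[o]]$meta$patient_id <- obs$patient_id[o]
      tr[[o]]$meta$limb <- obs$limb[o]
      tr[[o]]$meta$obs_id <- o
      rated[o] <- simulate_manual_rating(obs$true_grade[o], raters[[r]], scale,
                                         seed = .sub_seed(config$seed, o, r, 4L))
    }
    traces[[ids[r]]] <- tr
    ratings[[r]] <- data.frame(obs_id = seq_len(n_obs), rater_id = ids[r],
                               rating = rated, stringsAsFactors = FALSE)
  }

  structure(list(observations = obs,
                 ratings = if (sessions) do.call(rbind, ratings) else NULL,
                 traces = traces, scale = scale, config = config,
                 kinematics = kinematics, raters = raters),
            class = "mrc_cohort")
}

#' @export
print.mrc_cohort <- function(x, ...) {
  cat("<mrc_cohort>", nrow(x$observations), "observations (",
      x$config$n_patients, "patients x", x$config$limbs_per_patient,
      "limbs ),", length(x$traces), "raters\n")
  print(table(true_grade = x$observations$true_grade))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes one trace CSV per (observation, rater) session
#' (columns t_s, ax_g, ay_g, az_g), a long-format ratings CSV
#' (patient_id, limb, rater_id, mrc_grade) and a manifest JSON tying trace
#' files to observations. `read_cohort()` reads the directory back into an
#' `mrc_cohort`-shaped list (observations, ratings, traces).
#'
#' @param cohort an `mrc_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mrc_cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_observations = nrow(cohort$observations),
                   raters = names(cohort$traces), sessions = list())
  k <- 0L
  for (rid in names(cohort$traces)) {
    for (o in seq_along(cohort$traces[[rid]])) {
      tr <- cohort$traces[[rid]][[o]]
      fn <- sprintf("traces/obs%03d_%s.csv", o, rid)
      utils::write.csv(data.frame(t_s = tr$time_s,
                                  ax_g = tr$acc_g[, 1],
                                  ay_g = tr$acc_g[, 2],
                                  az_g = tr$acc_g[, 3]),
                       file.path(dir, fn), row.names = FALSE)
      k <- k + 1L
      manifest$sessions[[k]] <- list(obs_id = o, rater_id = rid, file = fn,
                                     sample_rate_hz = tr$sample_rate_hz)
    }
  }
  rat <- merge(cohort$ratings, cohort$observations[, c("obs_id", "patient_id",
                                                       "limb")], by = "obs_id")
  utils::write.csv(data.frame(patient_id = rat$patient_id, limb = rat$limb,
                              rater_id = rat$rater_id, mrc_grade = rat$rating,
                              obs_id = rat$obs_id),
                   file.path(dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  obs <- utils::read.csv(file.path(dir, "observations.csv"))
  ratings <- utils::read.csv(file.path(dir, "ratings.csv"))
  traces <- list()
  for (s in manifest$sessions) {
    df <- utils::read.csv(file.path(dir, s$file))
    tr <- structure(list(time_s = df$t_s,
                         acc_g = as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
                         sample_rate_hz = s$sample_rate_hz,
                         reference = c(0, 0, 1),
                         meta = list(rater_id = s$rater_id, obs_id = s$obs_id)),
                    class = "drift_trace")
    traces[[s$rater_id]][[s$obs_id]] <- tr
  }
  list(observations = obs, ratings = ratings, traces = traces)
}
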