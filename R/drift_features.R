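#' Convert an accelerometer trace to a drift-angle trajectory
#'
#' In a static-tilt reading the accelerometer measures the gravity vector in
#' the sensor frame, so the angle between the (normalised) sample and a
#' reference orientation is the limb's angular deviation:
#' `drift_deg[k] = acos(clamp(<a_k/|a_k|, reference>, -1, 1)) * 180 / pi`.
#'
#' Samples with `|a_k| < 0.1` g carry no usable gravity direction (free-fall
#' artifact); they are flagged and their angle is linearly interpolated from
#' the nearest clean neighbours. More than 10% flagged samples is an error.
#'
#' @param trace a `drift_trace` (see [simulate_trace()]); needs `acc_g`
#'   (n x 3), uniform `time_s` and at least 2 samples.
#' @param reference unit 3-vector, or `"auto"` to use the normalised mean of
#'   the first 0.5 s of samples (assumes the limb starts at rest; a patient
#'   who moves immediately biases the reference).
#' @param smooth logical; apply a 4th-order low-pass Butterworth filter
#'   (cutoff `cutoff_hz`) to each axis before the angle computation. Needs
#'   the \pkg{signal} package. Off by default.
#' @param cutoff_hz low-pass cutoff in Hz when `smooth = TRUE`.
#' @return A `drift_trajectory`: list with `drift_deg` (same length as the
#'   trace, values in \[0, 180\]), `time_s`, `reference`, `flagged` (indices
#'   of free-fall samples) and `meta` carried over from the trace.
#' @export
to_drift_trajectory <- function(trace, reference = "auto", smooth = FALSE,
                                cutoff_hz = 5) {
  acc <- trace$acc_g
  if (is.null(dim(acc)) || ncol(acc) != 3 || nrow(acc) < 2) {
    stop("trace must have an n x 3 acc_g matrix with n >= 2")
  }
  dt <- diff(trace$time_s)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
    stop("timestamps must be strictly increasing and uniform")
  }
  if (smooth) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("smoothing requires the 'signal' package")
    }
    fs <- trace$sample_rate_hz
    bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
    acc <- apply(acc, 2, function(col) signal::filtfilt(bf, col))
  }

  norms <- sqrt(rowSums(acc^2))
  flagged <- which(norms < 0.1)
  if (length(flagged) > 0.10 * nrow(acc)) {
    stop(length(flagged), " of ", nrow(acc),
         " samples are free-fall artifacts (|a| < 0.1 g): trace unusable")
  }

  if (identical(reference, "auto")) {
    head_idx <- which(trace$time_s <= trace$time_s[1] + 0.5)
    head_idx <- setdiff(head_idx, flagged)
    if (length(head_idx) == 0) stop("no clean samples in the first 0.5 s")
    ref <- colMeans(acc[head_idx, , drop = FALSE])
    ref <- ref / sqrt(sum(ref^2))
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != 3 || abs(sqrt(sum(ref^2)) - 1) > 1e-6) {
      stop("reference must be a unit 3-vector or \"auto\"")
    }
  }

  cosang <- pmin(pmax(as.numeric(acc %*% ref) / norms, -1), 1)
  drift <- acos(cosang) * 180 / pi
  if (length(flagged)) {
    ok <- setdiff(seq_along(drift), flagged)
    drift[flagged] <- stats::approx(ok, drift[ok], xout = flagged,
                                    rule = 2)$y
  }
  structure(list(drift_deg = drift, time_s = trace$time_s, reference = ref,
                 flagged = flagged, meta = trace$meta),
            class = "drift_trajectory")
}

#' Kinematic feature extraction
#'
#' Summarises a drift-angle trajectory over the observation window:
#' * `mean_drift` — mean angular deviation (degrees);
#' * `max_drift`  — maximum angular deviation (degrees);
#' * `sum_osc`    — accumulated oscillation, the total variation
#'   `sum_k |drift[k] - drift[k-1]|` (degrees).
#'
#' @param traj a `drift_trajectory` (or a bare numeric vector of angles in
#'   degrees).
#' @param demographics optional named list/row with `age` and `gender`,
#'   attached to the output.
#' @return A one-row data.frame with mean_drift, max_drift, sum_osc and any
#'   demographics.
#' @examples
#' extract_features(c(0, 2, 4))  # mean 2, max 4, sum_osc 4
#' @export
extract_features <- function(traj, demographics = NULL) {
  drift <- if (inherits(traj, "drift_trajectory")) traj$drift_deg else
    as.numeric(traj)
  if (length(drift) == 0) stop("empty trajectory")
  out <- data.frame(mean_drift = mean(drift), max_drift = max(drift),
                    sum_osc = sum(abs(diff(drift))))
  if (!is.null(demographics)) {
    for (nm in names(demographics)) out[[nm]] <- demographics[[nm]]
  }
  out
}

#' Feature table for a whole cohort
#'
#' Runs [to_drift_trajectory()] + [extract_features()] on every
#' (observation, rater) session of a cohort and returns one long table.
#'
#' @param cohort an `mrc_cohort` from [generate_cohort()].
#' @param raters character vector of rater ids (default: all in the cohort).
#' @param reference passed to [to_drift_trajectory()]; the default uses each
#'   trace's known gravity reference when present, else "auto".
#' @return data.frame with obs_id, patient_id, limb, rater_id, mean_drift,
#'   max_drift, sum_osc, age, gender, mrc_manual, mrc_true.
#' @export
cohort_feature_table <- function(cohort, raters = names(cohort$traces),
                                 reference = NULL) {
  obs <- cohort$observations
  rows <- vector("list", length(raters) * nrow(obs))
  k <- 0L
  for (rid in raters) {
    trs <- cohort$traces[[rid]]
    if (is.null(trs)) stop("no sessions for rater '", rid, "'")
    have <- which(!vapply(trs, is.null, logical(1)))
    if (length(trs) < nrow(obs) || length(have) < nrow(obs)) {
      missing_obs <- setdiff(obs$obs_id, intersect(have, seq_along(trs)))
      stop("missing sessions for rater '", rid, "': observations ",
           paste(missing_obs, collapse = ", "))
    }
    rat <- cohort$ratings[cohort$ratings$rater_id == rid, ]
    rat <- rat[order(rat$obs_id), ]
    for (o in seq_len(nrow(obs))) {
      ref <- if (!is.null(reference)) reference else
        if (!is.null(trs[[o]]$reference)) trs[[o]]$reference else "auto"
      fe <- extract_features(to_drift_trajectory(trs[[o]], reference = ref))
      k <- k + 1L
      rows[[k]] <- data.frame(obs_id = obs$obs_id[o],
                              patient_id = obs$patient_id[o],
                              limb = obs$limb[o], rater_id = rid,
                              fe,
                              age = obs$age[o], gender = obs$gender[o],
                              mrc_manual = rat$rating[o],
                              mrc_true = obs$true_grade[o],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname cohort_feature_table
#' @param x feature table to write / path to read.
#' @param path CSV path.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_feature_table
#' @export
read_feature_table <- function(path) utils::read.csv(path)
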