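#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the cohort source, the
#' balancing target, the cost mode, whether SMOTE augmentation is applied,
#' the model-selection budget, the rater roles and the master seed.
#'
#' @param cohort a [cohort_config()] (synthetic cohort source).
#' @param kinematics a [grade_kinematics()].
#' @param raters list of [rater_profile()]s.
#' @param gs_rater id of the gold-standard (expert) rater; its manual
#'   ratings are the training labels.
#' @param test_raters ids of the non-expert sessions to be re-scored by the
#'   model; must not include `gs_rater`.
#' @param balance_n balanced training-set size N (default 600); must be
#'   divisible by the number of observed classes.
#' @param cost_mode "linear" (ordinal distance), "imbalance" (distance
#'   scaled by class imbalance) or "none" (0/1).
#' @param augmentation apply boosting-factor SMOTE balancing before
#'   training.
#' @param select_iterations model-selection budget (evaluations of the CV
#'   objective). 0 trains the fixed `ensemble` spec directly.
#' @param ensemble fallback [ensemble_spec()] used when
#'   `select_iterations = 0`.
#' @param labels train on the expert's manual ratings ("gs_manual", the
#'   study protocol) or on the simulated true grades ("truth", for oracle
#'   studies).
#' @param smote_k SMOTE neighbour count.
#' @param seed master seed; every downstream stream is derived from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              kinematics = grade_kinematics(),
                              raters = default_raters(),
                              gs_rater = "GS",
                              test_raters = c("TS1", "TS2"),
                              balance_n = 600L,
                              cost_mode = c("linear", "imbalance", "none"),
                              augmentation = TRUE,
                              select_iterations = 0L,
                              ensemble = ensemble_spec("bagging",
                                                       n_learners = 60L,
                                                       max_depth = 4L),
                              labels = c("gs_manual", "truth"),
                              smote_k = 5L,
                              seed = 1L) {
  cost_mode <- match.arg(cost_mode)
  labels <- match.arg(labels)
  if (gs_rater %in% test_raters) {
    stop("the gold-standard rater must be distinct from the test raters")
  }
  ids <- vapply(raters, function(r) r$rater_id, character(1))
  missing_ids <- setdiff(c(gs_rater, test_raters), ids)
  if (length(missing_ids)) {
    stop("configured rater(s) absent from the panel: ",
         paste(missing_ids, collapse = ", "))
  }
  structure(list(cohort = cohort, kinematics = kinematics, raters = raters,
                 gs_rater = gs_rater, test_raters = test_raters,
                 balance_n = as.integer(balance_n), cost_mode = cost_mode,
                 augmentation = isTRUE(augmentation),
                 select_iterations = as.integer(select_iterations),
                 ensemble = ensemble, labels = labels,
                 smote_k = as.integer(smote_k), seed = as.integer(seed)),
            class = "experiment_config")
}

.feature_cols <- c("mean_drift", "max_drift", "sum_osc", "age", "gender_num")

# rating vectors (by obs order) for a rater id
.rating_vec <- function(ratings, rid, n_obs) {
  r <- ratings[ratings$rater_id == rid, ]
  out <- rep(NA_integer_, n_obs)
  out[r$obs_id] <- r$rating
  out
}

# agreement/reliability block for a set of raters (first one = reference)
.reliability_block <- function(rating_list, scale) {
  ids <- names(rating_list)
  gs <- rating_list[[1]]
  pairwise <- list()
  confusion <- list()
  for (j in seq_along(rating_list)[-1]) {
    key <- paste0(ids[1], "-", ids[j])
    pairwise[[key]] <- percent_agreement(gs, rating_list[[j]])
    confusion[[key]] <- confusion_matrix(gs, rating_list[[j]], scale)
  }
  sets <- c(lapply(seq_along(ids)[-1], function(j) c(1L, j)),
            list(seq_along(ids)))
  alpha <- list(); kappa <- list()
  for (s in sets) {
    key <- paste(ids[s], collapse = "-")
    m <- do.call(cbind, rating_list[s])
    alpha[[key]] <- krippendorff_alpha(m, metric = "nominal")
    kappa[[key]] <- fleiss_kappa(m)
  }
  list(percent_agreement = pairwise,
       mean_percent_agreement = mean(unlist(pairwise)),
       krippendorff_alpha = alpha, fleiss_kappa = kappa,
       confusion = confusion)
}

# per-feature Bland-Altman (GS vs each test session) and ICC across sessions
.feature_agreement <- function(ft, gs, tests) {
  feats <- c("mean_drift", "max_drift", "sum_osc")
  wide <- function(col) {
    sapply(c(gs, tests), function(rid) {
      f <- ft[ft$rater_id == rid, ]
      f[order(f$obs_id), col]
    })
  }
  out <- list()
  for (fe in feats) {
    w <- wide(fe)
    ba <- lapply(tests, function(rid) {
      bland_altman(w[, gs], w[, rid])
    })
    names(ba) <- paste0(gs, "-", tests)
    out[[fe]] <- list(bland_altman = ba, icc = icc_2k(w))
  }
  out
}

#' Run the manual-vs-ML scaling experiment
#'
#' Full pipeline on one cohort: simulate (or reuse) the cohort, extract
#' kinematic features for every rater session, train a cost-sensitive
#' ensemble on the gold-standard session (features from the GS session,
#' labels from the GS manual ratings), re-score the non-expert sessions with
#' the model (AI ratings), and compute the agreement/reliability report for
#' both the manual panel (GS, TS1, TS2, ...) and the ML panel
#' (GS, AI_TS1, AI_TS2, ...). The model never sees the non-experts' manual
#' ratings.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-built `mrc_cohort` (e.g. shared across ablation
#'   rows); by default one is generated from `config`.
#' @return A `reliability_report`: list with `manual` and `ml` statistic
#'   blocks (pairwise percent agreement, Krippendorff alpha, Fleiss kappa,
#'   confusion matrices), `features` (per-feature Bland-Altman + ICC(2,k)),
#'   `model_info`, `ml_ratings` and `config` echoes.
#' @export
run_experiment <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort, config$kinematics, config$raters)
  }
  scale_all <- cohort$scale
  n_obs <- nrow(cohort$observations)
  ft <- cohort_feature_table(cohort)
  ft$gender_num <- as.numeric(factor(ft$gender, levels = c("F", "M"))) - 1

  gs_ft <- ft[ft$rater_id == config$gs_rater, ]
  gs_ft <- gs_ft[order(gs_ft$obs_id), ]
  labels_grade <- if (config$labels == "gs_manual") gs_ft$mrc_manual else
    gs_ft$mrc_true

  # classes observed in the labels define the model's scale
  obs_grades <- sort(unique(labels_grade))
  if (length(obs_grades) < 2) stop("training labels contain a single grade")
  scale <- grade_scale(obs_grades)
  M <- scale$M

  train_df <- gs_ft[, .feature_cols]
  train_df$class_idx <- grade_to_index(scale, labels_grade)

  if (config$augmentation) {
    sbt <- balance_training_set(train_df, N = config$balance_n,
                                k = config$smote_k,
                                seed = .sub_seed(config$seed, 0L, 0L, 10L))
  } else {
    sbt <- train_df
    sbt$origin <- "original"
  }

  sbt_counts <- tabulate(sbt$class_idx, nbins = M)
  cost <- switch(config$cost_mode,
                 linear = linear_cost_matrix(M),
                 imbalance = imbalance_cost_matrix(sbt_counts, M),
                 none = zero_one_cost_matrix(M))

  if (config$select_iterations > 0) {
    sel <- select_model(sbt, cost, iterations = config$select_iterations,
                        seed = .sub_seed(config$seed, 0L, 0L, 11L))
    model <- sel$model
    model_info <- list(selected = TRUE, spec = sel$spec,
                       objective = sel$objective, history = sel$state)
  } else {
    sp <- config$ensemble
    sp$seed <- .sub_seed(config$seed, 0L, 0L, 12L)
    model <- train_ensemble(sbt, sp, cost = cost, M = M)
    model_info <- list(selected = FALSE, spec = sp, objective = NA_real_)
  }

  ml_ratings <- list()
  for (rid in config$test_raters) {
    f <- ft[ft$rater_id == rid, ]
    if (nrow(f) < n_obs) {
      stop("missing sessions for rater '", rid, "': observations ",
           paste(setdiff(cohort$observations$obs_id, f$obs_id),
                 collapse = ", "))
    }
    f <- f[order(f$obs_id), ]
    ml_ratings[[paste0("AI_", rid)]] <-
      predict_grade(model, f[, .feature_cols], scale = scale)
  }

  manual_list <- c(
    stats::setNames(list(.rating_vec(cohort$ratings, config$gs_rater, n_obs)),
                    config$gs_rater),
    stats::setNames(lapply(config$test_raters, .rating_vec,
                           ratings = cohort$ratings, n_obs = n_obs),
                    config$test_raters))
  ml_list <- c(manual_list[1], ml_ratings)

  report <- list(
    method = if (config$augmentation && config$cost_mode != "none") {
      "machine_learning_dataaug_costadj"
    } else if (config$augmentation) "machine_learning_dataaug" else
      "machine_learning",
    manual = .reliability_block(manual_list, scale_all),
    ml = .reliability_block(ml_list, scale_all),
    features = .feature_agreement(ft, config$gs_rater, config$test_raters),
    model_info = model_info,
    ml_ratings = ml_ratings,
    class_counts = table(factor(labels_grade, levels = scale_all$grades)),
    seed = config$seed,
    cohort_hash = .cohort_hash(cohort)
  )
  class(report) <- "reliability_report"
  report
}

# cheap deterministic digest of the cohort's defining content
.cohort_hash <- function(cohort) {
  raw <- serialize(list(cohort$observations, cohort$ratings), NULL,
                   version = 2)
  sprintf("%d-%.0f", length(raw), sum(as.integer(raw)))
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>", x$method, "\n")
  cat("  manual alpha (all raters):",
      format(x$manual$krippendorff_alpha[[length(x$manual$krippendorff_alpha)]],
             digits = 3), "\n")
  cat("  ML alpha (all raters):    ",
      format(x$ml$krippendorff_alpha[[length(x$ml$krippendorff_alpha)]],
             digits = 3), "\n")
  cat("  mean percent agreement: manual",
      format(x$manual$mean_percent_agreement, digits = 3), "| ML",
      format(x$ml$mean_percent_agreement, digits = 3), "\n")
  invisible(x)
}

#' Ablation over the scaling method
#'
#' Runs the experiment three ways on one shared cohort: manual scaling only,
#' machine learning with data augmentation (0/1 cost), and machine learning
#' with data augmentation plus ordinal cost adjustment. The manual block is
#' identical across rows by construction (same cohort, same seeds).
#'
#' @param config an [experiment_config()]; its `augmentation`/`cost_mode`
#'   are overridden per row.
#' @return list with `reports` (named list of `reliability_report`s for
#'   `dataaug` and `dataaug_costadj`), `manual` (the manual block), and
#'   `comparison`: a data.frame with one row per (method, metric, rater-set)
#'   cell.
#' @export
run_ablation <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort, config$kinematics, config$raters)

  cfg_aug <- config; cfg_aug$augmentation <- TRUE; cfg_aug$cost_mode <- "none"
  cfg_adj <- config; cfg_adj$augmentation <- TRUE; cfg_adj$cost_mode <- "linear"
  rep_aug <- run_experiment(cfg_aug, cohort = cohort)
  rep_adj <- run_experiment(cfg_adj, cohort = cohort)

  rows <- list()
  add_rows <- function(method, block, prefix) {
    for (key in names(block$krippendorff_alpha)) {
      rows[[length(rows) + 1]] <<- data.frame(
        method = method, metric = "k_alpha", rater_set = key,
        value = block$krippendorff_alpha[[key]])
      rows[[length(rows) + 1]] <<- data.frame(
        method = method, metric = "fleiss_kappa", rater_set = key,
        value = block$fleiss_kappa[[key]])
    }
  }
  add_rows("manual", rep_aug$manual)
  add_rows("ml_dataaug", rep_aug$ml)
  add_rows("ml_dataaug_costadj", rep_adj$ml)

  list(reports = list(dataaug = rep_aug, dataaug_costadj = rep_adj),
       manual = rep_aug$manual,
       comparison = do.call(rbind, rows),
       cohort_hash = rep_aug$cohort_hash)
}

#' Serialise a reliability report
#'
#' `report_to_json()` writes the full report (statistics, confusion
#' matrices, model metadata) as JSON; `report_to_csv()` flattens the scalar
#' statistics into a tidy CSV (block, statistic, key, value).
#'
#' @param report a `reliability_report`.
#' @param path output path; for JSON, `NULL` returns the string.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- report
  obj$model_info$history <- NULL
  obj$manual$confusion <- lapply(obj$manual$confusion, unclass)
  obj$ml$confusion <- lapply(obj$ml$confusion, unclass)
  obj$features <- lapply(obj$features, function(fe) {
    list(bland_altman = lapply(fe$bland_altman, function(ba)
      ba[c("mean_diff", "sd_diff", "loa_low", "loa_high", "n")]),
      icc = fe$icc[c("icc", "ci_low", "ci_high", "p_value")])
  })
  obj$class_counts <- as.list(obj$class_counts)
  class(obj) <- NULL
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    invisible(path)
  }
}

#' @rdname report_to_json
#' @export
report_to_csv <- function(report, path) {
  rows <- list()
  flat <- function(block, bname) {
    for (key in names(block$percent_agreement)) {
      rows[[length(rows) + 1]] <<- data.frame(
        block = bname, statistic = "percent_agreement", key = key,
        value = block$percent_agreement[[key]])
    }
    for (key in names(block$krippendorff_alpha)) {
      rows[[length(rows) + 1]] <<- data.frame(
        block = bname, statistic = "krippendorff_alpha", key = key,
        value = block$krippendorff_alpha[[key]])
      rows[[length(rows) + 1]] <<- data.frame(
        block = bname, statistic = "fleiss_kappa", key = key,
        value = block$fleiss_kappa[[key]])
    }
  }
  flat(report$manual, "manual")
  flat(report$ml, "ml")
  for (fe in names(report$features)) {
    icc <- report$features[[fe]]$icc
    rows[[length(rows) + 1]] <- data.frame(
      block = "features", statistic = paste0("icc_2k_", fe), key = "all",
      value = icc$icc)
    for (key in names(report$features[[fe]]$bland_altman)) {
      ba <- report$features[[fe]]$bland_altman[[key]]
      rows[[length(rows) + 1]] <- data.frame(
        block = "features", statistic = paste0("ba_mean_diff_", fe),
        key = key, value = ba$mean_diff)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
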