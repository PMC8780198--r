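#' Ensemble specification
#'
#' Hyperparameters of one candidate cost-sensitive ensemble over CART
#' (rpart) base learners.
#'
#' @param family one of "bagging", "adaboost", "rusboost".
#' @param n_learners number of base learners (>= 1).
#' @param max_depth depth limit of each tree.
#' @param learning_rate boosting shrinkage in (0, 1]; ignored by bagging.
#' @param undersample_ratio RUSBoost per-round sampling ratio: each class is
#'   sampled down to `ratio * min class count` (capped at the class size).
#' @param seed integer seed for the training randomness.
#' @export
ensemble_spec <- function(family = c("bagging", "adaboost", "rusboost"),
                          n_learners = 100L, max_depth = 3L,
                          learning_rate = 0.5, undersample_ratio = 1,
                          seed = 1L) {
  family <- match.arg(family)
  if (n_learners < 1) stop("n_learners must be >= 1")
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1]")
  }
  structure(list(family = family, n_learners = as.integer(n_learners),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 undersample_ratio = undersample_ratio,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Posterior matrix from one rpart tree, with columns for all M classes.
.tree_posterior <- function(tree, newdata, M) {
  p <- stats::predict(tree, newdata = newdata, type = "prob")
  out <- matrix(0, nrow(newdata), M)
  cols <- as.integer(colnames(p))
  out[, cols] <- p
  out
}

#' Train a cost-sensitive ensemble classifier
#'
#' Fits a bagging, AdaBoost (SAMME) or RUSBoost ensemble of CART trees on a
#' balanced training set. For the boosting families, instance weights after
#' each round are multiplied by `exp(alpha * c_norm(pred, true))` where
#' `c_norm` is the attached cost matrix rescaled to max 1 (a correctly
#' classified instance has cost 0), so distant ordinal mistakes are
#' up-weighted harder than adjacent ones; with `cost_in_boosting = FALSE`
#' (or no cost matrix) this reduces to the usual 0/1 misclassification
#' update. RUSBoost additionally trains each round on a random
#' class-balanced undersample drawn with probability proportional to the
#' current weights.
#'
#' @param data data.frame containing the feature columns and a `class_idx`
#'   column of integer class indices (1..M).
#' @param spec an [ensemble_spec()].
#' @param cost optional `cost_matrix` (attached to the model and used by
#'   [predict_grade()]); when `NULL`, 0/1 costs are used throughout.
#' @param M number of classes; default `max(data$class_idx)` or
#'   `nrow(cost)`.
#' @param feature_cols feature column names; default: every column except
#'   `class_idx` and `origin`.
#' @param cost_in_boosting apply the cost matrix inside the boosting weight
#'   update (in addition to the prediction rule).
#' @return An `ensemble_model`: fitted trees, per-learner weights, class
#'   count, attached cost and training metadata.
#' @export
train_ensemble <- function(data, spec, cost = NULL, M = NULL,
                           feature_cols = NULL, cost_in_boosting = TRUE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  data <- as.data.frame(data)
  if (!"class_idx" %in% names(data)) stop("data needs a 'class_idx' column")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data), c("class_idx", "origin"))
  }
  if (is.null(M)) M <- if (!is.null(cost)) nrow(cost) else max(data$class_idx)
  y <- factor(data$class_idx, levels = seq_len(M))
  if (length(unique(data$class_idx)) < 2) {
    stop("training set contains a single class")
  }
  x <- data[, feature_cols, drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  if (any(vapply(x[num], function(col) any(!is.finite(col)), logical(1)))) {
    stop("non-finite feature values in training data")
  }
  n <- nrow(data)
  K <- length(unique(data$class_idx))

  cn <- if (!is.null(cost) && cost_in_boosting) {
    unclass(cost) / max(cost)
  } else {
    1 - diag(M)
  }

  ctrl <- rpart::rpart.control(maxdepth = spec$max_depth, cp = 0,
                               minsplit = 5, minbucket = 2, xval = 0)
  df <- cbind(x, .y = y)
  fml <- stats::as.formula(paste(".y ~", paste(feature_cols, collapse = "+")))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  learners <- vector("list", spec$n_learners)
  alphas <- numeric(spec$n_learners)
  w <- rep(1 / n, n)
  b_used <- 0L
  for (b in seq_len(spec$n_learners)) {
    if (spec$family == "bagging") {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- rpart::rpart(fml, data = df[idx, , drop = FALSE], method = "class",
                          control = ctrl)
      alpha <- 1
    } else {
      if (spec$family == "rusboost") {
        cls_n <- tabulate(data$class_idx, nbins = M)
        m_min <- min(cls_n[cls_n > 0])
        take <- unlist(lapply(which(cls_n > 0), function(ci) {
          members <- which(data$class_idx == ci)
          n_take <- min(length(members),
                        max(2L, round(spec$undersample_ratio * m_min)))
          pw <- w[members]
          if (sum(pw) <= 0) pw <- rep(1, length(members))
          sample(members, n_take, replace = FALSE, prob = pw)
        }))
        wt <- w[take] / sum(w[take])
        fit <- rpart::rpart(fml, data = df[take, , drop = FALSE],
                            weights = wt, method = "class", control = ctrl)
      } else {
        fit <- rpart::rpart(fml, data = df, weights = w, method = "class",
                            control = ctrl)
      }
      post <- .tree_posterior(fit, x, M)
      pred <- max.col(post, ties.method = "first")
      miss <- pred != data$class_idx
      err <- sum(w[miss])
      err <- min(max(err, 1e-10), 1 - 1e-10)
      alpha <- spec$learning_rate * (log((1 - err) / err) + log(K - 1))
      if (alpha <= 0) {         # weak learner no better than chance: reset
        w <- rep(1 / n, n)
        learners[[b]] <- fit
        alphas[b] <- 0
        b_used <- b
        next
      }
      cost_mult <- cn[cbind(pred, data$class_idx)]
      w <- w * exp(alpha * cost_mult)
      w <- w / sum(w)
    }
    learners[[b]] <- fit
    alphas[b] <- alpha
    b_used <- b
  }
  if (all(alphas == 0)) alphas[] <- 1   # degenerate: fall back to plain vote

  structure(list(learners = learners[seq_len(b_used)],
                 alphas = alphas[seq_len(b_used)],
                 M = M, spec = spec, cost = cost,
                 feature_cols = feature_cols,
                 n_train = n),
            class = "ensemble_model")
}

#' Posterior class probabilities of an ensemble
#'
#' Bagging averages the trees' class-probability outputs; the boosting
#' families take the alpha-weight-normalised hard votes of their learners.
#' Rows are valid probability vectors (nonnegative, sum to 1).
#'
#' @param model an `ensemble_model` from [train_ensemble()].
#' @param newdata data.frame with the model's feature columns.
#' @return numeric matrix, one row per instance, `model$M` columns.
#' @export
predict_posterior <- function(model, newdata) {
  if (!inherits(model, "ensemble_model") || length(model$learners) == 0) {
    stop("model is not a fitted ensemble")
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(model$feature_cols, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- newdata[, model$feature_cols, drop = FALSE]
  M <- model$M
  acc <- matrix(0, nrow(x), M)
  if (model$spec$family == "bagging") {
    for (b in seq_along(model$learners)) {
      acc <- acc + .tree_posterior(model$learners[[b]], x, M)
    }
    acc <- acc / length(model$learners)
  } else {
    total <- 0
    for (b in seq_along(model$learners)) {
      a <- model$alphas[b]
      if (a <= 0) next
      post <- .tree_posterior(model$learners[[b]], x, M)
      vote <- max.col(post, ties.method = "first")
      acc[cbind(seq_len(nrow(x)), vote)] <-
        acc[cbind(seq_len(nrow(x)), vote)] + a
      total <- total + a
    }
    if (total == 0) {  # all-zero alphas: uniform posterior
      acc[] <- 1 / M
      total <- 1
      return(acc)
    }
    acc <- acc / total
  }
  acc
}

#' Minimum-expected-cost grade prediction
#'
#' Computes the expected misclassification cost of predicting each class,
#' `E_i = sum_j c_ij p_j`, and returns the class minimising it. Ties are
#' broken toward the lower class index, i.e. the more severe grade (the
#' clinically conservative choice). With 0/1 costs this is argmax posterior.
#'
#' @param model an `ensemble_model`; its attached cost matrix is used unless
#'   `cost` overrides it (no cost at all means 0/1).
#' @param newdata feature data.frame.
#' @param cost optional `cost_matrix` override.
#' @param scale optional [grade_scale()]; when given, returns grades instead
#'   of class indices.
#' @return integer vector of class indices, or grades when `scale` is given.
#' @export
predict_grade <- function(model, newdata, cost = NULL, scale = NULL) {
  post <- predict_posterior(model, newdata)
  C <- if (!is.null(cost)) cost else model$cost
  if (is.null(C)) C <- zero_one_cost_matrix(model$M)
  idx <- min_cost_class(post, C)
  if (!is.null(scale)) index_to_grade(scale, idx) else idx
}

#' @rdname predict_grade
#' @param posterior matrix (rows = instances) or vector of class
#'   probabilities.
#' @details `min_cost_class()` is the bare decision rule
#'   `argmin_i sum_j c_ij p_j`, exposed for testing and reuse.
#' @export
min_cost_class <- function(posterior, cost) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  expected <- posterior %*% t(unclass(cost))   # E[, i] = sum_j p_j c_ij
  as.integer(apply(expected, 1, which.min))    # which.min -> lowest index tie
}

#' Cross-validated expected-cost objective
#'
#' Mean over stratified folds of the mean expected misclassification cost
#' `c(pred, true)` on held-out *original* instances. Synthetic (SMOTE)
#' instances never enter a validation fold — they stay in every training
#' fold — so the objective is free of interpolation leakage.
#'
#' @param spec an [ensemble_spec()].
#' @param sbt balanced training set with `class_idx` and `origin` columns.
#' @param cost `cost_matrix` used both for training and for scoring.
#' @param folds number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param cost_in_boosting passed to [train_ensemble()].
#' @return scalar objective (lower is better).
#' @export
cv_cost_objective <- function(spec, sbt, cost, folds = 5L, seed = 1L,
                              cost_in_boosting = TRUE) {
  if (folds < 2) stop("folds must be >= 2")
  sbt <- as.data.frame(sbt)
  if (!"origin" %in% names(sbt)) sbt$origin <- "original"
  orig_idx <- which(sbt$origin == "original")
  if (length(orig_idx) < folds) stop("fewer original instances than folds")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # stratified fold labels over originals
  fold_of <- integer(length(orig_idx))
  for (ci in unique(sbt$class_idx[orig_idx])) {
    members <- which(sbt$class_idx[orig_idx] == ci)
    fold_of[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  per_fold <- vapply(seq_len(folds), function(f) {
    hold <- orig_idx[fold_of == f]
    if (length(hold) == 0) return(NA_real_)
    train <- sbt[-hold, , drop = FALSE]
    if (length(unique(train$class_idx)) < 2) {
      stop("a training fold lost all but one class; use more data or fewer folds")
    }
    sp <- spec
    sp$seed <- spec$seed + f
    m <- train_ensemble(train, sp, cost = cost,
                        M = nrow(cost), cost_in_boosting = cost_in_boosting)
    pred <- predict_grade(m, sbt[hold, , drop = FALSE])
    mean(unclass(cost)[cbind(pred, sbt$class_idx[hold])])
  }, numeric(1))
  mean(per_fold, na.rm = TRUE)
}

# ---- model selection -------------------------------------------------------

.sample_spec <- function(candidates, n_learners_range, depth_range, lr_range,
                         seed_base) {
  fam <- sample(candidates, 1)
  ensemble_spec(family = fam,
                n_learners = sample(seq(n_learners_range[1],
                                        n_learners_range[2]), 1),
                max_depth = sample(seq(depth_range[1], depth_range[2]), 1),
                learning_rate = exp(stats::runif(1, log(lr_range[1]),
                                                 log(lr_range[2]))),
                seed = seed_base)
}

.encode_spec <- function(spec, candidates, n_learners_range, depth_range,
                         lr_range) {
  onehot <- as.numeric(candidates == spec$family)
  c(onehot,
    (spec$n_learners - n_learners_range[1]) / max(1, diff(n_learners_range)),
    (spec$max_depth - depth_range[1]) / max(1, diff(depth_range)),
    (log(spec$learning_rate) - log(lr_range[1])) /
      (log(lr_range[2]) - log(lr_range[1])))
}

# Gaussian-process surrogate (RBF kernel, nugget) + expected improvement.
.gp_ei <- function(X, y, Xcand, lengthscale = 0.5, nugget = 1e-6) {
  ymu <- mean(y); ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ymu) / ysd
  sq <- function(A, B) outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  Kxx <- exp(-0.5 * pmax(sq(X, X), 0) / lengthscale^2) +
    diag(nugget + 1e-8, nrow(X))
  L <- chol(Kxx)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Kxs <- exp(-0.5 * pmax(sq(Xcand, X), 0) / lengthscale^2)
  mu <- as.numeric(Kxs %*% alpha)
  v <- forwardsolve(t(L), t(Kxs))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- min(ys)
  z <- (best - mu) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  ei
}

#' Iterative model selection over ensemble families
#'
#' Minimises [cv_cost_objective()] over the mixed hyperparameter space
#' (family x n_learners x tree depth x learning rate). The default engine
#' fits a Gaussian-process surrogate (RBF kernel on a continuous encoding
#' with the family one-hot) to the evaluation history and picks the next
#' configuration by expected improvement over a random candidate pool; the
#' `"random"` engine is a seeded random search fallback. The incumbent
#' (best-so-far) objective is non-increasing by construction, and the
#' returned model is the incumbent retrained on the full balanced set.
#'
#' @param sbt balanced training set (`class_idx`, `origin`, features).
#' @param cost `cost_matrix`.
#' @param candidates subset of c("bagging", "adaboost", "rusboost").
#' @param iterations total number of objective evaluations (>= 1).
#' @param seed integer seed.
#' @param folds CV folds for the objective.
#' @param engine "gp" (surrogate + expected improvement) or "random".
#' @param n_learners_range,depth_range,lr_range search-space bounds.
#' @param cost_in_boosting passed through to training.
#' @return list with `model` (retrained incumbent `ensemble_model`), `spec`,
#'   `objective`, and `state`: the history data.frame (family, n_learners,
#'   max_depth, learning_rate, objective, best_so_far).
#' @export
select_model <- function(sbt, cost,
                         candidates = c("bagging", "adaboost", "rusboost"),
                         iterations = 50L, seed = 1L, folds = 5L,
                         engine = c("gp", "random"),
                         n_learners_range = c(10L, 300L),
                         depth_range = c(1L, 8L),
                         lr_range = c(0.01, 1),
                         cost_in_boosting = TRUE) {
  engine <- match.arg(engine)
  if (length(candidates) == 0) stop("empty candidate list")
  if (iterations < 1) stop("iterations must be >= 1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  history <- list()
  specs <- list()
  evaluate <- function(sp) {
    cv_cost_objective(sp, sbt, cost, folds = folds, seed = seed,
                      cost_in_boosting = cost_in_boosting)
  }

  n_init <- min(max(4L, length(candidates) + 1L), iterations)
  for (i in seq_len(n_init)) {
    sp <- .sample_spec(candidates, n_learners_range, depth_range, lr_range,
                       seed_base = seed + i)
    sp$family <- candidates[((i - 1) %% length(candidates)) + 1]  # cover all
    specs[[i]] <- sp
    history[[i]] <- evaluate(sp)
  }

  while (length(history) < iterations) {
    i <- length(history) + 1L
    if (engine == "gp" && length(history) >= 3) {
      X <- t(vapply(specs, .encode_spec, numeric(length(candidates) + 3),
                    candidates, n_learners_range, depth_range, lr_range))
      y <- unlist(history)
      cand <- lapply(seq_len(128), function(j)
        .sample_spec(candidates, n_learners_range, depth_range, lr_range,
                     seed_base = seed + i))
      Xc <- t(vapply(cand, .encode_spec, numeric(length(candidates) + 3),
                     candidates, n_learners_range, depth_range, lr_range))
      ei <- tryCatch(.gp_ei(X, y, Xc), error = function(e) NULL)
      sp <- if (is.null(ei)) cand[[1]] else cand[[which.max(ei)]]
    } else {
      sp <- .sample_spec(candidates, n_learners_range, depth_range, lr_range,
                         seed_base = seed + i)
    }
    specs[[i]] <- sp
    history[[i]] <- evaluate(sp)
  }

  y <- unlist(history)
  best_i <- which.min(y)
  hist_df <- data.frame(
    family = vapply(specs, `[[`, character(1), "family"),
    n_learners = vapply(specs, `[[`, integer(1), "n_learners"),
    max_depth = vapply(specs, `[[`, integer(1), "max_depth"),
    learning_rate = vapply(specs, `[[`, numeric(1), "learning_rate"),
    objective = y,
    best_so_far = cummin(y)
  )
  best_spec <- specs[[best_i]]
  best_spec$seed <- seed
  final <- train_ensemble(sbt, best_spec, cost = cost, M = nrow(cost),
                          cost_in_boosting = cost_in_boosting)
  list(model = final, spec = best_spec, objective = y[best_i],
       state = hist_df)
}
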