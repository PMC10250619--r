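#' @name automl
#' @title Automated training of interpretable tree classifiers
#'
#' @description
#' `automl()` searches three tree-model families — a decision tree
#' (`rpart`), a random forest (`ranger`) and gradient-boosted trees
#' (`xgboost`) — with `trials_per_family` sequential Bayesian-optimization
#' trials each (default 25, hence 75 trained configurations). Every trial
#' is scored by the mean balanced accuracy over the folds of `partition`,
#' with inverse-class-frequency per-sample weights applied during fitting
#' and per-training-fold median imputation of missing feature values. The
#' best configuration overall is refitted on all labeled cells.
#'
#' The per-family optimizer spends the first 5 trials on uniform random
#' exploration of the (unit-scaled) hyperparameter space and the remaining
#' trials maximizing expected improvement under a Gaussian-process surrogate
#' (squared-exponential kernel on the scaled space). Search spaces:
#'
#' * decision tree — depth 2–20, minimum leaf size 1–20;
#' * random forest — 50–500 trees, depth 2–20, feature-subsample fraction
#'   0.1–1.0;
#' * gradient-boosted trees — 50–500 rounds, learning rate `1e-3`–0.3
#'   (log-uniform), 7–127 leaves.
#'
#' Ties between trials are broken by the earlier trial index.
#'
#' @param labeled data.frame of labeled cells: `cell_id`, `image_id`,
#'   `label` plus numeric feature columns (the output of [merge_labels()]).
#' @param partition a [make_partition()] result for the same rows.
#' @param trials_per_family Bayesian-optimization steps per family.
#' @param seed integer seed controlling the whole search.
#' @return List with `bundle` (a `model_bundle`: `family`, `params`, the
#'   fitted `model`, `cv_balanced_accuracy`, normalized `importances`,
#'   imputation medians, classes, and out-of-fold predictions of the winning
#'   configuration) and `history` (data.frame of all trials: `trial`,
#'   `family`, `params`, per-fold scores, `mean_score`, `degenerate_folds`).
NULL

automl_families <- function() {
  c("decision_tree", "random_forest", "gradient_boosted_trees")
}

family_space <- function(family) {
  switch(family,
    decision_tree = list(
      maxdepth = list(type = "int", lower = 2, upper = 20),
      minbucket = list(type = "int", lower = 1, upper = 20)),
    random_forest = list(
      num_trees = list(type = "int", lower = 50, upper = 500),
      max_depth = list(type = "int", lower = 2, upper = 20),
      mtry_frac = list(type = "num", lower = 0.1, upper = 1.0)),
    gradient_boosted_trees = list(
      nrounds = list(type = "int", lower = 50, upper = 500),
      learning_rate = list(type = "lognum", lower = 1e-3, upper = 0.3),
      num_leaves = list(type = "int", lower = 7, upper = 127)),
    stop(sprintf("unknown model family '%s'", family)))
}

unit_to_params <- function(space, u) {
  stopifnot(length(space) == length(u))
  out <- list()
  for (i in seq_along(space)) {
    s <- space[[i]]
    val <- switch(s$type,
      int = as.integer(round(s$lower + u[i] * (s$upper - s$lower))),
      num = s$lower + u[i] * (s$upper - s$lower),
      lognum = exp(log(s$lower) + u[i] * (log(s$upper) - log(s$lower))))
    out[[names(space)[i]]] <- val
  }
  out
}

params_string <- function(params) {
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(v) format(v, digits = 4), "")),
        collapse = ";")
}

# ---- model families -------------------------------------------------------

fit_family <- function(family, params, x, y, w, seed = 0L) {
  y <- factor(y)
  if (family == "decision_tree") {
    df <- data.frame(.y = y, x, check.names = TRUE)
    fit <- rpart::rpart(
      .y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = params$maxdepth,
                                     minbucket = params$minbucket,
                                     cp = 0, xval = 0))
    list(family = family, fit = fit, levels = levels(y),
         colmap = colnames(df)[-1L], orig = colnames(x))
  } else if (family == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      max.depth = params$max_depth,
      mtry = max(1L, round(params$mtry_frac * ncol(x))),
      case.weights = w, importance = "impurity",
      seed = seed, num.threads = 1L)
    list(family = family, fit = fit, levels = levels(y))
  } else if (family == "gradient_boosted_trees") {
    nclass <- nlevels(y)
    lab <- as.integer(y) - 1L
    dtrain <- xgboost::xgb.DMatrix(x, label = lab, weight = w)
    obj <- if (nclass == 2L) list(objective = "binary:logistic")
           else list(objective = "multi:softprob", num_class = nclass)
    fit <- xgboost::xgb.train(
      params = c(list(eta = params$learning_rate,
                      max_leaves = params$num_leaves,
                      grow_policy = "lossguide", max_depth = 0L,
                      tree_method = "hist", nthread = 1L,
                      seed = seed), obj),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
    list(family = family, fit = fit, levels = levels(y))
  } else stop(sprintf("unknown model family '%s'", family))
}

predict_family <- function(model, x) {
  if (model$family == "decision_tree") {
    df <- as.data.frame(x)
    colnames(df) <- model$colmap[match(colnames(x), model$orig)]
    as.character(predict(model$fit, newdata = df, type = "class"))
  } else if (model$family == "random_forest") {
    as.character(predict(model$fit, data = x, num.threads = 1L)$predictions)
  } else {
    pr <- predict(model$fit, xgboost::xgb.DMatrix(x))
    if (length(model$levels) == 2L) {
      model$levels[(pr > 0.5) + 1L]
    } else {
      pr <- matrix(pr, ncol = length(model$levels), byrow = TRUE)
      model$levels[max.col(pr, ties.method = "first")]
    }
  }
}

# ---- objective ------------------------------------------------------------

feature_matrix <- function(labeled) {
  drop <- c("cell_id", "image_id", "label", "predicted_label", "label_source")
  cols <- setdiff(names(labeled), drop)
  x <- as.matrix(labeled[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  colnames(x) <- cols
  x
}

impute_medians <- function(x) {
  meds <- apply(x, 2L, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  meds
}

apply_imputation <- function(x, meds) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- meds[j]
  }
  x
}

cv_score <- function(family, params, x, y, partition, seed = 0L,
                     keep_oof = FALSE) {
  k <- partition$k
  scores <- numeric(k)
  degenerate <- logical(k)
  oof <- rep(NA_character_, length(y))
  for (f in seq_len(k)) {
    tr <- partition$fold != f
    va <- !tr
    if (!any(va)) { scores[f] <- NA_real_; next }
    meds <- impute_medians(x[tr, , drop = FALSE])
    xtr <- apply_imputation(x[tr, , drop = FALSE], meds)
    xva <- apply_imputation(x[va, , drop = FALSE], meds)
    ytr <- y[tr]
    cw <- class_weights(ytr)
    w <- as.numeric(cw[as.character(ytr)])
    model <- fit_family(family, params, xtr, ytr, w, seed = seed + f)
    pred <- predict_family(model, xva)
    degenerate[f] <- !all(unique(y[va]) %in% unique(as.character(ytr)))
    scores[f] <- balanced_accuracy(y[va], pred)
    if (keep_oof) oof[va] <- pred
  }
  list(fold_scores = scores, mean_score = mean(scores, na.rm = TRUE),
       degenerate = degenerate, oof = oof)
}

# ---- Gaussian-process expected improvement --------------------------------

# posterior mean/sd of a zero-mean GP with squared-exponential kernel on the
# unit cube; y is standardized by the caller
gp_posterior <- function(U, y, Ucand, lengthscale = 0.25, noise = 1e-3) {
  d2 <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0)
  }
  K <- exp(-0.5 * d2(U, U) / lengthscale^2)
  diag(K) <- diag(K) + noise
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  Ks <- exp(-0.5 * d2(Ucand, U) / lengthscale^2)
  mu <- as.numeric(Ks %*% alpha)
  vtmp <- forwardsolve(t(L), t(Ks))
  var <- pmax(1 - colSums(vtmp^2), 1e-12)
  list(mu = mu, sd = sqrt(var))
}

expected_improvement <- function(mu, sd, best, xi = 0.01) {
  z <- (mu - best - xi) / sd
  (mu - best - xi) * pnorm(z) + sd * dnorm(z)
}

propose_next <- function(U, y, dim, n_cand = 256L) {
  Ucand <- matrix(runif(n_cand * dim), n_cand, dim)
  ys <- (y - mean(y)) / (if (sd(y) > 0) sd(y) else 1)
  post <- gp_posterior(U, ys, Ucand)
  ei <- expected_improvement(post$mu, post$sd, max(ys))
  Ucand[which.max(ei), ]
}

# ---- the search -----------------------------------------------------------

#' @rdname automl
#' @export
automl <- function(labeled, partition, trials_per_family = 25L, seed = 0L) {
  if (length(unique(labeled$label)) < 2L)
    stop("automl requires at least two classes in the labeled data")
  x <- feature_matrix(labeled)
  y <- as.character(labeled$label)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  history <- list()
  trial_no <- 0L
  n_init <- min(5L, trials_per_family)
  for (fi in seq_along(automl_families())) {
    family <- automl_families()[fi]
    space <- family_space(family)
    dim <- length(space)
    set.seed(seed + fi)
    U <- matrix(NA_real_, trials_per_family, dim)
    yscore <- numeric(trials_per_family)
    for (t in seq_len(trials_per_family)) {
      u <- if (t <= n_init) runif(dim)
           else propose_next(U[seq_len(t - 1L), , drop = FALSE],
                             yscore[seq_len(t - 1L)], dim)
      U[t, ] <- u
      params <- unit_to_params(space, u)
      res <- cv_score(family, params, x, y, partition,
                      seed = seed + 97L * fi + t)
      yscore[t] <- res$mean_score
      trial_no <- trial_no + 1L
      history[[trial_no]] <- data.frame(
        trial = trial_no, family = family,
        params = params_string(params),
        mean_score = res$mean_score,
        degenerate_folds = sum(res$degenerate),
        stringsAsFactors = FALSE)
      history[[trial_no]]$fold_scores <- I(list(res$fold_scores))
      attr(history[[trial_no]], "params_list") <- params
    }
  }
  params_by_trial <- lapply(history, attr, "params_list")
  history <- do.call(rbind, history)
  best_idx <- which.max(history$mean_score)   # earlier trial wins ties
  best_family <- history$family[best_idx]
  best_params <- params_by_trial[[best_idx]]

  # out-of-fold predictions of the winning configuration, then final refit
  best_cv <- cv_score(best_family, best_params, x, y, partition,
                      seed = seed + 97L * match(best_family, automl_families()) +
                        ((best_idx - 1L) %% trials_per_family) + 1L,
                      keep_oof = TRUE)
  meds <- impute_medians(x)
  xall <- apply_imputation(x, meds)
  cw <- class_weights(y)
  w <- as.numeric(cw[y])
  set.seed(seed)
  model <- fit_family(best_family, best_params, xall, y, w, seed = seed)
  imp <- normalized_importance(model, colnames(x))
  bundle <- structure(list(
    family = best_family, params = best_params, model = model,
    cv_balanced_accuracy = history$mean_score[best_idx],
    fold_scores = history$fold_scores[[best_idx]],
    importances = imp, impute_medians = meds,
    feature_names = colnames(x), classes = sort(unique(y)),
    oof_predictions = best_cv$oof, best_trial = best_idx,
    seed = seed), class = "model_bundle")
  list(bundle = bundle, history = history)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s (%s)\n  CV balanced accuracy: %.4f\n",
              x$family, params_string(x$params), x$cv_balanced_accuracy))
  top <- head(x$importances, 3L)
  cat("  top features:", paste(sprintf("%s (%.2f)", names(top), top),
                               collapse = ", "), "\n")
  invisible(x)
}

# ---- interpretation -------------------------------------------------------

#' Normalized feature importances of a fitted bundle
#'
#' Decision tree and random forest report impurity-decrease (information
#' gain) importances; gradient-boosted trees report split counts (how many
#' node splits use each feature across all trees). All scores are divided
#' by the maximum, so the most important feature scores exactly 1.
#'
#' @param bundle a `model_bundle` from [automl()].
#' @return Named numeric vector over all training features, sorted
#'   decreasing, maximum exactly 1 (all zeros if the model made no split).
#' @export
importance <- function(bundle) bundle$importances

normalized_importance <- function(model, feature_names) {
  raw <- setNames(rep(0, length(feature_names)), feature_names)
  if (model$family == "decision_tree") {
    vi <- model$fit$variable.importance
    if (!is.null(vi)) {
      nm <- feature_names[match(names(vi), make.names(feature_names))]
      ok <- !is.na(nm)
      raw[nm[ok]] <- vi[ok]
    }
  } else if (model$family == "random_forest") {
    vi <- ranger::importance(model$fit)
    raw[names(vi)] <- vi
  } else {
    dt <- tryCatch(xgboost::xgb.model.dt.tree(model = model$fit),
                   error = function(e) NULL)
    if (!is.null(dt)) {
      dt <- as.data.frame(dt)
      splits <- dt$Feature[dt$Feature != "Leaf"]
      if (length(splits)) {
        tab <- table(splits)
        nm <- intersect(names(tab), feature_names)
        raw[nm] <- as.numeric(tab[nm])
      }
    }
  }
  if (max(raw) > 0) raw <- raw / max(raw)
  sort(raw, decreasing = TRUE)
}

#' Predict labels for unlabeled cells
#'
#' Applies a fitted bundle to the full feature table: annotated rows keep
#' their expert label (`label_source = "annotated"`), all other rows get the
#' model's prediction (`label_source = "predicted"`).
#'
#' @param bundle a `model_bundle`.
#' @param features the full `feature_table`.
#' @param labels the label table (columns `cell_id`, `label`).
#' @return `features` with `predicted_label` and `label_source` columns.
#' @export
predict_unlabeled <- function(bundle, features, labels) {
  x <- feature_matrix(features)
  missing <- setdiff(bundle$feature_names, colnames(x))
  if (length(missing))
    stop(sprintf("feature table lacks training columns: %s",
                 paste(missing, collapse = ", ")))
  x <- x[, bundle$feature_names, drop = FALSE]
  x <- apply_imputation(x, bundle$impute_medians)
  pred <- predict_family(bundle$model, x)
  out <- features
  out$predicted_label <- pred
  out$label_source <- "predicted"
  m <- merge_labels(features, labels)
  idx <- match(m$labeled$cell_id, out$cell_id)
  out$predicted_label[idx] <- m$labeled$label
  out$label_source[idx] <- "annotated"
  out
}
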