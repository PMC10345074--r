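# Nested cross-validated outcome prediction with and without the nocturnal
# HR feature: regularized logistic regression (glmnet ridge path over the
# inverse-regularization grid) and gradient-boosted trees (xgboost), with
# unit-norm feature importances (absolute standardized coefficients /
# TreeSHAP attributions) and a two-sample t comparison over shuffles.

# Inverse regularization strengths (C) tuned for the logistic model; the
# 50-point grid spans 0.1..1000 roughly log-uniformly.
logistic_c_grid <- c(0.1, 0.12, 0.15, 0.18, 0.21, 0.26, 0.31, 0.37, 0.45,
                     0.54, 0.66, 0.79, 0.95, 1.15, 1.39, 1.68, 2.02, 2.44,
                     2.95, 3.56, 4.29, 5.18, 6.25, 7.54, 9.1, 10.9, 13.3,
                     16.0, 19.3, 23.3, 28.1, 33.9, 40.9, 49.4, 59.6, 72.0,
                     86.9, 105.0, 126.0, 153.0, 184.0, 222.0, 268.0, 324.0,
                     391.0, 471.0, 569.0, 687.0, 829.0, 1000.0)

#' Model and hyperparameter-grid specification
#'
#' @param family `"logistic"` (ridge logistic regression tuned over the
#'   inverse regularization strength) or `"boosting"` (gradient-boosted
#'   trees tuned over depth, learning rate, row subsampling and L2 leaf
#'   regularization).
#' @param c_grid Inverse regularization strengths for the logistic family.
#' @param depth_grid,eta_grid,subsample_grid,lambda_grid Boosting grids;
#'   defaults: depth {2,4,6}, 20 learning rates in [0.03, 0.3], subsampling
#'   {0.6, 0.8, 1}, L2 regularization {3, 10, 100, 500}.
#' @param nrounds Boosting rounds per fit (fixed, not tuned).
#' @return An object of class `circdip_model_spec`.
#' @export
model_spec <- function(family = c("logistic", "boosting"),
                       c_grid = logistic_c_grid,
                       depth_grid = c(2, 4, 6),
                       eta_grid = seq(0.03, 0.3, length.out = 20),
                       subsample_grid = seq(0.6, 1, length.out = 3),
                       lambda_grid = c(3, 10, 100, 500),
                       nrounds = 50) {
  family <- match.arg(family)
  stopifnot(length(c_grid) > 0, all(c_grid > 0), all(depth_grid >= 1),
            all(eta_grid > 0), all(subsample_grid > 0), all(lambda_grid >= 0))
  grid <- if (family == "boosting") {
    # complexity-ascending order: ties during tuning resolve to the
    # simplest candidate (smaller depth, stronger regularization)
    g <- expand.grid(max_depth = sort(depth_grid),
                     lambda = sort(lambda_grid, decreasing = TRUE),
                     eta = sort(eta_grid), subsample = sort(subsample_grid),
                     KEEP.OUT.ATTRS = FALSE)
    g[order(g$max_depth, -g$lambda, g$eta, g$subsample), , drop = FALSE]
  } else NULL
  structure(list(family = family, c_grid = sort(c_grid), grid = grid,
                 nrounds = nrounds), class = "circdip_model_spec")
}

#' Assemble the outcome-prediction feature table
#'
#' Builds the feature matrix used by the outcome models: age, sex (0 =
#' female, 1 = male), NIHSS, comorbidity flags, ordinal troponin category
#' (0/1/2), GFR and optionally the nocturnal HR feature; the label is the
#' dichotomized discharge outcome (1 = unfavorable). Patients with any
#' missing feature are dropped and counted.
#'
#' @param covariates Cohort covariate table (must contain `mrs_discharge`).
#' @param troponin Long troponin table (`patient_id`, `value`), categorized
#'   via [categorize_troponin()].
#' @param nocturnal_hr Optional data frame `patient_id`, `nocturnal_hr`;
#'   when supplied the feature is included.
#' @return A data frame with attribute `n_dropped` (patients excluded for
#'   missing features); column `label` is 0/1.
#' @export
feature_table <- function(covariates, troponin, nocturnal_hr = NULL) {
  trop_cat <- vapply(covariates$patient_id, function(pid) {
    v <- troponin$value[troponin$patient_id == pid]
    cat <- categorize_troponin(v[order(troponin$sample_idx[
      troponin$patient_id == pid])])
    if (is.na(cat)) NA_real_ else as.numeric(cat)
  }, 0)
  tab <- data.frame(
    patient_id = covariates$patient_id,
    age = covariates$age,
    sex = as.numeric(covariates$sex == "male"),
    nihss = as.numeric(covariates$nihss),
    hypertension = as.numeric(covariates$hypertension),
    diabetes = as.numeric(covariates$diabetes),
    prior_mi = as.numeric(covariates$prior_mi),
    cad = as.numeric(covariates$cad),
    pneumonia = as.numeric(covariates$pneumonia),
    troponin_category = unname(trop_cat),
    gfr = covariates$gfr,
    stringsAsFactors = FALSE)
  if (!is.null(nocturnal_hr))
    tab <- merge(tab, nocturnal_hr, by = "patient_id", all.x = TRUE,
                 sort = FALSE)
  tab$label <- as.numeric(dichotomize_outcome(covariates$mrs_discharge)[
    match(tab$patient_id, covariates$patient_id)] == "unfavorable")
  complete <- stats::complete.cases(tab)
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!complete)
  out
}

# Stratified k-fold assignment: within each class, a random permutation is
# dealt round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

unit_norm <- function(v) {
  nr <- sqrt(sum(v^2))
  if (nr == 0) {
    attr(v, "all_zero") <- TRUE
    return(v)
  }
  v / nr
}

fit_logistic <- function(X, y, C) {
  lam <- 1 / (nrow(X) * C)
  glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lam,
                 standardize = FALSE)
}

fit_boosting <- function(X, y, par, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = par$max_depth, eta = par$eta,
                                   subsample = par$subsample,
                                   lambda = par$lambda,
                                   nthread = 1, seed = seed,
                                   verbosity = 0),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Unit-norm global feature importance of a fitted model
#'
#' Logistic family: absolute values of the standardized coefficients.
#' Boosting family: mean absolute per-sample additive (TreeSHAP)
#' attribution per feature. Both are scaled to unit Euclidean norm for
#' comparability across models; an all-zero vector is returned unnormalized
#' with attribute `all_zero`.
#'
#' @param model A fitted `glmnet` (logistic) or `xgb.Booster` (boosting)
#'   model.
#' @param family `"logistic"` or `"boosting"`.
#' @param X Feature matrix (required for the boosting family: attributions
#'   are accumulated over these rows).
#' @return Named numeric vector with Euclidean norm 1 (or all zeros).
#' @export
feature_importance <- function(model, family = c("logistic", "boosting"),
                               X = NULL) {
  family <- match.arg(family)
  if (family == "logistic") {
    co <- as.numeric(stats::coef(model))[-1]
    names(co) <- rownames(stats::coef(model))[-1]
    unit_norm(abs(co))
  } else {
    stopifnot(!is.null(X))
    contrib <- stats::predict(model, xgboost::xgb.DMatrix(X),
                              predcontrib = TRUE)
    # the bias/intercept column is last (named "BIAS" or "(Intercept)"
    # depending on the xgboost version)
    if (!is.null(colnames(contrib))) {
      contrib <- contrib[, setdiff(colnames(contrib),
                                   c("BIAS", "(Intercept)")), drop = FALSE]
    } else {
      contrib <- contrib[, -ncol(contrib), drop = FALSE]
      colnames(contrib) <- colnames(X)
    }
    unit_norm(colMeans(abs(contrib)))
  }
}

#' Nested cross-validated evaluation of an outcome model
#'
#' Per shuffle: a stratified 4:1 outer 5-fold split; per outer fold,
#' features are standardized to zero mean / unit variance using
#' training-fold statistics only, hyperparameters are tuned by an inner
#' stratified 5-fold grid search maximizing inner AUC (ties resolved toward
#' the less complex candidate), the winning model is refit on the full
#' outer-training fold and scored by AUC on the held-out fold, and its
#' unit-norm feature importance recorded. Repeated over `n_shuffles` random
#' shuffles re-seeding both fold levels.
#'
#' @param table Feature table from [feature_table()] (needs `label` and at
#'   least 10 patients per class).
#' @param spec A [model_spec()].
#' @param n_shuffles Number of repeated shuffles (50 in the full analysis).
#' @param n_outer,n_inner Fold counts (default 5/5).
#' @param seed Master seed; identical seeds give identical results.
#' @return Object of class `circdip_cv`: `folds` (per shuffle x fold AUC
#'   and chosen hyperparameters), `shuffle_auc` (per-shuffle mean AUC),
#'   `importance` (matrix, one row per shuffle x fold), `mean_auc`,
#'   `sd_auc`, `feature_names`, `family`.
#' @export
nested_cv_evaluate <- function(table, spec = model_spec("logistic"),
                               n_shuffles = 50, n_outer = 5, n_inner = 5,
                               seed = 1) {
  stopifnot(inherits(spec, "circdip_model_spec"), "label" %in% names(table))
  y <- table$label
  stopifnot(min(table(y)) >= 10)
  feat_names <- setdiff(names(table), c("patient_id", "label"))
  X <- as.matrix(table[, feat_names, drop = FALSE])
  n <- nrow(X)
  shuffle_seeds <- derive_seeds(seed, n_shuffles)

  fold_rows <- list(); imp_rows <- list()
  for (s in seq_len(n_shuffles)) {
    set.seed(shuffle_seeds[s])
    outer <- stratified_folds(y, n_outer)
    for (f in seq_len(n_outer)) {
      tr <- outer != f; te <- !tr
      sc <- scale_train(X[tr, , drop = FALSE])
      Xtr <- scale_apply(X[tr, , drop = FALSE], sc)
      Xte <- scale_apply(X[te, , drop = FALSE], sc)
      ytr <- y[tr]; yte <- y[te]
      inner <- stratified_folds(ytr, n_inner)

      if (spec$family == "logistic") {
        lam_grid <- 1 / (sum(tr) * spec$c_grid)      # aligned with c_grid
        lam_sorted <- sort(lam_grid, decreasing = TRUE)
        auc_by_lam <- matrix(NA_real_, n_inner, length(lam_sorted))
        for (g in seq_len(n_inner)) {
          itr <- inner != g
          fit <- glmnet::glmnet(Xtr[itr, , drop = FALSE], ytr[itr],
                                family = "binomial", alpha = 0,
                                lambda = lam_sorted, standardize = FALSE)
          pr <- stats::predict(fit, Xtr[!itr, , drop = FALSE], s = lam_sorted)
          auc_by_lam[g, ] <- apply(pr, 2, auc_score, labels = ytr[!itr])
        }
        mean_auc_in <- colMeans(auc_by_lam, na.rm = TRUE)
        # ties -> largest lambda (strongest regularization)
        best <- which(mean_auc_in >= max(mean_auc_in) - 1e-12)[1]
        best_lam <- lam_sorted[best]
        fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                              lambda = best_lam, standardize = FALSE)
        pred <- as.numeric(stats::predict(fit, Xte))
        imp <- feature_importance(fit, "logistic")
        chosen <- sprintf("C=%.4g", 1 / (sum(tr) * best_lam))
      } else {
        grid <- spec$grid
        auc_in <- matrix(NA_real_, n_inner, nrow(grid))
        for (g in seq_len(n_inner)) {
          itr <- inner != g
          for (j in seq_len(nrow(grid))) {
            fit <- fit_boosting(Xtr[itr, , drop = FALSE], ytr[itr],
                                grid[j, ], spec$nrounds,
                                shuffle_seeds[s] %% 100000L + j)
            pr <- stats::predict(fit, xgboost::xgb.DMatrix(
              Xtr[!itr, , drop = FALSE]))
            auc_in[g, j] <- auc_score(pr, ytr[!itr])
          }
        }
        mean_auc_in <- colMeans(auc_in, na.rm = TRUE)
        best <- which(mean_auc_in >= max(mean_auc_in) - 1e-12)[1]
        fit <- fit_boosting(Xtr, ytr, grid[best, ], spec$nrounds,
                            shuffle_seeds[s] %% 100000L)
        pred <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
        imp <- feature_importance(fit, "boosting", X = Xtr)
        chosen <- paste(sprintf("%s=%g", names(grid), unlist(grid[best, ])),
                        collapse = ",")
      }
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(shuffle = s, fold = f, auc = auc_score(pred, yte),
                   chosen = chosen, stringsAsFactors = FALSE)
      imp_rows[[length(imp_rows) + 1L]] <- imp
    }
  }
  folds <- do.call(rbind, fold_rows)
  importance <- do.call(rbind, imp_rows)
  colnames(importance) <- feat_names
  shuffle_auc <- tapply(folds$auc, folds$shuffle, mean)
  structure(list(folds = folds, shuffle_auc = as.numeric(shuffle_auc),
                 importance = importance,
                 mean_auc = mean(shuffle_auc), sd_auc = stats::sd(shuffle_auc),
                 mean_importance = unit_norm(colMeans(importance)),
                 feature_names = feat_names, family = spec$family,
                 n_shuffles = n_shuffles),
            class = "circdip_cv")
}

#' @export
print.circdip_cv <- function(x, ...) {
  cat(sprintf("Nested CV (%s): AUC %.3f +/- %.3f over %d shuffles\n",
              x$family, x$mean_auc, x$sd_auc, x$n_shuffles))
  imp <- sort(x$mean_importance, decreasing = TRUE)
  cat("Top features:", paste(sprintf("%s (%.2f)", names(imp)[1:min(5, length(imp))],
                                     imp[1:min(5, length(imp))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare two nested-CV configurations by a two-sample t test
#'
#' Applies a standard two-sample location t test to the per-shuffle mean
#' AUCs of two configurations (e.g. with vs without the nocturnal HR
#' feature). Identical AUC vectors yield `t = 0, p = 1`.
#'
#' @param result_a,result_b `circdip_cv` objects with equal shuffle counts.
#' @return List: `t_statistic`, `p_value`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `delta` (mean_b - mean_a).
#' @export
compare_feature_sets <- function(result_a, result_b) {
  a <- result_a$shuffle_auc; b <- result_b$shuffle_auc
  if (length(a) != length(b))
    stop("shuffle counts differ between configurations", call. = FALSE)
  if (isTRUE(all.equal(a, b))) {
    tt <- list(statistic = 0, p.value = 1)
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(t_statistic = tt$statistic, p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b),
       delta = mean(b) - mean(a))
}
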