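# Subphenotype predictability from pre-index information: cross-sectional
# feature aggregation up to the index date (first MCI diagnosis), penalized
# linear models and gradient boosting with resampling and seeded
# random-search hyperparameter tuning inside cross-validation folds, and
# permutation feature importance.

#' Aggregate pre-index features per patient
#'
#' Builds one cross-sectional binary vector per patient from everything
#' recorded up to and including the index date (default: the first MCI
#' diagnosis date): OR-aggregation of the mapped diagnosis / drug / vital
#' category bits over all pre-index days, and demographics evaluated at the
#' index date. Nothing dated after the index contributes, so erasing
#' post-index rows leaves the features unchanged. Patients without an index
#' date are excluded and reported.
#'
#' @param cohort an `ehr_cohort`
#' @param index_dates named Date vector (patient id -> index date); computed
#'   from the first MCI code when NULL
#' @param maps code maps
#' @param mci_codes,ad_codes ICD lists used when `index_dates` is NULL
#' @return object of class `pre_index_features`: binary matrix `X`
#'   (patients x features), `index_dates`, `excluded`
#' @export
aggregate_pre_index <- function(cohort, index_dates = NULL,
                                maps = default_code_maps(),
                                mci_codes = MCI_ICD_CODES,
                                ad_codes = AD_ICD_CODES) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  fs <- feature_space(maps)
  if (is.null(index_dates)) {
    tl <- state_timelines(cohort, mci_codes, ad_codes)
    index_dates <- setNames(tl$first_mci_date, tl$patient_id)
  }
  excluded <- names(index_dates)[is.na(index_dates)]
  index_dates <- index_dates[!is.na(index_dates)]
  ids <- names(index_dates)
  X <- matrix(0L, length(ids), length(fs$names),
              dimnames = list(ids, fs$names))
  col_of <- setNames(seq_along(fs$names), fs$names)

  mark <- function(pid, colname) {
    keep <- !is.na(colname) & pid %in% ids
    X[cbind(match(pid[keep], ids), col_of[colname[keep]])] <<- 1L
  }
  dx <- cohort$diagnoses
  pre <- dx$patient_id %in% ids & dx$date <= index_dates[dx$patient_id]
  mark(dx$patient_id[pre],
       paste0("phecode_", apply_code_map(dx$code[pre], maps$diagnosis)))
  rx <- cohort$drugs
  pre <- rx$patient_id %in% ids & rx$date <= index_dates[rx$patient_id]
  mark(rx$patient_id[pre],
       paste0("atc_", apply_code_map(rx$code[pre], maps$drug)))
  vt <- cohort$vitals
  pre <- vt$patient_id %in% ids & vt$date <= index_dates[vt$patient_id]
  vtp <- vt[pre, , drop = FALSE]
  mark(vtp$patient_id, paste0("bmi_", bmi_category(vtp$bmi)))
  bp <- bp_category(vtp$systolic, vtp$diastolic)
  mark(vtp$patient_id[!is.na(bp)], paste0("bp_", bp[!is.na(bp)]))
  sm <- smoking_category(vtp$smoking)
  mark(vtp$patient_id[!is.na(sm)],
       paste0("smoking_", gsub("-", "_", sm[!is.na(sm)])))

  demo <- cohort$demographics
  birth <- setNames(demo$birth_date, demo$patient_id)[ids]
  age <- floor(as.numeric(index_dates - birth) / 365.25)
  X[cbind(seq_along(ids), col_of[age_bin(age)])] <- 1L
  sex <- setNames(demo$sex, demo$patient_id)[ids]
  X[cbind(seq_along(ids),
          col_of[ifelse(sex %in% c("F", "M"), paste0("sex_", sex),
                        "sex_other")])] <- 1L
  race <- setNames(demo$race_ethnicity, demo$patient_id)[ids]
  race[!(race %in% RACE_LEVELS)] <- "Unknown"
  X[cbind(seq_along(ids), col_of[paste0("race_",
                                        gsub(" ", "_", race))])] <- 1L

  structure(list(X = X, index_dates = index_dates, excluded = excluded,
                 feature_space = fs),
            class = "pre_index_features")
}

resample_indices <- function(idx, y, method, K = NULL) {
  if (method == "none") return(idx)
  counts <- table(y[idx])
  split_idx <- split(idx, y[idx])
  if (method == "oversample") {
    target <- max(counts)
    unlist(lapply(split_idx, function(v) {
      c(v, sample(v, target - length(v), replace = TRUE))
    }), use.names = FALSE)
  } else {
    target <- min(counts)
    unlist(lapply(split_idx, function(v) sample(v, target)),
           use.names = FALSE)
  }
}

stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  out
}

# one-vs-rest glmnet probability matrix at one lambda
predict_ovr <- function(fits, X, lambda, classes) {
  raw <- vapply(classes, function(cl) {
    as.numeric(predict(fits[[cl]], X, s = lambda, type = "response"))
  }, numeric(nrow(X)))
  raw <- rbind(raw)
  colnames(raw) <- classes
  raw / pmax(rowSums(raw), 1e-12)
}

fit_linear_model <- function(X, y, alpha, lambda_grid, fold_id, resampling,
                             classes) {
  # per-fold OVR glmnet paths over a shared lambda grid; macro AUROC by
  # lambda, averaged over folds, selects lambda
  folds <- sort(unique(fold_id))
  auc_by_lambda <- matrix(NA_real_, length(folds), length(lambda_grid))
  for (f in folds) {
    tr <- which(fold_id != f)
    tr <- resample_indices(tr, y, resampling)
    te <- which(fold_id == f)
    fits <- lapply(classes, function(cl) {
      glmnet::glmnet(X[tr, , drop = FALSE], as.integer(y[tr] == cl),
                     family = "binomial", alpha = alpha,
                     lambda = lambda_grid)
    })
    names(fits) <- classes
    for (li in seq_along(lambda_grid)) {
      prob <- predict_ovr(fits, X[te, , drop = FALSE], lambda_grid[li],
                          classes)
      auc_by_lambda[f, li] <- macro_auroc(prob, y[te])$macro
    }
  }
  mean_auc <- colMeans(auc_by_lambda, na.rm = TRUE)
  best_li <- which.max(mean_auc)
  tr <- resample_indices(seq_along(y), y, resampling)
  fits <- lapply(classes, function(cl) {
    glmnet::glmnet(X[tr, , drop = FALSE], as.integer(y[tr] == cl),
                   family = "binomial", alpha = alpha, lambda = lambda_grid)
  })
  names(fits) <- classes
  list(kind = "ovr_glmnet", fits = fits, lambda = lambda_grid[best_li],
       classes = classes, cv_auroc = mean_auc[best_li],
       best_params = list(alpha = alpha, lambda = lambda_grid[best_li]))
}

xgb_prob <- function(bst, X, n_class) {
  p <- predict(bst, xgboost::xgb.DMatrix(X))
  if (!is.matrix(p)) p <- matrix(p, ncol = n_class, byrow = TRUE)
  p
}

fit_xgb_model <- function(X, y, n_trials, fold_id, resampling, classes,
                          seed) {
  folds <- sort(unique(fold_id))
  yi <- match(y, classes) - 1L
  train_one <- function(rows, par) {
    xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes), eta = par$eta,
                    max_depth = par$max_depth, subsample = par$subsample,
                    colsample_bytree = par$colsample_bytree,
                    min_child_weight = par$min_child_weight, nthread = 1),
      data = xgboost::xgb.DMatrix(X[rows, , drop = FALSE],
                                  label = yi[rows]),
      nrounds = par$nrounds, verbose = 0)
  }
  draw <- function() list(
    eta = exp(stats::runif(1, log(0.03), log(0.3))),
    max_depth = sample(2:6, 1L),
    nrounds = sample(seq(50L, 250L, 25L), 1L),
    subsample = stats::runif(1, 0.6, 1),
    colsample_bytree = stats::runif(1, 0.6, 1),
    min_child_weight = sample(1:5, 1L))
  best <- list(auc = -Inf)
  for (trial in seq_len(n_trials)) {
    par <- draw()
    aucs <- vapply(folds, function(f) {
      tr <- resample_indices(which(fold_id != f), y, resampling)
      te <- which(fold_id == f)
      bst <- train_one(tr, par)
      prob <- xgb_prob(bst, X[te, , drop = FALSE], length(classes))
      colnames(prob) <- classes
      macro_auroc(prob, y[te])$macro
    }, numeric(1))
    if (mean(aucs, na.rm = TRUE) > best$auc) {
      best <- list(auc = mean(aucs, na.rm = TRUE), params = par)
    }
  }
  bst <- train_one(resample_indices(seq_along(y), y, resampling),
                   best$params)
  list(kind = "xgboost", fits = bst, classes = classes,
       cv_auroc = best$auc, best_params = best$params)
}

#' Class-probability predictions from a fitted subphenotype predictor
#' @param model one element of [fit_predictors()]'s `models`
#' @param X feature matrix
#' @return probability matrix (rows sum to 1), columns named by class
#' @export
predict_subphenotype <- function(model, X) {
  X <- as.matrix(X)
  if (model$kind == "ovr_glmnet") {
    predict_ovr(model$fits, X, model$lambda, model$classes)
  } else {
    prob <- xgb_prob(model$fits, X, length(model$classes))
    colnames(prob) <- model$classes
    prob
  }
}

#' Fit subphenotype prediction models with tuned hyperparameters
#'
#' Trains multiclass predictors of cluster membership from pre-index
#' features: one-vs-rest penalized logistic regressions (plain logistic,
#' lasso, ridge, elastic net via glmnet) and gradient boosting (xgboost).
#' Hyperparameters are tuned by seeded random search with k-fold
#' cross-validation *on the training split only*, and any resampling
#' (random over-/under-sampling of classes) is applied inside training folds
#' only, never to validation or test data. Discrimination is reported as
#' macro one-vs-rest AUROC with per-class sensitivity/specificity/precision
#' on the held-out test split.
#'
#' @param features a `pre_index_features` or a plain binary matrix with
#'   patient rownames
#' @param labels named cluster labels (names = patient ids)
#' @param models subset of c("logistic", "lasso", "ridge", "elastic_net",
#'   "gradient_boosting")
#' @param resampling "none", "oversample" or "undersample"
#' @param n_trials random-search budget for gradient boosting
#' @param folds CV folds for tuning
#' @param test_frac held-out fraction
#' @param seed RNG seed
#' @return object of class `subphenotype_predictors` with per-model fits,
#'   CV and test metrics
#' @export
fit_predictors <- function(features, labels,
                           models = c("logistic", "lasso", "ridge",
                                      "elastic_net", "gradient_boosting"),
                           resampling = c("none", "oversample",
                                          "undersample"),
                           n_trials = 50L, folds = 5L, test_frac = 0.3,
                           seed = 1L) {
  resampling <- match.arg(resampling)
  X <- if (inherits(features, "pre_index_features")) features$X
       else as.matrix(features)
  ids <- intersect(rownames(X), names(labels))
  X <- X[ids, , drop = FALSE]
  y <- as.character(labels[ids])
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  if (min(table(y)) < 5L) warning("a class has fewer than 5 members; stratification degraded")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  test_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(test_frac * length(idx))))
  }), use.names = FALSE)
  train_idx <- setdiff(seq_along(y), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]
  fold_id <- stratified_folds(ytr, folds)
  lambda_grid <- exp(seq(log(1), log(1e-4), length.out = 25L))

  alphas <- c(logistic = 0, lasso = 1, ridge = 0, elastic_net = 0.5)
  out <- list()
  for (m in models) {
    set.seed(derive_seed(seed, match(m, c("logistic", "lasso", "ridge",
                                          "elastic_net",
                                          "gradient_boosting"))))
    fit <- if (m == "gradient_boosting") {
      fit_xgb_model(Xtr, ytr, n_trials, fold_id, resampling, classes, seed)
    } else if (m == "logistic") {
      # near-unpenalized logistic baseline (tiny ridge for stability)
      f <- fit_linear_model(Xtr, ytr, alpha = 0, lambda_grid = c(1e-4),
                            fold_id = fold_id, resampling = resampling,
                            classes = classes)
      f$best_params$note <- "fixed minimal penalty"
      f
    } else {
      fit_linear_model(Xtr, ytr, alpha = alphas[[m]],
                       lambda_grid = lambda_grid, fold_id = fold_id,
                       resampling = resampling, classes = classes)
    }
    prob <- predict_subphenotype(fit, Xte)
    fit$test_metrics <- classification_metrics(prob, yte)
    out[[m]] <- fit
  }
  structure(list(models = out, classes = classes, resampling = resampling,
                 test_ids = ids[test_idx], train_ids = ids[train_idx]),
            class = "subphenotype_predictors")
}

#' @export
print.subphenotype_predictors <- function(x, ...) {
  for (m in names(x$models)) {
    cat(sprintf("%-18s cv macro AUROC %.3f | test macro AUROC %.3f\n", m,
                x$models[[m]]$cv_auroc,
                x$models[[m]]$test_metrics$macro[["auroc"]]))
  }
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in macro one-vs-rest AUROC when
#' a feature's column is shuffled, averaged over `n_repeats` shuffles
#' (per-class AUROC drops are reported as well). This is the contract-bearing
#' importance method; SHAP-style attributions can be layered on externally.
#'
#' @param model one element of [fit_predictors()]'s `models`
#' @param X evaluation feature matrix (e.g. the held-out test rows)
#' @param y true labels for `X`'s rows
#' @param n_repeats shuffles per feature
#' @param seed RNG seed
#' @param features optional subset of feature names to score
#' @return data frame ranked by decreasing importance
#' @export
permutation_importance <- function(model, X, y, n_repeats = 20L, seed = 1L,
                                   features = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  features <- features %||% colnames(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  base <- macro_auroc(predict_subphenotype(model, X), y)
  drops <- vapply(features, function(f) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, f] <- sample(Xp[, f])
      base$macro - macro_auroc(predict_subphenotype(model, Xp), y)$macro
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = features, importance = drops)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_macro_auroc") <- base$macro
  out
}
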