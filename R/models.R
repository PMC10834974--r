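#' Default specifications for the five classifier families
#'
#' Modest grids (every grid has at most 12 combinations) for ridge-penalized
#' logistic regression, linear-kernel SVM, CART decision tree, random forest
#' and gradient boosting. The \code{fast} variant uses single-point grids
#' and lighter ensembles, intended for replicated simulation studies where
#' the protocol, not the tuning, is under test.
#'
#' @param seed integer seed stored in each spec.
#' @param cv_folds inner tuning cross-validation folds.
#' @param fast use single-point grids and smaller ensembles.
#' @return named list of five [ModelSpec-class] objects.
#' @examples
#' names(defaultModelSpecs())
#' @export
defaultModelSpecs <- function(seed = 1L, cv_folds = 3L, fast = FALSE) {
  if (fast) {
    grids <- list(
      logistic_regression = list(lambda = 0.01),
      svm_linear = list(cost = 1),
      decision_tree = list(cp = 0.01, maxdepth = 4),
      random_forest = list(mtry_frac = 0.2, ntree = 150),
      gradient_boosting = list(max_depth = 2, nrounds = 60, eta = 0.1))
  } else {
    grids <- list(
      logistic_regression = list(lambda = c(0.001, 0.01, 0.1, 1)),
      svm_linear = list(cost = c(0.01, 0.1, 1, 10)),
      decision_tree = list(cp = c(0.001, 0.01, 0.05), maxdepth = c(3, 5)),
      random_forest = list(mtry_frac = c(0.1, 0.33), ntree = 300),
      gradient_boosting = list(max_depth = c(2, 3), nrounds = c(80, 150),
                               eta = 0.1))
  }
  out <- lapply(names(grids), function(a)
    ModelSpec(a, grids[[a]], cv_folds = cv_folds, seed = seed))
  names(out) <- names(grids)
  out
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of \code{k} folds so that class proportions
#' per fold are within one subject of the global proportions; deterministic
#' given the seed.
#'
#' @param labels class labels (factor or vector).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in \code{1:k}.
#' @examples
#' table(makeFolds(rep(c("a", "b"), c(36, 76)), 4, seed = 1))
#' @export
makeFolds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  if (k < 2) stopf("need at least 2 folds")
  counts <- table(labels)
  if (any(counts < k))
    stopf("class '%s' has %d member(s), fewer than %d folds",
          names(counts)[which.min(counts)], min(counts), k)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ---- internal fitting layer ------------------------------------------------

scaleTrain <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

scaleApply <- function(x, ctr, scl) sweep(sweep(x, 2, ctr), 2, scl, "/")

needsScaling <- function(algorithm)
  algorithm %in% c("logistic_regression", "svm_linear")

fitOne <- function(algorithm, params, x, y, seed) {
  pos <- levels(y)[2L]
  switch(algorithm,
    logistic_regression =
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = params$lambda, standardize = FALSE),
    svm_linear =
      withSeed(seed,
        e1071::svm(x, y, kernel = "linear", cost = params$cost,
                   probability = TRUE, scale = FALSE)),
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  maxdepth = params$maxdepth,
                                                  xval = 0))
    },
    random_forest =
      withSeed(seed,
        randomForest::randomForest(
          x, y, ntree = params$ntree,
          mtry = max(1L, floor(params$mtry_frac * ncol(x))))),
    gradient_boosting =
      withSeed(seed, {
        dm <- xgboost::xgb.DMatrix(x, label = as.numeric(y == pos),
                                   nthread = 1)
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = params$max_depth,
                                         eta = params$eta, nthread = 1),
                           data = dm, nrounds = params$nrounds,
                           verbose = 0)
      }),
    stopf("unknown algorithm '%s'", algorithm))
}

scoreOne <- function(algorithm, fit, x, positive) {
  switch(algorithm,
    logistic_regression =
      as.numeric(stats::predict(fit, x, type = "response")),
    svm_linear = {
      pr <- attr(stats::predict(fit, x, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, positive])
    },
    decision_tree =
      as.numeric(stats::predict(fit, data.frame(x, check.names = FALSE),
                                type = "prob")[, positive]),
    random_forest =
      as.numeric(stats::predict(fit, x, type = "prob")[, positive]),
    gradient_boosting =
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))))
}

# ---- tuning ----------------------------------------------------------------

#' Grid-search tuning and final fit on a training set
#'
#' Exhaustive search over the spec's hyper-parameter grid, scored by
#' out-of-fold AUC under stratified inner cross-validation on the training
#' data; the best combination (ties broken toward the first grid row) is
#' refitted on the full training set. For linear models the feature matrix
#' is z-scored with statistics estimated on the training data only; tree
#' ensembles take raw features. Deterministic given the spec seed.
#'
#' @param spec a [ModelSpec-class].
#' @param x numeric feature matrix (subjects x features).
#' @param y two-level factor; the second level is the positive (case)
#'   class.
#' @return an object of class \code{TunedClassifier}: a list with elements
#'   \code{algorithm}, \code{best} (named list of hyper-parameters),
#'   \code{fit}, \code{center}/\code{scale} (or NULL), \code{features},
#'   \code{levels}, \code{cv_auc} (per grid row, NA for single-point
#'   grids).
#' @examples
#' x <- matrix(rnorm(60 * 4), 60)
#' colnames(x) <- paste0("f", 1:4)
#' y <- factor(rep(c("ctl", "case"), 30), levels = c("ctl", "case"))
#' fit <- tuneAndFit(defaultModelSpecs(fast = TRUE)$decision_tree, x, y)
#' fit$best
#' @export
tuneAndFit <- function(spec, x, y) {
  stopifnot(is(spec, "ModelSpec"), is.matrix(x))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stopf("training labels are degenerate")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  pos <- levels(y)[2L]
  sc <- NULL
  xs <- x
  if (needsScaling(spec@algorithm)) {
    sc <- scaleTrain(x)
    xs <- sc$x
  }
  grid <- spec@grid
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    fold <- makeFolds(y, spec@cv_folds, seed = spec@seed)
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      aucs <- vapply(seq_len(spec@cv_folds), function(f) {
        tr <- fold != f
        xtr <- x[tr, , drop = FALSE]
        xte <- x[!tr, , drop = FALSE]
        if (needsScaling(spec@algorithm)) {
          s <- scaleTrain(xtr)
          xtr <- s$x
          xte <- scaleApply(xte, s$center, s$scale)
        }
        fit <- fitOne(spec@algorithm, params, xtr, y[tr],
                      childSeed(spec@seed, g * 100 + f))
        aucFromScores(scoreOne(spec@algorithm, fit, xte, pos),
                      y[!tr], pos)
      }, numeric(1))
      cv_auc[g] <- mean(aucs)
    }
    best_i <- which(cv_auc >= max(cv_auc) - 1e-12)[1]
  } else best_i <- 1L
  best <- as.list(grid[best_i, , drop = FALSE])
  attributes(best) <- list(names = names(best))
  fit <- fitOne(spec@algorithm, best, xs, y, childSeed(spec@seed, 0))
  structure(list(algorithm = spec@algorithm, best = best, fit = fit,
                 center = sc$center, scale = sc$scale,
                 features = colnames(x), levels = levels(y),
                 cv_auc = cv_auc),
            class = "TunedClassifier")
}

#' @export
print.TunedClassifier <- function(x, ...) {
  cat("TunedClassifier:", x$algorithm, "\n  best:",
      paste(names(x$best), unlist(x$best), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict case-class probabilities from a tuned classifier
#'
#' @param model a \code{TunedClassifier} from [tuneAndFit()].
#' @param x feature matrix with the training columns.
#' @return numeric vector of probabilities of the positive (second-level)
#'   class.
#' @export
predictScores <- function(model, x) {
  stopifnot(inherits(model, "TunedClassifier"))
  x <- x[, model$features, drop = FALSE]
  if (!is.null(model$center))
    x <- scaleApply(x, model$center, model$scale)
  scoreOne(model$algorithm, model$fit, x, model$levels[2L])
}

#' Ranked feature set of a fitted classifier
#'
#' Linear models (logistic regression, linear SVM) rank features by the
#' absolute standardized coefficient; tree-based models by impurity
#' importance (Gini decrease, rpart variable importance, xgboost gain).
#' Features absent from a tree model's importance table score zero.
#'
#' @param model a \code{TunedClassifier}.
#' @param top_k number of top features to return (default 15);
#'   \code{top_k = 0} gives an empty set.
#' @return data.frame with columns \code{feature}, \code{importance},
#'   sorted decreasing.
#' @export
modelFeatureSet <- function(model, top_k = 15) {
  stopifnot(inherits(model, "TunedClassifier"))
  imp <- switch(model$algorithm,
    logistic_regression = {
      b <- as.matrix(stats::coef(model$fit))[, 1]
      abs(b[model$features])
    },
    svm_linear = {
      w <- t(model$fit$coefs) %*% model$fit$SV
      stats::setNames(abs(as.numeric(w)), colnames(model$fit$SV))[
        model$features]
    },
    decision_tree = {
      vi <- model$fit$variable.importance
      out <- stats::setNames(rep(0, length(model$features)), model$features)
      if (!is.null(vi)) out[names(vi)] <- vi
      out
    },
    random_forest = {
      im <- randomForest::importance(model$fit)[, 1]
      stats::setNames(rep(0, length(model$features)), model$features) +
        im[model$features]
    },
    gradient_boosting = {
      it <- xgboost::xgb.importance(model = model$fit)
      out <- stats::setNames(rep(0, length(model$features)), model$features)
      out[it$Feature] <- it$Gain
      out
    })
  imp[is.na(imp)] <- 0
  ord <- order(imp, decreasing = TRUE)
  df <- data.frame(feature = model$features[ord],
                   importance = unname(imp[ord]),
                   stringsAsFactors = FALSE)
  utils::head(df, max(0, top_k))
}

#' Build a ModelEvaluation from pooled scores
#'
#' Confusion matrix at the decision threshold, closed-form metrics, ROC
#' points and rank AUC. A single-class label vector yields an NA AUC with
#' a warning.
#'
#' @param scores pooled out-of-fold probabilities of the positive class.
#' @param labels true labels aligned with \code{scores}.
#' @param algorithm classifier family label stored in the result.
#' @param positive positive class label; default the last factor level.
#' @param threshold decision threshold on the probability scale (default
#'   0.5); set to \code{"youden"} for the Youden-optimal cutoff.
#' @param best_hyperparameters named list recorded in the result.
#' @param feature_importance optional data.frame recorded in the result.
#' @return a [ModelEvaluation-class].
#' @export
evaluateModel <- function(scores, labels, algorithm = "classifier",
                          positive = NULL, threshold = 0.5,
                          best_hyperparameters = list(),
                          feature_importance = data.frame()) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  single_class <- length(unique(labels)) < 2
  if (identical(threshold, "youden")) {
    ys <- youdenScan(scores[labels != positive], scores[labels == positive])
    threshold <- ys$cutoff
  }
  cm <- cmFromScores(scores, labels, positive, threshold)
  auc <- if (single_class) {
    warnf("single-class labels; AUC undefined")
    NA_real_
  } else aucFromScores(scores, labels, positive)
  roc <- if (single_class) data.frame(fpr = c(0, 1), tpr = c(0, 1))
         else rocCurvePoints(scores, labels, positive)
  new("ModelEvaluation", algorithm = algorithm,
      best_hyperparameters = best_hyperparameters, cm = cm,
      metrics = c(cmMetrics(cm), auc_roc = auc), roc_points = roc,
      feature_importance = feature_importance,
      scores = as.numeric(scores), labels = labels)
}

#' Cross-model consensus diagnostic panel
#'
#' Keeps features that (i) appear in at least \code{min_models} of the
#' per-model top feature sets and (ii) pass the univariate significance
#' filter; ordered by the number of supporting models, then univariate
#' AUC.
#'
#' @param feature_sets list (one per model) of character vectors or of
#'   data.frames with a \code{feature} column, as returned by
#'   [modelFeatureSet()].
#' @param screen univariate screen results from [screenMetabolites()].
#' @param min_models minimum number of supporting models (default 3, a
#'   majority of five).
#' @return data.frame with columns \code{feature}, \code{n_models},
#'   \code{auc}.
#' @export
consensusPanel <- function(feature_sets, screen, min_models = 3) {
  if (length(feature_sets) < 2)
    stopf("need feature sets from at least 2 models")
  sets <- lapply(feature_sets, function(s)
    if (is.data.frame(s)) s$feature else as.character(s))
  counts <- table(unlist(lapply(sets, unique)))
  passers <- screen$metabolite[screen$passes_filter]
  keep <- names(counts)[counts >= min_models & names(counts) %in% passers]
  auc <- screen$auc[match(keep, screen$metabolite)]
  out <- data.frame(feature = keep, n_models = as.integer(counts[keep]),
                    auc = auc, stringsAsFactors = FALSE)
  out <- out[order(-out$n_models, -out$auc), ]
  rownames(out) <- NULL
  out
}

#' Train and evaluate all classifier families end to end
#'
#' The evaluation protocol: one stratified \code{folds}-fold split of the
#' cohort is shared by all models; within each training fold the model is
#' grid-search tuned by inner cross-validation and refitted, and its
#' predictions on the held-out fold are pooled, so each subject is scored
#' exactly once by a model that never saw it. The pooled scores give one
#' full-cohort confusion matrix and AUC per model. Feature sets for the
#' consensus panel come from a final tuned refit on the full cohort.
#'
#' @param table a [ConcentrationTable-class] (typically age-adjusted, with
#'   ratios appended).
#' @param specs list of [ModelSpec-class]; default [defaultModelSpecs()].
#' @param screen optional univariate results from [screenMetabolites()];
#'   computed from \code{table} when absent (used by the consensus
#'   filter).
#' @param folds outer folds (default 5).
#' @param seed integer seed controlling fold assignment and stochastic
#'   fits.
#' @param features optional character vector restricting the feature set.
#' @param positive positive class label; default the case (second) level.
#' @param top_k per-model feature-set size for consensus voting.
#' @param min_models consensus majority threshold.
#' @param threshold decision threshold passed to [evaluateModel()].
#' @return an object of class \code{DiagnosticReport}: list with
#'   \code{evaluations} (named list of [ModelEvaluation-class]),
#'   \code{metrics_table} (one row per model), \code{consensus},
#'   \code{screen}, \code{folds}, \code{seed}.
#' @examples
#' \donttest{
#' tab <- generateCohort(CohortConfig(seed = 3), buildDefaultPanel())
#' adj <- applyCorrection(tab, fitAgeCorrection(tab))
#' rep <- runAllModels(deriveRatios(adj), defaultModelSpecs(fast = TRUE),
#'                     folds = 3, seed = 3)
#' rep
#' }
#' @export
runAllModels <- function(table, specs = defaultModelSpecs(), screen = NULL,
                         folds = 5, seed = 1L, features = NULL,
                         positive = NULL, top_k = 15, min_models = 3,
                         threshold = 0.5) {
  stopifnot(is(table, "ConcentrationTable"))
  if (is.null(screen)) screen <- screenMetabolites(table)
  x <- t(concentrations(table))
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  ok <- stats::complete.cases(x)
  if (any(!ok)) {
    warnf("%d subject(s) with missing feature values excluded", sum(!ok))
    x <- x[ok, , drop = FALSE]
  }
  y <- droplevels(subjectGroups(table)[ok])
  if (is.null(positive)) positive <- levels(y)[2L]
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))

  fold <- makeFolds(y, folds, seed = seed)
  evaluations <- list()
  feature_sets <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    oof <- rep(NA_real_, length(y))
    best_by_fold <- vector("list", folds)
    for (f in seq_len(folds)) {
      spec_f <- spec
      spec_f@seed <- childSeed(seed, i * 1000 + f)
      model <- tuneAndFit(spec_f, x[fold != f, , drop = FALSE],
                          y[fold != f])
      oof[fold == f] <- predictScores(model, x[fold == f, , drop = FALSE])
      best_by_fold[[f]] <- model$best
    }
    spec_full <- spec
    spec_full@seed <- childSeed(seed, i * 1000)
    full_model <- tuneAndFit(spec_full, x, y)
    fi <- modelFeatureSet(full_model, top_k = top_k)
    ev <- evaluateModel(oof, y, algorithm = spec@algorithm,
                        positive = positive, threshold = threshold,
                        best_hyperparameters = full_model$best,
                        feature_importance = fi)
    evaluations[[spec@algorithm]] <- ev
    feature_sets[[spec@algorithm]] <- fi
  }
  consensus <- consensusPanel(feature_sets, screen, min_models = min_models)
  mt <- do.call(rbind, lapply(evaluations, function(ev) {
    m <- ev@metrics
    data.frame(algorithm = ev@algorithm, tp = ev@cm@tp, fp = ev@cm@fp,
               fn = ev@cm@fn, tn = ev@cm@tn,
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               accuracy = m[["accuracy"]], f1 = m[["f1"]],
               recall = m[["recall"]], auc_roc = m[["auc_roc"]],
               stringsAsFactors = FALSE)
  }))
  rownames(mt) <- NULL
  structure(list(evaluations = evaluations, metrics_table = mt,
                 consensus = consensus, screen = screen, folds = folds,
                 seed = seed, positive = positive),
            class = "DiagnosticReport")
}

#' @export
print.DiagnosticReport <- function(x, ...) {
  cat("DiagnosticReport:", length(x$evaluations), "models,", x$folds,
      "outer folds, seed", x$seed, "\n\n")
  mt <- x$metrics_table
  mt[, 6:11] <- round(mt[, 6:11], 2)
  print(mt, row.names = FALSE)
  cat("\nConsensus panel (", nrow(x$consensus), " features):\n", sep = "")
  print(x$consensus, row.names = FALSE)
  invisible(x)
}
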