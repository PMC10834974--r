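# Small separable dataset used across model tests: two features carry all
# the signal.
separableData <- function(n = 60, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    y <- factor(rep(c("control", "case"), each = n / 2),
                levels = c("control", "case"))
    x <- cbind(f1 = rnorm(n, ifelse(y == "case", 4, 0)),
               f2 = rnorm(n, ifelse(y == "case", -4, 0)),
               f3 = rnorm(n), f4 = rnorm(n))
    list(x = x, y = y)
  })
}

test_that("stratified folds keep class proportions within one subject", {
  labels <- rep(c("control", "case"), c(36, 76))
  fold <- makeFolds(labels, 4, seed = 1)
  for (f in 1:4) {
    expect_equal(sum(fold == f & labels == "control"), 9L)
    expect_equal(sum(fold == f & labels == "case"), 19L)
  }
  expect_identical(fold, makeFolds(labels, 4, seed = 1))
  expect_false(identical(fold, makeFolds(labels, 4, seed = 2)))
  expect_error(makeFolds(rep(c("a", "b"), c(2, 40)), 5, seed = 1),
               "fewer than")
})

test_that("every classifier family interpolates a separable training set", {
  d <- separableData()
  for (spec in defaultModelSpecs(seed = 5, fast = TRUE)) {
    model <- tuneAndFit(spec, d$x, d$y)
    scores <- predictScores(model, d$x)
    acc <- mean((scores >= 0.5) == (d$y == "case"))
    expect_gte(acc, 0.97)  # training accuracy ~1 on separable data
  }
})

test_that("grid search is deterministic and honours single-point grids", {
  d <- separableData(seed = 2)
  spec1 <- ModelSpec("decision_tree", list(cp = 0.02, maxdepth = 4),
                     seed = 3)
  m1 <- tuneAndFit(spec1, d$x, d$y)
  expect_equal(m1$best, list(cp = 0.02, maxdepth = 4))

  spec <- ModelSpec("random_forest",
                    list(mtry_frac = c(0.25, 0.5), ntree = 100), seed = 3)
  m2 <- tuneAndFit(spec, d$x, d$y)
  m3 <- tuneAndFit(spec, d$x, d$y)
  expect_identical(m2$best, m3$best)
  expect_identical(predictScores(m2, d$x), predictScores(m3, d$x))

  expect_error(tuneAndFit(spec, d$x, factor(rep("case", 60))),
               "degenerate")
})

test_that("tuning never sees the held-out fold", {
  d <- separableData(seed = 4)
  spec <- ModelSpec("logistic_regression", list(lambda = c(0.01, 1)),
                    seed = 6)
  train <- 1:40
  m_before <- suppressWarnings(tuneAndFit(spec, d$x[train, ], d$y[train]))
  # shuffling labels outside the training fold cannot change tuning
  y_shuffled <- d$y
  y_shuffled[41:60] <- sample(y_shuffled[41:60])
  m_after <- suppressWarnings(tuneAndFit(spec, d$x[train, ],
                                         y_shuffled[train]))
  expect_identical(m_before$best, m_after$best)
})

test_that("evaluation reproduces the degenerate classifier limits", {
  labels <- factor(rep(c("control", "case"), each = 10),
                   levels = c("control", "case"))
  perfect <- evaluateModel(as.numeric(labels == "case"), labels,
                           positive = "case")
  m <- evaluationMetrics(perfect)
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy", "f1",
                          "auc_roc")]), rep(1, 5))
  cm <- confusion(perfect)
  expect_equal(c(cm@tp, cm@fp, cm@fn, cm@tn), c(10L, 0L, 0L, 10L))

  constant <- evaluateModel(rep(0, 20), labels, positive = "case")
  mc <- evaluationMetrics(constant)
  expect_equal(unname(mc["sensitivity"]), 0)
  expect_equal(unname(mc["specificity"]), 1)

  set.seed(12)
  noisy <- as.numeric(labels == "case") + rnorm(20, sd = 0.4)
  ev <- evaluateModel(noisy, labels, positive = "case")
  expect_equal(unname(evaluationMetrics(ev)["auc_roc"]),
               bruteForceAUC(noisy[labels == "control"],
                             noisy[labels == "case"]), tolerance = 1e-12)

  expect_warning(single <- evaluateModel(runif(5),
                                         factor(rep("case", 5),
                                                levels = c("control",
                                                           "case")),
                                         positive = "case"), "single-class")
  expect_true(is.na(evaluationMetrics(single)["auc_roc"]))
})

test_that("feature ranking surfaces injected signal features", {
  panel <- signalPanel(n_affected = 5, n_filler = 25, noise_cv = 0.15)
  cfg <- CohortConfig(n_control = 60, n_case = 60, seed = 19,
                      control_age = c(34, 26, 44), case_age = c(34, 26, 44))
  tab <- generateCohort(cfg, panel)
  x <- t(concentrations(tab))
  y <- subjectGroups(tab)
  spec <- ModelSpec("random_forest", list(mtry_frac = 0.3, ntree = 200),
                    seed = 7)
  model <- tuneAndFit(spec, x, y)
  top10 <- modelFeatureSet(model, top_k = 10)$feature
  expect_gte(sum(sprintf("Signal%02d", 1:5) %in% top10), 5)

  expect_equal(nrow(modelFeatureSet(model, top_k = 0)), 0L)
  full <- modelFeatureSet(model, top_k = 1000)
  expect_equal(nrow(full), 30L)
  expect_false(is.unsorted(rev(full$importance)))
})

test_that("consensus panel applies majority vote and the univariate filter", {
  screen <- S4Vectors::DataFrame(
    metabolite = c("A", "B", "C", "D"),
    auc = c(0.9, 0.8, 0.95, 0.7),
    passes_filter = c(TRUE, TRUE, FALSE, TRUE))
  sets <- list(c("A", "B", "C"), c("A", "C"), c("A", "B", "C"),
               c("A", "D"), c("B", "C"))
  panel <- consensusPanel(sets, screen, min_models = 3)
  expect_equal(panel$feature, c("A", "B"))  # C fails filter, D has 1 vote
  expect_equal(panel$n_models, c(4L, 3L))

  union_panel <- consensusPanel(sets, screen, min_models = 1)
  expect_setequal(union_panel$feature, c("A", "B", "D"))

  # panel size is non-increasing in min_models
  sizes <- vapply(1:5, function(k)
    nrow(consensusPanel(sets, screen, min_models = k)), integer(1))
  expect_false(is.unsorted(rev(sizes)))

  expect_error(consensusPanel(sets[1], screen), "at least 2")
})

test_that("the full model stage is deterministic and internally consistent", {
  panel <- signalPanel(n_affected = 6, n_filler = 14, noise_cv = 0.2)
  cfg <- CohortConfig(n_control = 30, n_case = 40, seed = 23,
                      control_age = c(34, 26, 44), case_age = c(34, 26, 44))
  tab <- generateCohort(cfg, panel)
  specs <- defaultModelSpecs(seed = 23, fast = TRUE)
  r1 <- runAllModels(tab, specs, folds = 3, seed = 23)
  r2 <- runAllModels(tab, specs, folds = 3, seed = 23)
  expect_identical(r1$metrics_table, r2$metrics_table)
  expect_identical(r1$consensus, r2$consensus)
  expect_length(r1$evaluations, 5)

  for (ev in r1$evaluations) {
    cm <- confusion(ev)
    m <- evaluationMetrics(ev)
    expect_equal(unname(m["accuracy"]),
                 (cm@tp + cm@tn) / (cm@tp + cm@fp + cm@fn + cm@tn))
    expect_equal(unname(m["auc_roc"]),
                 aucFromScores(ev@scores, ev@labels, "case"),
                 tolerance = 1e-12)
    roc <- rocPoints(ev)
    expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  }
})
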