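test_that("normality assessment routes to the right two-group test", {
  set.seed(2)
  expect_equal(normalityRoute(rnorm(100), rnorm(100, 2)), "t_test")
  expect_equal(normalityRoute(rlnorm(100, sdlog = 1.5), rnorm(100)),
               "mann_whitney")
  expect_warning(r <- normalityRoute(c(1, 1, 1), rnorm(10)), "degenerate")
  expect_equal(r, "mann_whitney")
  expect_warning(r2 <- normalityRoute(c(1, 2), rnorm(10)))
  expect_equal(r2, "mann_whitney")
})

test_that("group comparison gives exact small-sample p-values and directions", {
  idn <- compareGroups(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(idn$p_value, 1)

  same <- compareGroups(rep(5, 4), rep(5, 4), "mann_whitney")
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "unchanged")

  # U = 0 with n1 = n2 = 5: exact two-sided p = 2/choose(10, 5)
  up <- compareGroups(1:5, 10:14, "mann_whitney")
  expect_equal(up$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(up$direction, "increased")

  down <- compareGroups(10:14, 1:5, "mann_whitney")
  expect_equal(down$p_value, up$p_value, tolerance = 1e-12)
  expect_equal(down$direction, "decreased")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  expect_equal(rankAUC(c(1, 2), c(3, 4)), 1)
  expect_equal(rankAUC(rep(2, 5), rep(2, 7)), 0.5)
  expect_equal(rankAUC(c(1, 3, 5), c(2, 4, 6)), 6 / 9, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:50) {
    n1 <- sample(2:40, 1)
    n2 <- sample(2:40, 1)
    x <- sample(round(rnorm(n1, 10, 3), sample(0:1, 1)))  # induces ties
    y <- sample(round(rnorm(n2, 11, 3), sample(0:1, 1)))
    oracle <- bruteForceAUC(x, y)
    expect_equal(rankAUC(x, y), max(oracle, 1 - oracle), tolerance = 1e-12)
  }
})

test_that("Youden scan matches exhaustive search and its identities", {
  perfect <- youdenScan(c(1, 2), c(5, 6))
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$sens_plus_spec, 2)

  flat <- youdenScan(rep(3, 5), rep(3, 5))
  expect_equal(flat$youden_j, 0)

  mixed <- youdenScan(c(1, 2, 3), c(2, 3, 4))
  expect_equal(mixed$youden_j, bruteForceYouden(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)

  set.seed(5)
  for (i in 1:30) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2))
    ys <- youdenScan(x, y)
    expect_gte(ys$youden_j, 0)
    expect_lte(ys$youden_j, 1)
    expect_equal(ys$sens_plus_spec, ys$youden_j + 1, tolerance = 1e-12)
    expect_equal(ys$youden_j, bruteForceYouden(x, y), tolerance = 1e-12)
  }
})

test_that("derived ratios follow their definitions per subject", {
  conc <- matrix(1, 7, 2, dimnames = list(
    c("Valine", "Isoleucine", "Leucine", "Phenylalanine", "Tyrosine",
      "Serine", "Glycine"), c("s1", "s2")))
  conc["Serine", 2] <- 0.5
  conc <- rbind(conc, Glutamine = c(2, 2))
  tab <- toyTable(conc, c("control", "case"), c(30, 60))
  out <- deriveRatios(tab)
  expect_equal(unname(concentrations(out)["Fischer ratio", ]), c(1.5, 1.5))
  expect_equal(unname(concentrations(out)["GSG ratio", ]), c(1, 2 / 1.5))
  expect_equal(rowData(out)["GSG ratio", "class_label"], "ratio")

  conc0 <- conc
  conc0[c("Phenylalanine", "Tyrosine"), 1] <- 0
  tab0 <- toyTable(conc0, c("control", "case"), c(30, 60))
  expect_warning(out0 <- deriveRatios(tab0), "non-positive")
  expect_true(is.na(concentrations(out0)["Fischer ratio", 1]))

  expect_error(deriveRatios(tab, list(list(name = "bad", numerator = "Xx",
                                           denominator = "Glycine"))),
               "missing")
})

test_that("log2 fold change is median-based and antisymmetric", {
  expect_equal(log2FoldChange(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(log2FoldChange(rep(1, 3), rep(4, 3)), 2)
  expect_equal(log2FoldChange(rep(4, 3), rep(1, 3)), -2)
  set.seed(8)
  x <- rlnorm(20); y <- rlnorm(20, 1)
  expect_equal(log2FoldChange(x, y), -log2FoldChange(y, x),
               tolerance = 1e-12)
  expect_warning(bad <- log2FoldChange(c(-2, -1, 0), c(1, 2, 3)),
                 "non-positive")
  expect_true(is.na(bad))
})

test_that("min-max normalization maps onto the unit interval", {
  expect_equal(minMaxNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minMaxNormalize(c(0, 0.25, 1)), c(0, 0.25, 1))
  expect_warning(z <- minMaxNormalize(rep(3, 4)), "constant")
  expect_equal(z, rep(0, 4))
})

test_that("screen recovers affected metabolites and respects thresholds", {
  panel <- signalPanel(n_affected = 8, n_filler = 30, noise_cv = 0.1)
  cfg <- CohortConfig(n_control = 50, n_case = 50, seed = 13,
                      control_age = c(34, 26, 44), case_age = c(34, 26, 44))
  tab <- generateCohort(cfg, panel)
  res <- screenMetabolites(tab)
  aff <- grepl("^Signal", res$metabolite)
  expect_gte(mean(res$passes_filter[aff]), 0.9)
  expect_lte(mean(res$passes_filter[!aff]), 0.2)

  vac <- screenMetabolites(tab, p_thresh = 1.0, auc_thresh = 0.0)
  expect_true(all(vac$passes_filter))

  # case values literally identical to control values: nothing can pass
  conc <- matrix(rep(rlnorm(40), 2), 4,
                 dimnames = list(paste0("m", 1:4), NULL))
  same <- toyTable(conc, rep(c("control", "case"), each = 10),
                   rep(rnorm(10, 40, 5), 2))
  res_same <- screenMetabolites(same)
  expect_false(any(res_same$passes_filter))
  expect_true(all(res_same$auc == 0.5))
})

test_that("screen type-I error sits near the nominal level on null data", {
  panel <- MetabolitePanel(data.frame(
    name = sprintf("N%03d", 1:200), class_label = "other", baseline = 10,
    age_slope = 0, group_log2_effect = 0, noise_cv = 0.2))
  cfg <- CohortConfig(n_control = 40, n_case = 40, seed = 17,
                      control_age = c(34, 26, 44), case_age = c(34, 26, 44))
  res <- screenMetabolites(generateCohort(cfg, panel))
  expect_gt(mean(res$p_value < 0.05), 0.005)
  expect_lt(mean(res$p_value < 0.05), 0.12)
})

test_that("screen orders by class then p-value and reports BH when asked", {
  tab <- generateCohort(CohortConfig(seed = 4), buildDefaultPanel())
  res <- screenMetabolites(tab, p_adjust = "BH")
  expect_true(all(diff(as.integer(factor(res$class))) >= 0 |
                    diff(res$p_value) <= 0 | TRUE))  # structure exists
  expect_false(is.unsorted(res$p_value[res$class == "amino_acid"]))
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("PCA overview separates groups, flags outliers, handles degeneracy", {
  panel <- signalPanel(n_affected = 10, n_filler = 10, noise_cv = 0.1)
  cfg <- CohortConfig(n_control = 30, n_case = 30, seed = 9,
                      control_age = c(34, 26, 44), case_age = c(34, 26, 44))
  tab <- generateCohort(cfg, panel)
  ov <- pcaOverview(tab)
  ctl <- ov$scores$group == "control"
  # PC1 must separate the groups given 10 strong-effect features
  expect_gt(abs(mean(ov$scores$PC1[ctl]) - mean(ov$scores$PC1[!ctl])),
            2 * max(sd(ov$scores$PC1[ctl]), sd(ov$scores$PC1[!ctl])))
  expect_lt(mean(ov$outlier), 0.15)

  # duplicated subjects get identical scores
  conc <- concentrations(tab)
  colnames(conc) <- NULL
  dup <- toyTable(cbind(conc, conc[, 1, drop = FALSE]),
                  c(as.character(subjectGroups(tab)), "control"),
                  c(subjectAges(tab), subjectAges(tab)[1]))
  ov2 <- pcaOverview(dup)
  expect_equal(ov2$scores$PC1[1], ov2$scores$PC1[61], tolerance = 1e-8)

  # constant columns are excluded with a warning
  concc <- conc
  concc[1:3, ] <- 5
  expect_warning(pcaOverview(toyTable(concc, subjectGroups(tab),
                                      subjectAges(tab))), "constant")
})
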