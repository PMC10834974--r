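mkTable <- function(ages, groups = rep("control", length(ages)),
                    conc = NULL) {
  n <- length(ages)
  if (is.null(conc))
    conc <- matrix(seq_len(2 * n), 2, n,
                   dimnames = list(c("A", "B"), NULL))
  toyTable(conc, groups, ages)
}

test_that("age strata are anchored half-open bins with midpoint representatives", {
  tab <- mkTable(c(26, 27, 33, 34, 44))
  s <- stratifyByAge(tab, width = 5)
  expect_equal(s$low, c(25, 30, 40))
  expect_equal(s$high, c(30, 35, 45))
  expect_equal(s$n, c(2L, 2L, 1L))
  expect_equal(s$representative_age, c(27.5, 32.5, 42.5))
  # every control in exactly one stratum
  expect_equal(sum(s$n), 5L)

  s1 <- stratifyByAge(mkTable(31), width = 5)
  expect_equal(nrow(s1), 1L)
  expect_equal(c(s1$low, s1$high), c(30, 35))

  tab2 <- mkTable(seq(26, 44, by = 2))
  s2 <- stratifyByAge(tab2, width = 5)
  expect_true(all(s2$representative_age %in% c(27.5, 32.5, 37.5, 42.5)))
})

test_that("stratum medians use the order statistic and drop sparse strata", {
  conc <- matrix(c(1, 3, 2, 4, 100, 7), 1,
                 dimnames = list("A", NULL))
  tab <- mkTable(ages = c(26, 27, 31, 32, 33, 44), conc = conc)
  s <- stratifyByAge(tab, width = 5)
  expect_warning(m <- stratumMedians(s, tab, "A"), "fewer than")
  expect_equal(m$median, c(2, 4))  # {1,3} -> 2; {2,4,100} -> 4 (robust)

  m1 <- stratumMedians(s, tab, "A", min_stratum_size = 1)
  expect_equal(m1$median[3], 7)  # singleton median kept when allowed

  sm <- stratifyByAge(mkTable(c(20, 30, 40)), width = 5)
  expect_error(
    suppressWarnings(stratumMedians(sm, mkTable(c(20, 30, 40)), "A",
                                    min_stratum_size = 2)),
    "fewer than")
})

test_that("OLS on stratum medians matches closed-form regression", {
  f <- fitAgeModel(data.frame(representative_age = c(27.5, 32.5, 37.5),
                              median = c(10, 20, 30)))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  flat <- fitAgeModel(data.frame(representative_age = c(25, 30, 35, 40),
                                 median = rep(7, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  set.seed(42)
  x <- c(25, 30, 35, 40, 45)
  y <- 3 + 0.8 * x + rnorm(5, sd = 0.5)
  f2 <- fitAgeModel(data.frame(representative_age = x, median = y))
  oracle <- olsOracle(x, y)
  expect_equal(f2$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, oracle$intercept, tolerance = 1e-10)
  expect_lt(abs(f2$slope - 0.8) / 0.8, 0.1)

  expect_warning(null <- fitAgeModel(data.frame(representative_age = 30,
                                                median = 5)), "null")
  expect_true(is.na(null$slope))
})

test_that("age delta is slope times distance from the reference age", {
  co <- data.frame(metabolite = c("A", "B"), slope = c(2, -0.5),
                   intercept = c(0, 0), r2 = c(1, 1), n_strata = c(3, 3))
  model <- new("AgeCorrectionModel", coefficients = co, reference_age = 40,
               stratum_width = 5, min_stratum_size = 2L)
  expect_equal(ageDelta(model, "A", 50), 20)
  expect_equal(ageDelta(model, "A", 40), 0)
  expect_equal(ageDelta(model, "B", 30), 5)  # negative slope, younger age
  expect_error(ageDelta(model, "Z", 50), "unknown")
})

test_that("correction subtracts the delta and is the identity at zero slope", {
  co0 <- data.frame(metabolite = c("A", "B"), slope = c(0, 0),
                    intercept = 0, r2 = NA, n_strata = 3)
  m0 <- new("AgeCorrectionModel", coefficients = co0, reference_age = 40,
            stratum_width = 5, min_stratum_size = 2L)
  tab <- mkTable(c(30, 45, 50, 60), groups = c("control", "control",
                                               "case", "case"))
  expect_equal(concentrations(applyCorrection(tab, m0)),
               concentrations(tab))

  co <- data.frame(metabolite = c("A", "B"), slope = c(2, 0),
                   intercept = 0, r2 = 1, n_strata = 3)
  m <- new("AgeCorrectionModel", coefficients = co, reference_age = 40,
           stratum_width = 5, min_stratum_size = 2L)
  conc <- matrix(c(120, 1), 2, 1, dimnames = list(c("A", "B"), NULL))
  t1 <- toyTable(conc, "control", 50)
  adj <- applyCorrection(t1, m)
  expect_equal(unname(concentrations(adj)["A", 1]), 100)  # 120 - 2*10
  expect_equal(unname(concentrations(adj)["B", 1]), 1)

  bad <- mkTable(c(30, 40))
  rownames(bad) <- c("A", "C")
  expect_error(applyCorrection(bad, m), "does not cover")
})

test_that("correction removes injected linear age trends in controls", {
  panel <- toyPanel(n_null = 3, slope = 2, noise_cv = 0.05)
  cfg <- CohortConfig(n_control = 200, n_case = 50, seed = 31,
                      reference_age = 40)
  tab <- generateCohort(cfg, panel)
  model <- suppressWarnings(fitAgeCorrection(tab))
  adj <- suppressMessages(applyCorrection(tab, model))
  ctl <- subjectGroups(adj) == "control"
  fit <- lm(concentrations(adj)["Marker", ctl] ~ subjectAges(adj)[ctl])
  expect_lt(abs(coef(fit)[2]), 0.1 * 2)  # residual slope < 10% of injected
})

test_that("within a fixed age the correction is a pure location shift", {
  ages <- rep(c(30, 35, 50), each = 4)
  conc <- matrix(rlnorm(24, 3, 0.3), 2, 12,
                 dimnames = list(c("A", "B"), NULL))
  tab <- mkTable(ages, groups = rep(c("control", "case"), 6), conc = conc)
  co <- data.frame(metabolite = c("A", "B"), slope = c(1.5, -2),
                   intercept = 0, r2 = 1, n_strata = 4)
  m <- new("AgeCorrectionModel", coefficients = co, reference_age = 40,
           stratum_width = 5, min_stratum_size = 2L)
  adj <- suppressMessages(applyCorrection(tab, m))
  for (a in unique(ages)) {
    d <- concentrations(tab)[, ages == a] - concentrations(adj)[, ages == a]
    expect_equal(apply(d, 1, sd), c(A = 0, B = 0), tolerance = 1e-12)
    expect_equal(apply(concentrations(adj)[, ages == a], 1, var),
                 apply(concentrations(tab)[, ages == a], 1, var),
                 tolerance = 1e-12)
  }
})

test_that("correction strongly reduces age-confounded false positives", {
  # groups differ only in age; metabolites have strong slopes, zero effects
  k <- 60
  panel <- MetabolitePanel(data.frame(
    name = sprintf("M%02d", 1:k), class_label = "other", baseline = 100,
    age_slope = 1, group_log2_effect = 0, noise_cv = 0.2))
  cfg <- CohortConfig(n_control = 60, n_case = 60, seed = 7,
                      control_age = c(34, 26, 44), case_age = c(64, 58, 71))
  tab <- generateCohort(cfg, panel)
  pre <- screenMetabolites(tab)
  model <- suppressWarnings(fitAgeCorrection(tab))
  post <- screenMetabolites(suppressMessages(applyCorrection(tab, model)))
  fp_pre <- mean(pre$p_value < 0.05)
  fp_post <- mean(post$p_value < 0.05)
  expect_gt(fp_pre, 0.5)
  expect_lt(fp_post, fp_pre / 2)
})

test_that("model file round-trips through delimited text", {
  tab <- generateCohort(CohortConfig(seed = 2), buildDefaultPanel())
  model <- suppressWarnings(fitAgeCorrection(tab))
  f <- tempfile(fileext = ".csv")
  writeAgeCorrectionModel(model, f)
  back <- readAgeCorrectionModel(f)
  expect_equal(coef(back)$slope, coef(model)$slope, tolerance = 1e-12)
  expect_equal(referenceAge(back), referenceAge(model))
})
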