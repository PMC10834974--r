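#' Choose the parametric or non-parametric two-group test
#'
#' Shapiro-Wilk normality is assessed in each group at level \code{alpha};
#' the Student t route is taken only when both groups look normal,
#' otherwise the Mann-Whitney U route. Groups with fewer than 3 values, or
#' with zero variance, route to Mann-Whitney with a warning.
#'
#' @param control_values,case_values numeric vectors.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return \code{"t_test"} or \code{"mann_whitney"}.
#' @examples
#' normalityRoute(rnorm(50), rnorm(50))
#' @export
normalityRoute <- function(control_values, case_values, alpha = 0.05) {
  shapiro_p <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  p1 <- shapiro_p(control_values)
  p2 <- shapiro_p(case_values)
  if (anyNA(c(p1, p2))) {
    warnf("group too small or degenerate for normality assessment; %s",
          "routing to mann_whitney")
    return("mann_whitney")
  }
  if (p1 >= alpha && p2 >= alpha) "t_test" else "mann_whitney"
}

#' Two-group comparison along the routed test
#'
#' Two-sided Student t-test or Mann-Whitney U test; the direction of change
#' is the sign of the case-minus-control median difference.
#'
#' @inheritParams normalityRoute
#' @param route \code{"t_test"} or \code{"mann_whitney"} (see
#'   [normalityRoute()]).
#' @return list with \code{p_value} and \code{direction}
#'   (\code{"increased"}, \code{"decreased"} or \code{"unchanged"}, case
#'   vs control).
#' @examples
#' compareGroups(1:5, 10:14, "mann_whitney")
#' @export
compareGroups <- function(control_values, case_values,
                          route = c("mann_whitney", "t_test")) {
  route <- match.arg(route)
  x <- control_values[is.finite(control_values)]
  y <- case_values[is.finite(case_values)]
  mx <- stats::median(x)
  my <- stats::median(y)
  direction <- if (my > mx) "increased" else if (my < mx) "decreased"
               else "unchanged"
  if (stats::sd(c(x, y)) == 0)
    return(list(p_value = 1, direction = "unchanged"))
  p <- if (route == "t_test") {
    tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
             error = function(e)
               suppressWarnings(stats::wilcox.test(x, y)$p.value))
  } else {
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  list(p_value = p, direction = direction)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' AUC computed as \eqn{U/(n_1 n_2)} with midrank tie handling, i.e. the
#' probability that a random case value exceeds a random control value
#' (ties counting one half). Reported direction-agnostically as
#' \code{max(a, 1 - a)}, so the value is always in [0.5, 1]; the side is
#' carried by the direction of change.
#'
#' @inheritParams normalityRoute
#' @return AUC in [0.5, 1].
#' @examples
#' rankAUC(c(1, 3, 5), c(2, 4, 6))  # 2/3
#' @export
rankAUC <- function(control_values, case_values) {
  x <- control_values[is.finite(control_values)]
  y <- case_values[is.finite(case_values)]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  ry <- r[(length(x) + 1):(length(x) + length(y))]
  a <- (sum(ry) - length(y) * (length(y) + 1) / 2) /
    (as.numeric(length(x)) * length(y))
  max(a, 1 - a)
}

#' Youden cutoff scan
#'
#' Scans every empirical cutoff (midpoints between adjacent sorted unique
#' pooled values, plus cutoffs outside the data range) in both
#' orientations and returns the maximum of
#' \code{J = sensitivity + specificity - 1}, together with
#' \code{sensitivity + specificity} (the quantity some reports print as a
#' "Youden index" exceeding 1) and the optimal cutoff. Ties in J break
#' toward the cutoff with higher specificity.
#'
#' @inheritParams normalityRoute
#' @return list with \code{youden_j}, \code{sens_plus_spec}, \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{case_side}
#'   (\code{"high"} if cases are called above the cutoff).
#' @examples
#' youdenScan(c(1, 2, 3), c(2, 3, 4))
#' @export
youdenScan <- function(control_values, case_values) {
  x <- control_values[is.finite(control_values)]
  y <- case_values[is.finite(case_values)]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  v <- sort(unique(c(x, y)))
  cuts <- if (length(v) == 1) c(v - 1, v + 1)
          else c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  best <- list(j = -Inf, spec = -Inf)
  for (side in c("high", "low")) for (cut in cuts) {
    if (side == "high") {
      sens <- mean(y > cut); spec <- mean(x <= cut)
    } else {
      sens <- mean(y < cut); spec <- mean(x >= cut)
    }
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(j = j, spec = spec, sens = sens, cut = cut, side = side)
    }
  }
  list(youden_j = max(0, best$j), sens_plus_spec = max(0, best$j) + 1,
       cutoff = best$cut, sensitivity = best$sens,
       specificity = best$spec, case_side = best$side)
}

#' Default derived amino-acid ratio definitions
#'
#' The Fischer ratio (branched-chain over aromatic amino acids,
#' (Val + Ile + Leu)/(Phe + Tyr)) and the GSG ratio of
#' glutathione-synthesis amino acids (glutamine over serine plus glycine).
#'
#' @return list of ratio definitions (name, numerator, denominator).
#' @export
defaultRatioDefinitions <- function() {
  list(
    list(name = "Fischer ratio",
         numerator = c("Valine", "Isoleucine", "Leucine"),
         denominator = c("Phenylalanine", "Tyrosine")),
    list(name = "GSG ratio",
         numerator = "Glutamine",
         denominator = c("Serine", "Glycine")))
}

#' Append derived ratio features to a concentration table
#'
#' Each ratio is computed per subject as the sum of the numerator
#' concentrations over the sum of the denominator concentrations.
#' Subjects with a non-positive denominator get a missing ratio value
#' (with a warning).
#'
#' @param table a [ConcentrationTable-class].
#' @param definitions list of ratio definitions; see
#'   [defaultRatioDefinitions()].
#' @return the table with one appended row per ratio (class label
#'   \code{"ratio"}).
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' tab2 <- deriveRatios(tab)
#' tail(metaboliteNames(tab2), 2)
#' @export
deriveRatios <- function(table, definitions = defaultRatioDefinitions()) {
  stopifnot(is(table, "ConcentrationTable"))
  conc <- concentrations(table)
  extra <- matrix(NA_real_, length(definitions), ncol(conc),
                  dimnames = list(vapply(definitions, `[[`, "", "name"),
                                  colnames(conc)))
  for (i in seq_along(definitions)) {
    d <- definitions[[i]]
    missing <- setdiff(c(d$numerator, d$denominator), rownames(conc))
    if (length(missing))
      stopf("ratio '%s' references missing metabolite(s): %s", d$name,
            paste(missing, collapse = ", "))
    num <- colSums(conc[d$numerator, , drop = FALSE])
    den <- colSums(conc[d$denominator, , drop = FALSE])
    bad <- den <= 0
    if (any(bad))
      warnf("ratio '%s': %d subject(s) with non-positive denominator set %s",
            d$name, sum(bad), "to missing")
    extra[i, ] <- ifelse(bad, NA_real_, num / den)
  }
  cd <- colData(table)
  out <- ConcentrationTable(rbind(conc, extra), group = cd$group,
                            age = cd$age, sex = cd$sex,
                            class_label = c(rowData(table)$class_label,
                                            rep("ratio", nrow(extra))),
                            subject_id = cd$subject_id)
  metadata(out) <- metadata(table)
  out
}

#' Median-based log2 fold change
#'
#' \code{log2(median(case) / median(control))}, computed on the raw
#' (pre-correction) scale where concentrations are positive.
#'
#' @inheritParams normalityRoute
#' @param use_mean use group means instead of medians.
#' @return log2 fold change, or \code{NA} (with a warning) when either
#'   group summary is non-positive.
#' @examples
#' log2FoldChange(c(1, 1, 1), c(4, 4, 4))  # 2
#' @export
log2FoldChange <- function(control_values, case_values, use_mean = FALSE) {
  f <- if (use_mean) mean else stats::median
  mc <- f(control_values[is.finite(control_values)])
  ma <- f(case_values[is.finite(case_values)])
  if (!isTRUE(mc > 0) || !isTRUE(ma > 0)) {
    warnf("non-positive group summary; log2 fold change undefined")
    return(NA_real_)
  }
  log2(ma / mc)
}

#' Min-max normalization to [0, 1]
#'
#' @param values numeric vector.
#' @return \code{(x - min)/(max - min)}; a constant vector maps to all
#'   zeros with a warning.
#' @examples
#' minMaxNormalize(c(2, 4, 6))
#' @export
minMaxNormalize <- function(values) {
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2]) {
    warnf("constant values; min-max normalization returns zeros")
    return(rep(0, length(values)))
  }
  (values - r[1]) / (r[2] - r[1])
}

#' Univariate metabolite screen
#'
#' For every metabolite (and derived ratio) row: Shapiro-Wilk routed group
#' comparison, direction of change, rank AUC, Youden cutoff scan and log2
#' fold change; features with \code{p_value < p_thresh} and
#' \code{auc > auc_thresh} pass the significance filter. No
#' multiple-testing correction is applied by default (reproducing the raw
#' per-metabolite screen); set \code{p_adjust = "BH"} for
#' Benjamini-Hochberg, in which case the filter uses the adjusted p-value.
#'
#' @param table an age-adjusted [ConcentrationTable-class], typically with
#'   ratios appended by [deriveRatios()].
#' @param raw optional raw (pre-correction) table used for log2 fold
#'   changes; when absent, fold changes are computed from \code{table}.
#' @param p_thresh,auc_thresh significance filter thresholds (defaults
#'   0.05 and 0.65).
#' @param alpha_normality Shapiro-Wilk level for test routing.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return a [S4Vectors::DataFrame] with one row per feature, sorted by
#'   class then p-value: \code{metabolite}, \code{class},
#'   \code{test_used}, \code{p_value}, \code{direction}, \code{auc},
#'   \code{youden_j}, \code{sens_plus_spec}, \code{optimal_cutoff},
#'   \code{log2fc}, \code{passes_filter} (and \code{p_adjusted} when
#'   requested).
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' res <- screenMetabolites(deriveRatios(tab))
#' sum(res$passes_filter)
#' @export
screenMetabolites <- function(table, raw = NULL, p_thresh = 0.05,
                              auc_thresh = 0.65, alpha_normality = 0.05,
                              p_adjust = c("none", "BH")) {
  stopifnot(is(table, "ConcentrationTable"))
  p_adjust <- match.arg(p_adjust)
  conc <- concentrations(table)
  if (nrow(conc) == 0) stopf("table has no metabolite rows")
  ctrl <- subjectGroups(table) == controlLevel(table)
  raw_conc <- if (is.null(raw)) NULL else concentrations(raw)
  rows <- lapply(seq_len(nrow(conc)), function(i) {
    x <- conc[i, ctrl]
    y <- conc[i, !ctrl]
    route <- suppressWarnings(normalityRoute(x, y, alpha_normality))
    cmp <- compareGroups(x, y, route)
    auc <- rankAUC(x, y)
    yo <- youdenScan(x, y)
    fc_src <- if (!is.null(raw_conc) && rownames(conc)[i] %in%
                    rownames(raw_conc)) {
      list(raw_conc[rownames(conc)[i], ctrl],
           raw_conc[rownames(conc)[i], !ctrl])
    } else list(x, y)
    lfc <- suppressWarnings(log2FoldChange(fc_src[[1]], fc_src[[2]]))
    data.frame(metabolite = rownames(conc)[i],
               class = rowData(table)$class_label[i],
               test_used = route, p_value = cmp$p_value,
               direction = cmp$direction, auc = auc,
               youden_j = yo$youden_j,
               sens_plus_spec = yo$sens_plus_spec,
               optimal_cutoff = yo$cutoff, log2fc = lfc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_for_filter <- res$p_value
  if (p_adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    p_for_filter <- res$p_adjusted
  }
  res$passes_filter <- p_for_filter < p_thresh & res$auc > auc_thresh
  res <- res[order(res$class, res$p_value), ]
  rownames(res) <- NULL
  DataFrame(res)
}

#' PCA overview with outlier flagging
#'
#' Principal component analysis of the subjects-by-metabolites matrix with
#' unit-variance scaling (concentration scales span orders of magnitude).
#' Subjects whose Mahalanobis distance in the first two component scores
#' exceeds the \code{outlier_quantile} chi-square quantile are flagged —
#' never removed.
#'
#' @param table a [ConcentrationTable-class] with at least 3 subjects.
#' @param outlier_quantile chi-square quantile for the flag threshold
#'   (default 0.975).
#' @return list with \code{scores} (data.frame: subject_id, group, PC1,
#'   PC2), \code{outlier} (logical), \code{var_explained} (first two
#'   proportions), and \code{pca} (the \code{prcomp} fit).
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' ov <- pcaOverview(tab)
#' sum(ov$outlier)
#' @export
pcaOverview <- function(table, outlier_quantile = 0.975) {
  stopifnot(is(table, "ConcentrationTable"))
  if (ncol(table) < 3) stopf("need at least 3 subjects for a PCA overview")
  m <- t(concentrations(table))
  keep <- apply(m, 2, stats::sd) > 0
  if (any(!keep))
    warnf("%d constant metabolite column(s) excluded from PCA", sum(!keep))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) {
    warnf("degenerate covariance; no PCA outliers flagged")
    return(list(scores = NULL, outlier = rep(FALSE, ncol(table)),
                var_explained = NULL, pca = NULL))
  }
  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  sc <- pca$x[, 1:2, drop = FALSE]
  sdev <- pca$sdev[1:2]
  if (any(sdev == 0)) {
    warnf("degenerate covariance; no PCA outliers flagged")
    out <- rep(FALSE, nrow(sc))
  } else {
    d2 <- (sc[, 1] / sdev[1])^2 + (sc[, 2] / sdev[2])^2
    out <- d2 > stats::qchisq(outlier_quantile, df = 2)
  }
  list(scores = data.frame(subject_id = colData(table)$subject_id,
                           group = subjectGroups(table),
                           PC1 = sc[, 1], PC2 = sc[, 2]),
       outlier = unname(out),
       var_explained = (pca$sdev^2 / sum(pca$sdev^2))[1:2],
       pca = pca)
}
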