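#' Bin control subjects into fixed-width age strata
#'
#' Strata are half-open intervals \code{[low, high)} anchored at multiples
#' of \code{width} from age zero (e.g. [25,30), [30,35) for the default
#' 5-year width); the representative age of a stratum is its midpoint.
#' Empty strata are omitted.
#'
#' @param table a [ConcentrationTable-class]; only subjects in the control
#'   (first) group level are used.
#' @param width stratum width in years (default 5).
#' @param offset anchoring offset in years (default 0).
#' @return data.frame with columns \code{low}, \code{high},
#'   \code{representative_age}, \code{n} and a list column
#'   \code{member_ids}.
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' stratifyByAge(tab)
#' @export
stratifyByAge <- function(table, width = 5, offset = 0) {
  stopifnot(is(table, "ConcentrationTable"), width > 0)
  ctrl <- subjectGroups(table) == controlLevel(table)
  if (!any(ctrl)) stopf("no control subjects in table")
  age <- subjectAges(table)[ctrl]
  ids <- colData(table)$subject_id[ctrl]
  low <- floor((age - offset) / width) * width + offset
  strata <- sort(unique(low))
  out <- data.frame(low = strata, high = strata + width,
                    representative_age = strata + width / 2,
                    n = as.integer(tabulate(match(low, strata),
                                            length(strata))))
  out$member_ids <- lapply(strata, function(s) ids[low == s])
  out
}

#' Per-stratum median concentrations of one metabolite
#'
#' Strata with fewer than \code{min_stratum_size} control subjects are
#' dropped with a warning (a median of one observation is noisy). The
#' median is the standard order statistic (mean of the two central values
#' for even counts).
#'
#' @param strata output of [stratifyByAge()].
#' @param table the [ConcentrationTable-class] the strata were built from.
#' @param metabolite metabolite (row) name.
#' @param min_stratum_size minimum stratum membership (default 2).
#' @return data.frame with columns \code{representative_age}, \code{median},
#'   \code{n}.
#' @export
stratumMedians <- function(strata, table, metabolite, min_stratum_size = 2) {
  if (!metabolite %in% metaboliteNames(table))
    stopf("unknown metabolite '%s'", metabolite)
  keep <- strata$n >= min_stratum_size
  if (!any(keep))
    stopf("all %d strata have fewer than %d members", nrow(strata),
          min_stratum_size)
  if (any(!keep))
    warnf("dropping %d stratum/strata with fewer than %d members",
          sum(!keep), min_stratum_size)
  conc <- concentrations(table)[metabolite, ]
  ids <- colData(table)$subject_id
  med <- vapply(strata$member_ids[keep], function(m)
    stats::median(conc[match(m, ids)]), numeric(1))
  data.frame(representative_age = strata$representative_age[keep],
             median = med, n = strata$n[keep])
}

#' Ordinary least squares on stratum-median points
#'
#' Fits \code{median ~ age} by unweighted OLS (optionally weighted by
#' stratum size). With fewer than two points, or no age spread, the slope
#' is null (\code{NA}) and the metabolite passes through the correction
#' unchanged.
#'
#' @param points data.frame with columns \code{representative_age} (or
#'   \code{age}) and \code{median}, optionally \code{n}.
#' @param weighted weight points by stratum size \code{n} (default FALSE,
#'   the literal stratified-median algorithm).
#' @return list with \code{slope}, \code{intercept}, \code{r2},
#'   \code{n_points}.
#' @examples
#' fitAgeModel(data.frame(representative_age = c(27.5, 32.5, 37.5),
#'                        median = c(10, 20, 30)))
#' @export
fitAgeModel <- function(points, weighted = FALSE) {
  x <- if ("representative_age" %in% names(points)) points$representative_age
       else points$age
  y <- points$median
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0) {
    warnf("cannot fit age trend on %d point(s); slope set to null",
          length(x))
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n_points = length(x)))
  }
  w <- if (weighted && "n" %in% names(points)) points$n[ok]
       else rep(1, length(x))
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(w * fit$residuals^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, n_points = length(x))
}

#' Fit the age-correction model for every metabolite
#'
#' Runs the stratified-median regression on the control group: ages are
#' binned into fixed-width strata, per-stratum medians of each metabolite
#' are computed, and an OLS line through the (stratum midpoint, median)
#' points gives each metabolite's age slope.
#'
#' @inheritParams stratifyByAge
#' @inheritParams stratumMedians
#' @param reference_age age at which the correction delta is zero:
#'   \code{"auto"} (the default) uses the control-group median age rounded
#'   to the nearest year, anchoring corrected values to the reference
#'   population's center.
#' @param weighted passed to [fitAgeModel()].
#' @return An [AgeCorrectionModel-class].
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' fitAgeCorrection(tab)
#' @export
fitAgeCorrection <- function(table, width = 5, reference_age = "auto",
                             min_stratum_size = 2, offset = 0,
                             weighted = FALSE) {
  stopifnot(is(table, "ConcentrationTable"))
  if (identical(reference_age, "auto")) {
    ctrl <- subjectGroups(table) == controlLevel(table)
    reference_age <- round(stats::median(subjectAges(table)[ctrl]))
  }
  strata <- stratifyByAge(table, width = width, offset = offset)
  usable <- strata$n >= min_stratum_size
  if (any(!usable))
    warnf("%d of %d strata below the minimum size of %d are dropped",
          sum(!usable), nrow(strata), min_stratum_size)
  fits <- lapply(metaboliteNames(table), function(m) {
    pts <- suppressWarnings(
      stratumMedians(strata, table, m, min_stratum_size))
    suppressWarnings(fitAgeModel(pts, weighted = weighted))
  })
  co <- data.frame(metabolite = metaboliteNames(table),
                   slope = vapply(fits, `[[`, numeric(1), "slope"),
                   intercept = vapply(fits, `[[`, numeric(1), "intercept"),
                   r2 = vapply(fits, `[[`, numeric(1), "r2"),
                   n_strata = vapply(fits, `[[`, numeric(1), "n_points"))
  if (any(is.na(co$slope)))
    warnf("%d metabolite(s) have a null slope and pass through uncorrected",
          sum(is.na(co$slope)))
  new("AgeCorrectionModel", coefficients = co,
      reference_age = as.numeric(reference_age),
      stratum_width = as.numeric(width),
      min_stratum_size = as.integer(min_stratum_size))
}

#' Age-associated concentration delta
#'
#' \code{delta = slope * (age - reference_age)}; zero at the reference age
#' and for null-slope metabolites.
#'
#' @param model an [AgeCorrectionModel-class].
#' @param metabolite metabolite name.
#' @param age age(s) in years.
#' @return numeric delta(s) in concentration units.
#' @examples
#' \dontrun{ageDelta(model, "Cystathionine", 50)}
#' @export
ageDelta <- function(model, metabolite, age) {
  co <- coef(model)
  i <- match(metabolite, co$metabolite)
  if (is.na(i)) stopf("unknown metabolite '%s'", metabolite)
  s <- co$slope[i]
  if (is.na(s)) return(rep(0, length(age)))
  s * (age - model@reference_age)
}

#' Subtract the age-associated delta from every concentration
#'
#' Applies the control-derived correction to all subjects (both groups):
#' \code{adjusted = raw - slope * (age - reference_age)} per metabolite.
#' Adjusted values may be negative; they are preserved (the correction is a
#' statistical transform, not a concentration estimate) and their count is
#' reported, unless \code{clip = TRUE}.
#'
#' @param table a [ConcentrationTable-class].
#' @param model an [AgeCorrectionModel-class] covering all metabolites in
#'   \code{table}; null-slope metabolites pass unchanged.
#' @param clip clip negative adjusted values at zero (default FALSE).
#' @return A new age-adjusted [ConcentrationTable-class]; the input is
#'   untouched. \code{metadata(x)$n_negative_adjusted} records the count of
#'   negative adjusted values.
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 1), buildDefaultPanel())
#' adj <- applyCorrection(tab, fitAgeCorrection(tab))
#' @export
applyCorrection <- function(table, model, clip = FALSE) {
  stopifnot(is(table, "ConcentrationTable"), is(model, "AgeCorrectionModel"))
  co <- coef(model)
  missing <- setdiff(metaboliteNames(table), co$metabolite)
  if (length(missing))
    stopf("model does not cover metabolite(s): %s",
          paste(missing, collapse = ", "))
  conc <- concentrations(table)
  age <- subjectAges(table)
  slopes <- co$slope[match(rownames(conc), co$metabolite)]
  slopes[is.na(slopes)] <- 0
  adj <- conc - outer(slopes, age - model@reference_age)
  n_neg <- sum(adj < 0)
  if (n_neg > 0) {
    if (clip) adj[adj < 0] <- 0
    message(sprintf("%d adjusted value(s) %s", n_neg,
                    if (clip) "clipped at zero" else "are negative (kept)"))
  }
  out <- table
  SummarizedExperiment::assay(out, "concentration") <- adj
  metadata(out)$age_adjusted <- TRUE
  metadata(out)$n_negative_adjusted <- n_neg
  metadata(out)$correction_reference_age <- model@reference_age
  out
}
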