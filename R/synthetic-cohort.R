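#' Cohort simulation settings
#'
#' Group sizes, age summaries (median and interquartile range, as typically
#' reported in a baseline-characteristics table), the RNG seed and the set
#' of metabolites that receive their panel group effect. Defaults emulate
#' the motivating IHD study: 36 controls aged 34 [26-44] years versus 76
#' cases aged 64 [58-71] years.
#'
#' @slot n_control,n_case group sizes.
#' @slot control_age,case_age numeric length-3 vectors (median, q1, q3) in
#'   years.
#' @slot seed integer RNG seed.
#' @slot affected metabolite names receiving their \code{group_log2_effect};
#'   \code{NA} means "all panel metabolites with a non-zero effect".
#' @slot reference_age age at which the generative linear trend equals the
#'   baseline.
#' @seealso [generateCohort()]
#' @export
setClass("CohortConfig",
         representation(n_control = "integer", n_case = "integer",
                        control_age = "numeric", case_age = "numeric",
                        seed = "integer", affected = "character",
                        reference_age = "numeric"))

setValidity("CohortConfig", function(object) {
  if (object@n_control < 1 || object@n_case < 1)
    return("group sizes must be positive")
  for (a in list(object@control_age, object@case_age)) {
    if (length(a) != 3) return("age distributions are (median, q1, q3)")
    if (!(a[2] <= a[1] && a[1] <= a[3]))
      return("age summaries must satisfy q1 <= median <= q3")
    if (a[2] <= 0) return("ages must be positive")
  }
  TRUE
})

#' @rdname CohortConfig-class
#' @param n_control,n_case group sizes.
#' @param control_age,case_age (median, q1, q3) age summaries in years.
#' @param seed integer RNG seed.
#' @param affected metabolites receiving their group effect; default
#'   \code{NA}: every panel metabolite with a non-zero
#'   \code{group_log2_effect}.
#' @param reference_age generative reference age in years.
#' @export
CohortConfig <- function(n_control = 36L, n_case = 76L,
                         control_age = c(34, 26, 44),
                         case_age = c(64, 58, 71),
                         seed = 1L, affected = NA_character_,
                         reference_age = 40) {
  new("CohortConfig", n_control = as.integer(n_control),
      n_case = as.integer(n_case), control_age = as.numeric(control_age),
      case_age = as.numeric(case_age), seed = as.integer(seed),
      affected = as.character(affected),
      reference_age = as.numeric(reference_age))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0("CohortConfig: %d controls (age %g [%g-%g]) vs %d cases",
                     " (age %g [%g-%g]), seed %d\n"),
              object@n_control, object@control_age[1], object@control_age[2],
              object@control_age[3], object@n_case, object@case_age[1],
              object@case_age[2], object@case_age[3], object@seed))
})

#' Sample subject ages matching a median/IQR summary
#'
#' Ages are drawn from a normal distribution with mean equal to the target
#' median and standard deviation IQR/1.349, truncated to [18, 95] years by
#' inverse-CDF sampling. This is the simplest family that reproduces a
#' median/IQR summary of an adult cohort.
#'
#' @param group_dist numeric length-3 vector (median, q1, q3) in years.
#' @param n number of subjects (>= 1).
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @param lower,upper truncation bounds in years.
#' @return numeric vector of \code{n} positive ages.
#' @examples
#' a <- sampleAges(c(34, 26, 44), 1000, seed = 1)
#' median(a)
#' @export
sampleAges <- function(group_dist, n, seed = NULL, lower = 18, upper = 95) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stopf("n must be a positive integer, got %s", deparse(n))
  stopifnot(length(group_dist) == 3)
  med <- group_dist[1]
  iqr <- group_dist[3] - group_dist[2]
  sd <- if (iqr > 0) iqr / (stats::qnorm(0.75) - stats::qnorm(0.25)) else 0
  draw <- function() {
    if (sd == 0) return(rep(med, n))
    plo <- stats::pnorm(lower, med, sd)
    phi <- stats::pnorm(upper, med, sd)
    stats::qnorm(stats::runif(n, plo, phi), med, sd)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Generate a synthetic case-control concentration table
#'
#' For subject \eqn{i} and metabolite \eqn{m} the concentration is
#' \deqn{c_{im} = \max(\epsilon,\; (b_m + s_m (a_i - a_0)) \cdot
#'   2^{\delta_m I[i \in case,\, m \in affected]} \cdot \eta_{im})}
#' with baseline \eqn{b_m}, age slope \eqn{s_m}, reference age \eqn{a_0},
#' log2 group effect \eqn{\delta_m} and multiplicative log-normal noise
#' \eqn{\eta_{im}} with unit mean and the spec's coefficient of variation.
#' The floor \eqn{\epsilon = 10^{-9}} keeps concentrations positive under
#' steep negative trends. The draw is fully deterministic given the config
#' seed; the generating panel and config are stored in
#' \code{metadata(x)$ground_truth}.
#'
#' @param config a [CohortConfig-class].
#' @param panel a [MetabolitePanel-class].
#' @return A [ConcentrationTable-class] with groups \code{control} and
#'   \code{case}.
#' @examples
#' tab <- generateCohort(CohortConfig(seed = 7), buildDefaultPanel())
#' tab
#' @export
generateCohort <- function(config, panel) {
  stopifnot(is(config, "CohortConfig"), is(panel, "MetabolitePanel"))
  sp <- as.data.frame(panel)
  if (nrow(sp) == 0) stopf("empty metabolite panel")
  affected <- config@affected
  if (length(affected) == 1 && is.na(affected))
    affected <- sp$name[sp$group_log2_effect != 0]
  unknown <- setdiff(affected, sp$name)
  if (length(unknown))
    stopf("affected metabolites not in panel: %s",
          paste(unknown, collapse = ", "))

  n_c <- config@n_control
  n_a <- config@n_case
  width5 <- diff(range(config@control_age[2:3])) / 5
  if (width5 > 0 && n_c / max(1, width5) < 2)
    warnf("fewer than ~2 controls per 5-year stratum on average")

  withSeed(config@seed, {
    age <- c(sampleAges(config@control_age, n_c),
             sampleAges(config@case_age, n_a))
    group <- factor(rep(c("control", "case"), c(n_c, n_a)),
                    levels = c("control", "case"))
    # sex frequencies typical of an IHD cohort (~80% / ~86% male)
    sex <- ifelse(stats::runif(n_c + n_a) <
                    ifelse(group == "control", 0.80, 0.86), "m", "f")
    n <- n_c + n_a
    conc <- matrix(NA_real_, nrow(sp), n,
                   dimnames = list(sp$name,
                                   sprintf("S%03d", seq_len(n))))
    is_case <- group == "case"
    for (j in seq_len(nrow(sp))) {
      mu <- sp$baseline[j] + sp$age_slope[j] * (age - config@reference_age)
      eff <- ifelse(is_case & sp$name[j] %in% affected,
                    2 ^ sp$group_log2_effect[j], 1)
      sdl <- sqrt(log(1 + sp$noise_cv[j]^2))
      noise <- stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
      conc[j, ] <- pmax(1e-9, mu * eff * noise)
    }
    tab <- ConcentrationTable(conc, group = group, age = age, sex = sex,
                              class_label = sp$class_label)
    metadata(tab)$ground_truth <- list(panel = sp,
                                       config = configAsList(config),
                                       affected = affected)
    tab
  })
}

#' @rdname generateCohort
#' @param x a generated [ConcentrationTable-class]
#' @return \code{groundTruth}: the list of generative parameters stored at
#'   generation time (panel specs, config, affected set), or \code{NULL}.
#' @export
groundTruth <- function(x) metadata(x)$ground_truth

configAsList <- function(config) {
  list(n_control = config@n_control, n_case = config@n_case,
       control_age = config@control_age, case_age = config@case_age,
       seed = config@seed, affected = config@affected,
       reference_age = config@reference_age)
}

#' Study-flow exclusion arithmetic
#'
#' Final group size after screening and exclusions:
#' \code{enrolled - sum(exclusions)}.
#'
#' @param enrolled non-negative integer count of initially enrolled subjects.
#' @param exclusions non-negative integer vector of exclusion counts.
#' @return integer final group size.
#' @examples
#' cohortFlowFilter(84, c(diet = 5, alcohol = 3))  # 76
#' cohortFlowFilter(43, c(diet = 4, alcohol = 3))  # 36
#' @export
cohortFlowFilter <- function(enrolled, exclusions = integer()) {
  if (length(enrolled) != 1 || is.na(enrolled) || enrolled < 0 ||
      enrolled != round(enrolled))
    stopf("enrolled must be a single non-negative integer")
  if (length(exclusions) && (anyNA(exclusions) || any(exclusions < 0) ||
                             any(exclusions != round(exclusions))))
    stopf("exclusions must be non-negative integers")
  total <- sum(exclusions)
  if (total > enrolled)
    stopf("exclusions (%d) exceed enrolled (%d)", total, enrolled)
  as.integer(enrolled - total)
}
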