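#' Read and write concentration tables as delimited text
#'
#' The on-disk layout is wide: a header row, then one row per subject with
#' columns \code{subject_id}, \code{group}, \code{age}, \code{sex}
#' followed by one numeric column per metabolite. Metabolite column names
#' are matched case- and whitespace-insensitively and short panel codes
#' (C0, C16-OH, ADMA, ...) are resolved via [metaboliteAliases()].
#'
#' @param path file path; \code{.tsv}/\code{.txt} files are read and
#'   written tab-separated, anything else comma-separated.
#' @param group_levels two labels, control group first, used to order the
#'   group factor; defaults to the file order of appearance with
#'   \code{"control"}/\code{"case"} recognised.
#' @return \code{readConcentrationTable}: a [ConcentrationTable-class].
#' @examples
#' tab <- generateCohort(CohortConfig(n_control = 5, n_case = 5, seed = 1),
#'                       buildDefaultPanel())
#' f <- tempfile(fileext = ".csv")
#' writeConcentrationTable(tab, f)
#' tab2 <- readConcentrationTable(f)
#' @export
readConcentrationTable <- function(path, group_levels = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("empty table: %s", path)
  is_meta <- tolower(trimws(names(df))) %in% c("subject_id", "group",
                                               "age", "sex")
  names(df)[is_meta] <- tolower(trimws(names(df)[is_meta]))
  need <- c("subject_id", "group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stopf("duplicated subject_id: %s", paste(unique(dup), collapse = ", "))
  meta_cols <- intersect(c("subject_id", "group", "age", "sex"), names(df))
  met_cols <- setdiff(names(df), meta_cols)
  if (!length(met_cols)) stopf("no metabolite columns found")
  conc <- matrix(NA_real_, length(met_cols), nrow(df),
                 dimnames = list(canonicalNames(met_cols), df$subject_id))
  for (j in seq_along(met_cols)) {
    v <- df[[met_cols[j]]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v))
        stopf("non-numeric concentration in column '%s', row %d",
              met_cols[j], which(is.na(num))[1])
      v <- num
    }
    conc[j, ] <- v
  }
  if (anyDuplicated(rownames(conc)))
    stopf("metabolite columns collapse to duplicate names after %s",
          "normalization")
  grp <- as.character(df$group)
  if (is.null(group_levels)) {
    group_levels <- unique(grp)
    if (all(c("control", "case") %in% group_levels))
      group_levels <- c("control", "case")
    if (length(group_levels) != 2)
      stopf("group column must have exactly 2 labels, found: %s",
            paste(group_levels, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age)) stopf("non-numeric or missing age values")
  ConcentrationTable(conc, group = factor(grp, levels = group_levels),
                     age = age,
                     sex = if ("sex" %in% names(df)) df$sex else NULL,
                     subject_id = df$subject_id)
}

canonicalNames <- function(x) {
  ali <- metaboliteAliases()
  key <- trimws(x)
  hit <- match(toupper(key), toupper(names(ali)))
  ifelse(!is.na(hit), unname(ali[hit]), key)
}

#' @rdname readConcentrationTable
#' @param table a [ConcentrationTable-class].
#' @return \code{writeConcentrationTable}: the path, invisibly.
#' @export
writeConcentrationTable <- function(table, path) {
  stopifnot(is(table, "ConcentrationTable"))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  cd <- colData(table)
  df <- data.frame(subject_id = cd$subject_id,
                   group = as.character(cd$group), age = cd$age,
                   sex = cd$sex, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(concentrations(table)),
                                check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize the age-correction model as delimited text
#'
#' One row per metabolite (name, slope, intercept, r2, n_strata) plus a
#' commented header carrying the global settings — the package's analogue
#' of a published conversion-factor table.
#'
#' @param model an [AgeCorrectionModel-class].
#' @param path output file path (comma-separated).
#' @return the path, invisibly.
#' @export
writeAgeCorrectionModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference_age=%g stratum_width=%g min_stratum_size=%d",
                     model@reference_age, model@stratum_width,
                     model@min_stratum_size), con)
  utils::write.csv(coef(model), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAgeCorrectionModel
#' @return \code{readAgeCorrectionModel}: the deserialized
#'   [AgeCorrectionModel-class].
#' @export
readAgeCorrectionModel <- function(path) {
  hdr <- readLines(path, n = 1)
  g <- function(k) as.numeric(sub(sprintf(".*%s=([-0-9.]+).*", k), "\\1", hdr))
  co <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new("AgeCorrectionModel", coefficients = co,
      reference_age = g("reference_age"), stratum_width = g("stratum_width"),
      min_stratum_size = as.integer(g("min_stratum_size")))
}

#' Serialize generative ground truth
#'
#' Writes the panel specs and cohort configuration of a generated table as
#' a YAML document; [readGroundTruth()] restores them losslessly, enabling
#' parameter-recovery studies on stored cohorts.
#'
#' @param truth list as stored by [generateCohort()] in
#'   \code{metadata(x)$ground_truth}.
#' @param path YAML file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  yaml::write_yaml(list(panel = truth$panel, config = truth$config,
                        affected = truth$affected), path,
                   precision = 15)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return \code{readGroundTruth}: list with elements \code{panel}
#'   (data.frame), \code{config} (list) and \code{affected}.
#' @export
readGroundTruth <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$panel <- as.data.frame(lapply(raw$panel, unlist),
                             stringsAsFactors = FALSE)
  raw$config[c("control_age", "case_age")] <-
    lapply(raw$config[c("control_age", "case_age")], unlist)
  raw$affected <- unlist(raw$affected)
  raw
}

#' Run the full diagnostic pipeline
#'
#' Executes, in order: cohort simulation (or loading), PCA overview, age
#' adjustment estimated on the control group, derived-ratio computation,
#' univariate screening, the five-classifier stage and consensus panel
#' selection. All stages are deterministic given the seeds in
#' \code{config}. When \code{config$out_dir} is set, the intermediate
#' tables (raw and adjusted cohort, correction coefficients, screen
#' results, per-model metrics and ROC points, consensus panel) are written
#' as delimited text.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure) with elements: either \code{input} (path of a
#'   concentration table) or \code{simulate} (list of [CohortConfig()]
#'   arguments); optional \code{stratum_width} (default 5),
#'   \code{reference_age} (default \code{"auto"}), \code{p_thresh} (0.05),
#'   \code{auc_thresh} (0.65), \code{folds} (5), \code{seed} (1),
#'   \code{fast_models} (FALSE), \code{out_dir}.
#' @return an object of class \code{RunReport}: list with the config echo,
#'   per-stage summaries, the [ModelEvaluation-class] list, consensus
#'   panel and collected warnings.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(simulate = list(seed = 1), folds = 3,
#'                         fast_models = TRUE, seed = 1))
#' rep$consensus
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$input) && is.null(config$simulate))
    stopf("config needs either 'input' or 'simulate'")
  if (!is.null(config$input) && !file.exists(config$input))
    stopf("input table not found: %s", config$input)
  cfg <- utils::modifyList(
    list(stratum_width = 5, reference_age = "auto", p_thresh = 0.05,
         auc_thresh = 0.65, folds = 5, seed = 1L, fast_models = FALSE,
         top_k = 15, min_models = 3, out_dir = NULL),
    config)
  warnings_log <- character()
  logw <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run <- function(expr) withCallingHandlers(expr, warning = logw)

  raw <- if (!is.null(cfg$input)) run(readConcentrationTable(cfg$input))
         else run(generateCohort(do.call(CohortConfig, cfg$simulate),
                                 buildDefaultPanel()))
  overview <- run(pcaOverview(raw))
  model <- run(fitAgeCorrection(raw, width = cfg$stratum_width,
                                reference_age = cfg$reference_age))
  adjusted <- suppressMessages(run(applyCorrection(raw, model)))
  adjusted <- run(deriveRatios(adjusted))
  raw_ratios <- run(deriveRatios(raw))
  screen <- run(screenMetabolites(adjusted, raw = raw_ratios,
                                  p_thresh = cfg$p_thresh,
                                  auc_thresh = cfg$auc_thresh))
  specs <- defaultModelSpecs(seed = cfg$seed, fast = cfg$fast_models)
  models <- run(runAllModels(adjusted, specs, screen = screen,
                             folds = cfg$folds, seed = cfg$seed,
                             top_k = cfg$top_k,
                             min_models = cfg$min_models))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(cfg$out_dir, ...)
    writeConcentrationTable(raw, p("cohort_raw.csv"))
    writeConcentrationTable(adjusted, p("cohort_adjusted.csv"))
    writeAgeCorrectionModel(model, p("age_correction.csv"))
    utils::write.csv(as.data.frame(screen), p("screen_results.csv"),
                     row.names = FALSE)
    utils::write.csv(models$metrics_table, p("model_metrics.csv"),
                     row.names = FALSE)
    for (nm in names(models$evaluations))
      utils::write.csv(rocPoints(models$evaluations[[nm]]),
                       p(sprintf("roc_%s.csv", nm)), row.names = FALSE)
    utils::write.csv(models$consensus, p("consensus_panel.csv"),
                     row.names = FALSE)
    if (!is.null(groundTruth(raw)))
      writeGroundTruth(groundTruth(raw), p("ground_truth.yaml"))
  }
  structure(list(
    config = cfg,
    n_subjects = ncol(raw),
    n_metabolites = nrow(raw),
    pca_outliers = sum(overview$outlier),
    strata_used = max(coef(model)$n_strata, na.rm = TRUE),
    n_null_slope = sum(is.na(coef(model)$slope)),
    n_negative_adjusted = metadata(adjusted)$n_negative_adjusted,
    reference_age = referenceAge(model),
    n_pass_filter = sum(screen$passes_filter),
    screen = screen,
    correction = model,
    evaluations = models$evaluations,
    metrics_table = models$metrics_table,
    consensus = models$consensus,
    warnings = warnings_log), class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  cat(sprintf("  cohort: %d subjects x %d metabolites\n", x$n_subjects,
              x$n_metabolites))
  cat(sprintf("  PCA outlier flags: %d\n", x$pca_outliers))
  cat(sprintf("  age correction: reference %g y, %d null slopes, %d %s\n",
              x$reference_age, x$n_null_slope, x$n_negative_adjusted,
              "negative adjusted values"))
  cat(sprintf("  univariate screen: %d features pass the filter\n",
              x$n_pass_filter))
  mt <- x$metrics_table
  mt[, 6:11] <- round(mt[, 6:11], 2)
  print(mt, row.names = FALSE)
  cat(sprintf("  consensus panel: %s\n",
              paste(x$consensus$feature, collapse = "; ")))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s) collected; see $warnings\n",
                length(x$warnings)))
  invisible(x)
}
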