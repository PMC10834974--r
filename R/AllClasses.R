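#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<- colData<-
NULL

.METABOLITE_CLASSES <- c("acylcarnitine", "amino_acid", "tryptophan_pathway",
                         "no_urea_cycle", "cystathionine_cycle", "ratio",
                         "other")

#' Panel of metabolite generative specifications
#'
#' A \code{MetabolitePanel} holds one row per metabolite with the generative
#' parameters used by [generateCohort()]: baseline concentration at the
#' reference age, a linear age slope, a log2 group effect applied to cases,
#' and the coefficient of variation of the multiplicative log-normal noise.
#'
#' @slot specs data.frame with columns \code{name}, \code{class_label},
#'   \code{baseline}, \code{age_slope}, \code{group_log2_effect},
#'   \code{noise_cv}.
#'
#' @seealso [buildDefaultPanel()], [generateCohort()]
#' @export
setClass("MetabolitePanel", representation(specs = "data.frame"))

setValidity("MetabolitePanel", function(object) {
  sp <- object@specs
  need <- c("name", "class_label", "baseline", "age_slope",
            "group_log2_effect", "noise_cv")
  if (!all(need %in% names(sp)))
    return(paste("specs must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp) == 0) return("panel is empty")
  if (anyDuplicated(sp$name)) return("metabolite names must be unique")
  if (any(!is.finite(sp$baseline)) || any(sp$baseline <= 0))
    return("baseline must be positive and finite")
  if (any(!is.finite(sp$noise_cv)) || any(sp$noise_cv <= 0))
    return("noise_cv must be positive and finite")
  if (!all(sp$class_label %in% .METABOLITE_CLASSES))
    return(paste("class_label must be one of:",
                 paste(.METABOLITE_CLASSES, collapse = ", ")))
  TRUE
})

#' Construct a MetabolitePanel
#'
#' @param specs data.frame of per-metabolite generative parameters; see
#'   the class documentation for required columns.
#' @return A [MetabolitePanel-class] object.
#' @examples
#' panel <- MetabolitePanel(data.frame(
#'   name = c("Glycine", "Serotonin"),
#'   class_label = c("amino_acid", "tryptophan_pathway"),
#'   baseline = c(220, 0.6), age_slope = c(0, 0.002),
#'   group_log2_effect = c(-0.6, 0.8), noise_cv = c(0.25, 0.25)))
#' panel
#' @export
MetabolitePanel <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  rownames(specs) <- NULL
  new("MetabolitePanel", specs = specs)
}

#' @describeIn MetabolitePanel-class number of metabolites in the panel
#' @param x a \code{MetabolitePanel}
#' @export
setMethod("length", "MetabolitePanel", function(x) nrow(x@specs))

#' @describeIn MetabolitePanel-class metabolite names
#' @export
setMethod("names", "MetabolitePanel", function(x) x@specs$name)

#' Coerce a MetabolitePanel to a data.frame of specs
#' @param x a \code{MetabolitePanel}
#' @param ... ignored
#' @export
setMethod("as.data.frame", "MetabolitePanel",
          function(x, ...) x@specs)

setMethod("show", "MetabolitePanel", function(object) {
  cat("MetabolitePanel with", length(object), "metabolites\n")
  print(table(object@specs$class_label))
  aff <- sum(object@specs$group_log2_effect != 0)
  cat(aff, "metabolites carry a non-zero group effect\n")
})

#' Subject-by-metabolite concentration container
#'
#' \code{ConcentrationTable} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"concentration"} stores metabolites as rows and subjects as columns;
#' \code{colData} carries \code{subject_id}, \code{group} (a two-level factor
#' whose first level is the control/reference group), \code{age} in years and
#' optionally \code{sex}; \code{rowData} carries the metabolite
#' \code{class_label}. Raw tables are non-negative; age-adjusted tables may
#' contain negative values (the correction is a statistical transform, not a
#' concentration estimate).
#'
#' @seealso [generateCohort()], [readConcentrationTable()], [applyCorrection()]
#' @export
setClass("ConcentrationTable", contains = "SummarizedExperiment")

setValidity("ConcentrationTable", function(object) {
  if (!"concentration" %in% SummarizedExperiment::assayNames(object))
    return("assay 'concentration' is required")
  cd <- colData(object)
  for (col in c("subject_id", "group", "age"))
    if (!col %in% names(cd)) return(paste("colData column", col, "is required"))
  if (anyDuplicated(cd$subject_id))
    return("subject_id values must be unique")
  if (!is.factor(cd$group) || nlevels(cd$group) != 2)
    return("group must be a factor with exactly 2 levels (control, case)")
  if (anyNA(cd$group) || anyNA(cd$age))
    return("group and age must not contain missing values")
  if (!is.numeric(cd$age) || any(cd$age <= 0))
    return("age must be positive")
  if (!"class_label" %in% names(rowData(object)))
    return("rowData column class_label is required")
  TRUE
})

#' Construct a ConcentrationTable
#'
#' @param concentration numeric matrix, metabolites x subjects, with
#'   dimnames.
#' @param group two-level factor (or character coerced to one); the first
#'   level is the control group.
#' @param age numeric vector of ages in years.
#' @param sex optional character/factor vector.
#' @param class_label metabolite class per row; defaults to "other".
#' @param subject_id subject identifiers; default the column names.
#' @return A [ConcentrationTable-class] object.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(c("Glycine", "Serine", "Carnitine"),
#'                             paste0("S", 1:4)))
#' ConcentrationTable(m, group = c("control", "control", "case", "case"),
#'                    age = c(30, 40, 60, 65))
#' @export
ConcentrationTable <- function(concentration, group, age, sex = NULL,
                               class_label = NULL, subject_id = NULL) {
  concentration <- as.matrix(concentration)
  if (is.null(subject_id)) subject_id <- colnames(concentration)
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(ncol(concentration)))
  colnames(concentration) <- subject_id
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (is.null(class_label)) class_label <- rep("other", nrow(concentration))
  cd <- DataFrame(subject_id = subject_id, group = group, age = age)
  cd$sex <- if (is.null(sex)) NA_character_ else as.character(sex)
  rd <- DataFrame(class_label = class_label,
                  row.names = rownames(concentration))
  new("ConcentrationTable",
      SummarizedExperiment(assays = list(concentration = concentration),
                           colData = cd, rowData = rd))
}

#' Accessors for ConcentrationTable
#'
#' \code{concentrations} returns the metabolites x subjects matrix;
#' \code{metaboliteNames} the row names; \code{subjectGroups} the two-level
#' group factor; \code{subjectAges} the ages; \code{controlLevel} /
#' \code{caseLevel} the group labels.
#'
#' @param x a [ConcentrationTable-class]
#' @return see individual descriptions.
#' @name concentration-accessors
NULL

#' @rdname concentration-accessors
#' @export
concentrations <- function(x) assay(x, "concentration")

#' @rdname concentration-accessors
#' @export
metaboliteNames <- function(x) rownames(x)

#' @rdname concentration-accessors
#' @export
subjectGroups <- function(x) colData(x)$group

#' @rdname concentration-accessors
#' @export
subjectAges <- function(x) colData(x)$age

#' @rdname concentration-accessors
#' @export
controlLevel <- function(x) levels(subjectGroups(x))[1L]

#' @rdname concentration-accessors
#' @export
caseLevel <- function(x) levels(subjectGroups(x))[2L]

setMethod("show", "ConcentrationTable", function(object) {
  g <- table(subjectGroups(object))
  cat("ConcentrationTable:", nrow(object), "metabolites x", ncol(object),
      "subjects\n")
  cat(sprintf("  groups: %s (n = %d, reference) vs %s (n = %d)\n",
              names(g)[1], g[1], names(g)[2], g[2]))
  a <- subjectAges(object)
  cat(sprintf("  age range: %.0f-%.0f years\n", min(a), max(a)))
  if (!is.null(metadata(object)$age_adjusted) &&
      isTRUE(metadata(object)$age_adjusted))
    cat("  values are age-adjusted\n")
})

#' Per-metabolite age-correction model
#'
#' Stores ordinary-least-squares coefficients fitted to control-group
#' stratum medians (one row per metabolite) together with the global
#' correction settings. The predicted age-associated delta for a subject is
#' \code{slope * (age - reference_age)}; metabolites with a null (NA) slope
#' pass through [applyCorrection()] unchanged.
#'
#' @slot coefficients data.frame with columns \code{metabolite},
#'   \code{slope}, \code{intercept}, \code{r2}, \code{n_strata}.
#' @slot reference_age age (years) at which the correction delta is zero.
#' @slot stratum_width width of the age strata in years.
#' @slot min_stratum_size minimum control count for a stratum to be used.
#'
#' @seealso [fitAgeCorrection()], [applyCorrection()], [ageDelta()]
#' @export
setClass("AgeCorrectionModel",
         representation(coefficients = "data.frame",
                        reference_age = "numeric",
                        stratum_width = "numeric",
                        min_stratum_size = "integer"))

setValidity("AgeCorrectionModel", function(object) {
  co <- object@coefficients
  need <- c("metabolite", "slope", "intercept", "r2", "n_strata")
  if (!all(need %in% names(co)))
    return(paste("coefficients must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(co$metabolite)) return("duplicate metabolite rows")
  bad <- !is.na(co$slope) & (!is.finite(co$slope) | co$n_strata < 2)
  if (any(bad))
    return("non-null slopes must be finite and based on >= 2 strata")
  if (length(object@reference_age) != 1 || !is.finite(object@reference_age))
    return("reference_age must be a single finite number")
  TRUE
})

setMethod("show", "AgeCorrectionModel", function(object) {
  co <- object@coefficients
  cat("AgeCorrectionModel for", nrow(co), "metabolites\n")
  cat(sprintf("  reference age %.0f y, stratum width %.0f y, min stratum size %d\n",
              object@reference_age, object@stratum_width,
              object@min_stratum_size))
  cat(sprintf("  %d metabolites with null slope (uncorrected)\n",
              sum(is.na(co$slope))))
})

#' @rdname AgeCorrectionModel-class
#' @param object an \code{AgeCorrectionModel}
#' @param ... ignored
#' @export
setMethod("coef", "AgeCorrectionModel", function(object, ...)
  object@coefficients)

#' @rdname AgeCorrectionModel-class
#' @export
referenceAge <- function(object) object@reference_age

#' Two-by-two confusion matrix
#'
#' Counts of true positives, false positives, false negatives and true
#' negatives from a binary classification.
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @seealso [cmMetrics()]
#' @export
setClass("ConfusionMatrix",
         representation(tp = "integer", fp = "integer",
                        fn = "integer", tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4 || anyNA(v) || any(v < 0))
    return("tp, fp, fn, tn must be single non-negative counts")
  if (sum(v) == 0) return("confusion matrix is empty")
  TRUE
})

#' @rdname ConfusionMatrix-class
#' @param tp,fp,fn,tn non-negative counts.
#' @return a \code{ConfusionMatrix} object.
#' @examples
#' ConfusionMatrix(26, 0, 8, 74)
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  cat("ConfusionMatrix (TP, FP, FN, TN) =",
      paste(c(object@tp, object@fp, object@fn, object@tn), collapse = ", "),
      "\n")
  print(m)
})

#' Evaluation of one diagnostic classifier
#'
#' Holds the pooled out-of-fold evaluation of one classifier family:
#' selected hyper-parameters, confusion matrix at the decision threshold,
#' derived metrics, ROC points, and the ranked feature set used for
#' consensus selection.
#'
#' @slot algorithm one of \code{logistic_regression}, \code{svm_linear},
#'   \code{decision_tree}, \code{random_forest}, \code{gradient_boosting}.
#' @slot best_hyperparameters named list.
#' @slot cm a [ConfusionMatrix-class].
#' @slot metrics named numeric vector (sensitivity, specificity, accuracy,
#'   precision, recall, f1, youden_j, auc_roc).
#' @slot roc_points data.frame with columns fpr, tpr.
#' @slot feature_importance data.frame with columns feature, importance,
#'   ranked decreasing.
#' @slot scores pooled out-of-fold scores (probability of the case class).
#' @slot labels true group labels aligned with scores.
#' @export
setClass("ModelEvaluation",
         representation(algorithm = "character",
                        best_hyperparameters = "list",
                        cm = "ConfusionMatrix",
                        metrics = "numeric",
                        roc_points = "data.frame",
                        feature_importance = "data.frame",
                        scores = "numeric",
                        labels = "factor"))

setMethod("show", "ModelEvaluation", function(object) {
  cat("ModelEvaluation:", object@algorithm, "\n")
  cat("  confusion (TP, FP, FN, TN):",
      paste(c(object@cm@tp, object@cm@fp, object@cm@fn, object@cm@tn),
            collapse = ", "), "\n")
  m <- object@metrics
  cat(sprintf("  sens %.2f  spec %.2f  acc %.2f  f1 %.2f  AUC %.2f\n",
              m["sensitivity"], m["specificity"], m["accuracy"], m["f1"],
              m["auc_roc"]))
})

#' @rdname ModelEvaluation-class
#' @param object a \code{ModelEvaluation}
#' @export
evaluationMetrics <- function(object) object@metrics

#' @rdname ModelEvaluation-class
#' @export
confusion <- function(object) object@cm

#' @rdname ModelEvaluation-class
#' @export
rocPoints <- function(object) object@roc_points

#' @rdname ModelEvaluation-class
#' @export
featureImportance <- function(object) object@feature_importance

#' Classifier specification for grid-search tuning
#'
#' @slot algorithm classifier family label.
#' @slot grid data.frame of candidate hyper-parameter combinations (one row
#'   per combination).
#' @slot cv_folds folds of the inner tuning cross-validation.
#' @slot scoring scoring label (only \code{"auc"} is implemented).
#' @slot seed integer seed controlling fold assignment and stochastic fits.
#' @seealso [defaultModelSpecs()], [tuneAndFit()]
#' @export
setClass("ModelSpec",
         representation(algorithm = "character", grid = "data.frame",
                        cv_folds = "integer", scoring = "character",
                        seed = "integer"))

.MODEL_ALGORITHMS <- c("logistic_regression", "svm_linear", "decision_tree",
                       "random_forest", "gradient_boosting")

setValidity("ModelSpec", function(object) {
  if (!object@algorithm %in% .MODEL_ALGORITHMS)
    return(paste("algorithm must be one of:",
                 paste(.MODEL_ALGORITHMS, collapse = ", ")))
  if (nrow(object@grid) < 1) return("hyperparameter grid must be non-empty")
  if (object@cv_folds < 2) return("cv_folds must be >= 2")
  TRUE
})

#' @rdname ModelSpec-class
#' @param algorithm classifier family label.
#' @param grid data.frame (or list expanded via [expand.grid()]) of
#'   candidate hyper-parameters.
#' @param cv_folds inner cross-validation folds used for tuning.
#' @param scoring scoring label.
#' @param seed integer seed.
#' @export
ModelSpec <- function(algorithm, grid, cv_folds = 3L, scoring = "auc",
                      seed = 1L) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid, stringsAsFactors = FALSE)
  new("ModelSpec", algorithm = algorithm, grid = grid,
      cv_folds = as.integer(cv_folds), scoring = scoring,
      seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (%d grid point%s, %d-fold tuning CV, seed %d)\n",
              object@algorithm, nrow(object@grid),
              if (nrow(object@grid) == 1) "" else "s",
              object@cv_folds, object@seed))
})
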