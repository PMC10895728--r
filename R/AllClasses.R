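#' @import methods
#' @importFrom stats median pnorm ks.test t.test wilcox.test p.adjust phyper
#'   quantile approx rnorm rgamma rpois runif sd setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

.VALID_UNITS <- c("g", "mg", "ug")

#' Food-composition table
#'
#' Per-100 g energy and nutrient contents for a catalogue of foods, organised
#' in a three-level hierarchy (group > subgroup > item, e.g. "oils, butter and
#' margarine" > "oils and vegetable fats" > "olive oil"). Each nutrient column
#' carries exactly one declared unit (g, mg or ug) table-wide.
#'
#' @slot table data.frame with columns `food_id`, `name`, `group`, `subgroup`,
#'   `item`, `energy_kcal_per_100g`, and one numeric column per nutrient
#'   (amount per 100 g edible portion).
#' @slot units named character vector, one unit per nutrient column.
#' @export
setClass("FoodComposition",
  representation(table = "data.frame", units = "character"))

setValidity("FoodComposition", function(object) {
  tab <- object@table
  need <- c("food_id", "name", "group", "subgroup", "item",
            "energy_kcal_per_100g")
  if (!all(need %in% names(tab)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  dup <- tab$food_id[duplicated(tab$food_id)]
  if (length(dup))
    return(paste("duplicated food_id:", paste(unique(dup), collapse = ", ")))
  nut <- setdiff(names(tab), need)
  if (!setequal(nut, names(object@units)))
    return("units must name exactly the nutrient columns")
  bad <- setdiff(object@units, .VALID_UNITS)
  if (length(bad))
    return(paste("unknown nutrient unit:", paste(unique(bad), collapse = ", ")))
  vals <- as.matrix(tab[, c("energy_kcal_per_100g", nut), drop = FALSE])
  if (any(!is.na(vals) & vals < 0))
    return("energy and nutrient amounts must be >= 0")
  TRUE
})

#' Per-subject mean daily intakes
#'
#' Mean daily energy, nutrient intakes (averaged over the full 7-day record;
#' days with no entries count as zero intake) and food-group intakes at the
#' group, subgroup and item levels of the composition hierarchy.
#'
#' @slot subjects character vector of subject identifiers.
#' @slot energy named numeric, kcal/day per subject.
#' @slot nutrients numeric matrix, subjects x nutrients, amount/day in the
#'   nutrient's native unit.
#' @slot units named character, unit per nutrient column.
#' @slot groupIntake data.frame `subject_id`, `level` (group/subgroup/item),
#'   `name`, `g_per_day`.
#' @export
setClass("IntakeProfiles",
  representation(subjects = "character", energy = "numeric",
                 nutrients = "matrix", units = "character",
                 groupIntake = "data.frame"))

setValidity("IntakeProfiles", function(object) {
  if (anyDuplicated(object@subjects)) return("duplicated subject ids")
  if (!identical(names(object@energy), object@subjects))
    return("energy must be named by subjects, in order")
  if (!identical(rownames(object@nutrients), object@subjects))
    return("nutrient matrix rows must match subjects")
  if (!setequal(colnames(object@nutrients), names(object@units)))
    return("units must name the nutrient columns")
  if (any(object@energy < 0) || any(object@nutrients < 0))
    return("intakes must be >= 0")
  TRUE
})

#' DII reference table
#'
#' Per-parameter global mean and standard deviation of daily intake, and the
#' literature-derived inflammatory effect score in [-1, +1] (negative =
#' anti-inflammatory). These values are configuration: the packaged defaults
#' are illustrative, not the published global database.
#'
#' @slot table data.frame `parameter`, `unit`, `global_mean`, `global_sd`,
#'   `effect_score`.
#' @slot quantiles named list; optional empirical reference quantiles per
#'   parameter (probabilities attached as names), used instead of the normal
#'   CDF when present.
#' @export
setClass("DIIReference",
  representation(table = "data.frame", quantiles = "list"))

setValidity("DIIReference", function(object) {
  tab <- object@table
  need <- c("parameter", "unit", "global_mean", "global_sd", "effect_score")
  if (!all(need %in% names(tab)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  if (anyDuplicated(tab$parameter)) return("parameters must be unique")
  if (any(tab$global_sd <= 0)) return("global_sd must be > 0")
  if (any(abs(tab$effect_score) > 1))
    return("effect_score must lie in [-1, +1]")
  if (length(object@quantiles) &&
      !all(names(object@quantiles) %in% tab$parameter))
    return("quantiles must be named by reference parameters")
  TRUE
})

#' Per-subject DII scores with contribution breakdown
#'
#' @slot totals data.frame `subject_id`, `dii_total`, `n_parameters_used`.
#' @slot contributions data.frame `subject_id`, `parameter`, `intake`, `z`,
#'   `centered_percentile`, `contribution`.
#' @export
setClass("DIIResult",
  representation(totals = "data.frame", contributions = "data.frame"))

setValidity("DIIResult", function(object) {
  tot <- object@totals
  if (!all(c("subject_id", "dii_total", "n_parameters_used") %in% names(tot)))
    return("totals must have subject_id, dii_total, n_parameters_used")
  agg <- tapply(object@contributions$contribution,
                object@contributions$subject_id, sum)
  chk <- tot$dii_total[match(names(agg), tot$subject_id)]
  if (any(abs(chk - agg) > 1e-8))
    return("dii_total must equal the sum of contributions")
  TRUE
})

#' Median split of a cohort on DII
#'
#' Subjects at or above the sample median are labelled "high", the rest "low"
#' (tie-to-upper rule, which reproduces a 332/331 split for 663 distinct
#' values).
#'
#' @slot subjects character subject ids.
#' @slot dii numeric DII per subject.
#' @slot medianDII numeric scalar, the sample median.
#' @slot label factor with levels low, high.
#' @export
setClass("CohortSplit",
  representation(subjects = "character", dii = "numeric",
                 medianDII = "numeric", label = "factor"))

setValidity("CohortSplit", function(object) {
  if (anyDuplicated(object@subjects)) return("duplicated subject ids")
  if (length(object@dii) != length(object@subjects) ||
      length(object@label) != length(object@subjects))
    return("dii and label must match subjects in length")
  if (!identical(levels(object@label), c("low", "high")))
    return("label levels must be low, high")
  if (any((object@dii >= object@medianDII) != (object@label == "high")))
    return("labels inconsistent with the tie-to-upper median rule")
  TRUE
})

#' NPX experiment container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay `npx`
#' of log2-scale relative protein abundances, rows = proteins, columns =
#' subjects. Missing values are allowed and dropped pairwise downstream.
#'
#' @export
#' @import SummarizedExperiment
setClass("NPXExperiment", contains = "SummarizedExperiment")

setValidity("NPXExperiment", function(object) {
  if (!"npx" %in% assayNames(object)) return("assay 'npx' is required")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("protein (row) and subject (column) names are required")
  if (anyDuplicated(rownames(object))) return("duplicated protein ids")
  if (anyDuplicated(colnames(object))) return("duplicated subject ids")
  TRUE
})
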