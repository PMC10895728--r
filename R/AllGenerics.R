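#' @rdname FoodComposition-class
#' @param x a `FoodComposition`
#' @export
setGeneric("foodTable", function(x) standardGeneric("foodTable"))
#' @rdname FoodComposition-class
#' @export
setGeneric("nutrientUnits", function(x) standardGeneric("nutrientUnits"))
#' @rdname IntakeProfiles-class
#' @param x an `IntakeProfiles`
#' @export
setGeneric("intakeMatrix", function(x) standardGeneric("intakeMatrix"))
#' @rdname IntakeProfiles-class
#' @export
setGeneric("dailyEnergy", function(x) standardGeneric("dailyEnergy"))
#' @rdname IntakeProfiles-class
#' @export
setGeneric("foodGroupIntake", function(x) standardGeneric("foodGroupIntake"))
#' @rdname DIIReference-class
#' @param x a `DIIReference`
#' @export
setGeneric("referenceTable", function(x) standardGeneric("referenceTable"))
#' @rdname DIIResult-class
#' @param x a `DIIResult`
#' @export
setGeneric("diiTotals", function(x) standardGeneric("diiTotals"))
#' @rdname DIIResult-class
#' @export
setGeneric("diiContributions", function(x) standardGeneric("diiContributions"))
#' @rdname CohortSplit-class
#' @param x a `CohortSplit`
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname CohortSplit-class
#' @export
setGeneric("medianDII", function(x) standardGeneric("medianDII"))
#' @rdname NPXExperiment-class
#' @param x an `NPXExperiment`
#' @export
setGeneric("npx", function(x) standardGeneric("npx"))

#' @rdname FoodComposition-class
setMethod("foodTable", "FoodComposition", function(x) x@table)
#' @rdname FoodComposition-class
setMethod("nutrientUnits", "FoodComposition", function(x) x@units)
#' @rdname IntakeProfiles-class
setMethod("intakeMatrix", "IntakeProfiles", function(x) x@nutrients)
#' @rdname IntakeProfiles-class
setMethod("dailyEnergy", "IntakeProfiles", function(x) x@energy)
#' @rdname IntakeProfiles-class
setMethod("foodGroupIntake", "IntakeProfiles", function(x) x@groupIntake)
#' @rdname IntakeProfiles-class
setMethod("nutrientUnits", "IntakeProfiles", function(x) x@units)
#' @rdname DIIReference-class
setMethod("referenceTable", "DIIReference", function(x) x@table)
#' @rdname DIIResult-class
setMethod("diiTotals", "DIIResult", function(x) x@totals)
#' @rdname DIIResult-class
setMethod("diiContributions", "DIIResult", function(x) x@contributions)
#' @rdname CohortSplit-class
setMethod("groupLabels", "CohortSplit", function(x)
  setNames(x@label, x@subjects))
#' @rdname CohortSplit-class
setMethod("medianDII", "CohortSplit", function(x) x@medianDII)
#' @rdname NPXExperiment-class
setMethod("npx", "NPXExperiment", function(x) assay(x, "npx"))

setMethod("show", "FoodComposition", function(object) {
  cat("FoodComposition:", nrow(object@table), "foods,",
      length(object@units), "nutrients\n")
  cat("  groups:", paste(unique(object@table$group), collapse = ", "), "\n")
})

setMethod("show", "IntakeProfiles", function(object) {
  cat("IntakeProfiles:", length(object@subjects), "subjects,",
      ncol(object@nutrients), "nutrients\n")
  cat("  mean daily energy:",
      sprintf("%.0f kcal/day (range %.0f-%.0f)", mean(object@energy),
              min(object@energy), max(object@energy)), "\n")
})

setMethod("show", "DIIReference", function(object) {
  cat("DIIReference:", nrow(object@table), "parameters; effect scores in [",
      sprintf("%.2f, %.2f", min(object@table$effect_score),
              max(object@table$effect_score)), "]\n")
})

setMethod("show", "DIIResult", function(object) {
  cat("DIIResult:", nrow(object@totals), "subjects; DII range",
      sprintf("[%.3f, %.3f]", min(object@totals$dii_total),
              max(object@totals$dii_total)), "\n")
})

setMethod("show", "CohortSplit", function(object) {
  n <- table(object@label)
  cat("CohortSplit: median DII =", sprintf("%.4f;", object@medianDII),
      n[["high"]], "high /", n[["low"]], "low\n")
})
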