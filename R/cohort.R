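#' Split a cohort at the median DII
#'
#' Computes the standard sample median of the DII values and labels subjects
#' with DII at or above the median "high" and the rest "low" (tie-to-upper
#' rule). For an odd number of distinct values this puts the median subject
#' in the high group, e.g. 663 distinct values split 332 high / 331 low.
#'
#' @param dii named numeric vector of DII values, or a [DIIResult-class].
#' @return a [CohortSplit-class] object.
#' @examples
#' medianSplit(c(a = 1, b = 2, c = 2, d = 2, e = 3))  # high = 4, low = 1
#' @export
medianSplit <- function(dii) {
  if (is(dii, "DIIResult")) {
    tot <- diiTotals(dii)
    dii <- setNames(tot$dii_total, tot$subject_id)
  }
  if (length(dii) < 2)
    stop("median split needs at least 2 subjects", call. = FALSE)
  if (any(!is.finite(dii))) stop("DII values must be finite", call. = FALSE)
  if (is.null(names(dii))) names(dii) <- seq_along(dii)
  med <- median(dii)
  lab <- factor(ifelse(dii >= med, "high", "low"), levels = c("low", "high"))
  new("CohortSplit", subjects = names(dii), dii = unname(dii),
      medianDII = med, label = lab)
}
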