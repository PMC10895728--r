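#' Load a DII reference table
#'
#' TSV with header `parameter unit global_mean global_sd effect_score`.
#' Effect scores lie in [-1, +1]: negative values mark anti-inflammatory
#' parameters (e.g. fiber), positive values pro-inflammatory ones (e.g.
#' saturated fat). The values are configuration — the scoring algorithm's
#' published global database is not redistributed here.
#'
#' @param path path to the TSV file.
#' @return a [DIIReference-class] object.
#' @export
loadDIIReference <- function(path) {
  tab <- readTSV(path)
  tab$unit <- normalizeUnit(tab$unit)
  new("DIIReference", table = tab, quantiles = list())
}

#' Centered percentile of a z-score
#'
#' Maps a z-scored intake to `2 * Phi(z) - 1` in (-1, 1), where `Phi` is the
#' standard normal CDF: the percentile of the intake in the reference
#' distribution, doubled and shifted so that the reference mean maps to 0.
#' Odd and strictly increasing in z.
#'
#' @param z numeric vector of finite z-scores.
#' @return numeric vector in (-1, 1).
#' @examples
#' centeredPercentile(0)   # 0
#' centeredPercentile(2)   # 0.9544997
#' @export
centeredPercentile <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  2 * pnorm(z) - 1
}

# Centered percentile from an empirical reference distribution supplied as
# quantiles (names = probabilities), linearly interpolated, clamped to the
# open interval.
centeredPercentileEmpirical <- function(x, quantiles) {
  p <- as.numeric(names(quantiles))
  f <- approx(quantiles, p, xout = x, rule = 2, ties = "ordered")$y
  2 * pmin(pmax(f, 1e-12), 1 - 1e-12) - 1
}

#' Compute the Dietary Inflammatory Index
#'
#' For every reference parameter available in the intake profile, the mean
#' daily intake is z-scored against the reference global mean and SD,
#' converted to a centered percentile, and multiplied by the parameter's
#' inflammatory effect score; the per-subject DII is the sum of these
#' contributions. Parameters listed in the reference but absent from the
#' profile are skipped (`missing = "skip"`, recorded in
#' `n_parameters_used`) or raise an error (`missing = "error"`).
#'
#' @param profiles an [IntakeProfiles-class].
#' @param reference a [DIIReference-class].
#' @param missing missing-parameter policy, `"skip"` or `"error"`.
#' @return a [DIIResult-class] with per-subject totals and a per-parameter
#'   contribution breakdown.
#' @export
computeDII <- function(profiles, reference, missing = c("skip", "error")) {
  stopifnot(is(profiles, "IntakeProfiles"), is(reference, "DIIReference"))
  missing <- match.arg(missing)
  ref <- referenceTable(reference)
  nut <- intakeMatrix(profiles)
  present <- ref$parameter %in% colnames(nut)
  if (missing == "error" && !all(present))
    stop("parameters absent from intake profile: ",
         paste(ref$parameter[!present], collapse = ", "), call. = FALSE)
  ref <- ref[present, , drop = FALSE]
  if (nrow(ref) == 0)
    stop("no reference parameter is present in the intake profile",
         call. = FALSE)
  mism <- ref$parameter[ref$unit != nutrientUnits(profiles)[ref$parameter]]
  if (length(mism))
    stop("unit mismatch between profile and reference for parameter: ",
         paste(mism, collapse = ", "), call. = FALSE)

  contrib <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    p <- ref$parameter[i]
    x <- nut[, p]
    z <- (x - ref$global_mean[i]) / ref$global_sd[i]
    cp <- if (p %in% names(reference@quantiles))
      centeredPercentileEmpirical(x, reference@quantiles[[p]])
    else centeredPercentile(z)
    data.frame(subject_id = rownames(nut), parameter = p, intake = x, z = z,
               centered_percentile = cp,
               contribution = cp * ref$effect_score[i])
  }))
  rownames(contrib) <- NULL

  tot <- tapply(contrib$contribution, factor(contrib$subject_id,
                levels = rownames(nut)), sum)
  totals <- data.frame(subject_id = rownames(nut),
                       dii_total = as.vector(tot),
                       n_parameters_used = nrow(ref))
  new("DIIResult", totals = totals, contributions = contrib)
}
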