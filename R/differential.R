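#' Construct an NPX experiment
#'
#' @param mat numeric matrix of NPX values (log2-scale relative abundance),
#'   rows = proteins, columns = subjects, both named.
#' @param panel optional character vector of panel annotations per protein.
#' @return an [NPXExperiment-class].
#' @export
NPXExperiment <- function(mat, panel = NULL) {
  rd <- if (is.null(panel)) NULL else S4Vectors::DataFrame(panel = panel)
  se <- SummarizedExperiment(assays = list(npx = mat), rowData = rd)
  new("NPXExperiment", se)
}

#' Read an NPX matrix from TSV
#'
#' Accepts either a long table with header `subject_id protein npx` or a wide
#' table whose first column is `subject_id` and remaining columns are
#' proteins; the layout is auto-detected from the header. NPX values are
#' log2-scale; missing values are allowed.
#'
#' @param path path to the TSV file.
#' @return an [NPXExperiment-class] (proteins x subjects).
#' @export
readNPX <- function(path) {
  tab <- readTSV(path)
  if (identical(sort(names(tab)), sort(c("subject_id", "protein", "npx")))) {
    subjects <- unique(tab$subject_id)
    proteins <- unique(tab$protein)
    mat <- matrix(NA_real_, length(proteins), length(subjects),
                  dimnames = list(proteins, subjects))
    mat[cbind(match(tab$protein, proteins),
              match(tab$subject_id, subjects))] <- tab$npx
  } else {
    if (names(tab)[1] != "subject_id")
      stop("wide NPX table must start with a subject_id column",
           call. = FALSE)
    mat <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(mat) <- as.character(tab$subject_id)
  }
  NPXExperiment(mat)
}

#' Write an NPX experiment as a wide TSV
#'
#' @param x an [NPXExperiment-class].
#' @param path output path.
#' @export
writeNPX <- function(x, path) {
  mat <- t(npx(x))
  writeTSV(data.frame(subject_id = rownames(mat), mat, check.names = FALSE),
           path)
}

#' Choose between t-test and Mann-Whitney per the normality gate
#'
#' Each group is screened with a one-sample Kolmogorov-Smirnov test against a
#' normal distribution with the group's own mean and SD. If normality is not
#' rejected at `alphaNormality` in both groups the t-test is used, otherwise
#' the Mann-Whitney U-test. A group with zero variance is treated as
#' non-normal.
#'
#' @param high,low numeric vectors (at least 3 observations each).
#' @param alphaNormality significance level of the normality gate.
#' @return `"t"` or `"mann-whitney"`.
#' @export
chooseTest <- function(high, low, alphaNormality = 0.05) {
  if (length(high) < 3 || length(low) < 3)
    stop("normality gate needs at least 3 observations per group",
         call. = FALSE)
  normalish <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(FALSE)
    p <- suppressWarnings(ks.test(x, "pnorm", mean(x), s)$p.value)
    p > alphaNormality
  }
  if (normalish(high) && normalish(low)) "t" else "mann-whitney"
}

# Two-sided Mann-Whitney p: exact (doubling rule) when the pooled sample has
# no ties and total n <= 20, else normal approximation with continuity and
# tie correction. Identical pooled values give p = 1 by convention.
mannWhitneyP <- function(high, low) {
  pooled <- c(high, low)
  if (length(unique(pooled)) == 1L) return(1)
  exact <- length(pooled) <= 20 && !anyDuplicated(pooled)
  suppressWarnings(
    wilcox.test(high, low, exact = exact, correct = TRUE)$p.value)
}

#' Differential NPX testing between DII groups
#'
#' For every protein, compares NPX between the high- and low-DII groups with
#' the gated test choice (see [chooseTest()]): Welch t-test when both groups
#' pass the normality screen, Mann-Whitney U otherwise. The log2 fold change
#' is the difference of group means (NPX is already log2-scale). Missing
#' values are dropped pairwise; proteins with too few observations in a group
#' are flagged untestable and excluded from the Benjamini-Hochberg
#' adjustment.
#'
#' @param x an [NPXExperiment-class].
#' @param split a [CohortSplit-class] covering the experiment's subjects.
#' @param alphaNormality significance level of the normality gate.
#' @param test `"auto"` (the gate), or force `"t"` / `"mann-whitney"`.
#' @return data.frame with one row per protein: `protein`, `n_high`,
#'   `n_low`, `mean_high`, `mean_low`, `log2fc`, `test_used`, `p_raw`,
#'   `q_bh`, `untestable`.
#' @export
testAllProteins <- function(x, split, alphaNormality = 0.05,
                            test = c("auto", "t", "mann-whitney")) {
  stopifnot(is(x, "NPXExperiment"), is(split, "CohortSplit"))
  test <- match.arg(test)
  lab <- groupLabels(split)
  if (!all(colnames(x) %in% names(lab)))
    stop("split does not cover all subjects in the NPX matrix", call. = FALSE)
  lab <- lab[colnames(x)]
  mat <- npx(x)
  minN <- if (test == "auto") 3L else 2L

  rows <- lapply(rownames(mat), function(pr) {
    v <- mat[pr, ]
    hi <- v[lab == "high" & !is.na(v)]
    lo <- v[lab == "low" & !is.na(v)]
    if (length(hi) < minN || length(lo) < minN)
      return(data.frame(protein = pr, n_high = length(hi),
                        n_low = length(lo), mean_high = NA_real_,
                        mean_low = NA_real_, log2fc = NA_real_,
                        test_used = "none", p_raw = NA_real_,
                        untestable = TRUE))
    used <- if (test == "auto") chooseTest(hi, lo, alphaNormality) else test
    p <- if (used == "t")
      t.test(hi, lo)$p.value
    else mannWhitneyP(hi, lo)
    data.frame(protein = pr, n_high = length(hi), n_low = length(lo),
               mean_high = mean(hi), mean_low = mean(lo),
               log2fc = mean(hi) - mean(lo), test_used = used,
               p_raw = p, untestable = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_bh <- NA_real_
  res$q_bh[!res$untestable] <- bhFDR(res$p_raw[!res$untestable])
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]); values are monotone
#' after sorting and capped at 1. An empty input returns an empty vector.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return numeric vector of adjusted values.
#' @export
bhFDR <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Volcano table
#'
#' One row per testable protein with the log2 fold change, -log10 raw p, and
#' a significance flag under the active mode: `"fdr"` flags `q_bh < alpha`
#' (the default), `"paper"` flags raw `p < alpha` with no multiplicity
#' adjustment (the uncorrected convention some cohort reports use).
#'
#' @param results data.frame from [testAllProteins()].
#' @param sigMode `"fdr"` or `"paper"`.
#' @param alpha significance threshold.
#' @return data.frame `protein`, `log2fc`, `neg_log10_p`, `significant`.
#' @export
volcanoTable <- function(results, sigMode = c("fdr", "paper"),
                         alpha = 0.05) {
  if (nrow(results) == 0) stop("no test results", call. = FALSE)
  sigMode <- match.arg(sigMode)
  res <- results[!results$untestable, , drop = FALSE]
  sig <- if (sigMode == "paper") res$p_raw < alpha else res$q_bh < alpha
  data.frame(protein = res$protein, log2fc = res$log2fc,
             neg_log10_p = -log10(res$p_raw), significant = sig)
}

#' Significant proteins under the active mode
#'
#' @param results data.frame from [testAllProteins()].
#' @param sigMode `"fdr"` or `"paper"` (see [volcanoTable()]).
#' @param alpha significance threshold.
#' @return character vector of protein ids.
#' @export
significantProteins <- function(results, sigMode = c("fdr", "paper"),
                                alpha = 0.05) {
  v <- volcanoTable(results, sigMode, alpha)
  v$protein[v$significant]
}
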