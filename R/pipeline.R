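.STAGES <- c("simulate", "nutrients", "dii", "split", "diffexp", "classify",
             "enrich")

#' Pipeline configuration
#'
#' One flat configuration for the staged pipeline. Input paths default to the
#' files the `simulate` stage writes under `<outdir>/inputs`, so
#' `runPipeline()` with all stages is self-contained; point the paths at real
#' data to skip simulation. All stage seeds derive from the single global
#' seed.
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @param sigMode significance mode for downstream feature selection:
#'   `"fdr"` (Benjamini-Hochberg, default) or `"paper"` (uncorrected p).
#' @param alpha significance threshold.
#' @param topN optional number of top-importance proteins to report
#'   separately (the full ranking is always written).
#' @param tune run the classifier's cross-validated grid search.
#' @param synthetic optional [syntheticConfig()] (defaults to the study
#'   conditions, seeded from `seed`).
#' @param classifier optional [classifierConfig()] (seeded from `seed`).
#' @param paths named list overriding input paths: `composition`, `records`,
#'   `substitutions`, `reference`, `npx`, `gmt`.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outdir, seed = 1L, sigMode = c("fdr", "paper"),
                           alpha = 0.05, topN = NULL, tune = TRUE,
                           synthetic = NULL, classifier = NULL,
                           paths = list()) {
  sigMode <- match.arg(sigMode)
  seed <- as.integer(seed)
  synthetic <- synthetic %||% syntheticConfig(seed = childSeed(seed,
                                                               "simulate"))
  classifier <- classifier %||% classifierConfig(seed = childSeed(seed,
                                                                  "classify"))
  inputs <- file.path(outdir, "inputs")
  defaults <- list(composition = file.path(inputs, "composition.tsv"),
                   records = file.path(inputs, "records.tsv"),
                   substitutions = file.path(inputs, "substitutions.tsv"),
                   reference = file.path(inputs, "dii_reference.tsv"),
                   npx = file.path(inputs, "npx.tsv"),
                   gmt = file.path(inputs, "annotations.gmt"))
  defaults[names(paths)] <- paths
  structure(list(outdir = outdir, seed = seed, sigMode = sigMode,
                 alpha = alpha, topN = topN, tune = tune,
                 synthetic = synthetic, classifier = classifier,
                 paths = defaults),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [pipelineConfig()] arguments (flat; `synthetic`
#' and `classifier` may be nested maps of their constructor arguments).
#'
#' @param path YAML file.
#' @param outdir overrides the file's `outdir` if given.
#' @return a [pipelineConfig()].
#' @export
loadPipelineConfig <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  pipelineConfig(
    outdir = outdir %||% y$outdir %||% ".",
    seed = seed,
    sigMode = y$sig_mode %||% "fdr",
    alpha = y$alpha %||% 0.05,
    topN = y$top_n,
    tune = y$tune %||% TRUE,
    synthetic = if (!is.null(y$synthetic))
      do.call(syntheticConfig,
              c(y$synthetic,
                if (is.null(y$synthetic$seed))
                  list(seed = childSeed(seed, "simulate")))),
    classifier = if (!is.null(y$classifier))
      do.call(classifierConfig,
              c(y$classifier,
                if (is.null(y$classifier$seed))
                  list(seed = childSeed(seed, "classify")))),
    paths = y$paths %||% list())
}

# Hash of the analytic configuration (output/input locations excluded, so
# the same analysis written elsewhere hashes identically).
hashConfig <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$outdir <- cfg$paths <- NULL
  flat <- rapply(cfg, function(x)
    if (is.data.frame(x)) as.list(x) else x, how = "replace")
  jsonlite::write_json(flat, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

needInput <- function(stage, what, path) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires missing upstream artifact '", what,
         "' (", path, ")", call. = FALSE)
  path
}

rebuildProfiles <- function(intakePath, groupPath) {
  tab <- readTSV(intakePath)
  nutCols <- setdiff(names(tab), c("subject_id", "energy_kcal_per_day"))
  m <- regmatches(nutCols, regexec("^(.*)\\[(.*)\\]$", nutCols))
  nutNames <- vapply(m, `[`, "", 2L)
  units <- setNames(normalizeUnit(vapply(m, `[`, "", 3L)), nutNames)
  mat <- as.matrix(tab[, nutCols, drop = FALSE])
  dimnames(mat) <- list(tab$subject_id, nutNames)
  new("IntakeProfiles", subjects = tab$subject_id,
      energy = setNames(tab$energy_kcal_per_day, tab$subject_id),
      nutrients = mat, units = units, groupIntake = readTSV(groupPath))
}

splitFromFile <- function(path) {
  tab <- readTSV(path)
  medianSplit(setNames(tab$dii, tab$subject_id))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (write a synthetic
#' input bundle), `nutrients` (dietary records to mean daily intakes and
#' energy shares), `dii` (DII scoring), `split` (median split), `diffexp`
#' (differential NPX testing), `classify` (boosted classifier with ROC),
#' `enrich` (over-representation of the significant proteins) — each reading
#' the previous stage's files, so any suffix of the chain can be rerun. A
#' manifest (package version, seed, config hash, per-stage outputs with row
#' counts) is written to `<outdir>/manifest.json`.
#'
#' @param config a [pipelineConfig()].
#' @param stages subset of the stage names, in any order (executed in
#'   pipeline order).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, stages = .STAGES) {
  stopifnot(inherits(config, "pipelineConfig"))
  bad <- setdiff(stages, .STAGES)
  if (length(bad))
    stop("unknown stage: ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- .STAGES[.STAGES %in% stages]
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- config$paths
  outputs <- list()
  note <- function(stage, files) {
    outputs[[stage]] <<- lapply(files, function(f)
      list(path = sub(paste0("^", out, "/?"), "", f),
           rows = if (grepl("\\.tsv$", f)) length(readLines(f)) - 1L
                  else NA))
  }

  for (stage in stages) {
    message("[", stage, "] running")
    switch(stage,
      simulate = {
        paths <- emitFixture(file.path(out, "inputs"),
                             config = config$synthetic)
        note(stage, as.list(unname(paths)))
      },
      nutrients = {
        comp <- loadFoodComposition(needInput(stage, "composition",
                                              p$composition))
        rec <- loadDietaryRecords(needInput(stage, "records", p$records))
        subs <- if (file.exists(p$substitutions))
          loadSubstitutions(p$substitutions) else NULL
        prof <- computeIntake(rec, comp, subs)
        units <- nutrientUnits(prof)
        nut <- intakeMatrix(prof)
        colnames(nut) <- sprintf("%s[%s]", colnames(nut),
                                 units[colnames(nut)])
        f1 <- writeTSV(data.frame(subject_id = prof@subjects,
                                  energy_kcal_per_day = dailyEnergy(prof),
                                  nut, check.names = FALSE),
                       file.path(out, "intake_nutrients.tsv"))
        f2 <- writeTSV(computeEnergyShares(prof),
                       file.path(out, "energy_shares.tsv"))
        f3 <- writeTSV(foodGroupIntake(prof),
                       file.path(out, "food_group_intake.tsv"))
        note(stage, list(f1, f2, f3))
      },
      dii = {
        prof <- rebuildProfiles(
          needInput(stage, "intake_nutrients",
                    file.path(out, "intake_nutrients.tsv")),
          needInput(stage, "food_group_intake",
                    file.path(out, "food_group_intake.tsv")))
        ref <- loadDIIReference(needInput(stage, "reference", p$reference))
        res <- computeDII(prof, ref)
        f1 <- writeTSV(diiTotals(res), file.path(out, "dii_scores.tsv"))
        f2 <- writeTSV(diiContributions(res),
                       file.path(out, "dii_contributions.tsv"))
        note(stage, list(f1, f2))
      },
      split = {
        tab <- readTSV(needInput(stage, "dii_scores",
                                 file.path(out, "dii_scores.tsv")))
        sp <- medianSplit(setNames(tab$dii_total, tab$subject_id))
        f1 <- writeTSV(data.frame(subject_id = sp@subjects, dii = sp@dii,
                                  group = as.character(sp@label)),
                       file.path(out, "groups.tsv"))
        note(stage, list(f1))
      },
      diffexp = {
        x <- readNPX(needInput(stage, "npx", p$npx))
        sp <- splitFromFile(needInput(stage, "groups",
                                      file.path(out, "groups.tsv")))
        res <- testAllProteins(x, sp)
        f1 <- writeTSV(res, file.path(out, "diffexp.tsv"))
        f2 <- writeTSV(volcanoTable(res, config$sigMode, config$alpha),
                       file.path(out, "volcano.tsv"))
        note(stage, list(f1, f2))
      },
      classify = {
        res <- readTSV(needInput(stage, "diffexp",
                                 file.path(out, "diffexp.tsv")))
        feats <- significantProteins(res, config$sigMode, config$alpha)
        if (length(feats) < 2)
          stop("classify needs >= 2 significant proteins under mode '",
               config$sigMode, "'", call. = FALSE)
        x <- readNPX(needInput(stage, "npx", p$npx))
        sp <- splitFromFile(needInput(stage, "groups",
                                      file.path(out, "groups.tsv")))
        lab <- groupLabels(sp)[colnames(x)]
        part <- stratifiedSplit(lab, config$classifier)
        X <- t(npx(x)[feats, , drop = FALSE])
        fit <- fitBoostedClassifier(X[part$train, , drop = FALSE],
                                    lab[part$train], config$classifier,
                                    tune = config$tune)
        roc <- evaluateROC(fit$model, X[part$test, , drop = FALSE],
                           lab[part$test],
                           seed = childSeed(config$seed, "roc"))
        f1 <- writeTSV(fit$ranking, file.path(out, "importance.tsv"))
        f2 <- writeTSV(roc$curve, file.path(out, "roc_points.tsv"))
        f3 <- file.path(out, "roc_report.json")
        jsonlite::write_json(
          list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
               p_value = roc$p_value, n_train = length(part$train),
               n_test = length(part$test), n_features = length(feats),
               top_features = if (!is.null(config$topN))
                 selectTopFeatures(fit$ranking,
                                   min(config$topN, nrow(fit$ranking))),
               params = as.list(fit$params), seed = config$seed),
          f3, auto_unbox = TRUE, digits = NA)
        note(stage, list(f1, f2, f3))
      },
      enrich = {
        res <- readTSV(needInput(stage, "diffexp",
                                 file.path(out, "diffexp.tsv")))
        query <- significantProteins(res, config$sigMode, config$alpha)
        if (!length(query))
          stop("enrich: no significant proteins under mode '",
               config$sigMode, "'", call. = FALSE)
        coll <- readGMT(needInput(stage, "gmt", p$gmt),
                        background = res$protein)
        enr <- enrich(query, coll, config$alpha)
        f1 <- writeTSV(enr, file.path(out, "enrichment.tsv"))
        f2 <- writeTSV(categoryTally(enr),
                       file.path(out, "enrichment_categories.tsv"))
        note(stage, list(f1, f2))
      })
  }

  manifest <- list(package = "DIIprofiler",
                   version = as.character(utils::packageVersion("DIIprofiler")),
                   seed = config$seed, sig_mode = config$sigMode,
                   config_hash = hashConfig(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = outputs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
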