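# Catalogue of food subgroups: per-100 g nutrient centroids, a typical
# portion size, and the relative preference weight of each dietary archetype.
# The "western" archetype favours red/processed meat, cheese, animal fats and
# sweets; the "prudent" archetype favours vegetables, fruit, fish and
# vegetable oils. Values are illustrative, chosen to realize those contrasts,
# not measurements of any national food database.
subgroupCatalogue <- function() {
  cols <- c("group", "subgroup", "item_stub", "portion_g", "w_western",
            "w_prudent", "protein", "carbohydrate", "soluble_carbs", "fat",
            "saturated_fat", "mufa", "pufa", "omega3", "omega6", "fiber",
            "alcohol", "vitamin_c", "magnesium", "beta_carotene")
  rows <- list(
    list("cereals", "bread", "bread", 80, 1.3, 1.1,
         9, 55, 3, 2, 0.4, 0.6, 0.8, 0.05, 0.7, 4, 0, 0, 35, 0),
    list("cereals", "pasta and rice", "pasta", 90, 1.2, 1.2,
         11, 72, 3, 1.5, 0.3, 0.3, 0.7, 0.03, 0.6, 3, 0, 0, 50, 0),
    list("vegetables", "leafy vegetables", "leafy_veg", 80, 0.5, 2.0,
         2.5, 3, 2, 0.3, 0.05, 0.02, 0.15, 0.10, 0.05, 2.8, 0, 45, 30, 3500),
    list("vegetables", "other vegetables", "other_veg", 100, 0.5, 1.8,
         1.5, 5, 3, 0.3, 0.05, 0.02, 0.12, 0.05, 0.06, 2.5, 0, 30, 20, 1500),
    list("fruits", "fresh fruit", "fruit", 150, 0.6, 2.0,
         0.6, 12, 10.5, 0.3, 0.05, 0.02, 0.10, 0.03, 0.06, 2.4, 0, 35, 12, 400),
    list("fish", "fatty fish", "fatty_fish", 120, 0.4, 1.5,
         20, 0, 0, 11, 2.2, 4, 3.3, 2.4, 0.6, 0, 0, 0, 30, 0),
    list("fish", "lean fish", "lean_fish", 120, 0.5, 1.5,
         21, 0, 0, 1.5, 0.3, 0.4, 0.5, 0.35, 0.1, 0, 0, 0, 28, 0),
    list("meat", "red and processed meat", "red_meat", 110, 2.2, 0.7,
         17, 0.5, 0.5, 24, 9.5, 10.5, 2.2, 0.15, 1.9, 0, 0, 0, 18, 0),
    list("meat", "poultry", "poultry", 110, 1.2, 1.0,
         21, 0, 0, 7, 2, 3, 1.4, 0.10, 1.2, 0, 0, 0, 22, 0),
    list("dairy", "cheese", "cheese", 50, 1.8, 0.8,
         22, 2, 2, 28, 18, 7.5, 1, 0.20, 0.7, 0, 0, 0, 25, 150),
    list("dairy", "milk and yogurt", "milk", 180, 1.1, 1.1,
         3.3, 4.8, 4.8, 3.4, 2.1, 0.9, 0.1, 0.02, 0.07, 0, 0, 1, 11, 20),
    list("oils, butter and margarine", "oils and vegetable fats",
         "olive_oil", 12, 0.7, 1.8,
         0, 0, 0, 99.9, 14, 71, 9.8, 0.8, 8.8, 0, 0, 0, 0, 100),
    list("oils, butter and margarine", "animal fats", "butter", 10, 2.0, 0.5,
         0.8, 0.6, 0.6, 82, 52, 21, 2.5, 0.3, 2, 0, 0, 0, 2, 500),
    list("sweets", "desserts and confectionery", "dessert", 70, 2.0, 0.7,
         5, 60, 42, 19, 10, 6, 1.8, 0.10, 1.5, 1.5, 0, 0, 25, 30),
    list("alcoholic beverages", "wine", "wine", 150, 1.2, 1.0,
         0.1, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 10.5, 0, 10, 0))
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    setNames(r, cols))))
  for (c in cols[-(1:3)]) out[[c]] <- as.numeric(out[[c]])
  for (c in cols[1:3]) out[[c]] <- as.character(out[[c]])
  out
}

.NUTRIENT_UNITS <- c(protein = "g", carbohydrate = "g", soluble_carbs = "g",
                     fat = "g", saturated_fat = "g", mufa = "g", pufa = "g",
                     omega3 = "g", omega6 = "g", fiber = "g", alcohol = "g",
                     vitamin_c = "mg", magnesium = "mg", beta_carotene = "ug")

#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions the pipeline targets: two
#' dietary archetypes (the "western" one higher in saturated fat and lower in
#' PUFA, fiber and micronutrients than the "prudent" one), an Olink-sized
#' panel of 368 proteins with a 0.5-SD mean NPX shift planted in 30 of them
#' for the exposed group, and Gaussian log2-scale noise.
#'
#' @param nSubjects cohort size.
#' @param archetypeFraction share of "western" subjects.
#' @param foodsPerSubgroup foods generated per catalogue subgroup.
#' @param nProteins panel size.
#' @param nPlanted number of proteins carrying a planted shift.
#' @param plantedShift planted mean shift, in units of the NPX noise SD.
#' @param plantedUpFraction share of planted proteins shifted upward in the
#'   exposed group.
#' @param npxSubjectSd SD of the per-subject random offset (NPX units).
#' @param npxNoiseSd SD of the residual NPX noise (NPX units).
#' @param entriesPerDayMean mean number of record entries per subject-day.
#' @param linkMode `"archetype"` plants the shift in western subjects
#'   (indirect DII link); `"dii-quantile"` plants it in subjects at or above
#'   the median DII.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nSubjects = 400, archetypeFraction = 0.5,
                            foodsPerSubgroup = 3, nProteins = 368,
                            nPlanted = 30, plantedShift = 0.5,
                            plantedUpFraction = 0.9, npxSubjectSd = 0.2,
                            npxNoiseSd = 1, entriesPerDayMean = 9,
                            linkMode = c("archetype", "dii-quantile"),
                            seed = 1L) {
  stopifnot(nSubjects >= 2, archetypeFraction > 0, archetypeFraction < 1,
            foodsPerSubgroup >= 1, nProteins >= 2, nPlanted >= 0,
            npxSubjectSd > 0, npxNoiseSd > 0, entriesPerDayMean > 2)
  if (nPlanted > nProteins)
    stop("planted count exceeds protein count", call. = FALSE)
  structure(list(nSubjects = nSubjects,
                 archetypeFraction = archetypeFraction,
                 foodsPerSubgroup = foodsPerSubgroup, nProteins = nProteins,
                 nPlanted = nPlanted, plantedShift = plantedShift,
                 plantedUpFraction = plantedUpFraction,
                 npxSubjectSd = npxSubjectSd, npxNoiseSd = npxNoiseSd,
                 entriesPerDayMean = entriesPerDayMean,
                 linkMode = match.arg(linkMode), seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Illustrative DII reference table matched to the synthetic food catalogue
#'
#' Global means are the design expectation of daily intake under an equal mix
#' of the two archetypes (computed in closed form from the catalogue
#' centroids, portion sizes and preference weights); global SDs are set to
#' 25% of the mean. Effect scores carry the field's usual signs — positive
#' for saturated and total fat, negative for fiber, PUFA (incl. omega-3) and
#' micronutrients — with illustrative magnitudes. This table is configuration
#' for testing, not the published scoring database.
#'
#' @param entriesPerDayMean mean record entries per subject-day (must match
#'   the generator config for the means to be centred).
#' @return a [DIIReference-class].
#' @export
defaultDIIReference <- function(entriesPerDayMean = 9) {
  cat <- subgroupCatalogue()
  scores <- c(saturated_fat = 0.43, fat = 0.30, protein = 0.02,
              carbohydrate = 0.10, soluble_carbs = 0.05, mufa = -0.01,
              pufa = -0.44, omega3 = -0.44, omega6 = -0.16, fiber = -0.66,
              alcohol = -0.28, vitamin_c = -0.42, magnesium = -0.48,
              beta_carotene = -0.58)
  meanIntake <- vapply(names(scores), function(nu) {
    perArch <- vapply(c("w_western", "w_prudent"), function(w) {
      p <- cat[[w]] / sum(cat[[w]])
      entriesPerDayMean * sum(p * cat$portion_g * cat[[nu]] / 100)
    }, numeric(1))
    mean(perArch)
  }, numeric(1))
  tab <- data.frame(parameter = names(scores),
                    unit = unname(.NUTRIENT_UNITS[names(scores)]),
                    global_mean = unname(meanIntake),
                    global_sd = pmax(0.25 * unname(meanIntake), 1e-3),
                    effect_score = unname(scores))
  new("DIIReference", table = tab, quantiles = list())
}

# Draw a food pool around the catalogue centroids (lognormal jitter per
# nutrient); energy is recomputed from the jittered macros so the table is
# internally consistent. Caller provides the RNG state.
generateComposition <- function(config) {
  cat <- subgroupCatalogue()
  nut <- names(.NUTRIENT_UNITS)
  rows <- do.call(rbind, lapply(seq_len(nrow(cat)), function(s) {
    do.call(rbind, lapply(seq_len(config$foodsPerSubgroup), function(j) {
      amounts <- pmin(
        as.numeric(cat[s, nut]) * exp(rnorm(length(nut), 0, 0.12)), 100)
      df <- as.data.frame(as.list(setNames(amounts, nut)))
      cbind(data.frame(
        food_id = sprintf("F%02d_%d", s, j),
        name = sprintf("%s_%d", cat$item_stub[s], j),
        group = cat$group[s], subgroup = cat$subgroup[s],
        item = sprintf("%s_%d", cat$item_stub[s], j),
        energy_kcal_per_100g = 4 * (df$protein + df$carbohydrate) +
          9 * df$fat + 7 * df$alcohol), df)
    }))
  }))
  rownames(rows) <- NULL
  new("FoodComposition", table = rows, units = .NUTRIENT_UNITS)
}

# Seven-day records for one archetype assignment. Caller provides RNG state.
generateRecords <- function(config, composition, archetype) {
  tab <- foodTable(composition)
  cat <- subgroupCatalogue()
  si <- match(tab$subgroup, cat$subgroup)
  wts <- list(western = cat$w_western[si], prudent = cat$w_prudent[si])
  portion <- cat$portion_g[si]
  cells <- expand.grid(day = 1:7, subject_id = names(archetype),
                       stringsAsFactors = FALSE)
  k <- rpois(nrow(cells), config$entriesPerDayMean - 2) + 2L
  sub <- rep(cells$subject_id, k)
  day <- rep(cells$day, k)
  # inverse-CDF sampling so all subjects of one archetype share one draw pass
  u <- runif(length(sub))
  f <- integer(length(sub))
  for (a in names(wts)) {
    rows <- archetype[sub] == a
    f[rows] <- findInterval(u[rows] * sum(wts[[a]]),
                            cumsum(wts[[a]]), left.open = TRUE) + 1L
  }
  data.frame(subject_id = sub, day = day, food_id = tab$food_id[f],
             grams = round(portion[f] * rgamma(length(f), 6, rate = 6), 1))
}

# NPX matrix with planted mean shifts for the exposed subjects.
generateNPX <- function(config, exposed) {
  subjects <- names(exposed)
  proteins <- sprintf("PROT%03d", seq_len(config$nProteins))
  planted <- if (config$nPlanted > 0)
    sort(sample(proteins, config$nPlanted)) else character(0)
  nUp <- round(config$plantedUpFraction * length(planted))
  sign <- setNames(rep(0, config$nProteins), proteins)
  sign[planted] <- c(rep(1, nUp), rep(-1, length(planted) - nUp))
  base <- rnorm(config$nProteins, 5, 1.5)
  subj <- rnorm(length(subjects), 0, config$npxSubjectSd)
  shift <- config$plantedShift * config$npxNoiseSd * sign
  mat <- base + outer(rep(1, config$nProteins), subj) +
    outer(shift, as.numeric(exposed)) +
    matrix(rnorm(config$nProteins * length(subjects), 0, config$npxNoiseSd),
           config$nProteins)
  dimnames(mat) <- list(proteins, subjects)
  list(npx = NPXExperiment(round(mat, 4)),
       planted = data.frame(protein = planted,
                            sign = unname(sign[planted])))
}

# Annotation collection over the synthetic panel: one term concentrating the
# planted proteins plus background terms of mixed category.
generateAnnotations <- function(proteins, planted, nTerms = 12) {
  cats <- c("immune-inflammatory", "cell-cell signaling", "metabolic",
            "other")
  terms <- list()
  core <- if (length(planted))
    sample(planted, max(1, round(0.8 * length(planted)))) else character(0)
  terms[["inflammatory_response_synthetic"]] <-
    unique(c(core, sample(setdiff(proteins, planted),
                          min(5, length(proteins) - length(planted)))))
  lo <- min(8, length(proteins))
  hi <- min(30, length(proteins))
  for (i in seq_len(nTerms - 1)) {
    sz <- if (lo >= hi) hi else sample(lo:hi, 1)
    terms[[sprintf("synthetic_process_%02d", i)]] <- sample(proteins, sz)
  }
  category <- setNames(c("immune-inflammatory",
                         cats[(seq_len(nTerms - 1) %% 4) + 1]), names(terms))
  annotationCollection(terms, background = proteins, category = category)
}

#' Generate a complete synthetic cohort
#'
#' Draws, from one seed: a food-composition pool around the packaged
#' subgroup catalogue; seven-day dietary records for a mix of "western" and
#' "prudent" archetype subjects (western subjects preferentially draw
#' saturated-fat-rich foods and fewer vegetables, fruit, fish and vegetable
#' oils); the matched illustrative DII reference; an NPX matrix with a
#' planted mean shift in a subset of proteins for the exposed group plus null
#' proteins; and a gene-set annotation collection over the panel.
#'
#' @param config a [syntheticConfig()].
#' @return list with `composition` ([FoodComposition-class]), `records`
#'   (data.frame), `reference` ([DIIReference-class]), `npx`
#'   ([NPXExperiment-class]), `annotations` ([annotationCollection()]) and
#'   `truth` (archetype per subject, planted proteins with shift signs, the
#'   config).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  withSeed(config$seed, {
    subjects <- sprintf("S%04d", seq_len(config$nSubjects))
    nW <- round(config$archetypeFraction * config$nSubjects)
    archetype <- setNames(
      sample(c(rep("western", nW),
               rep("prudent", config$nSubjects - nW))), subjects)
    composition <- generateComposition(config)
    records <- generateRecords(config, composition, archetype)
    reference <- defaultDIIReference(config$entriesPerDayMean)

    exposed <- if (config$linkMode == "archetype") {
      archetype == "western"
    } else {
      dii <- computeDII(computeIntake(records, composition,
                                      subjects = subjects), reference)
      groupLabels(medianSplit(dii))[subjects] == "high"
    }
    names(exposed) <- subjects
    gen <- generateNPX(config, exposed)
    annotations <- generateAnnotations(rownames(gen$npx),
                                       gen$planted$protein)
    list(composition = composition, records = records,
         reference = reference, npx = gen$npx, annotations = annotations,
         truth = list(archetype = archetype, planted = gen$planted,
                      exposed = exposed, config = config))
  })
}

#' Write a synthetic input bundle to disk
#'
#' Emits exactly the file dialects the loaders consume: `composition.tsv`,
#' `records.tsv`, `substitutions.tsv` (with a few record entries rewritten to
#' alias ids so the substitution path is exercised), `dii_reference.tsv`,
#' `npx.tsv` (wide), `annotations.gmt` and `ground_truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param size `"tiny"` (20 subjects, 30 foods, 40 proteins; used by unit
#'   tests) or `"default"` (the full study conditions).
#' @param seed integer seed.
#' @param config optional [syntheticConfig()] overriding `size`/`seed`.
#' @return invisibly, the named vector of written paths.
#' @export
emitFixture <- function(dir, size = c("default", "tiny"), seed = 1L,
                        config = NULL) {
  size <- match.arg(size)
  if (is.null(config))
    config <- if (size == "tiny")
      syntheticConfig(nSubjects = 20, foodsPerSubgroup = 2, nProteins = 40,
                      nPlanted = 6, seed = seed)
    else syntheticConfig(seed = seed)
  coh <- generateCohort(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tab <- foodTable(coh$composition)
  units <- nutrientUnits(coh$composition)
  nut <- names(units)
  names(tab)[match(nut, names(tab))] <- sprintf("%s[%s]", nut, units)
  paths <- c(composition = file.path(dir, "composition.tsv"),
             records = file.path(dir, "records.tsv"),
             substitutions = file.path(dir, "substitutions.tsv"),
             reference = file.path(dir, "dii_reference.tsv"),
             npx = file.path(dir, "npx.tsv"),
             gmt = file.path(dir, "annotations.gmt"),
             truth = file.path(dir, "ground_truth.json"))
  writeTSV(tab, paths["composition"])

  rec <- coh$records
  aliasOf <- unique(rec$food_id)[1:2]
  alias <- paste0("ALIAS_", aliasOf)
  for (i in 1:2) {
    hit <- which(rec$food_id == aliasOf[i])[1:2]
    rec$food_id[hit[!is.na(hit)]] <- alias[i]
  }
  writeTSV(rec, paths["records"])
  writeTSV(data.frame(missing_food_id = alias,
                      replacement_food_id = aliasOf),
           paths["substitutions"])
  writeTSV(referenceTable(coh$reference), paths["reference"])
  writeNPX(coh$npx, paths["npx"])
  writeLines(vapply(names(coh$annotations$terms), function(tm)
    paste(c(tm, coh$annotations$category[[tm]],
            coh$annotations$terms[[tm]]), collapse = "\t"), ""),
    paths["gmt"])
  jsonlite::write_json(
    list(archetype = as.list(coh$truth$archetype),
         planted = coh$truth$planted,
         exposed = as.list(coh$truth$exposed),
         seed = config$seed, link_mode = config$linkMode),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
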