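#' Load a food-composition table
#'
#' Reads a tab-separated composition table with header
#' `food_id name group subgroup item energy_kcal_per_100g <nutrient>[unit] ...`
#' where each nutrient column declares its unit in brackets (g, mg or ug;
#' "µg" and "mcg" are accepted and normalized to "ug"). All amounts are per
#' 100 g edible portion.
#'
#' @param path path to the TSV file.
#' @return a [FoodComposition-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("food_id\tname\tgroup\tsubgroup\titem\tenergy_kcal_per_100g\tfiber[g]",
#'              "F1\tapple\tfruits\tfresh fruit\tapple\t52\t2.4"), tf)
#' loadFoodComposition(tf)
#' @export
loadFoodComposition <- function(path) {
  tab <- readTSV(path)
  fixed <- c("food_id", "name", "group", "subgroup", "item",
             "energy_kcal_per_100g")
  if (!all(fixed %in% names(tab)))
    stop("composition table must have columns: ",
         paste(fixed, collapse = ", "), call. = FALSE)
  nutCols <- setdiff(names(tab), fixed)
  m <- regmatches(nutCols, regexec("^(.*)\\[(.*)\\]$", nutCols))
  bad <- nutCols[vapply(m, length, 1L) != 3L]
  if (length(bad))
    stop("nutrient columns must be named <nutrient>[unit]; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  nutNames <- vapply(m, `[`, "", 2L)
  units <- normalizeUnit(vapply(m, `[`, "", 3L))
  names(tab)[match(nutCols, names(tab))] <- nutNames
  names(units) <- nutNames
  dup <- unique(tab$food_id[duplicated(tab$food_id)])
  if (length(dup))
    stop("duplicated food_id: ", paste(dup, collapse = ", "), call. = FALSE)
  tab$food_id <- as.character(tab$food_id)
  new("FoodComposition", table = tab, units = units)
}

#' Load seven-day dietary records
#'
#' Reads a TSV with header `subject_id day food_id grams`; `day` must lie in
#' 1..7 and `grams` must be non-negative. A subject may have days with no
#' entries (those days count as zero intake when averaging).
#'
#' @param path path to the TSV file.
#' @return data.frame of validated record entries.
#' @export
loadDietaryRecords <- function(path) {
  rec <- readTSV(path)
  need <- c("subject_id", "day", "food_id", "grams")
  if (!all(need %in% names(rec)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rec$subject_id <- as.character(rec$subject_id)
  rec$food_id <- as.character(rec$food_id)
  if (any(!rec$day %in% 1:7))
    stop("day must be an integer in 1..7", call. = FALSE)
  if (any(rec$grams < 0)) stop("grams must be >= 0", call. = FALSE)
  rec
}

#' Load a food substitution map
#'
#' Two-column TSV `missing_food_id replacement_food_id` mapping foods absent
#' from the composition table to a nutritionally analogous replacement.
#' Chains are allowed; cycles are rejected at resolution time.
#'
#' @param path path to the TSV file.
#' @return named character vector (missing id -> replacement id).
#' @export
loadSubstitutions <- function(path) {
  tab <- readTSV(path)
  if (ncol(tab) < 2)
    stop("substitution map needs two columns", call. = FALSE)
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

# Resolve food ids against the composition, following substitution chains.
resolveFoods <- function(foodIds, composition, subs) {
  known <- foodTable(composition)$food_id
  out <- foodIds
  for (i in seq_len(length(subs) + 1L)) {
    miss <- !(out %in% known) & out %in% names(subs)
    if (!any(miss)) break
    out[miss] <- subs[out[miss]]
  }
  if (any(!(out %in% known) & out %in% names(subs)))
    stop("substitution map contains a cycle", call. = FALSE)
  out
}

#' Aggregate dietary records into per-subject mean daily intakes
#'
#' For each subject, each nutrient intake is the 7-day mean of
#' `sum(grams/100 * amount_per_100g)` over that day's foods; energy is
#' computed the same way from the composition table's own kcal values. Days
#' with no entries contribute zero (the denominator is fixed at 7). Food
#' intakes (g/day) are also aggregated at the group, subgroup and item levels
#' of the composition hierarchy.
#'
#' @param records data.frame as returned by [loadDietaryRecords()].
#' @param composition a [FoodComposition-class].
#' @param subs optional named character substitution map
#'   (see [loadSubstitutions()]).
#' @param subjects optional character vector of subjects to include (defaults
#'   to those present in `records`; subjects with no entries get zero intakes).
#' @return an [IntakeProfiles-class] object.
#' @export
computeIntake <- function(records, composition, subs = NULL,
                          subjects = NULL) {
  stopifnot(is(composition, "FoodComposition"))
  subs <- subs %||% character(0)
  subjects <- subjects %||% sort(unique(records$subject_id))
  tab <- foodTable(composition)
  nutNames <- names(nutrientUnits(composition))

  resolved <- resolveFoods(records$food_id, composition, subs)
  idx <- match(resolved, tab$food_id)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    msg <- paste(sprintf("subject %s day %d food %s",
                         records$subject_id[bad], records$day[bad],
                         records$food_id[bad]), collapse = "; ")
    stop("unresolvable food_id: ", msg, call. = FALSE)
  }

  si <- factor(records$subject_id, levels = subjects)
  scale <- records$grams / 100
  energy <- tapply(scale * tab$energy_kcal_per_100g[idx], si, sum,
                   default = 0) / 7
  nutrients <- vapply(nutNames, function(n)
    tapply(scale * tab[[n]][idx], si, sum, default = 0) / 7,
    numeric(length(subjects)))
  if (is.null(dim(nutrients)))
    nutrients <- matrix(nutrients, nrow = length(subjects),
                        dimnames = list(subjects, nutNames))
  rownames(nutrients) <- subjects

  groupIntake <- do.call(rbind, lapply(
    c("group", "subgroup", "item"), function(level) {
      g <- tapply(records$grams,
                  list(si, factor(tab[[level]][idx])), sum, default = 0) / 7
      data.frame(subject_id = rep(rownames(g), ncol(g)),
                 level = level,
                 name = rep(colnames(g), each = nrow(g)),
                 g_per_day = as.vector(g))
    }))
  rownames(groupIntake) <- NULL

  new("IntakeProfiles", subjects = subjects,
      energy = setNames(as.vector(energy), subjects),
      nutrients = nutrients, units = nutrientUnits(composition),
      groupIntake = groupIntake)
}

#' Default energy-conversion factors (kcal per gram)
#'
#' Atwater-style factors: 4 kcal/g for carbohydrate and protein, 9 kcal/g for
#' all lipid classes, 7 kcal/g for alcohol. Names must match nutrient names
#' in the intake profile; all mapped nutrients must be in grams.
#'
#' @return named numeric vector of kcal/g factors.
#' @export
defaultEnergyFactors <- function() {
  c(fat = 9, saturated_fat = 9, mufa = 9, pufa = 9, omega3 = 9, omega6 = 9,
    protein = 4, carbohydrate = 4, soluble_carbs = 4, alcohol = 7)
}

#' Percent of daily energy by macronutrient
#'
#' Computes `%En(x) = g/day(x) * kcal_per_g(x) / mean_daily_energy * 100` for
#' every factor-mapped nutrient present in the profile. Total energy is the
#' profile's own (composition-derived) energy, so the factors only apportion
#' shares.
#'
#' @param profiles an [IntakeProfiles-class].
#' @param factors named numeric kcal/g factors, see [defaultEnergyFactors()].
#' @return data.frame, one row per subject, one `pct_energy_*` column per
#'   mapped nutrient.
#' @export
computeEnergyShares <- function(profiles, factors = defaultEnergyFactors()) {
  stopifnot(is(profiles, "IntakeProfiles"))
  en <- dailyEnergy(profiles)
  if (any(en <= 0))
    stop("energy shares undefined for subjects with zero energy intake: ",
         paste(names(en)[en <= 0], collapse = ", "), call. = FALSE)
  nut <- intakeMatrix(profiles)
  use <- intersect(names(factors), colnames(nut))
  badUnit <- use[nutrientUnits(profiles)[use] != "g"]
  if (length(badUnit))
    stop("energy-share nutrients must be in grams: ",
         paste(badUnit, collapse = ", "), call. = FALSE)
  shares <- sweep(nut[, use, drop = FALSE] %*% diag(factors[use],
                                                    length(use)),
                  1, en, "/") * 100
  colnames(shares) <- paste0("pct_energy_", use)
  data.frame(subject_id = rownames(nut), shares, check.names = FALSE)
}
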