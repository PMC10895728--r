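# Fixtures built in code; everything is seeded and small.

tinyConfig <- function(seed = 42L, ...) {
  args <- utils::modifyList(list(nSubjects = 20, foodsPerSubgroup = 2,
                                 nProteins = 40, nPlanted = 6, seed = seed),
                            list(...))
  do.call(syntheticConfig, args)
}

# Memoised tiny cohort shared across tests that only read it.
tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateCohort(tinyConfig())
    cache
  }
})

# A minimal hand-written composition: 3 foods, 2 nutrients.
miniComposition <- function() {
  tab <- data.frame(
    food_id = c("A", "B", "C"),
    name = c("white bread", "olive oil", "apple"),
    group = c("cereals", "oils", "fruits"),
    subgroup = c("bread", "vegetable fats", "fresh fruit"),
    item = c("white bread", "olive oil", "apple"),
    energy_kcal_per_100g = c(270, 884, 52),
    fat = c(10, 99.9, 0.2),
    fiber = c(4, 0, 2.4))
  new("FoodComposition", table = tab, units = c(fat = "g", fiber = "g"))
}

recordRow <- function(subject, day, food, grams)
  data.frame(subject_id = subject, day = day, food_id = food, grams = grams)

# IntakeProfiles straight from a matrix (bypasses record aggregation).
profilesFromMatrix <- function(mat, units, energy = NULL) {
  energy <- energy %||% setNames(rep(2000, nrow(mat)), rownames(mat))
  new("IntakeProfiles", subjects = rownames(mat), energy = energy,
      nutrients = mat, units = units,
      groupIntake = data.frame(subject_id = character(0),
                               level = character(0), name = character(0),
                               g_per_day = numeric(0)))
}

# CohortSplit with prescribed group sizes (n1 high, n2 low).
splitOfSizes <- function(n1, n2) {
  subj <- sprintf("s%02d", seq_len(n1 + n2))
  dii <- c(rep(1, n1), rep(0, n2))
  new("CohortSplit", subjects = subj, dii = dii, medianDII = 0.5,
      label = factor(ifelse(dii >= 0.5, "high", "low"),
                     levels = c("low", "high")))
}

# Restrict a CohortSplit to a subject subset, keeping the global median and
# labels (used for leakage-free feature selection inside a training set).
subsetSplit <- function(sp, subjects) {
  i <- match(subjects, sp@subjects)
  new("CohortSplit", subjects = subjects, dii = sp@dii[i],
      medianDII = sp@medianDII, label = sp@label[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fastClassifierConfig <- function(seed = 1L, nRounds = 60)
  classifierConfig(nRounds = nRounds, learningRate = 0.05,
                   grid = data.frame(max_depth = 3L, subsample = 1.0),
                   seed = seed)
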