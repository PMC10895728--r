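writeComposition <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

compHeader <- "food_id\tname\tgroup\tsubgroup\titem\tenergy_kcal_per_100g\tfat[g]\tfiber[g]"

test_that("composition loader parses a well-formed table and validates units and ids", {
  tf <- writeComposition(c(compHeader,
    "A\tbread\tcereals\tbread\twhite bread\t270\t10\t4",
    "B\toil\toils\tvegetable fats\tolive oil\t884\t99.9\t0",
    "C\tapple\tfruits\tfresh fruit\tapple\t52\t0.2\t2.4"))
  comp <- loadFoodComposition(tf)
  expect_s4_class(comp, "FoodComposition")
  expect_equal(nrow(foodTable(comp)), 3)
  expect_equal(nutrientUnits(comp), c(fat = "g", fiber = "g"))

  dupFile <- writeComposition(c(compHeader,
    "A\tx\tg\ts\ti\t100\t1\t1", "A\ty\tg\ts\ti\t100\t1\t1"))
  expect_error(loadFoodComposition(dupFile), "A")

  ozFile <- writeComposition(c(sub("fiber\\[g\\]", "fiber[oz]", compHeader),
    "A\tx\tg\ts\ti\t100\t1\t1"))
  expect_error(loadFoodComposition(ozFile), "oz")

  mcg <- writeComposition(c(sub("fiber\\[g\\]", "b12[mcg]", compHeader),
    "A\tx\tg\ts\ti\t100\t1\t1"))
  expect_equal(unname(nutrientUnits(loadFoodComposition(mcg))["b12"]), "ug")
})

test_that("intake aggregation matches hand arithmetic and handles empty weeks", {
  comp <- miniComposition()

  # one entry: 200 g of 10 g fat/100 g on day 1 -> (200/100*10)/7 g/day
  prof <- computeIntake(recordRow("s1", 1, "A", 200), comp)
  expect_equal(intakeMatrix(prof)["s1", "fat"], 2.857142857, tolerance = 1e-9)
  expect_equal(unname(dailyEnergy(prof)["s1"]), 200 / 100 * 270 / 7)

  # two entries of the same food on different days, 100 g each, fiber 2.4/100g
  rec <- rbind(recordRow("s1", 2, "C", 100), recordRow("s1", 5, "C", 100))
  prof2 <- computeIntake(rec, comp)
  expect_equal(intakeMatrix(prof2)["s1", "fiber"], 2 * 2.4 / 7)

  # a subject that eats nothing all week has all-zero intakes
  prof3 <- computeIntake(recordRow("s1", 1, "A", 50), comp,
                         subjects = c("s1", "s2"))
  expect_true(all(intakeMatrix(prof3)["s2", ] == 0))
  expect_equal(unname(dailyEnergy(prof3)["s2"]), 0)
})

test_that("unresolvable foods error with subject/day/food; substitutions resolve chains and reject cycles", {
  comp <- miniComposition()
  expect_error(computeIntake(recordRow("s9", 3, "NOPE", 10), comp),
               "s9.*3.*NOPE")
  # one-step and chained substitution
  rec <- recordRow("s1", 1, "X", 100)
  profDirect <- computeIntake(recordRow("s1", 1, "A", 100), comp)
  profSub <- computeIntake(rec, comp, subs = c(X = "A"))
  expect_equal(intakeMatrix(profSub), intakeMatrix(profDirect))
  profChain <- computeIntake(rec, comp, subs = c(X = "Y", Y = "A"))
  expect_equal(intakeMatrix(profChain), intakeMatrix(profDirect))
  expect_error(computeIntake(rec, comp, subs = c(X = "Y", Y = "X")), "cycle")
})

test_that("intakes are linear in entries and conserve the food-group hierarchy", {
  coh <- tinyCohort()
  rec <- coh$records
  prof <- computeIntake(rec, coh$composition)

  # doubling every grams doubles nutrients and energy, leaves %En unchanged
  rec2 <- rec; rec2$grams <- 2 * rec2$grams
  prof2 <- computeIntake(rec2, coh$composition)
  expect_equal(intakeMatrix(prof2), 2 * intakeMatrix(prof))
  expect_equal(computeEnergyShares(prof2), computeEnergyShares(prof),
               tolerance = 1e-12)

  # merging two subjects' entries sums their profiles
  a <- rec[rec$subject_id == rec$subject_id[1], ]
  b <- rec[rec$subject_id == rec$subject_id[nrow(rec)], ]
  merged <- rbind(a, transform(b, subject_id = a$subject_id[1]))
  pm <- computeIntake(merged, coh$composition)
  pa <- computeIntake(a, coh$composition)
  pb <- computeIntake(b, coh$composition)
  expect_equal(as.vector(intakeMatrix(pm)),
               as.vector(intakeMatrix(pa) + intakeMatrix(pb)))

  # item totals sum to subgroup totals, subgroup to group
  gi <- foodGroupIntake(prof)
  tot <- tapply(gi$g_per_day, gi$level, sum)
  expect_equal(tot[["item"]], tot[["subgroup"]])
  expect_equal(tot[["subgroup"]], tot[["group"]])
})

test_that("aggregation agrees with a brute-force entry-by-entry oracle", {
  coh <- tinyCohort()
  rec <- coh$records
  tab <- foodTable(coh$composition)
  prof <- computeIntake(rec, coh$composition)
  nut <- names(nutrientUnits(coh$composition))
  for (s in unique(rec$subject_id)[1:5]) {
    rs <- rec[rec$subject_id == s, ]
    expected <- setNames(numeric(length(nut)), nut)
    for (i in seq_len(nrow(rs))) {
      row <- tab[tab$food_id == rs$food_id[i], ]
      for (n in nut) expected[n] <- expected[n] + rs$grams[i] / 100 * row[[n]]
    }
    expect_equal(intakeMatrix(prof)[s, ], expected / 7, tolerance = 1e-9)
  }
})

test_that("energy shares follow the kcal-per-gram arithmetic", {
  mat <- matrix(c(40, 0, 10), 1, 3,
                dimnames = list("s1", c("fat", "saturated_fat", "alcohol")))
  prof <- profilesFromMatrix(mat,
    units = c(fat = "g", saturated_fat = "g", alcohol = "g"),
    energy = c(s1 = 1800))
  sh <- computeEnergyShares(prof)
  expect_equal(sh$pct_energy_fat, 20.0)            # 40*9/1800*100
  expect_equal(sh$pct_energy_saturated_fat, 0)
  prof2 <- profilesFromMatrix(mat, units = c(fat = "g", saturated_fat = "g",
                                             alcohol = "g"),
                              energy = c(s1 = 1400))
  expect_equal(computeEnergyShares(prof2)$pct_energy_alcohol, 5.0) # 10*7/1400
  prof0 <- profilesFromMatrix(mat, units = c(fat = "g", saturated_fat = "g",
                                             alcohol = "g"),
                              energy = c(s1 = 0))
  expect_error(computeEnergyShares(prof0), "zero energy")
})
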