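test_that("the generator is deterministic and rejects impossible configs", {
  a <- generateCohort(tinyConfig(5))
  b <- generateCohort(tinyConfig(5))
  expect_identical(npx(a$npx), npx(b$npx))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$planted, b$truth$planted)
  c <- generateCohort(tinyConfig(6))
  expect_false(identical(npx(a$npx), npx(c$npx)))
  expect_error(syntheticConfig(nProteins = 10, nPlanted = 11), "planted")
})

test_that("a zero planted shift leaves all proteins null on average", {
  coh <- generateCohort(tinyConfig(9, plantedShift = 0, nSubjects = 60))
  exposed <- coh$truth$exposed
  mat <- npx(coh$npx)
  d <- rowMeans(mat[, exposed]) - rowMeans(mat[, !exposed])
  expect_lt(abs(mean(d)), 0.15)
  expect_lt(max(abs(d)), 1)
})

test_that("western subjects exceed prudent in saturated-fat energy share and in DII", {
  diiGap <- satFatGap <- numeric(5)
  for (i in 1:5) {
    coh <- generateCohort(syntheticConfig(nSubjects = 80, nProteins = 10,
                                          nPlanted = 2, seed = 300 + i))
    prof <- computeIntake(coh$records, coh$composition)
    west <- coh$truth$archetype[prof@subjects] == "western"
    sh <- computeEnergyShares(prof)
    satFatGap[i] <- mean(sh$pct_energy_saturated_fat[west]) -
      mean(sh$pct_energy_saturated_fat[!west])
    dii <- diiTotals(computeDII(prof, coh$reference))$dii_total
    diiGap[i] <- median(dii[west]) - median(dii[!west])
  }
  expect_true(all(satFatGap > 0))
  expect_true(all(diiGap > 0))
})

test_that("planted NPX shifts point the directions recorded in the ground truth", {
  coh <- generateCohort(syntheticConfig(nSubjects = 400, nProteins = 60,
                                        nPlanted = 10, seed = 23))
  mat <- npx(coh$npx)
  exposed <- coh$truth$exposed
  pl <- coh$truth$planted
  d <- rowMeans(mat[pl$protein, exposed]) - rowMeans(mat[pl$protein, !exposed])
  expect_true(all(sign(d) == pl$sign))
})

test_that("the emitted bundle round-trips through every loader", {
  dir <- file.path(tempdir(), "bundle")
  paths <- emitFixture(dir, size = "tiny", seed = 31)
  comp <- loadFoodComposition(paths["composition"])
  expect_equal(nrow(foodTable(comp)), 30)
  rec <- loadDietaryRecords(paths["records"])
  subs <- loadSubstitutions(paths["substitutions"])
  prof <- computeIntake(rec, comp, subs)      # aliases resolve via the map
  expect_equal(length(prof@subjects), 20)
  ref <- loadDIIReference(paths["reference"])
  expect_s4_class(computeDII(prof, ref), "DIIResult")
  x <- readNPX(paths["npx"])
  expect_equal(dim(x), c(40L, 20L))
  coll <- readGMT(paths["gmt"], background = rownames(x))
  expect_s3_class(enrich(rownames(x)[1:5], coll), "data.frame")
  truth <- jsonlite::read_json(paths["truth"])
  expect_length(truth$archetype, 20)

  # byte-identical re-emission under the same seed
  dir2 <- file.path(tempdir(), "bundle_again")
  paths2 <- emitFixture(dir2, size = "tiny", seed = 31)
  for (nm in names(paths))
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]),
                     label = nm)
})

test_that("long and wide NPX layouts load identically", {
  coh <- tinyCohort()
  wide <- tempfile(fileext = ".tsv")
  writeNPX(coh$npx, wide)
  mat <- npx(coh$npx)
  long <- tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = rep(colnames(mat), each = nrow(mat)),
                   protein = rep(rownames(mat), ncol(mat)),
                   npx = as.vector(mat))
  write.table(df, long, sep = "\t", quote = FALSE, row.names = FALSE)
  xw <- readNPX(wide)
  xl <- readNPX(long)
  expect_equal(npx(xl)[rownames(xw), colnames(xw)], npx(xw))
})
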