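refRow <- function(parameter, mean, sd, score, unit = "g")
  data.frame(parameter = parameter, unit = unit, global_mean = mean,
             global_sd = sd, effect_score = score)

test_that("centered percentile is 2*Phi(z)-1: odd, increasing, matches numerical integration", {
  expect_equal(centeredPercentile(0), 0)
  z <- c(-2.5, -1, -0.3, 0.7, 1.9, 2)
  expect_equal(centeredPercentile(-z), -centeredPercentile(z))
  expect_equal(centeredPercentile(2), 0.954499736, tolerance = 1e-9)
  expect_equal(centeredPercentile(z), 2 * normCdfNumeric(z) - 1,
               tolerance = 1e-10)
  expect_true(all(diff(centeredPercentile(seq(-4, 4, 0.1))) > 0))
  expect_error(centeredPercentile(Inf), "finite")
})

test_that("DII composes z-score, centered percentile and effect score", {
  ref <- new("DIIReference", quantiles = list(),
             table = refRow("fat", 10, 2, 0.5))
  # intake at the global mean scores zero
  prof <- profilesFromMatrix(matrix(10, 1, 1, dimnames = list("s1", "fat")),
                             units = c(fat = "g"))
  expect_equal(diiTotals(computeDII(prof, ref))$dii_total, 0)
  # z = 2 -> 0.954499736 * 0.5
  prof14 <- profilesFromMatrix(matrix(14, 1, 1, dimnames = list("s1", "fat")),
                               units = c(fat = "g"))
  expect_equal(diiTotals(computeDII(prof14, ref))$dii_total, 0.477249868,
               tolerance = 1e-9)
  # zero effect score contributes exactly zero whatever the intake
  ref0 <- new("DIIReference", quantiles = list(),
              table = refRow("fat", 10, 2, 0))
  expect_equal(diiTotals(computeDII(prof14, ref0))$dii_total, 0)
})

test_that("missing-parameter policy, unit mismatch and empty overlap are enforced", {
  tab <- rbind(refRow("fat", 10, 2, 0.5), refRow("fiber", 20, 5, -0.6))
  ref <- new("DIIReference", table = tab, quantiles = list())
  prof <- profilesFromMatrix(matrix(14, 1, 1, dimnames = list("s1", "fat")),
                             units = c(fat = "g"))
  res <- computeDII(prof, ref)                      # default: skip
  expect_equal(diiTotals(res)$n_parameters_used, 1)
  expect_error(computeDII(prof, ref, missing = "error"), "fiber")

  refMg <- new("DIIReference", quantiles = list(),
               table = refRow("fat", 10, 2, 0.5, unit = "mg"))
  expect_error(computeDII(prof, refMg), "unit mismatch.*fat")

  refOther <- new("DIIReference", quantiles = list(),
                  table = refRow("zinc", 10, 2, 0.5, unit = "mg"))
  expect_error(computeDII(prof, refOther), "no reference parameter")
})

test_that("DII is monotone in intake, bounded by the effect scores, and order-invariant", {
  set.seed(7)
  tab <- rbind(refRow("fat", 30, 8, 0.4), refRow("fiber", 18, 6, -0.66),
               refRow("pufa", 10, 4, -0.44))
  ref <- new("DIIReference", table = tab, quantiles = list())
  units <- c(fat = "g", fiber = "g", pufa = "g")
  base <- matrix(runif(30, 5, 40), 10, 3,
                 dimnames = list(sprintf("s%d", 1:10), names(units)))
  prof <- profilesFromMatrix(base, units)
  dii <- diiTotals(computeDII(prof, ref))$dii_total

  up <- base; up[, "fat"] <- up[, "fat"] + 5        # pro-inflammatory up
  diiUp <- diiTotals(computeDII(profilesFromMatrix(up, units), ref))$dii_total
  expect_true(all(diiUp >= dii))
  fUp <- base; fUp[, "fiber"] <- fUp[, "fiber"] + 5 # anti-inflammatory up
  diiF <- diiTotals(computeDII(profilesFromMatrix(fUp, units), ref))$dii_total
  expect_true(all(diiF <= dii))

  expect_true(all(abs(dii) < sum(abs(tab$effect_score))))

  refPerm <- new("DIIReference", table = tab[c(3, 1, 2), ],
                 quantiles = list())
  expect_equal(diiTotals(computeDII(prof, refPerm))$dii_total, dii)
})

test_that("DII equals the brute-force numerical-CDF oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    params <- sprintf("nut%d", seq_len(k))
    tab <- do.call(rbind, lapply(params, function(p)
      refRow(p, runif(1, 1, 100), runif(1, 0.5, 30), runif(1, -1, 1))))
    ref <- new("DIIReference", table = tab, quantiles = list())
    units <- setNames(rep("g", k), params)
    mat <- matrix(runif(3 * k, 0, 150), 3, k,
                  dimnames = list(c("a", "b", "c"), params))
    got <- diiTotals(computeDII(profilesFromMatrix(mat, units), ref))
    for (i in 1:3) {
      want <- diiBruteForce(setNames(as.list(mat[i, ]), params), tab)
      expect_equal(got$dii_total[i], want, tolerance = 1e-9)
    }
  }
})

test_that("an empirical reference distribution overrides the normal CDF", {
  tab <- refRow("fat", 10, 2, 1)
  q <- setNames(seq(0, 40, length.out = 101), seq(0, 1, length.out = 101))
  ref <- new("DIIReference", table = tab, quantiles = list(fat = q))
  prof <- profilesFromMatrix(matrix(30, 1, 1, dimnames = list("s1", "fat")),
                             units = c(fat = "g"))
  # intake 30 sits at the 75th percentile of the uniform 0..40 reference
  expect_equal(diiTotals(computeDII(prof, ref))$dii_total, 2 * 0.75 - 1,
               tolerance = 1e-9)
})
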