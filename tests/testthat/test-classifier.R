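test_that("stratified split preserves class proportions and is seed-determined", {
  lab <- setNames(factor(rep(c("high", "low"), each = 50),
                         levels = c("low", "high")),
                  sprintf("s%03d", 1:100))
  cc <- classifierConfig(seed = 9)
  part <- stratifiedSplit(lab, cc)
  expect_length(part$train, 60)
  expect_equal(as.vector(table(lab[part$train])), c(30, 30))
  expect_identical(part, stratifiedSplit(lab, cc))
  expect_length(intersect(part$train, part$test), 0)

  # 663 subjects labelled 332/331: train within one subject of 60% per class
  lab663 <- setNames(factor(c(rep("high", 332), rep("low", 331)),
                            levels = c("low", "high")),
                     sprintf("t%03d", 1:663))
  p663 <- stratifiedSplit(lab663, cc)
  expect_true(length(p663$train) %in% c(397, 398))
  byClass <- table(lab663[p663$train])
  expect_true(abs(byClass[["high"]] - 0.6 * 332) <= 1)
  expect_true(abs(byClass[["low"]] - 0.6 * 331) <= 1)

  expect_error(stratifiedSplit(setNames(factor(c("a", "a", "b")),
                                        c("x", "y", "z"))),
               "at least 2")
})

test_that("concordance AUC equals the brute-force pair count, including ties", {
  expect_equal(aucConcordance(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucConcordance(c(0.7, 0.3), c(0.6, 0.4)), 0.5)
  expect_equal(aucConcordance(rep(0.5, 4), rep(0.5, 6)), 0.5)
  set.seed(21)
  for (i in 1:30) {
    pos <- sample(seq(0, 1, 0.05), sample(2:25, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.05), sample(2:25, 1), replace = TRUE)
    expect_equal(aucConcordance(pos, neg), aucBruteForce(pos, neg))
  }
})

test_that("a perfectly separating feature takes essentially all the importance", {
  set.seed(4)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(signal = y * 2 - 1 + rnorm(n, 0, 0.05), noise = rnorm(n))
  rownames(X) <- sprintf("s%d", 1:n)
  fit <- fitBoostedClassifier(X, y, fastClassifierConfig(4), tune = FALSE)
  expect_equal(fit$ranking$protein[1], "signal")
  expect_gt(fit$ranking$normalized_share[1], 0.95)
  expect_equal(sum(fit$ranking$normalized_share), 1)
  expect_true(all(diff(fit$ranking$importance) <= 0))
  expect_error(fitBoostedClassifier(X[, 1, drop = FALSE], y,
                                    fastClassifierConfig(4)),
               "at least 2 features")
})

test_that("permuted labels give chance-level test AUC; planted signal is learned", {
  set.seed(6)
  n <- 200
  y <- setNames(factor(rep(c("low", "high"), each = n / 2),
                       levels = c("low", "high")), sprintf("s%d", 1:n))
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(names(y), sprintf("P%d", 1:8)))
  X[y == "high", 1:4] <- X[y == "high", 1:4] + 1.2
  cc <- fastClassifierConfig(6, nRounds = 120)
  part <- stratifiedSplit(y, cc)
  fit <- fitBoostedClassifier(X[part$train, ], y[part$train], cc,
                              tune = FALSE)
  roc <- evaluateROC(fit$model, X[part$test, ], y[part$test], seed = 6)
  expect_gt(roc$auc, 0.8)

  yPerm <- setNames(sample(y), names(y))
  fitP <- fitBoostedClassifier(X[part$train, ], yPerm[part$train], cc,
                               tune = FALSE)
  rocP <- evaluateROC(fitP$model, X[part$test, ], yPerm[part$test], seed = 6)
  expect_gt(rocP$auc, 0.35)
  expect_lt(rocP$auc, 0.65)
})

test_that("ROC report is internally consistent and seed-deterministic", {
  set.seed(10)
  scores <- c(rnorm(40, 1), rnorm(40))
  y <- rep(c(1, 0), each = 40)
  r1 <- evaluateROC(NULL, NULL, y, seed = 99, scores = scores)
  r2 <- evaluateROC(NULL, NULL, y, seed = 99, scores = scores)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)
  expect_equal(r1$curve$fpr[1], 0)
  expect_equal(r1$curve$tpr[nrow(r1$curve)], 1)
  expect_true(all(diff(r1$curve$fpr) >= 0))
  expect_true(all(diff(r1$curve$tpr) >= 0))
  expect_error(evaluateROC(NULL, NULL, rep(1, 10), scores = rnorm(10)),
               "both classes")
})

test_that("top-feature selection is rank-ordered with lexicographic ties", {
  ranking <- data.frame(protein = c("B", "A", "C"),
                        importance = c(0.5, 0.3, 0.2),
                        normalized_share = c(0.5, 0.3, 0.2), rank = 1:3)
  expect_equal(selectTopFeatures(ranking, 3), c("B", "A", "C"))
  expect_equal(selectTopFeatures(ranking, 1), "B")
  expect_error(selectTopFeatures(ranking, 0), ">= 1")
  expect_error(selectTopFeatures(ranking, 4), "exceeds")
  # ties broken lexicographically by the constructor's ordering
  set.seed(1)
  n <- 40
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("zeta", "alpha")))
  fit <- fitBoostedClassifier(X, y, fastClassifierConfig(1, 10), tune = FALSE)
  ties <- fit$ranking$importance[1] == fit$ranking$importance[2]
  if (ties) expect_equal(fit$ranking$protein, c("alpha", "zeta"))
})
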