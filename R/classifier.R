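#' Configuration of the boosted DII-group classifier
#'
#' Defaults follow the study design this pipeline mirrors: a random 60/40
#' train/test split, 1000 boosting rounds at a learning rate below 0.001
#' (0.0005 by default), and hyperparameter tuning by k-fold cross-validation
#' internal to the training set over a small grid of tree depth and row
#' subsampling.
#'
#' @param trainFraction share of subjects in the training set.
#' @param nRounds boosting rounds.
#' @param learningRate shrinkage (eta), must be positive.
#' @param kFolds folds for hyperparameter tuning.
#' @param grid data.frame of hyperparameter combinations with columns
#'   `max_depth` and `subsample`.
#' @param seed integer seed driving the split, fold assignment and training.
#' @return a list of class `classifierConfig`.
#' @export
classifierConfig <- function(trainFraction = 0.6, nRounds = 1000,
                             learningRate = 5e-4, kFolds = 5,
                             grid = expand.grid(max_depth = c(2L, 3L, 4L),
                                                subsample = c(0.8, 1.0)),
                             seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1, nRounds >= 1,
            learningRate > 0, kFolds >= 2,
            all(c("max_depth", "subsample") %in% names(grid)))
  structure(list(trainFraction = trainFraction, nRounds = nRounds,
                 learningRate = learningRate, kFolds = kFolds, grid = grid,
                 seed = as.integer(seed)),
            class = "classifierConfig")
}

#' Stratified train/test split
#'
#' Random split preserving class proportions: within each class,
#' `round(trainFraction * n_class)` subjects go to the training set. Fully
#' determined by the config seed.
#'
#' @param labels factor (or coercible) of class labels named by subject.
#' @param config a [classifierConfig()].
#' @return list with character vectors `train` and `test` of subject ids.
#' @export
stratifiedSplit <- function(labels, config = classifierConfig()) {
  labels <- as.factor(labels)
  if (is.null(names(labels)))
    stop("labels must be named by subject id", call. = FALSE)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 members", call. = FALSE)
  train <- withSeed(config$seed, {
    unlist(lapply(levels(labels), function(cl) {
      ids <- names(labels)[labels == cl]
      sample(ids, round(config$trainFraction * length(ids)))
    }), use.names = FALSE)
  })
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

# Pick grid hyperparameters by stratified k-fold CV AUC on the training set
# only: every grid point is trained on the same fold assignment and scored by
# the mean held-out-fold AUC at the final round.
tuneByCV <- function(X, y, config) {
  fold <- withSeed(childSeed(config$seed, "folds"), {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep(seq_len(config$kFolds), length.out = length(idx)))
    }
    f
  })
  cvAuc <- vapply(seq_len(nrow(config$grid)), function(i) {
    params <- list(objective = "binary:logistic", eta = config$learningRate,
                   max_depth = config$grid$max_depth[i],
                   subsample = config$grid$subsample[i],
                   nthread = 1, tree_method = "hist", seed = config$seed)
    mean(vapply(seq_len(config$kFolds), function(k) {
      tr <- fold != k
      dk <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                 nthread = 1)
      mk <- withSeed(childSeed(config$seed, paste0("cv", i, "_", k)),
        xgboost::xgb.train(params = params, data = dk,
                           nrounds = config$nRounds, verbose = 0))
      sc <- predict(mk, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                             nthread = 1))
      aucConcordance(sc[y[!tr] == 1], sc[y[!tr] == 0])
    }, numeric(1)))
  }, numeric(1))
  config$grid[which.max(cvAuc), , drop = FALSE]
}

#' Fit the gradient-boosted DII-group classifier
#'
#' Trains an XGBoost binary classifier of high-vs-low DII membership on the
#' NPX values of the differentially abundant proteins. Hyperparameters
#' (tree depth, row subsampling) are chosen by k-fold cross-validated AUC on
#' the training set only; the final model is refit on the whole training set
#' at the configured rounds and learning rate. Feature importance is
#' gain-based and normalized to shares summing to 1.
#'
#' @param trainX numeric matrix, training subjects x features (proteins).
#' @param trainY labels: factor with "high" as the positive class, or 0/1.
#' @param config a [classifierConfig()].
#' @param tune run the cross-validated grid search (set `FALSE` to train at
#'   the first grid row directly).
#' @return list with elements `model` (an `xgb.Booster`), `ranking`
#'   (data.frame `protein`, `importance`, `normalized_share`, `rank`) and
#'   `params` (the chosen hyperparameters).
#' @export
fitBoostedClassifier <- function(trainX, trainY, config = classifierConfig(),
                                 tune = TRUE) {
  if (ncol(trainX) < 2)
    stop("classifier needs at least 2 features", call. = FALSE)
  y <- if (is.factor(trainY)) as.integer(trainY == "high") else
    as.integer(trainY)
  stopifnot(length(y) == nrow(trainX), all(y %in% 0:1))
  trainX <- as.matrix(trainX)
  dtrain <- xgboost::xgb.DMatrix(data = trainX, label = y, nthread = 1)
  best <- if (tune) tuneByCV(trainX, y, config) else
    config$grid[1, , drop = FALSE]
  params <- list(objective = "binary:logistic", eta = config$learningRate,
                 max_depth = best$max_depth, subsample = best$subsample,
                 nthread = 1, tree_method = "hist", seed = config$seed)
  model <- withSeed(childSeed(config$seed, "fit"),
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = config$nRounds, verbose = 0))

  imp <- xgboost::xgb.importance(model = model)
  gain <- setNames(rep(0, ncol(trainX)), colnames(trainX))
  gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, names(gain))
  ranking <- data.frame(protein = names(gain)[ord],
                        importance = unname(gain[ord]),
                        normalized_share = if (sum(gain) > 0)
                          unname(gain[ord]) / sum(gain) else
                          rep(0, length(gain)),
                        rank = seq_along(gain))
  list(model = model, ranking = ranking, params = best)
}

#' AUC by concordance counting
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted 1/2 — computed through midranks, which is exactly equivalent
#' to counting all positive/negative pairs.
#'
#' @param scoresPos,scoresNeg numeric scores of the two classes.
#' @return AUC in [0, 1].
#' @export
aucConcordance <- function(scoresPos, scoresNeg) {
  n1 <- length(scoresPos); n0 <- length(scoresNeg)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(c(scoresPos, scoresNeg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Empirical ROC curve points from (0,0) to (1,1), thresholds descending.
rocPoints <- function(scoresPos, scoresNeg) {
  th <- sort(unique(c(scoresPos, scoresNeg)), decreasing = TRUE)
  fpr <- vapply(th, function(t) mean(scoresNeg >= t), numeric(1))
  tpr <- vapply(th, function(t) mean(scoresPos >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' ROC evaluation on the held-out test set
#'
#' Scores the test subjects with the fitted model and reports the AUC
#' (concordance counting, ties 1/2), a 95% percentile-bootstrap confidence
#' interval over test subjects (widened if needed to cover the point
#' estimate), a p-value against AUC = 0.5 from the
#' rank-sum correspondence (the AUC is a rescaled Mann-Whitney U statistic),
#' and the empirical ROC curve points.
#'
#' @param model an `xgb.Booster` from [fitBoostedClassifier()], or `NULL` if
#'   `scores` are supplied directly.
#' @param testX numeric matrix of test subjects x features (ignored when
#'   `scores` given).
#' @param testY labels: factor with positive class "high", or 0/1.
#' @param nBootstrap bootstrap resamples for the CI.
#' @param seed integer seed for the bootstrap.
#' @param scores optional numeric vector of scores, bypassing the model.
#' @return list `auc`, `ci_low`, `ci_high`, `p_value`, `curve`, `n_pos`,
#'   `n_neg`.
#' @export
evaluateROC <- function(model, testX, testY, nBootstrap = 2000, seed = 1L,
                        scores = NULL) {
  y <- if (is.factor(testY)) as.integer(testY == "high") else
    as.integer(testY)
  if (length(unique(y)) < 2)
    stop("test set must contain both classes", call. = FALSE)
  if (is.null(scores))
    scores <- predict(model, xgboost::xgb.DMatrix(as.matrix(testX),
                                                  nthread = 1))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  auc <- aucConcordance(pos, neg)

  boot <- withSeed(seed, {
    n <- length(scores)
    vapply(seq_len(nBootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (length(unique(yb)) < 2) return(NA_real_)
      aucConcordance(scores[idx][yb == 1], scores[idx][yb == 0])
    }, numeric(1))
  })
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  # the percentile interval is widened, if needed, to cover the observed AUC
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  p <- if (length(unique(scores)) == 1L) 1 else
    suppressWarnings(wilcox.test(pos, neg, exact = FALSE,
                                 correct = TRUE)$p.value)
  list(auc = auc, ci_low = ci[1], ci_high = ci[2], p_value = p,
       curve = rocPoints(pos, neg), n_pos = length(pos),
       n_neg = length(neg))
}

#' Top features by importance
#'
#' First `n` features of the ranking, ties at the cutoff broken
#' lexicographically by protein id (the ranking is already ordered this way).
#'
#' @param ranking data.frame from [fitBoostedClassifier()].
#' @param n number of features, `1 <= n <= nrow(ranking)`.
#' @return character vector of protein ids.
#' @export
selectTopFeatures <- function(ranking, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n > nrow(ranking))
    stop("n exceeds the number of ranked features", call. = FALSE)
  ranking$protein[seq_len(n)]
}
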