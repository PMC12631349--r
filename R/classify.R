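#' @include AllClasses.R utils.R
NULL

#' Validation fold plan
#'
#' Describes how epochs are split for leakage-safe evaluation. Grouped
#' k-fold assigns whole groups (laps by default, so temporally contiguous
#' segment runs never straddle folds) to folds; a purge gap additionally
#' excludes training epochs whose segment lies within `purge_gap` positions
#' of any held-out segment of the same subject in session order, removing
#' autocorrelation leakage across fold boundaries. Split-sample performs a
#' single grouped train/test split; LOSO holds out each subject in turn;
#' cross-mode trains on manual-driving epochs and tests on replay epochs.
#'
#' @param scheme one of `"group-kfold"`, `"split-sample"`, `"loso"`,
#'   `"cross-mode"`.
#' @param n_folds folds for group-kfold (default 5).
#' @param group_key grouping unit for group-kfold: `"segment"` (default;
#'   one epoch per road segment, with the purge gap guarding temporal
#'   adjacency) or `"lap"` (whole laps held out; note that with few laps
#'   per mode this confounds a subject's training class balance, since
#'   each lap contains a single engagement mode).
#' @param purge_gap number of neighbouring segments (each side) excluded
#'   from training around held-out segments (default 1).
#' @param balance down-sample training classes to equal size within folds.
#' @param test_fraction held-out fraction for split-sample (default 0.25).
#' @param seed RNG seed for fold assignment and balancing.
#' @return A `FoldPlan` list.
#' @export
foldPlan <- function(scheme = c("group-kfold", "split-sample", "loso",
                                "cross-mode"),
                     n_folds = 5L, group_key = c("segment", "lap"),
                     purge_gap = 1L, balance = TRUE, test_fraction = 0.25,
                     seed = 1L) {
  structure(list(scheme = match.arg(scheme), n_folds = as.integer(n_folds),
                 group_key = match.arg(group_key),
                 purge_gap = as.integer(purge_gap), balance = balance,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "FoldPlan")
}

#' Random-forest classifier settings
#'
#' An ensemble of randomized decision trees exposing per-feature impurity
#' importances (normalized to sum to 1 when reported).
#'
#' @param n_trees number of trees (default 500).
#' @param max_depth maximal tree depth (0 = unlimited).
#' @param mtry features sampled per split (NULL = ranger default).
#' @param seed RNG seed for tree construction.
#' @return A `ClassifierSpec` list.
#' @export
classifierSpec <- function(n_trees = 500L, max_depth = 0L, mtry = NULL,
                           seed = 1L) {
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), mtry = mtry,
                 seed = as.integer(seed)), class = "ClassifierSpec")
}

# ---- internals -------------------------------------------------------------

featureMatrix <- function(features) {
  t(SummarizedExperiment::assay(features, "features")) # epochs x features
}

featureInfo <- function(features) {
  as.data.frame(SummarizedExperiment::colData(features))
}

# session-order index of each epoch's segment within its subject
globalSegmentIndex <- function(info) {
  idx <- numeric(nrow(info))
  for (s in unique(info$subject)) {
    sel <- info$subject == s
    ord <- order(info$lap[sel], info$segment[sel])
    idx[sel][ord] <- seq_len(sum(sel))
  }
  idx
}

#' Vectorized one-way ANOVA F statistics
#'
#' Classic between/within mean-square ratio of each feature across classes;
#' matches `stats::oneway.test(var.equal = TRUE)` and `aov`.
#'
#' @param X epochs x features numeric matrix.
#' @param labels class label per epoch (>= 2 classes).
#' @return Numeric vector of F statistics (0 where within-class variance
#'   vanishes with no between-class spread; Inf where only within vanishes).
#' @export
anovaFScores <- function(X, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  n <- nrow(X)
  k <- nlevels(labels)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (lv in levels(labels)) {
    sel <- labels == lv
    m <- colMeans(X[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[sel, , drop = FALSE], 2, m)^2)
  }
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  F[ssw == 0 & ssb == 0] <- 0
  F
}

#' Two-stage feature selection
#'
#' Stage 1 ranks all features by random-forest impurity importance (fitted
#' on the training rows only) and keeps the top `k1`; stage 2 re-ranks that
#' subset by univariate one-way ANOVA F across the classes and keeps the
#' top `k2 <= k1`. Deterministic for a fixed seed.
#'
#' @param X epochs x features training matrix (column names = features).
#' @param labels training class labels.
#' @param k1 stage-1 pool size (capped at the number of features).
#' @param k2 final count (`k2 <= k1`).
#' @param spec a [classifierSpec()] for the stage-1 forest.
#' @return Integer feature indices, ordered by decreasing F.
#' @export
twoStageSelect <- function(X, labels, k1 = 200L, k2 = 100L,
                           spec = classifierSpec()) {
  if (k2 > k1) stop("k2 must be <= k1")
  k1 <- min(k1, ncol(X)); k2 <- min(k2, k1)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- factor(labels)
  rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = spec$n_trees,
                       max.depth = spec$max_depth, mtry = spec$mtry,
                       importance = "impurity", seed = spec$seed,
                       num.threads = 1L)
  imp <- rf$variable.importance
  pool <- order(imp, decreasing = TRUE)[seq_len(k1)]
  F <- anovaFScores(X[, pool, drop = FALSE], labels)
  pool[order(F, decreasing = TRUE)[seq_len(k2)]]
}

# balanced down-sampling of class indices (training rows)
balanceIndices <- function(idx, labels, seed) {
  localSeed(seed, {
    tb <- table(labels[idx])
    nmin <- min(tb)
    unlist(lapply(names(tb), function(lv) {
      cand <- idx[labels[idx] == lv]
      if (length(cand) > nmin) sort(sample(cand, nmin)) else cand
    }), use.names = FALSE)
  })
}

# z-score columns by train statistics; returns list(train, test, mu, sd)
standardizeFold <- function(X, train, test, epsilon = 1e-8) {
  mu <- colMeans(X[train, , drop = FALSE])
  sg <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sg[sg < epsilon] <- epsilon
  list(train = sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, sg, "/"),
       test = sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/"),
       mu = mu, sd = sg)
}

fitPredictRF <- function(Xtr, ytr, Xte, spec, fold_seed) {
  df <- data.frame(Xtr, check.names = FALSE)
  df$.y <- factor(ytr)
  rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = spec$n_trees, max.depth = spec$max_depth,
                       mtry = spec$mtry, importance = "impurity",
                       seed = fold_seed, num.threads = 1L)
  pred <- stats::predict(rf, data.frame(Xte, check.names = FALSE),
                         num.threads = 1L)$predictions
  list(pred = as.character(pred), importance = rf$variable.importance)
}

confusionMatrix <- function(truth, pred, classes) {
  M <- matrix(0, length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth)) M[truth[i], pred[i]] <- M[truth[i], pred[i]] + 1
  M
}

normalizeConfusion <- function(M) {
  rs <- rowSums(M)
  sweep(M, 1, ifelse(rs == 0, 1, rs), "/")
}

macroF1 <- function(M) {
  f1 <- vapply(seq_len(nrow(M)), function(k) {
    tp <- M[k, k]
    prec <- if (sum(M[, k]) == 0) 0 else tp / sum(M[, k])
    rec <- if (sum(M[k, ]) == 0) 0 else tp / sum(M[k, ])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

# fold assignment of group ids: seeded shuffle then round-robin
assignFolds <- function(group_ids, n_folds, seed) {
  ug <- unique(group_ids)
  localSeed(seed, {
    shuffled <- sample(ug)
    f <- rep(seq_len(n_folds), length.out = length(ug))
    stats::setNames(f, shuffled)
  })
}

# ---- cross-validated evaluation -------------------------------------------

#' Leakage-safe cross-validated classification
#'
#' Runs the full nested pipeline per fold: class balancing by seeded
#' down-sampling, per-feature z-scoring fitted on training rows, two-stage
#' feature selection fitted on training rows, random-forest fit and
#' held-out prediction. A leakage audit asserts for every fold that no test
#' group appears in training, that no training epoch lies within the purge
#' gap of a held-out segment, and that the normalizer statistics equal a
#' train-only recomputation.
#'
#' @param features a [FeatureTable-class].
#' @param plan a [foldPlan()] (`"group-kfold"` or `"split-sample"`).
#' @param spec a [classifierSpec()].
#' @param k1,k2 two-stage selection sizes (defaults 200 and 100).
#' @param labels optional label vector overriding `colData(features)$label`
#'   (e.g. binary tasks).
#' @return An `EvalReport` list: `accuracy`, `accuracy_sd` (across folds),
#'   `macro_f1`, `per_class` (precision/recall), `confusion` (row
#'   normalized), `per_fold`, `chance_p`, `importance` (fold-averaged,
#'   sums to 1), `audit`.
#' @export
runCV <- function(features, plan = foldPlan(), spec = classifierSpec(),
                  k1 = 200L, k2 = 100L, labels = NULL) {
  stopifnot(is(features, "FeatureTable"))
  X <- featureMatrix(features)
  info <- featureInfo(features)
  y <- if (is.null(labels)) info$label else as.character(labels)
  classes <- sort(unique(y))
  segpos <- globalSegmentIndex(info)
  group <- if (plan$group_key == "lap")
    paste(info$subject, info$lap, sep = "/")
  else paste(info$subject, info$lap, info$segment, sep = "/")

  if (plan$scheme == "split-sample") {
    fold_of <- assignFolds(group, round(1 / plan$test_fraction), plan$seed)
    fold_sets <- list(which(fold_of[group] == 1L))
  } else {
    fold_of <- assignFolds(group, plan$n_folds, plan$seed)
    fold_sets <- lapply(seq_len(plan$n_folds),
                        function(f) which(fold_of[group] == f))
  }

  per_fold <- list(); preds <- character(0); truths <- character(0)
  imp_sum <- numeric(ncol(X)); names(imp_sum) <- colnames(X)
  audit <- list()
  for (f in seq_along(fold_sets)) {
    test <- fold_sets[[f]]
    if (length(test) == 0) next
    if (length(unique(y[test])) < 2) {
      warning(sprintf("fold %d has a single class in test; skipped", f))
      next
    }
    train <- setdiff(seq_len(nrow(X)), test)
    # purge: drop training epochs temporally adjacent to held-out segments
    purged <- integer(0)
    if (plan$purge_gap > 0) {
      for (s in unique(info$subject[test])) {
        tpos <- segpos[test][info$subject[test] == s]
        cand <- train[info$subject[train] == s]
        near <- cand[vapply(segpos[cand], function(p)
          any(abs(p - tpos) <= plan$purge_gap), logical(1))]
        purged <- c(purged, near)
      }
      train <- setdiff(train, purged)
    }
    if (plan$balance)
      train <- balanceIndices(train, y, childSeed(plan$seed, f, 1L))
    std <- standardizeFold(X, train, test)
    sel <- twoStageSelect(std$train, y[train], k1, k2,
                          classifierSpec(spec$n_trees, spec$max_depth,
                                         spec$mtry,
                                         childSeed(spec$seed, f, 2L)))
    fit <- fitPredictRF(std$train[, sel, drop = FALSE], y[train],
                        std$test[, sel, drop = FALSE], spec,
                        childSeed(spec$seed, f, 3L))
    acc <- mean(fit$pred == y[test])
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, n_train = length(train), n_test = length(test),
                 n_purged = length(purged), accuracy = acc)
    preds <- c(preds, fit$pred); truths <- c(truths, y[test])
    imp_sum[names(fit$importance)[order(-fit$importance)]] <- imp_sum[
      names(fit$importance)[order(-fit$importance)]] + fit$importance[
        order(-fit$importance)]
    # leakage audit
    stopifnot(length(intersect(group[train], group[test])) == 0)
    if (plan$purge_gap > 0 && length(train))
      for (s in unique(info$subject[test])) {
        tpos <- segpos[test][info$subject[test] == s]
        tr_s <- train[info$subject[train] == s]
        if (length(tr_s))
          stopifnot(all(vapply(segpos[tr_s], function(p)
            min(abs(p - tpos)) > plan$purge_gap, logical(1))))
      }
    mu_check <- colMeans(X[train, , drop = FALSE])
    stopifnot(max(abs(mu_check - std$mu)) < 1e-10)
    audit[[length(audit) + 1L]] <- sprintf(
      "fold %d: groups disjoint, %d epoch(s) purged, normalizer train-only",
      f, length(purged))
  }
  if (!length(per_fold)) stop("no usable folds")
  pf <- do.call(rbind, per_fold)
  M <- confusionMatrix(truths, preds, classes)
  Mn <- normalizeConfusion(M)
  per_class <- data.frame(
    class = classes,
    precision = vapply(seq_along(classes), function(k)
      if (sum(M[, k]) == 0) 0 else M[k, k] / sum(M[, k]), numeric(1)),
    recall = vapply(seq_along(classes), function(k)
      if (sum(M[k, ]) == 0) 0 else M[k, k] / sum(M[k, ]), numeric(1)))
  imp <- imp_sum / max(sum(imp_sum), .Machine$double.xmin)
  structure(list(
    accuracy = mean(pf$accuracy), accuracy_sd = stats::sd(pf$accuracy),
    macro_f1 = macroF1(M), per_class = per_class, confusion = Mn,
    confusion_counts = M, per_fold = pf,
    chance_p = chanceTest(sum(preds == truths), length(truths),
                          1 / length(classes)),
    importance = sort(imp[imp > 0], decreasing = TRUE),
    n_classes = length(classes), audit = unlist(audit)),
    class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: accuracy %.3f +/- %.3f (folds), macro-F1 %.3f, chance p = %.3g\n",
              x$accuracy, x$accuracy_sd, x$macro_f1, x$chance_p))
  invisible(x)
}

#' Leave-one-subject-out evaluation of binary tasks
#'
#' Each subject is held out in turn; the nested pipeline (balancing,
#' normalization, selection) is fitted on the remaining subjects. Tasks:
#' `"mode"` (MD vs AD), `"difficulty"` (Easy vs Hard pooled),
#' `"difficulty-MD"` / `"difficulty-AD"` (complexity within one mode).
#' Subjects with a single class are excluded with a warning. The subject
#' accuracies are tested against chance 0.5 with a one-sample t-test and
#' summarized with Cohen's d and a 95% confidence interval.
#'
#' @param features a [FeatureTable-class] spanning >= 3 subjects.
#' @param task character, see Details.
#' @param spec a [classifierSpec()].
#' @param k1,k2 selection sizes.
#' @param seed seed for balancing.
#' @return List: `task`, `per_subject` (data.frame), `mean_accuracy`,
#'   `sd_accuracy`, `ci`, `t`, `df`, `p`, `cohen_d`.
#' @export
runLOSO <- function(features, task = c("mode", "difficulty",
                                       "difficulty-MD", "difficulty-AD"),
                    spec = classifierSpec(), k1 = 200L, k2 = 100L,
                    seed = 1L) {
  task <- match.arg(task)
  stopifnot(is(features, "FeatureTable"))
  X <- featureMatrix(features)
  info <- featureInfo(features)
  sel_rows <- switch(task,
    "difficulty-MD" = info$mode == "MD",
    "difficulty-AD" = info$mode == "AD",
    rep(TRUE, nrow(info)))
  y <- if (task == "mode") info$mode else info$difficulty
  X <- X[sel_rows, , drop = FALSE]; y <- y[sel_rows]
  info <- info[sel_rows, , drop = FALSE]
  subjects <- sort(unique(info$subject))
  if (length(subjects) < 3) stop("LOSO needs >= 3 subjects")
  rows <- list()
  for (s in subjects) {
    test <- which(info$subject == s)
    train <- which(info$subject != s)
    if (length(unique(y[test])) < 2) {
      warning(sprintf("subject %s has a single class for task %s; excluded",
                      s, task))
      next
    }
    train <- balanceIndices(train, y, childSeed(seed, match(s, subjects)))
    std <- standardizeFold(X, train, test)
    fsel <- twoStageSelect(std$train, y[train], k1, k2,
                           classifierSpec(spec$n_trees, spec$max_depth,
                                          spec$mtry,
                                          childSeed(spec$seed,
                                                    match(s, subjects), 7L)))
    fit <- fitPredictRF(std$train[, fsel, drop = FALSE], y[train],
                        std$test[, fsel, drop = FALSE], spec,
                        childSeed(spec$seed, match(s, subjects), 8L))
    rows[[length(rows) + 1L]] <-
      data.frame(subject = s, n_test = length(test),
                 accuracy = mean(fit$pred == y[test]))
  }
  if (!length(rows)) stop("no usable subjects for LOSO")
  ps <- do.call(rbind, rows)
  tt <- oneSampleT(ps$accuracy, mu0 = 0.5, tails = "one",
                   direction = "greater")
  list(task = task, per_subject = ps, mean_accuracy = mean(ps$accuracy),
       sd_accuracy = stats::sd(ps$accuracy),
       ci = c(tt$ci_low, tt$ci_high), t = tt$t, df = tt$df, p = tt$p_raw,
       cohen_d = tt$cohen_d)
}

#' Cross-mode transfer test
#'
#' Trains an Easy-vs-Hard classifier on manual-driving epochs only and
#' tests it on replay epochs only, with an exact binomial test against
#' chance 0.5. Near-chance transfer indicates mode-specific difficulty
#' signatures.
#'
#' @param features a [FeatureTable-class] containing both modes.
#' @param spec a [classifierSpec()].
#' @param k1,k2 selection sizes.
#' @param seed balancing seed.
#' @return List: `accuracy`, `n_test`, `p` (binomial vs 0.5).
#' @export
crossModeTransfer <- function(features, spec = classifierSpec(),
                              k1 = 200L, k2 = 100L, seed = 1L) {
  stopifnot(is(features, "FeatureTable"))
  X <- featureMatrix(features)
  info <- featureInfo(features)
  if (!all(c("MD", "AD") %in% info$mode))
    stop("both modes must be present")
  train <- which(info$mode == "MD")
  test <- which(info$mode == "AD")
  y <- info$difficulty
  train <- balanceIndices(train, y, childSeed(seed, 11L))
  std <- standardizeFold(X, train, test)
  fsel <- twoStageSelect(std$train, y[train], k1, k2,
                         classifierSpec(spec$n_trees, spec$max_depth,
                                        spec$mtry, childSeed(spec$seed, 12L)))
  fit <- fitPredictRF(std$train[, fsel, drop = FALSE], y[train],
                      std$test[, fsel, drop = FALSE], spec,
                      childSeed(spec$seed, 13L))
  acc <- mean(fit$pred == y[test])
  list(accuracy = acc, n_test = length(test),
       p = chanceTest(sum(fit$pred == y[test]), length(test), 0.5))
}

#' Exact binomial test against a chance level
#'
#' Upper-tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n_total, chance_p)`.
#'
#' @param n_correct number of correct predictions.
#' @param n_total number of predictions (> 0).
#' @param chance_p chance probability in (0, 1).
#' @return One-sided p-value.
#' @export
chanceTest <- function(n_correct, n_total, chance_p = 0.25) {
  if (chance_p <= 0 || chance_p >= 1) stop("chance_p must be in (0, 1)")
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total)
    stop("n_correct must lie in [0, n_total]")
  stats::pbinom(n_correct - 1, n_total, chance_p, lower.tail = FALSE)
}
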