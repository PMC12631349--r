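# build a small feature table directly (no signal processing needed here)
syntheticFeatures <- function(n_per_class = 24, n_feat = 30, n_subj = 3,
                              effect = 2, seed = 20, classes = conditionLevels()) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  y <- rep(classes, each = n_per_class)
  X <- matrix(rnorm(n * n_feat), n, n_feat)
  colnames(X) <- sprintf("f%02d", seq_len(n_feat))
  # first two features carry class information
  X[, 1] <- X[, 1] + effect * as.numeric(factor(y))
  X[, 2] <- X[, 2] + effect * (as.numeric(factor(y)) %% 2)
  ord <- sample(n)
  X <- X[ord, ]; y <- y[ord]
  subj <- rep_len(seq_len(n_subj), n)
  lap <- rep_len(rep(1:4, each = 12), n)
  seg <- stats::ave(seq_len(n), paste(subj, lap), FUN = seq_along)
  cd <- S4Vectors::DataFrame(label = y, subject = subj, lap = lap,
                             segment = seg, mode = sub("-.*", "", y),
                             difficulty = sub(".*-", "", y))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)), colData = cd)
  new("FeatureTable", se)
}

test_that("two-stage selection ranks a perfectly separating feature first", {
  set.seed(21)
  n <- 80
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- sprintf("f%02d", 1:20)
  X[, 7] <- ifelse(y == "A", 5, -5) + rnorm(n, 0, 0.1)
  sel <- twoStageSelect(X, y, k1 = 10, k2 = 3, classifierSpec(100, seed = 2))
  expect_equal(sel[1], 7)
  # identity selection when k1 = k2 = all
  sel_all <- twoStageSelect(X, y, k1 = 20, k2 = 20,
                            classifierSpec(100, seed = 2))
  expect_setequal(sel_all, 1:20)
  expect_error(twoStageSelect(X, y, k1 = 5, k2 = 10), "k2")
  # permuted labels: informative feature no longer reliably selected first
  set.seed(22)
  hits <- mean(replicate(20, {
    yp <- sample(y)
    twoStageSelect(X, yp, 10, 1, classifierSpec(100,
                                                seed = sample.int(1e6, 1)))[1] == 7
  }))
  expect_lt(hits, 0.5)
})

test_that("vectorized ANOVA F matches aov and oneway.test", {
  set.seed(23)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("a", "b", "c"), each = 20)
  X[, 2] <- X[, 2] + as.numeric(factor(y))
  F <- anovaFScores(X, y)
  for (j in 1:4) {
    ref <- summary(aov(X[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(F[j], ref, tolerance = 1e-10)
    expect_equal(F[j], unname(oneway.test(X[, j] ~ factor(y),
                                          var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("grouped CV is leakage-audited, deterministic, with proper report", {
  ft <- syntheticFeatures()
  plan <- foldPlan(n_folds = 4, seed = 3)
  spec <- classifierSpec(n_trees = 150, seed = 5)
  r1 <- runCV(ft, plan, spec, k1 = 20, k2 = 10)
  r2 <- runCV(ft, plan, spec, k1 = 20, k2 = 10)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
  # confusion rows sum to 1; diagonal equals per-class recall
  expect_lt(max(abs(rowSums(r1$confusion) - 1)), 1e-12)
  expect_equal(unname(diag(r1$confusion)), r1$per_class$recall)
  expect_true(all(grepl("groups disjoint", r1$audit)))
  # the planted signal is learnable well above chance
  expect_gt(r1$accuracy, 0.5)
  expect_lt(r1$chance_p, 0.01)
  # importances normalized
  expect_lt(abs(sum(r1$importance) - 1), 1e-8)
})

test_that("label permutation drives grouped CV back to chance", {
  ft <- syntheticFeatures(effect = 3, seed = 24)
  info <- as.data.frame(SummarizedExperiment::colData(ft))
  set.seed(25)
  perm <- sample(info$label)
  r <- runCV(ft, foldPlan(n_folds = 4, seed = 6),
             classifierSpec(n_trees = 150, seed = 7), k1 = 20, k2 = 10,
             labels = perm)
  n <- sum(r$per_fold$n_test)
  half <- 1.96 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(r$accuracy - 0.25), half + 0.08)
})

test_that("purge gap removes training epochs adjacent to held-out segments", {
  ft <- syntheticFeatures()
  r0 <- runCV(ft, foldPlan(n_folds = 4, purge_gap = 0, seed = 3),
              classifierSpec(n_trees = 50, seed = 5), k1 = 10, k2 = 5)
  r2 <- runCV(ft, foldPlan(n_folds = 4, purge_gap = 2, seed = 3),
              classifierSpec(n_trees = 50, seed = 5), k1 = 10, k2 = 5)
  expect_true(all(r0$per_fold$n_purged == 0))
  expect_true(all(r2$per_fold$n_purged > 0))
  expect_true(all(r2$per_fold$n_train < r0$per_fold$n_train))
})

test_that("LOSO reports per-subject accuracies and a one-sample test", {
  ft <- syntheticFeatures(n_per_class = 30, n_subj = 4, effect = 2.5,
                          seed = 26)
  r <- runLOSO(ft, "difficulty", classifierSpec(n_trees = 150, seed = 8),
               k1 = 20, k2 = 10, seed = 9)
  expect_equal(nrow(r$per_subject), 4)
  expect_gt(r$mean_accuracy, 0.5)
  expect_lt(r$p, 0.05)
  expect_true(is.finite(r$cohen_d))
  tiny <- syntheticFeatures(n_subj = 2)
  expect_error(runLOSO(tiny, "mode"), ">= 3 subjects")
})

test_that("cross-mode transfer learns only mode-shared difficulty signal", {
  # difficulty signal present identically in both modes -> transfer works
  ft <- syntheticFeatures(n_per_class = 30, effect = 0, seed = 27)
  X <- SummarizedExperiment::assay(ft)
  info <- as.data.frame(SummarizedExperiment::colData(ft))
  X["f01", ] <- rnorm(ncol(X)) + 3 * (info$difficulty == "Hard")
  SummarizedExperiment::assay(ft) <- X
  r <- crossModeTransfer(ft, classifierSpec(n_trees = 150, seed = 10),
                         k1 = 20, k2 = 10)
  expect_gt(r$accuracy, 0.5)
  expect_lt(r$p, 0.05)
  # difficulty signal only in MD -> transfer stays near chance
  ft2 <- syntheticFeatures(n_per_class = 30, effect = 0, seed = 28)
  X2 <- SummarizedExperiment::assay(ft2)
  info2 <- as.data.frame(SummarizedExperiment::colData(ft2))
  X2["f01", ] <- rnorm(ncol(X2)) +
    3 * (info2$difficulty == "Hard" & info2$mode == "MD")
  SummarizedExperiment::assay(ft2) <- X2
  r2 <- crossModeTransfer(ft2, classifierSpec(n_trees = 150, seed = 11),
                          k1 = 20, k2 = 10)
  expect_lt(abs(r2$accuracy - 0.5), 0.15)
})

test_that("exact binomial chance test matches the direct tail sum", {
  # oracle: explicit sum over the binomial pmf
  tailSum <- function(k, n, p) sum(dbinom(k:n, n, p))
  expect_equal(chanceTest(25, 100, 0.25), tailSum(25, 100, 0.25),
               tolerance = 1e-12)
  # chance-level performance is clearly non-significant (~0.54)
  expect_gt(chanceTest(25, 100, 0.25), 0.5)
  expect_lt(chanceTest(25, 100, 0.25), 0.6)
  expect_equal(chanceTest(100, 100, 0.25), 0.25^100)
  expect_equal(chanceTest(0, 50, 0.25), 1)
  expect_error(chanceTest(5, 0, 0.25), "positive")
  expect_error(chanceTest(5, 4, 0.25), "n_correct")
  expect_error(chanceTest(1, 4, 1.2), "chance_p")
})
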