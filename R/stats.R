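#' @include utils.R
NULL

# Statistical layer: t-tests with Cohen's d, family-wise BH-FDR
# bookkeeping, bootstrap confidence intervals, Fisher's combination, and
# the subregional consistency metrics used to validate ROI groupings.

#' One-sample t-test with effect size
#'
#' Standard one-sample t against `mu0` with `df = n - 1`, Cohen's d
#' `(mean - mu0) / sd`, and a two-sided 95% t confidence interval for the
#' mean. One-tailed p-values are only produced when an explicit predicted
#' `direction` is supplied (directional hypotheses); otherwise the test is
#' two-tailed. Zero-variance input is degenerate: statistics are returned
#' as `NA` with `degenerate = TRUE`.
#'
#' @param values numeric vector, `n >= 2`, finite.
#' @param mu0 null value (default 0).
#' @param tails `"two"` or `"one"`.
#' @param direction predicted direction for one-tailed tests, `"greater"`
#'   or `"less"` (required when `tails = "one"`).
#' @param family optional test-family id recorded in the result.
#' @return A one-row data.frame: estimate, t, df, p_raw, p_fdr (NA until
#'   [adjustFamilies()]), cohen_d, ci_low, ci_high, tails, family,
#'   degenerate.
#' @export
oneSampleT <- function(values, mu0 = 0, tails = c("two", "one"),
                       direction = NULL, family = NA_character_) {
  tails <- match.arg(tails)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need >= 2 finite values")
  n <- length(values)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    return(data.frame(estimate = m - mu0, t = NA_real_, df = n - 1,
                      p_raw = NA_real_, p_fdr = NA_real_, cohen_d = NA_real_,
                      ci_low = m - mu0, ci_high = m - mu0, tails = tails,
                      family = family, degenerate = TRUE))
  }
  t <- (m - mu0) * sqrt(n) / s
  df <- n - 1
  p <- if (tails == "two") 2 * stats::pt(-abs(t), df)
  else {
    if (is.null(direction)) stop("one-tailed tests require a predicted direction")
    if (direction == "greater") stats::pt(t, df, lower.tail = FALSE)
    else stats::pt(t, df, lower.tail = TRUE)
  }
  half <- stats::qt(0.975, df) * s / sqrt(n)
  data.frame(estimate = m - mu0, t = t, df = df, p_raw = p, p_fdr = NA_real_,
             cohen_d = (m - mu0) / s, ci_low = m - mu0 - half,
             ci_high = m - mu0 + half, tails = tails, family = family,
             degenerate = FALSE)
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences `a - b`; used for
#' interaction contrasts such as complexity modulation between modes.
#'
#' @param values_a,values_b equal-length numeric vectors (`n >= 2`).
#' @inheritParams oneSampleT
#' @return As [oneSampleT()].
#' @export
pairedT <- function(values_a, values_b, tails = c("two", "one"),
                    direction = NULL, family = NA_character_) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  oneSampleT(values_a - values_b, mu0 = 0, tails = match.arg(tails),
             direction = direction, family = family)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment within one test family (wraps
#' `p.adjust(method = "BH")`, with the empty input passing through).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply family-wise FDR to a results table
#'
#' Adjusts `p_raw` within each level of `family`, fills `p_fdr`, and flags
#' survivors at the given q; non-survivors are to be reported descriptively
#' as trends.
#'
#' @param results data.frame with `p_raw` and `family` columns (rows with
#'   `NA` family form their own implicit family).
#' @param q FDR threshold for the survivor flag (default 0.05).
#' @return The table with `p_fdr` and logical `survives_fdr` filled in.
#' @export
adjustFamilies <- function(results, q = 0.05) {
  stopifnot(all(c("p_raw", "family") %in% names(results)))
  fam <- ifelse(is.na(results$family), ".none", results$family)
  for (f in unique(fam)) {
    sel <- which(fam == f & !is.na(results$p_raw))
    results$p_fdr[sel] <- bhAdjust(results$p_raw[sel])
  }
  results$survives_fdr <- !is.na(results$p_fdr) & results$p_fdr < q
  results
}

#' Bootstrap confidence interval and p-value
#'
#' Percentile bootstrap of an arbitrary statistic (default the mean) with a
#' two-sided bootstrap p-value for H0: statistic = 0, defined as
#' `2 min(P(stat* <= 0), P(stat* >= 0))` capped at 1. Deterministic for a
#' fixed seed. The study's default is 5000 iterations.
#'
#' @param values numeric vector, `n >= 3`.
#' @param n_boot bootstrap iterations (default 5000).
#' @param stat statistic function (default `mean`).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return List: `ci_low`, `ci_high`, `p_boot`, `n_boot`.
#' @export
bootstrapCI <- function(values, n_boot = 5000L, stat = mean, seed = 1L,
                        conf = 0.95) {
  if (length(values) < 3) stop("need n >= 3 for the bootstrap")
  localSeed(seed, {
    n <- length(values)
    reps <- vapply(seq_len(n_boot), function(b)
      stat(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
    p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
    list(ci_low = ci[1], ci_high = ci[2], p_boot = min(p, 1),
         n_boot = n_boot)
  })
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum(log p) ~ chi-squared(2k)` under the global null; returns the
#' upper-tail probability. Zero p-values are clipped to the smallest
#' positive double with a warning.
#'
#' @param p p-values in `(0, 1]`.
#' @return Combined p-value.
#' @export
fisherCombine <- function(p) {
  if (!length(p)) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clipped to the machine floor")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Subregional consistency metrics
#'
#' Validates an ROI grouping by three complementary checks on its
#' subregion time courses: (1) directional agreement — the fraction of
#' subregions whose window-mean contrast shares the majority sign
#' (threshold 80%); (2) mean pairwise Pearson correlation of the time
#' courses (threshold r > 0.5); (3) a one-way ANOVA across subregions,
#' where p > 0.05 is read as homogeneity. Identical time courses make the
#' ANOVA degenerate (no between-group variance), which is flagged.
#'
#' @param timecourses subregions x time numeric matrix (>= 2 rows).
#' @param window optional `c(t1, t2)` window (s) with `tmin`/`fs` to
#'   restrict the means; by default the full axis is used.
#' @param tmin,fs time axis parameters when `window` is given.
#' @return List: `agreement` (percent), `mean_r`, `anova_p`,
#'   `degenerate`.
#' @export
roiConsistency <- function(timecourses, window = NULL, tmin = 0, fs = 1) {
  if (is.null(dim(timecourses)) || nrow(timecourses) < 2)
    stop("need >= 2 subregions")
  V <- timecourses
  if (!is.null(window)) {
    idx <- windowIndices(window, tmin, fs, ncol(V))
    V <- V[, idx, drop = FALSE]
  }
  wm <- rowMeans(V)
  sgn <- sign(wm)
  sgn[sgn == 0] <- 1
  agreement <- 100 * max(table(sgn)) / length(sgn)
  cors <- stats::cor(t(V))
  mean_r <- mean(cors[upper.tri(cors)])
  df <- data.frame(value = as.numeric(t(V)),
                   subregion = factor(rep(seq_len(nrow(V)),
                                          each = ncol(V))))
  degenerate <- FALSE
  anova_p <- NA_real_
  btw <- stats::var(wm)
  wth <- mean(apply(V, 1, stats::var))
  if (btw < 1e-24 || wth < 1e-24) {
    degenerate <- TRUE
  } else {
    anova_p <- summary(stats::aov(value ~ subregion, df))[[1]][
      "subregion", "Pr(>F)"]
  }
  list(agreement = agreement, mean_r = mean_r, anova_p = anova_p,
       degenerate = degenerate)
}
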