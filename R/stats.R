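#' Shapiro-Wilk normality check for one group
#'
#' Report-only: the paired group comparison always uses the signed-rank
#' test; the normality p-value justifies that choice but never branches the
#' analysis.
#'
#' @param values Numeric vector.
#' @return List with `p` (Shapiro-Wilk p-value, `NA` when untestable) and
#'   `untestable` (`TRUE` for n < 3 or constant input).
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(unique(values)) < 2L)
    return(list(p = NA_real_, untestable = TRUE))
  list(p = stats::shapiro.test(values)$p.value, untestable = FALSE)
}

#' Exact-capable paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on `x - y` (or on `x` alone).  Zero
#' differences are dropped before ranking.  For n (non-zero differences)
#' up to 25 the exact null distribution of the positive-rank sum is
#' computed by dynamic programming over the (midrank-tied) ranks, so ties
#' do not force an approximation; above 25 the normal approximation with
#' continuity correction and the usual tie correction of the variance is
#' used.
#'
#' @param x Numeric vector (differences, or first member of the pairs).
#' @param y Optional numeric vector paired with `x`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (positive-rank sum V), `p_value`,
#'   `n_nonzero`, `n_zero`, `exact`, and `degenerate` (`TRUE` when all
#'   differences are zero, in which case `p_value = 1`).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 2/2^5 = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, n_zero = n_zero,
                exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .wsr_exact_p(r, V)
    exact <- TRUE
  } else {
    p <- .wsr_approx_p(r, V, n)
    exact <- FALSE
  }
  list(statistic = V, p_value = p, n_nonzero = n, n_zero = n_zero,
       exact = exact, degenerate = FALSE)
}

# exact two-sided p for the positive-rank sum V given the (mid)ranks r;
# DP over doubled ranks (midranks are multiples of 1/2)
.wsr_exact_p <- function(r, V) {
  w <- as.integer(round(2 * r))
  tot <- sum(w)
  f <- numeric(tot + 1L)       # f[s + 1] = count of subsets with doubled sum s
  f[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), f[seq_len(tot + 1L - wi)])
    f <- f + shifted
  }
  f <- f / 2^length(w)
  v2 <- as.integer(round(2 * V))
  p_le <- sum(f[seq_len(v2 + 1L)])
  p_ge <- sum(f[(v2 + 1L):(tot + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# normal approximation with continuity and tie corrections
.wsr_approx_p <- function(r, V, n) {
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Per-feature paired group comparison
#'
#' For each of the 25 features: group mean and SD, Shapiro-Wilk normality
#' p-value per group, and the two-sided paired Wilcoxon signed-rank p-value
#' for the lesion-control difference.  No multiple-testing correction is
#' applied by default (a Holm option is available).
#'
#' @param cohort A [cohort_table()].
#' @param alpha Significance level (default 0.05).
#' @param adjust Method for [stats::p.adjust()] (default `"none"`).
#' @param retained_only Restrict to non-deleted subjects.
#' @return Data frame of class `feature_test_table`: one row per feature
#'   with `feature`, `label`, `lesion_mean`, `lesion_sd`, `control_mean`,
#'   `control_sd`, `normality_p_lesion`, `normality_p_control`,
#'   `wilcoxon_p`, `p_adjusted`, `significant`, `degenerate`.
#' @export
feature_tests <- function(cohort, alpha = 0.05, adjust = "none",
                          retained_only = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), alpha > 0, alpha < 1)
  keep <- if (retained_only) !(cohort$screening$deleted %in% TRUE) else
    rep(TRUE, length(cohort$subject_id))
  les <- cohort$lesion[keep, , drop = FALSE]
  ctl <- cohort$control[keep, , drop = FALSE]
  res <- lapply(feature_names(), function(f) {
    w <- wilcoxon_signed_rank(les[, f], ctl[, f])
    data.frame(feature = f, label = unname(feature_labels()[f]),
               lesion_mean = mean(les[, f]), lesion_sd = stats::sd(les[, f]),
               control_mean = mean(ctl[, f]), control_sd = stats::sd(ctl[, f]),
               normality_p_lesion = normality_test(les[, f])$p,
               normality_p_control = normality_test(ctl[, f])$p,
               wilcoxon_p = w$p_value, degenerate = w$degenerate)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$wilcoxon_p, method = adjust)
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("feature_test_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_subjects") <- sum(keep)
  out
}

#' Per-sample screening statistic
#'
#' Each feature is first z-scored across all regions of the cohort (both
#' groups pooled), putting the 25 features — whose raw scales span many
#' orders of magnitude — on a common scale.  For each subject a two-sided
#' paired t-test across the 25 standardized feature values of its lesion
#' vs control vectors yields `per_sample_p`: large values mean the two
#' regions of that subject are statistically indistinguishable.
#'
#' Degenerate branches: all standardized differences zero gives p = 1; a
#' non-zero constant difference (zero variance, non-zero mean) is maximal
#' evidence of a difference and gives p = 0.  Both are flagged.
#'
#' @param cohort A [cohort_table()].
#' @return The cohort with `screening$per_sample_p` filled; the logical
#'   attribute `"screening_degenerate"` marks flagged subjects.
#' @export
per_sample_screening <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$subject_id)
  pooled <- rbind(cohort$lesion, cohort$control)
  z <- .zscore(pooled)
  lz <- z[seq_len(n), , drop = FALSE]
  cz <- z[n + seq_len(n), , drop = FALSE]
  p <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    d <- lz[i, ] - cz[i, ]
    if (all(d == 0)) {
      p[i] <- 1; degen[i] <- TRUE
    } else if (stats::sd(d) == 0) {
      p[i] <- 0; degen[i] <- TRUE
    } else {
      p[i] <- stats::t.test(d)$p.value
    }
  }
  cohort$screening$per_sample_p <- p
  attr(cohort, "screening_degenerate") <- degen
  cohort
}

#' Apply the sample-deletion rule
#'
#' A subject is deleted iff its per-sample p-value strictly exceeds the
#' cohort mean per-sample p-value AND it was flagged as misplaced in the
#' 2-D embedding.  Deleted subjects are excluded from all downstream
#' stages.
#'
#' @param cohort A [cohort_table()] with `per_sample_p` and `misplaced`
#'   populated for every subject.
#' @return The cohort with `screening$deleted` filled; the deletion report
#'   (a data frame) is attached as attribute `"deletion_report"`.
#' @export
deletion_rule <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$screening
  if (anyNA(s$per_sample_p) || anyNA(s$misplaced))
    stop("`per_sample_p` and `misplaced` must be populated for all subjects",
         call. = FALSE)
  mean_p <- mean(s$per_sample_p)
  cohort$screening$deleted <- s$per_sample_p > mean_p & s$misplaced
  attr(cohort, "deletion_report") <-
    data.frame(subject_id = s$subject_id, per_sample_p = s$per_sample_p,
               misplaced = s$misplaced, mean_p = mean_p,
               deleted = cohort$screening$deleted)
  cohort
}
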