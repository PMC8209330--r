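#' Construct an importance ranking
#'
#' Ranks are assigned by decreasing mean-decrease-Gini value; ties are
#' broken by the canonical feature order ([feature_names()]) for
#' determinism.
#'
#' @param mean_decrease_gini Numeric vector of importance values.
#' @param feature Feature names (defaults to [feature_names()] when the
#'   length matches).
#' @return Data frame of class `importance_ranking` with columns `feature`,
#'   `mean_decrease_gini`, `rank`.
#' @export
importance_ranking <- function(mean_decrease_gini, feature = NULL) {
  v <- as.numeric(mean_decrease_gini)
  if (is.null(feature)) {
    feature <- if (!is.null(names(mean_decrease_gini))) names(mean_decrease_gini)
               else if (length(v) == 25L) feature_names()
               else stop("`feature` names are required", call. = FALSE)
  }
  stopifnot(length(feature) == length(v), !anyDuplicated(feature))
  if (any(!is.finite(v)) || any(v < 0))
    stop("importance values must be finite and nonnegative", call. = FALSE)
  rnk <- integer(length(v))
  rnk[order(-v, seq_along(v))] <- seq_along(v)
  out <- data.frame(feature = as.character(feature),
                    mean_decrease_gini = v, rank = rnk)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Random-forest Gini importance ranking
#'
#' Fits a random-forest classifier on a stratified `train_fraction`
#' subsample of the regions and returns the per-feature mean decrease in
#' Gini impurity with ranks.  Deterministic given `seed`.
#'
#' @param x Numeric feature matrix, one row per region.
#' @param y Two-level factor of region labels.
#' @param train_fraction Fraction of regions used to fit the forest
#'   (default 0.8).
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split (default `floor(sqrt(ncol(x)))`).
#' @return An [importance_ranking()].
#' @export
gini_importance <- function(x, y, train_fraction = 0.8, seed = 1L,
                            ntree = 500L, mtry = max(1L, floor(sqrt(ncol(x))))) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("`y` must contain at least 2 classes", call. = FALSE)
  if (train_fraction <= 0 || train_fraction > 1)
    stop("`train_fraction` must lie in (0, 1]", call. = FALSE)
  imp <- withr::with_seed(as.integer(seed), {
    idx <- unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      sample(rows, max(1L, floor(train_fraction * length(rows))))
    }))
    rf <- randomForest::randomForest(x[idx, , drop = FALSE], y[idx],
                                     ntree = ntree, mtry = mtry)
    rf$importance[, "MeanDecreaseGini"]
  })
  importance_ranking(imp, feature = colnames(x))
}

#' Select the top-k features of a ranking
#'
#' @param ranking An [importance_ranking()].
#' @param k Number of features, `1 <= k <= nrow(ranking)`.
#' @return Character vector of the `k` smallest-rank features, in rank
#'   order.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "importance_ranking"))
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranking))
    stop(sprintf("`k` must lie in [1, %d]", nrow(ranking)), call. = FALSE)
  ranking$feature[order(ranking$rank)][seq_len(k)]
}

#' Worked-example Gini importance table
#'
#' Loads the mean-decrease-Gini values for the 25-feature panel reported in
#' a published brain-MRI texture study, shipped as a plain-text fixture.
#' Used as a worked example for [select_top_k()]; its top five features are
#' standard deviation, fourth-order moment, variance, third-order absolute
#' moment and third-order central moment.
#'
#' @return An [importance_ranking()] with the published values.
#' @export
example_gini_ranking <- function() {
  path <- system.file("extdata", "example_gini_ranking.csv", package = "texroi",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  importance_ranking(tab$mean_decrease_gini, feature = tab$feature)
}
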