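#' Repeated subject-level train/test splits
#'
#' Splits subjects (not regions) so that both regions of a subject always
#' land on the same side, preventing within-subject leakage.  Because each
#' subject contributes one lesion and one control region, every split is
#' automatically class-balanced on both sides.
#'
#' @param subject_id Character vector of retained subjects.
#' @param n_repeats Number of splits (default 5).
#' @param train_frac Fraction of subjects in the training set (default 0.7;
#'   the training size is `floor(train_frac * n)`).
#' @param seed Integer seed.
#' @return List of class `split_plan`; each element has `repeat_index`,
#'   `train` and `test` subject-id vectors.  Splits are pairwise distinct.
#' @export
make_splits <- function(subject_id, n_repeats = 5L, train_frac = 0.7, seed = 1L) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  if (n < 4L) stop("need at least 4 subjects to split", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 2L || n_train >= n)
    stop("`train_frac` must leave at least 2 training and 1 test subject",
         call. = FALSE)
  plans <- withr::with_seed(as.integer(seed), {
    seen <- character(0)
    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      for (try in 1:1000) {
        tr <- sort(sample(subject_id, n_train))
        key <- paste(tr, collapse = "|")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      out[[r]] <- list(repeat_index = r, train = tr,
                       test = setdiff(subject_id, tr))
    }
    out
  })
  structure(plans, class = "split_plan",
            train_frac = train_frac, seed = as.integer(seed))
}

#' Train one classifier on region features
#'
#' Features are z-scored with training-set statistics only (stored in the
#' handle and reapplied at prediction time).  All three classifiers expose
#' a continuous score in `[0, 1]` for the lesion class: the random forest's
#' vote fraction, the SVM's decision value mapped through the logistic
#' function, and the network's output activation.
#'
#' @param kind One of `"rf"`, `"svm"`, `"bp"`.
#' @param x Numeric training matrix (regions x selected features).
#' @param y Two-level factor with levels `control`, `lesion`.
#' @param seed Integer seed (forest bootstrap / network initialization).
#' @param hyper Optional hyperparameter overrides: `ntree` (RF, default
#'   500), `cost` (SVM, default 1), `gamma` (SVM, default from the
#'   median-distance heuristic), `size`/`decay`/`maxit` (BP, defaults 10 /
#'   0.01 / 1000).
#' @return Object of class `texroi_classifier` with a [predict()] method
#'   returning lesion scores.
#' @export
train_classifier <- function(kind = c("rf", "svm", "bp"), x, y, seed = 1L,
                             hyper = list()) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y, levels = c("control", "lesion"))
  if (anyNA(y) || nlevels(droplevels(y)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xz <- .zscore(x, center, scale)

  model <- withr::with_seed(as.integer(seed), switch(kind,
    rf = randomForest::randomForest(
      xz, y, ntree = hyper$ntree %||% 500L),
    svm = {
      dm <- stats::median(stats::dist(xz))
      gamma <- hyper$gamma %||% (if (dm > 0) 1 / (2 * dm^2) else 1 / ncol(xz))
      e1071::svm(xz, y, kernel = "radial", cost = hyper$cost %||% 1,
                 gamma = gamma, scale = FALSE)
    },
    bp = nnet::nnet(xz, as.numeric(y == "lesion"),
                    size = hyper$size %||% 10L,
                    decay = hyper$decay %||% 0.01,
                    maxit = hyper$maxit %||% 1000L,
                    entropy = TRUE, trace = FALSE)))
  structure(list(kind = kind, model = model, center = center, scale = scale),
            class = "texroi_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score new regions with a trained classifier
#'
#' @param object A [train_classifier()] handle.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric lesion scores in `[0, 1]`, one per row.
#' @export
predict.texroi_classifier <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  xz <- .zscore(newdata, object$center, object$scale)
  switch(object$kind,
    rf = unname(stats::predict(object$model, xz, type = "prob")[, "lesion"]),
    svm = {
      pr <- stats::predict(object$model, xz, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values are oriented toward the first class in the colname
      sgn <- if (startsWith(colnames(dv)[1L], "lesion")) 1 else -1
      unname(stats::plogis(sgn * dv[, 1L]))
    },
    bp = unname(stats::predict(object$model, xz)[, 1L]))
}

#' Evaluate classifier scores on a test set
#'
#' AUC is the rank statistic (probability that a random lesion region
#' outscores a random control region, ties counted 1/2), which equals the
#' trapezoidal area under the ROC curve.  The confusion matrix is taken at
#' `threshold` on the `[0, 1]` scores; sensitivity, specificity and error
#' rate are reported in percent.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Factor/character labels (`control`/`lesion`) aligned with
#'   `scores`; both classes must be present.
#' @param threshold Score threshold for the confusion matrix (default 0.5;
#'   a score `>= threshold` predicts lesion).
#' @return List of class `eval_entry`: `auc`, `error_rate`, `sensitivity`,
#'   `specificity` (percents), `roc` (data frame of `fpr`, `tpr` from (0,0)
#'   to (1,1)) and `confusion` (`tp`, `fn`, `tn`, `fp`).
#' @examples
#' evaluate_scores(c(0.9, 0.8, 0.85, 0.7),
#'                 c("lesion", "lesion", "control", "control"))$auc
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- as.character(labels) == "lesion"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("test set must contain both classes", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)

  o <- order(scores, decreasing = TRUE)
  sp <- scores[o]; pp <- pos[o]
  last_of_group <- c(sp[-length(sp)] != sp[-1L], TRUE)
  tpr <- cumsum(pp)[last_of_group] / np
  fpr <- cumsum(!pp)[last_of_group] / nn
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))

  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  structure(list(auc = auc,
                 error_rate = 100 * (fp + fn) / length(scores),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 roc = roc,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "eval_entry")
}

#' Trapezoidal area under an ROC polygon
#'
#' Numerical integration of an ROC data frame; equals the rank AUC of
#' [evaluate_scores()] up to floating-point error, which makes it a useful
#' consistency check on reported curves.
#'
#' @param roc Data frame with `fpr` and `tpr` columns ordered from (0,0)
#'   to (1,1).
#' @return The trapezoidal area as a single number.
#' @export
roc_trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Aggregate per-repeat evaluations for one classifier
#'
#' Unweighted arithmetic mean of AUC, error rate, sensitivity and
#' specificity across repeats; per-repeat values are retained and a
#' vertically averaged ROC (mean TPR on a common FPR grid) is produced for
#' plotting.
#'
#' @param entries List of [evaluate_scores()] results.
#' @return List of class `eval_aggregate`: `auc`, `error_rate`,
#'   `sensitivity`, `specificity` (means), `per_repeat` (data frame) and
#'   `mean_roc` (data frame `fpr`, `tpr`).
#' @export
aggregate_eval <- function(entries) {
  stopifnot(length(entries) >= 1L,
            all(vapply(entries, inherits, TRUE, "eval_entry")))
  per <- do.call(rbind, lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    data.frame(repeat_index = i, auc = e$auc, error_rate = e$error_rate,
               sensitivity = e$sensitivity, specificity = e$specificity)
  }))
  grid <- seq(0, 1, by = 0.01)
  tprs <- vapply(entries, function(e)
    stats::approx(e$roc$fpr, e$roc$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  structure(list(auc = mean(per$auc), error_rate = mean(per$error_rate),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 per_repeat = per,
                 mean_roc = data.frame(fpr = grid, tpr = rowMeans(tprs))),
            class = "eval_aggregate")
}

#' Train and evaluate the three classifiers over a split plan
#'
#' For each split and each classifier kind, trains on the training-set
#' regions of the selected features and evaluates the scores on the held
#' out regions.
#'
#' @param regions A [region_matrix()] result (or compatible list with `x`,
#'   `label`, `subject_id`).
#' @param selected Character vector of feature columns to use.
#' @param splits A [make_splits()] plan.
#' @param kinds Classifier kinds (default all three).
#' @param seed Integer seed; per-(repeat, classifier) seeds are derived
#'   from it.
#' @param hyper Named list of per-kind hyperparameter lists.
#' @param threshold Score threshold for confusion matrices.
#' @return List of class `eval_report`: per kind an `aggregate`
#'   ([aggregate_eval()]) and the list of per-repeat entries.
#' @export
evaluate_classifiers <- function(regions, selected, splits,
                                 kinds = c("rf", "svm", "bp"), seed = 1L,
                                 hyper = list(), threshold = 0.5) {
  stopifnot(all(selected %in% colnames(regions$x)))
  x <- regions$x[, selected, drop = FALSE]
  seeds <- withr::with_seed(as.integer(seed),
    matrix(sample.int(2147483646L, length(splits) * length(kinds)),
           length(splits), length(kinds)))
  out <- list()
  for (ki in seq_along(kinds)) {
    kind <- kinds[ki]
    entries <- lapply(seq_along(splits), function(si) {
      sp <- splits[[si]]
      tr <- regions$subject_id %in% sp$train
      te <- regions$subject_id %in% sp$test
      fit <- train_classifier(kind, x[tr, , drop = FALSE], regions$label[tr],
                              seed = seeds[si, ki], hyper = hyper[[kind]])
      evaluate_scores(predict(fit, x[te, , drop = FALSE]),
                      regions$label[te], threshold = threshold)
    })
    out[[kind]] <- list(aggregate = aggregate_eval(entries), entries = entries)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (kind in names(x)) {
    a <- x[[kind]]$aggregate
    cat(sprintf("  %-3s  AUC %.3f  error %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
                toupper(kind), a$auc, a$error_rate, a$sensitivity, a$specificity))
  }
  invisible(x)
}
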