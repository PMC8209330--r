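#' Construct a cohort feature table
#'
#' Per-subject paired feature vectors (lesion and control) plus screening
#' state (per-sample p-value, embedding-misplacement flag, deletion flag).
#'
#' @param subject_id Character vector of subject identifiers.
#' @param lesion,control Numeric matrices, one row per subject, 25 columns
#'   named as [feature_names()].
#' @return Object of class `cohort_table`: list with `subject_id`, `lesion`,
#'   `control` and a `screening` data frame (`per_sample_p`, `misplaced`,
#'   `deleted`; unset values are `NA`).
#' @export
cohort_table <- function(subject_id, lesion, control) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  stopifnot(is.matrix(lesion), is.matrix(control),
            nrow(lesion) == n, nrow(control) == n,
            ncol(lesion) == 25L, ncol(control) == 25L)
  if (anyDuplicated(subject_id))
    stop("`subject_id` must be unique", call. = FALSE)
  colnames(lesion) <- colnames(control) <- feature_names()
  rownames(lesion) <- rownames(control) <- subject_id
  structure(list(subject_id = subject_id, lesion = lesion, control = control,
                 screening = data.frame(subject_id = subject_id,
                                        per_sample_p = NA_real_,
                                        misplaced = NA,
                                        deleted = NA)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  nd <- sum(x$screening$deleted %in% TRUE)
  cat(sprintf("<cohort_table> %d paired subjects, 25 features%s\n",
              length(x$subject_id),
              if (nd > 0) sprintf(", %d deleted", nd) else ""))
  invisible(x)
}

#' Extract features for every region of a cohort
#'
#' @param cohort A [generate_cohort()] result or any list with `subject_id`,
#'   `lesion` and `control` lists of [gray_region()]s.
#' @param config A [feature_config()].
#' @return A [cohort_table()].
#' @export
extract_cohort_features <- function(cohort, config = feature_config()) {
  n <- length(cohort$subject_id)
  stopifnot(n >= 1L, length(cohort$lesion) == n, length(cohort$control) == n)
  les <- t(vapply(cohort$lesion, extract_features, numeric(25), config = config))
  ctl <- t(vapply(cohort$control, extract_features, numeric(25), config = config))
  cohort_table(cohort$subject_id, les, ctl)
}

#' Stack a cohort into a region-level feature matrix
#'
#' One row per region (all lesion rows, then all control rows) with labels
#' and subject ids; the representation consumed by the embedding, ranking
#' and classification stages.
#'
#' @param cohort A [cohort_table()].
#' @param retained_only Drop subjects flagged `deleted`.
#' @return List with `x` (matrix `2m x 25`), `label` (factor with levels
#'   `control`, `lesion`), and `subject_id`.
#' @export
region_matrix <- function(cohort, retained_only = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- if (retained_only) !(cohort$screening$deleted %in% TRUE) else
    rep(TRUE, length(cohort$subject_id))
  x <- rbind(cohort$lesion[keep, , drop = FALSE],
             cohort$control[keep, , drop = FALSE])
  m <- sum(keep)
  list(x = x,
       label = factor(rep(c("lesion", "control"), each = m),
                      levels = c("control", "lesion")),
       subject_id = rep(cohort$subject_id[keep], 2L))
}

# z-score columns; zero-spread columns map to 0
.zscore <- function(x, center = colMeans(x), scale = apply(x, 2L, stats::sd)) {
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}
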