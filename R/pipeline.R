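#' Pipeline run configuration
#'
#' Collects every tunable of the full analysis with validated defaults.
#' The configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param Ng,d,angles,run_directions,moments_normalize,moments_on_raw
#'   Feature-extraction settings; see [feature_config()].
#' @param alpha Significance level for the per-feature tests.
#' @param adjust Multiple-testing adjustment (default `"none"`; `"holm"`
#'   available).
#' @param top_k Number of features selected by importance rank (default 5).
#' @param train_frac,n_repeats Split settings (defaults 0.7 and 5).
#' @param perplexity,tsne_iter Embedding settings (defaults 15 and 1000).
#' @param threshold Score threshold for confusion matrices (default 0.5).
#' @param hyper Named list of per-classifier hyperparameter lists
#'   (`rf`, `svm`, `bp`); see [train_classifier()].
#' @param seed Master seed; every stochastic stage (embedding, clustering,
#'   ranking, splits, classifier fits) gets a seed derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(Ng = 16L, d = 1L, angles = c(0, 45, 90, 135),
                       run_directions = c(0, 45, 90, 135),
                       moments_normalize = TRUE, moments_on_raw = FALSE,
                       alpha = 0.05, adjust = "none", top_k = 5L,
                       train_frac = 0.7, n_repeats = 5L,
                       perplexity = 15, tsne_iter = 1000L, threshold = 0.5,
                       hyper = list(rf = list(), svm = list(), bp = list()),
                       seed = 1L) {
  fc <- feature_config(Ng, d, angles, run_directions,
                       moments_normalize, moments_on_raw)
  stopifnot(alpha > 0, alpha < 1, top_k >= 1L, top_k <= 25L,
            train_frac > 0, train_frac <= 1, n_repeats >= 1L,
            perplexity > 0, tsne_iter >= 10L, threshold > 0, threshold < 1)
  structure(list(features = fc, alpha = alpha, adjust = adjust,
                 top_k = as.integer(top_k), train_frac = train_frac,
                 n_repeats = as.integer(n_repeats), perplexity = perplexity,
                 tsne_iter = as.integer(tsne_iter), threshold = threshold,
                 hyper = hyper, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$features <- unclass(x$features)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- x$features
  run_config(Ng = f$Ng, d = f$d, angles = f$angles,
             run_directions = f$run_directions,
             moments_normalize = f$moments_normalize,
             moments_on_raw = f$moments_on_raw,
             alpha = x$alpha, adjust = x$adjust, top_k = x$top_k,
             train_frac = x$train_frac, n_repeats = x$n_repeats,
             perplexity = x$perplexity, tsne_iter = x$tsne_iter,
             threshold = x$threshold,
             hyper = lapply(x$hyper, as.list), seed = x$seed)
}

#' Extract features for every manifest region
#'
#' The extraction-only entry point: loads the manifest images and returns
#' the per-region feature table.
#'
#' @param manifest_path Manifest CSV (see [read_manifest()]).
#' @param config A [run_config()] (only its feature settings are used).
#' @return A [cohort_table()].
#' @export
extract_manifest_features <- function(manifest_path, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  extract_cohort_features(read_manifest(manifest_path), config$features)
}

#' Run the full paired texture-analysis pipeline
#'
#' Executes, in order: feature extraction; per-feature paired Wilcoxon
#' table; t-SNE embedding with misplacement flags plus the per-sample
#' screening statistic; sample deletion; Gini importance ranking on the
#' retained regions; top-k selection; repeated subject-level splits; RF,
#' SVM and BP training and evaluation; aggregation.  Every artifact is
#' written to `out_dir` as CSV/JSON together with the configuration and
#' the derived stage seeds, so a finished run directory is self-describing.
#'
#' @param manifest_path Manifest CSV of image paths (see [read_manifest()]),
#'   or a ready [cohort_table()] to skip extraction.
#' @param config A [run_config()].
#' @param out_dir Output directory for artifacts (created; default a fresh
#'   temporary directory).
#' @return Invisibly, a list with `cohort` (screened [cohort_table()]),
#'   `tests` ([feature_tests()] table), `embedding`, `ranking`, `selected`,
#'   `splits`, `report` ([evaluate_classifiers()] result) and `out_dir`.
#' @export
run_pipeline <- function(manifest_path, config = run_config(),
                         out_dir = tempfile("texroi_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seeds <- withr::with_seed(config$seed,
    stats::setNames(sample.int(2147483646L, 5L),
                    c("tsne", "kmeans", "ranking", "splits", "classifiers")))
  write_run_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(as.list(seeds), file.path(out_dir, "seeds.json"),
                       auto_unbox = TRUE)

  log_line("stage: extraction")
  cohort <- stage("extraction", {
    if (inherits(manifest_path, "cohort_table")) manifest_path
    else extract_manifest_features(manifest_path, config)
  })
  n <- length(cohort$subject_id)
  .write_features_csv(cohort, file.path(out_dir, "features.csv"))

  log_line("stage: feature tests")
  tests <- stage("feature tests",
                 feature_tests(cohort, alpha = config$alpha, adjust = config$adjust))
  utils::write.csv(as.data.frame(tests), file.path(out_dir, "feature_tests.csv"),
                   row.names = FALSE)

  log_line("stage: screening")
  regions_all <- region_matrix(cohort)
  emb <- stage("screening", {
    e <- tsne_embed(regions_all$x, labels = regions_all$label,
                    perplexity = config$perplexity, seed = seeds[["tsne"]],
                    max_iter = config$tsne_iter)
    flag_misplaced(e, seed = seeds[["kmeans"]])
  })
  # a subject is misplaced iff either of its two region points is
  subj_flag <- emb$misplaced[seq_len(n)] | emb$misplaced[n + seq_len(n)]
  cohort$screening$misplaced <- subj_flag
  cohort <- stage("screening", per_sample_screening(cohort))
  cohort <- stage("deletion", deletion_rule(cohort))
  deleted <- cohort$subject_id[cohort$screening$deleted]
  for (sid in deleted) log_line("deleted subject: %s", sid)
  utils::write.csv(attr(cohort, "deletion_report"),
                   file.path(out_dir, "screening.csv"), row.names = FALSE)
  utils::write.csv(data.frame(point = seq_len(2L * n),
                              subject_id = regions_all$subject_id,
                              label = regions_all$label,
                              x = emb$coords[, 1L], y = emb$coords[, 2L],
                              misplaced = emb$misplaced),
                   file.path(out_dir, "embedding.csv"), row.names = FALSE)

  log_line("stage: ranking")
  regions <- region_matrix(cohort, retained_only = TRUE)
  ranking <- stage("ranking",
                   gini_importance(regions$x, regions$label, seed = seeds[["ranking"]]))
  utils::write.csv(as.data.frame(ranking), file.path(out_dir, "importance.csv"),
                   row.names = FALSE)
  selected <- select_top_k(ranking, config$top_k)
  log_line("selected features: %s", paste(selected, collapse = ", "))

  log_line("stage: classification")
  retained <- cohort$subject_id[!(cohort$screening$deleted %in% TRUE)]
  splits <- stage("splits",
                  make_splits(retained, n_repeats = config$n_repeats,
                              train_frac = config$train_frac,
                              seed = seeds[["splits"]]))
  report <- stage("classification",
                  evaluate_classifiers(regions, selected, splits,
                                       seed = seeds[["classifiers"]],
                                       hyper = config$hyper,
                                       threshold = config$threshold))
  .write_report_csv(report, out_dir)
  log_line("done")
  invisible(list(cohort = cohort, tests = tests, embedding = emb,
                 ranking = ranking, selected = selected, splits = splits,
                 report = report, out_dir = out_dir))
}

.write_features_csv <- function(cohort, path) {
  n <- length(cohort$subject_id)
  df <- data.frame(subject_id = rep(cohort$subject_id, 2L),
                   group = rep(c("lesion", "control"), each = n))
  df <- cbind(df, rbind(cohort$lesion, cohort$control))
  utils::write.csv(df, path, row.names = FALSE)
}

.write_report_csv <- function(report, out_dir) {
  agg <- do.call(rbind, lapply(names(report), function(kind) {
    a <- report[[kind]]$aggregate
    data.frame(classifier = toupper(kind), auc = a$auc,
               error_rate = a$error_rate, sensitivity = a$sensitivity,
               specificity = a$specificity)
  }))
  utils::write.csv(agg, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  per <- do.call(rbind, lapply(names(report), function(kind)
    cbind(classifier = toupper(kind), report[[kind]]$aggregate$per_repeat)))
  utils::write.csv(per, file.path(out_dir, "metrics_repeats.csv"), row.names = FALSE)
  for (kind in names(report))
    utils::write.csv(report[[kind]]$aggregate$mean_roc,
                     file.path(out_dir, sprintf("roc_%s.csv", kind)),
                     row.names = FALSE)
}
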