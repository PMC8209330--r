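#' Read a grayscale region from a PNG file
#'
#' Reads an 8-bit grayscale PNG (color images are reduced to their first
#' channel), optionally cropping to a rectangular ROI and/or applying a
#' same-size binary mask image.
#'
#' @param path PNG file path.
#' @param roi Optional ROI string `"r1:r2,c1:c2"` (1-based, inclusive) or
#'   integer vector `c(r1, r2, c1, c2)`.
#' @param mask_path Optional path to a same-size PNG whose pixels > 0.5
#'   mark the region of interest (cropped with `roi` if both are given).
#' @return A [gray_region()] (8-bit).
#' @export
read_region_png <- function(path, roi = NULL, mask_path = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  px <- round(img * 255)
  mask <- NULL
  if (!is.null(mask_path) && !is.na(mask_path) && nzchar(mask_path)) {
    if (!file.exists(mask_path)) stop("cannot read mask: ", mask_path, call. = FALSE)
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (!identical(dim(m), dim(px)))
      stop("mask dimensions do not match image: ", mask_path, call. = FALSE)
    mask <- m > 0.5
  }
  if (!is.null(roi) && !(length(roi) == 1L && (is.na(roi) || !nzchar(roi)))) {
    r <- .parse_roi(roi)
    px <- px[r[1L]:r[2L], r[3L]:r[4L], drop = FALSE]
    if (!is.null(mask)) mask <- mask[r[1L]:r[2L], r[3L]:r[4L], drop = FALSE]
  }
  gray_region(px, mask = mask, bit_depth = 8L)
}

.parse_roi <- function(roi) {
  if (is.character(roi)) {
    parts <- as.integer(unlist(strsplit(roi, "[:,]")))
    if (length(parts) != 4L || anyNA(parts))
      stop("ROI must be of the form 'r1:r2,c1:c2'", call. = FALSE)
    roi <- parts
  }
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1L] > roi[2L] || roi[3L] > roi[4L] || any(roi < 1L))
    stop("invalid ROI rectangle", call. = FALSE)
  roi
}

#' Write a grayscale region as an 8-bit PNG
#'
#' @param region A [gray_region()] (written on the 8-bit scale).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_png <- function(region, path) {
  stopifnot(inherits(region, "gray_region"))
  v <- region$pixels * (255 / (2^region$bit_depth - 1))
  png::writePNG(v / 255, target = path)
  invisible(path)
}

#' Materialize a synthetic cohort as images plus a manifest
#'
#' Generates the cohort, writes one 8-bit grayscale PNG per region, a
#' manifest CSV (`subject_id`, `lesion_path`, `control_path`) and the
#' cohort specification as JSON (including the null-pair subject ids, for
#' validation; the manifest itself carries no such flag).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly; the generated
#'   `region_cohort` is attached as attribute `"cohort"`.
#' @export
make_synthetic_run <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  cohort <- generate_cohort(spec)
  n <- length(cohort$subject_id)
  lesion_path <- file.path(dir, sprintf("%s_lesion.png", cohort$subject_id))
  control_path <- file.path(dir, sprintf("%s_control.png", cohort$subject_id))
  for (i in seq_len(n)) {
    write_region_png(cohort$lesion[[i]], lesion_path[i])
    write_region_png(cohort$control[[i]], control_path[i])
  }
  manifest <- data.frame(subject_id = cohort$subject_id,
                         lesion_path = lesion_path,
                         control_path = control_path)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  meta <- c(unclass(spec)[c("n_pairs", "n_null_pairs", "seed")],
            list(lesion_spec = unclass(spec$lesion_spec),
                 control_spec = unclass(spec$control_spec),
                 null_subject_ids = cohort$subject_id[attr(cohort, "null_pairs")]))
  jsonlite::write_json(meta, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(invisible(manifest_path), cohort = cohort)
}

#' Read a cohort manifest and load its regions
#'
#' @param manifest_path CSV with columns `subject_id`, `lesion_path`,
#'   `control_path` and optionally `lesion_roi`, `control_roi`,
#'   `lesion_mask`, `control_mask`.  Relative image paths are resolved
#'   against the manifest's directory.
#' @return A list with `subject_id`, `lesion`, `control` (lists of
#'   [gray_region()]s), compatible with [extract_cohort_features()].
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("cannot read manifest: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "lesion_path", "control_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  col <- function(nm) if (nm %in% names(man)) man[[nm]] else rep(NA_character_, nrow(man))
  load_side <- function(side) {
    paths <- resolve(man[[paste0(side, "_path")]])
    rois <- col(paste0(side, "_roi"))
    masks <- col(paste0(side, "_mask"))
    masks <- ifelse(is.na(masks) | !nzchar(masks), NA, resolve(masks))
    lapply(seq_len(nrow(man)), function(i) {
      tryCatch(
        read_region_png(paths[i], roi = rois[i],
                        mask_path = if (is.na(masks[i])) NULL else masks[i]),
        error = function(e) stop(sprintf("manifest row %d (subject %s, %s): %s",
                                         i, man$subject_id[i], side,
                                         conditionMessage(e)), call. = FALSE))
    })
  }
  list(subject_id = as.character(man$subject_id),
       lesion = load_side("lesion"), control = load_side("control"))
}
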