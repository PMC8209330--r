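#' Construct a grayscale region
#'
#' A `gray_region` is the unit of feature extraction: a rectangular patch of
#' integer gray levels with an optional region-of-interest mask.
#'
#' @param pixels Numeric or integer matrix of gray levels; values are rounded
#'   to integers and must lie in `[0, 2^bit_depth - 1]`.
#' @param mask Optional logical matrix of the same dimensions; `TRUE` marks
#'   pixels inside the region of interest.  At least 4 pixels must be inside.
#' @param bit_depth Bit depth of the gray scale (default 8).
#' @return An object of class `gray_region` with elements `pixels`, `mask`
#'   and `bit_depth`.
#' @examples
#' r <- gray_region(matrix(0:15, 4, 4))
#' @export
gray_region <- function(pixels, mask = NULL, bit_depth = 8L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 16L)
    stop("`bit_depth` must be between 1 and 16", call. = FALSE)
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  maxv <- 2L^bit_depth - 1L
  if (any(px < 0L) || any(px > maxv))
    stop(sprintf("`pixels` must lie in [0, %d] for bit_depth %d", maxv, bit_depth),
         call. = FALSE)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(px)))
      stop("`mask` must be a logical matrix with the dimensions of `pixels`",
           call. = FALSE)
    if (sum(mask) < 4L)
      stop("`mask` must keep at least 4 pixels inside the region", call. = FALSE)
  }
  structure(list(pixels = px, mask = mask, bit_depth = bit_depth),
            class = "gray_region")
}

#' @export
print.gray_region <- function(x, ...) {
  cat(sprintf("<gray_region> %d x %d, %d-bit%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$mask)) "" else sprintf(", %d masked-in pixels", sum(x$mask))))
  invisible(x)
}

#' Quantize a grayscale region to Ng levels
#'
#' Fixed-range linear binning over the full bit-depth range:
#' `level = floor(v * Ng / 2^bit_depth)`.  Fixed-range (rather than
#' per-region min--max) binning keeps quantized features comparable across
#' regions of one cohort.
#'
#' @param region A [gray_region()].
#' @param Ng Number of gray levels; `2 <= Ng <= 2^bit_depth`.
#' @return An object of class `quantized_region` with elements `pixels`
#'   (levels in `[0, Ng - 1]`), `Ng` and `mask`.
#' @examples
#' q <- quantize(gray_region(matrix(c(0, 16, 128, 255), 2, 2)), Ng = 16)
#' q$pixels
#' @export
quantize <- function(region, Ng = 16L) {
  stopifnot(inherits(region, "gray_region"))
  Ng <- as.integer(Ng)
  if (Ng < 2L || Ng > 2L^region$bit_depth)
    stop(sprintf("`Ng` must lie in [2, %d] for bit_depth %d",
                 2L^region$bit_depth, region$bit_depth), call. = FALSE)
  lv <- (region$pixels * Ng) %/% (2L^region$bit_depth)
  structure(list(pixels = lv, Ng = Ng, mask = region$mask),
            class = "quantized_region")
}

# masked values of a (quantized or gray) region, as a numeric vector
.region_values <- function(x) {
  if (is.null(x$mask)) as.numeric(x$pixels) else as.numeric(x$pixels[x$mask])
}
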