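#' Specification of a synthetic grayscale patch
#'
#' Patches are smoothed-Gaussian-noise fields: white noise convolved with an
#' isotropic Gaussian kernel of width `smooth_len` (the spatial correlation
#' length, in pixels), rescaled so the field has theoretical mean
#' `mean_intensity` and standard deviation `sd_intensity`, then rounded and
#' clipped to the bit-depth range.  Two parameters control the first-order
#' statistics and one controls the spatial (co-occurrence / run-length)
#' structure.
#'
#' @param height,width Patch dimensions in pixels (each at least 4).
#' @param mean_intensity Target mean gray level on `[0, 2^bit_depth - 1]`.
#' @param sd_intensity Target standard deviation in gray levels (>= 0).
#' @param smooth_len Gaussian correlation length in pixels (>= 0; 0 means
#'   white noise).
#' @param bit_depth Bit depth (default 8).
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(height = 32L, width = 32L, mean_intensity = 100,
                       sd_intensity = 20, smooth_len = 2, bit_depth = 8L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 4L) stop("`height` must be at least 4 pixels", call. = FALSE)
  if (width < 4L) stop("`width` must be at least 4 pixels", call. = FALSE)
  if (sd_intensity < 0) stop("`sd_intensity` must be >= 0", call. = FALSE)
  if (smooth_len < 0) stop("`smooth_len` must be >= 0", call. = FALSE)
  maxv <- 2^as.integer(bit_depth) - 1
  if (mean_intensity < 0 || mean_intensity > maxv)
    stop(sprintf("`mean_intensity` must lie in [0, %d]", maxv), call. = FALSE)
  structure(list(height = height, width = width,
                 mean_intensity = mean_intensity, sd_intensity = sd_intensity,
                 smooth_len = smooth_len, bit_depth = as.integer(bit_depth)),
            class = "patch_spec")
}

#' Generate one synthetic patch
#'
#' Deterministic given `(spec, seed)`.  The white-noise field is generated
#' on a grid enlarged by the kernel radius and convolved with a normalized
#' Gaussian kernel (separably, keeping only the fully covered "valid"
#' region), so edge pixels have the same variance as interior pixels; the
#' smoothed field is divided by the theoretical standard deviation of the
#' smoothed unit noise (`sqrt(sum(kernel^2))`) before the affine map to the
#' target mean/sd.
#'
#' @param spec A [patch_spec()].
#' @param seed Integer seed.
#' @return A [gray_region()].
#' @examples
#' p <- generate_patch(patch_spec(sd_intensity = 0, mean_intensity = 5), seed = 1)
#' unique(as.vector(p$pixels))
#' @export
generate_patch <- function(spec, seed) {
  stopifnot(inherits(spec, "patch_spec"))
  h <- spec$height; w <- spec$width
  z <- withr::with_seed(as.integer(seed), {
    if (spec$smooth_len > 0) {
      r <- as.integer(ceiling(3 * spec$smooth_len))
      noise <- matrix(rnorm((h + 2L * r) * (w + 2L * r)), h + 2L * r, w + 2L * r)
      g <- exp(-((-r:r)^2) / (2 * spec$smooth_len^2))
      g <- g / sum(g)
      # separable valid convolution as banded matrix products
      A <- .conv_band(h, g)
      B <- .conv_band(w, g)
      (A %*% noise %*% t(B)) / sum(g^2)  # sqrt(sum(kernel2d^2)) = sum(g^2)
    } else {
      matrix(rnorm(h * w), h, w)
    }
  })
  v <- round(spec$mean_intensity + spec$sd_intensity * z)
  maxv <- 2^spec$bit_depth - 1
  v <- pmin(pmax(v, 0), maxv)
  gray_region(v, bit_depth = spec$bit_depth)
}

# n x (n + len(g) - 1) band matrix so that M %*% x is the valid 1-D
# convolution of x with the (symmetric) kernel g
.conv_band <- function(n, g) {
  k <- length(g)
  M <- matrix(0, n, n + k - 1L)
  idx <- cbind(rep(seq_len(n), each = k),
               rep(seq_len(n), each = k) + rep(seq_len(k) - 1L, n))
  M[idx] <- rep(g, n)
  M
}

#' Specification of a synthetic paired cohort
#'
#' A cohort of `n_pairs` subjects, each with one lesion patch and one
#' contralateral control patch.  `n_null_pairs` of the subjects are "null"
#' pairs whose two patches are drawn independently from the control
#' distribution (they differ by noise only), emulating ambiguous samples
#' with no real lesion/control contrast.
#'
#' @param n_pairs Number of subjects (default 40).
#' @param lesion_spec,control_spec [patch_spec()]s for the two regions.
#'   Defaults plant a brighter, more dispersed lesion (mean 120, sd 40)
#'   against the control (mean 100, sd 20).
#' @param n_null_pairs Number of null pairs (default 7; `0 <= n_null_pairs
#'   <= n_pairs`).
#' @param seed Integer cohort seed; per-patch seeds are derived from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 40L,
                        lesion_spec = patch_spec(mean_intensity = 120, sd_intensity = 40),
                        control_spec = patch_spec(mean_intensity = 100, sd_intensity = 20),
                        n_null_pairs = 7L, seed = 1L) {
  n_pairs <- as.integer(n_pairs); n_null_pairs <- as.integer(n_null_pairs)
  if (n_pairs < 2L) stop("`n_pairs` must be at least 2", call. = FALSE)
  if (n_null_pairs < 0L || n_null_pairs > n_pairs)
    stop("`n_null_pairs` must lie in [0, n_pairs]", call. = FALSE)
  stopifnot(inherits(lesion_spec, "patch_spec"), inherits(control_spec, "patch_spec"))
  structure(list(n_pairs = n_pairs, lesion_spec = lesion_spec,
                 control_spec = control_spec, n_null_pairs = n_null_pairs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic paired cohort
#'
#' The cohort seed deterministically draws (a) which subjects are null pairs
#' and (b) one sub-seed per patch (`sample.int(2^31 - 2, 2 * n_pairs)`), so
#' cohorts are reproducible element-wise.  Null pairs draw both regions from
#' `control_spec`.  The identity of the null pairs is attached as attribute
#' `"null_pairs"` (a logical vector) for validation purposes only; the
#' analysis pipeline never reads it.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `region_cohort`: list with `subject_id`,
#'   `lesion` and `control` (lists of [gray_region()]s) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_pairs
  draws <- withr::with_seed(spec$seed, {
    list(null_idx = sort(sample.int(n, spec$n_null_pairs)),
         seeds = matrix(sample.int(2147483646L, 2L * n), n, 2L))
  })
  is_null <- seq_len(n) %in% draws$null_idx
  lesion <- vector("list", n); control <- vector("list", n)
  for (i in seq_len(n)) {
    lspec <- if (is_null[i]) spec$control_spec else spec$lesion_spec
    lesion[[i]] <- generate_patch(lspec, draws$seeds[i, 1L])
    control[[i]] <- generate_patch(spec$control_spec, draws$seeds[i, 2L])
  }
  ids <- sprintf("S%03d", seq_len(n))
  structure(list(subject_id = ids, lesion = lesion, control = control,
                 spec = spec),
            class = "region_cohort", null_pairs = is_null)
}

#' Tiny hand-checkable fixture regions
#'
#' Three regions whose texture features can be computed by hand:
#' \describe{
#'   \item{const4}{4 x 4 constant patch of value 5 (8-bit).  All central and
#'     absolute moments are 0, `m1 = 5` at `Ng = 16` quantization is level 0;
#'     with `Ng = 16` the quantized patch is constant so energy = 1,
#'     entropy = 0, inertia = 0 and correlation = 0 (degenerate).}
#'   \item{step2}{the 2 x 2 patch `rbind(c(0,0), c(1,1))` (1-bit).  At
#'     `Ng = 2`: moments m = 0.5 (all orders), c2 = a2 = 0.25, c4 = a4 =
#'     0.0625, a1 = 0.5, a3 = 0.125; horizontal GLCM `[[0.5, 0], [0, 0.5]]`
#'     gives energy 0.5, entropy 1 bit, correlation 1; horizontal runs give
#'     SRE 0.25, LRE 4, GLN 1, RP 0.5.}
#'   \item{checker4}{alternating 0/1 4 x 4 checkerboard (1-bit); every
#'     horizontal run has length 1 (16 runs).}
#' }
#'
#' @return Named list of [gray_region()]s.
#' @export
fixture_images <- function() {
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  list(const4 = gray_region(matrix(5L, 4L, 4L), bit_depth = 8L),
       step2 = gray_region(rbind(c(0L, 0L), c(1L, 1L)), bit_depth = 1L),
       checker4 = gray_region(checker, bit_depth = 1L))
}
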