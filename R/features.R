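#' Canonical names of the 25-feature texture panel
#'
#' Order: four raw moments, four central moments, four absolute central
#' moments of the intensity histogram; long-run emphasis, short-run
#' emphasis, gray-level nonuniformity, run percentage from the run-length
#' matrix; energy, inertia (contrast), correlation, entropy, mean,
#' variance, standard deviation, homogeneity and dissimilarity from the
#' co-occurrence matrix.
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  c(paste0("m", 1:4), paste0("c", 1:4), paste0("a", 1:4),
    "lre", "sre", "gln", "rp",
    "energy", "inertia", "correlation", "entropy",
    "glcm_mean", "glcm_variance", "glcm_sd", "homogeneity", "dissimilarity")
}

#' Human-readable labels for the 25 texture features
#'
#' @return Named character vector mapping canonical feature names
#'   ([feature_names()]) to descriptive labels.
#' @export
feature_labels <- function() {
  c(m1 = "first-order moment", m2 = "second-order moment",
    m3 = "third-order moment", m4 = "fourth-order moment",
    c1 = "first-order central moment", c2 = "second-order central moment",
    c3 = "third-order central moment", c4 = "fourth-order central moment",
    a1 = "first-order absolute moment", a2 = "second-order absolute moment",
    a3 = "third-order absolute moment", a4 = "fourth-order absolute moment",
    lre = "long run emphasis", sre = "short run emphasis",
    gln = "gray level nonuniformity", rp = "total run-length percentage",
    energy = "energy", inertia = "inertia moment",
    correlation = "correlation", entropy = "entropy",
    glcm_mean = "mean", glcm_variance = "variance",
    glcm_sd = "standard deviation", homogeneity = "homogeneity",
    dissimilarity = "dissimilarity")
}

#' Histogram moment features
#'
#' Raw, central and absolute central moments of orders 1--4 of the
#' (masked) value histogram.  With `N` pixels of value `v` and mean `mu`:
#' `m_k = mean(v^k)`, `c_k = mean((v - mu)^k)`, `a_k = mean(|v - mu|^k)`.
#'
#' @param q A [quantize()]d region (moments are computed on quantized
#'   levels) or a raw [gray_region()].
#' @param normalize If `FALSE`, sums are reported instead of means.
#' @return Named numeric vector `m1..m4, c1..c4, a1..a4`.
#' @export
histogram_moments <- function(q, normalize = TRUE) {
  v <- .region_values(q)
  n <- length(v)
  if (n < 1L) stop("empty region: no masked pixels", call. = FALSE)
  agg <- if (normalize) function(x) sum(x) / n else sum
  mu <- sum(v) / n
  dv <- v - mu
  out <- c(vapply(1:4, function(k) agg(v^k), 0),
           vapply(1:4, function(k) agg(dv^k), 0),
           vapply(1:4, function(k) agg(abs(dv)^k), 0))
  names(out) <- c(paste0("m", 1:4), paste0("c", 1:4), paste0("a", 1:4))
  out
}

# offset (drow, dcol) for an angle in image convention
.angle_offset <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("`angle` must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts all ordered within-mask pixel pairs at offset distance `d` for
#' the requested angle(s), symmetrizes (each pair is counted in both
#' directions), accumulates over angles and normalizes to sum 1.
#'
#' @param q A [quantize()]d region.
#' @param d Offset distance in pixels (default 1).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @return Object of class `glcm_matrix`: list with the normalized `Ng x Ng`
#'   matrix `P`, `d`, `angles`, and flags `symmetric`, `normalized`.
#' @examples
#' q <- quantize(gray_region(rbind(c(0, 0), c(1, 1)), bit_depth = 1), Ng = 2)
#' glcm(q, d = 1, angles = 0)$P
#' @export
glcm <- function(q, d = 1L, angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(q, "quantized_region"))
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  Ng <- q$Ng
  C <- matrix(0, Ng, Ng)
  for (ang in angles) {
    cnt <- .glcm_counts(q$pixels, q$mask, .angle_offset(ang) * d, Ng)
    C <- C + cnt + t(cnt)
  }
  tot <- sum(C)
  if (tot == 0)
    stop("degenerate region: no valid pixel pairs at the requested offsets",
         call. = FALSE)
  structure(list(P = C / tot, d = d, angles = angles,
                 symmetric = TRUE, normalized = TRUE),
            class = "glcm_matrix")
}

# one-directional pair counts for offset (dr, dc)
.glcm_counts <- function(lv, mask, off, Ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  dr <- off[1L]; dc <- off[2L]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) < 1L || length(c1) < 1L || r1[1L] > r1[length(r1)])
    return(matrix(0, Ng, Ng))
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dr, c1 + dc, drop = FALSE]
  if (!is.null(mask)) {
    keep <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0L) return(matrix(0, Ng, Ng))
  matrix(tabulate(a * Ng + b + 1L, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
}

#' Co-occurrence features
#'
#' Nine features of a normalized symmetric co-occurrence matrix, using the
#' gray-level index `i = 0..Ng-1`, the marginal `p_x(i) = sum_j p(i,j)`,
#' `mu = sum i p_x(i)` and `sigma^2 = sum (i - mu)^2 p_x(i)`:
#' energy `sum p^2`, entropy `-sum p log2 p`, inertia (contrast)
#' `sum (i-j)^2 p`, correlation `(sum i j p - mu^2) / sigma^2` (defined as 0
#' when `sigma^2 = 0`), mean, variance, standard deviation, homogeneity
#' `sum p / (1 + (i-j)^2)` and dissimilarity `sum |i-j| p`.
#'
#' @param M A [glcm()] result (must be normalized and symmetric).
#' @return Named numeric vector of the nine co-occurrence features; carries
#'   attribute `degenerate_correlation = TRUE` when `sigma^2 = 0`.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "glcm_matrix"))
  P <- M$P
  if (abs(sum(P) - 1) > 1e-12 || !isTRUE(M$normalized))
    stop("co-occurrence matrix must be normalized to sum 1", call. = FALSE)
  if (max(abs(P - t(P))) > 1e-12)
    stop("co-occurrence matrix must be symmetric", call. = FALSE)
  Ng <- nrow(P)
  i <- 0:(Ng - 1L)
  I <- matrix(i, Ng, Ng)        # row index (varies down columns)
  J <- t(I)
  px <- rowSums(P)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  pos <- P > 0
  degenerate <- sig2 == 0
  corr <- if (degenerate) 0 else (sum(I * J * P) - mu^2) / sig2
  out <- c(energy        = sum(P^2),
           inertia       = sum((I - J)^2 * P),
           correlation   = corr,
           entropy       = -sum(P[pos] * log2(P[pos])),
           glcm_mean     = mu,
           glcm_variance = sig2,
           glcm_sd       = sqrt(sig2),
           homogeneity   = sum(P / (1 + (I - J)^2)),
           dissimilarity = sum(abs(I - J) * P))
  if (degenerate) attr(out, "degenerate_correlation") <- TRUE
  out
}

#' Gray-level run-length matrix
#'
#' `R[i, l]` counts the maximal within-mask collinear runs of level `i - 1`
#' with length `l` along one direction.  Masked-out pixels break runs.
#'
#' @param q A [quantize()]d region.
#' @param direction One of 0, 45, 90, 135 degrees.
#' @return Object of class `glrlm_matrix`: list with the `Ng x Lmax` count
#'   matrix `R`, the number of covered pixels `Np`, the total number of runs
#'   `Nr`, and `direction`.
#' @examples
#' q <- quantize(gray_region(rbind(c(0, 0), c(1, 1)), bit_depth = 1), Ng = 2)
#' glrlm(q, direction = 0)$R
#' @export
glrlm <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_region"))
  runs <- .rl_runs(q, direction)
  if (length(runs$lengths) == 0L)
    stop("empty region: no masked pixels", call. = FALSE)
  Lmax <- max(runs$lengths)
  R <- matrix(tabulate((runs$lengths - 1L) * q$Ng + runs$values + 1L,
                       nbins = q$Ng * Lmax), q$Ng, Lmax)
  structure(list(R = R, Np = sum(runs$lengths), Nr = length(runs$lengths),
                 direction = direction),
            class = "glrlm_matrix")
}

# run values/lengths along one direction; masked-out pixels break runs.
# Pixels are ordered line by line (column-major order within a line index
# group traverses the line consecutively); a run break occurs at a value
# change, a line change, or a masked-out pixel.
.rl_runs <- function(q, direction) {
  lv <- q$pixels
  if (!is.null(q$mask)) lv[!q$mask] <- NA_integer_
  g <- switch(as.character(direction),
              "0"   = row(lv),
              "90"  = col(lv),
              "45"  = row(lv) + col(lv),
              "135" = row(lv) - col(lv),
              stop("`direction` must be one of 0, 45, 90, 135", call. = FALSE))
  ord <- order(as.vector(g))
  v <- as.vector(lv)[ord]
  gg <- as.vector(g)[ord]
  n <- length(v)
  if (n == 1L) {
    new_run <- TRUE
  } else {
    chg <- v[-1L] != v[-n]
    chg[is.na(chg)] <- TRUE          # entering/leaving a masked stretch
    new_run <- c(TRUE, chg | gg[-1L] != gg[-n])
  }
  run_id <- cumsum(new_run)
  lens <- tabulate(run_id)
  vals <- v[new_run]
  keep <- !is.na(vals)
  list(values = as.integer(vals[keep]), lengths = as.integer(lens[keep]))
}

#' Run-length features
#'
#' Four features of a run-length matrix with `Nr` total runs over `Np`
#' pixels: short run emphasis `(1/Nr) sum R(i,l)/l^2`, long run emphasis
#' `(1/Nr) sum R(i,l) l^2`, gray-level nonuniformity
#' `(1/Nr) sum_i (sum_l R(i,l))^2`, and run percentage `Nr/Np`.
#'
#' @param R A [glrlm()] result.
#' @return Named numeric vector `lre, sre, gln, rp`.
#' @export
glrlm_features <- function(R) {
  stopifnot(inherits(R, "glrlm_matrix"))
  if (R$Nr < 1L) stop("run-length matrix has no runs", call. = FALSE)
  l2 <- seq_len(ncol(R$R))^2
  rl2 <- R$R %*% (1 / l2)
  c(lre = sum(R$R %*% l2) / R$Nr,
    sre = sum(rl2) / R$Nr,
    gln = sum(rowSums(R$R)^2) / R$Nr,
    rp  = R$Nr / R$Np)
}

#' Feature-extraction configuration
#'
#' @param Ng Number of quantization levels (default 16).
#' @param d Co-occurrence offset distance in pixels (default 1).
#' @param angles Co-occurrence angles in degrees; features are computed per
#'   angle and averaged.
#' @param run_directions Run-length directions in degrees; features are
#'   computed per direction and averaged.
#' @param moments_normalize Divide moment sums by the pixel count (default
#'   `TRUE`, the standard definition).
#' @param moments_on_raw Compute moments on raw gray values instead of
#'   quantized levels (default `FALSE`).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(Ng = 16L, d = 1L, angles = c(0, 45, 90, 135),
                           run_directions = c(0, 45, 90, 135),
                           moments_normalize = TRUE, moments_on_raw = FALSE) {
  stopifnot(length(angles) >= 1L, length(run_directions) >= 1L)
  structure(list(Ng = as.integer(Ng), d = as.integer(d), angles = angles,
                 run_directions = run_directions,
                 moments_normalize = isTRUE(moments_normalize),
                 moments_on_raw = isTRUE(moments_on_raw)),
            class = "feature_config")
}

#' Extract the 25-feature texture panel from a region
#'
#' Quantizes the region, computes histogram moments (on quantized levels by
#' default), run-length features averaged over the configured directions,
#' and co-occurrence features averaged over the configured angles.
#'
#' @param region A [gray_region()].
#' @param config A [feature_config()].
#' @return Named numeric vector of length 25 in [feature_names()] order.
#'   Carries attribute `degenerate_correlation = TRUE` if any angle had a
#'   zero-variance co-occurrence marginal.
#' @examples
#' extract_features(fixture_images()$const4)
#' @export
extract_features <- function(region, config = feature_config()) {
  stopifnot(inherits(region, "gray_region"), inherits(config, "feature_config"))
  q <- quantize(region, config$Ng)

  mom <- tryCatch(
    histogram_moments(if (config$moments_on_raw) region else q,
                      normalize = config$moments_normalize),
    error = function(e) stop("histogram moments: ", conditionMessage(e), call. = FALSE))

  rl <- tryCatch({
    per_dir <- vapply(config$run_directions,
                      function(dd) glrlm_features(glrlm(q, dd)), numeric(4))
    rowMeans(per_dir)
  }, error = function(e) stop("run-length features: ", conditionMessage(e), call. = FALSE))

  degen <- FALSE
  co <- tryCatch({
    per_ang <- vapply(config$angles, function(ang) {
      f <- glcm_features(glcm(q, d = config$d, angles = ang))
      if (isTRUE(attr(f, "degenerate_correlation"))) degen <<- TRUE
      f
    }, numeric(9))
    rowMeans(per_ang)
  }, error = function(e) stop("co-occurrence features: ", conditionMessage(e), call. = FALSE))

  out <- c(mom, rl, co)
  names(out) <- feature_names()
  if (degen) attr(out, "degenerate_correlation") <- TRUE
  out
}
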