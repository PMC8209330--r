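# Exact t-SNE (no tree approximation), suitable for the cohort sizes this
# package works at (~10^2 points): conditional Gaussian affinities with a
# per-point precision found by bisection on the perplexity, symmetrized, and
# a Student-t low-dimensional kernel minimized by gradient descent with
# momentum, adaptive gains and early exaggeration.

# perplexity-calibrated symmetric affinities from squared distances
.tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# gradient-descent layout; returns n x 2 coordinates
.tsne_layout <- function(P, seed, max_iter = 1000L, eta = 200,
                         exaggeration = 12, exaggerate_until = 250L) {
  n <- nrow(P)
  withr::with_seed(as.integer(seed), {
    Y <- matrix(rnorm(n * 2L, sd = 1e-4), n, 2L)
    dY <- matrix(0, n, 2L)
    gains <- matrix(1, n, 2L)
    Pex <- P * exaggeration
    for (it in seq_len(max_iter)) {
      Puse <- if (it <= exaggerate_until) Pex else P
      momentum <- if (it < exaggerate_until) 0.5 else 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Puse - Q) * num
      G <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- pmax(ifelse(sign(G) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
      dY <- momentum * dY - eta * gains * G
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y), "-")
    }
    Y
  })
}

#' Embed regions in two dimensions with t-SNE
#'
#' Features are z-scored column-wise before embedding.  The embedding is
#' exact (all pairwise affinities) and deterministic given `seed`.
#'
#' @param x Numeric matrix, one row per region.
#' @param labels Optional factor/character labels per row (e.g.
#'   lesion/control), carried into the embedding for misplacement flagging.
#' @param perplexity t-SNE perplexity (default 15, sized for cohorts of
#'   about 80 region points); requires `nrow(x) > 3 * perplexity`.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @return Object of class `tsne_embedding`: list with `coords`
#'   (`n x 2`), `labels`, `perplexity`, `seed` and `misplaced` (all `NA`
#'   until [flag_misplaced()] is applied).
#' @export
tsne_embed <- function(x, labels = NULL, perplexity = 15, seed = 1L,
                       max_iter = 1000L) {
  stopifnot(is.matrix(x), nrow(x) >= 4L)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    stop(sprintf("perplexity %g needs more than %d points (got %d)",
                 perplexity, ceiling(3 * perplexity), n), call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    stopifnot(length(labels) == n)
  }
  z <- .zscore(x)
  D2 <- as.matrix(stats::dist(z))^2
  P <- .tsne_affinities(D2, perplexity)
  Y <- .tsne_layout(P, seed = seed, max_iter = max_iter)
  structure(list(coords = Y, labels = labels, perplexity = perplexity,
                 seed = as.integer(seed), misplaced = rep(NA, n)),
            class = "tsne_embedding")
}

#' Flag points misplaced in the embedding
#'
#' An algorithmic proxy for visual cluster inspection: the 2-D coordinates
#' are split into two clusters by k-means, each cluster is assigned the
#' majority label of its points, and a point is misplaced iff its own label
#' differs from its cluster's majority label.  A cluster with a tied label
#' count gets no majority and flags none of its points.
#'
#' @param emb A [tsne_embed()] result with `labels` set.
#' @param seed Seed for the k-means restarts (defaults to the embedding
#'   seed, for reproducibility).
#' @return The embedding with logical `misplaced` filled.
#' @export
flag_misplaced <- function(emb, seed = emb$seed) {
  stopifnot(inherits(emb, "tsne_embedding"))
  if (is.null(emb$labels))
    stop("embedding has no labels to compare against clusters", call. = FALSE)
  n <- nrow(emb$coords)
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(emb$coords, centers = 2L, nstart = 10L))
  if (any(km$size == 0)) {
    warning("degenerate clustering (empty cluster); no points flagged")
    emb$misplaced <- rep(FALSE, n)
    return(emb)
  }
  flags <- rep(FALSE, n)
  for (cl in 1:2) {
    in_cl <- km$cluster == cl
    tab <- table(emb$labels[in_cl])
    top <- tab[tab == max(tab)]
    if (length(top) == 1L)
      flags[in_cl] <- emb$labels[in_cl] != names(top)
  }
  emb$misplaced <- flags
  emb
}
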