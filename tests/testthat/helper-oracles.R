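# Independent brute-force oracles for the texture features, the signed-rank
# null distribution and the rank AUC.  Deliberately written with explicit
# nested loops and no calls into the package's computational paths.

oracle_quantize <- function(px, Ng, bit_depth) {
  out <- px
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px)))
    out[i, j] <- floor(px[i, j] * Ng / 2^bit_depth)
  out
}

oracle_moments <- function(values) {
  n <- length(values)
  mu <- sum(values) / n
  out <- numeric(12)
  for (k in 1:4) {
    s_raw <- 0; s_cen <- 0; s_abs <- 0
    for (v in values) {
      s_raw <- s_raw + v^k
      s_cen <- s_cen + (v - mu)^k
      s_abs <- s_abs + abs(v - mu)^k
    }
    out[k] <- s_raw / n; out[4 + k] <- s_cen / n; out[8 + k] <- s_abs / n
  }
  names(out) <- c(paste0("m", 1:4), paste0("c", 1:4), paste0("a", 1:4))
  out
}

oracle_offset <- function(angle) {
  if (angle == 0) c(0L, 1L) else if (angle == 45) c(-1L, 1L) else
    if (angle == 90) c(-1L, 0L) else c(-1L, -1L)
}

# normalized symmetric co-occurrence matrix for one angle set
oracle_glcm <- function(lv, mask, Ng, d, angles) {
  nr <- nrow(lv); nc <- ncol(lv)
  P <- matrix(0, Ng, Ng)
  for (angle in angles) {
    off <- oracle_offset(angle) * d
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + off[1L]; j2 <- j + off[2L]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      if (!is.null(mask) && (!mask[i, j] || !mask[i2, j2])) next
      a <- lv[i, j] + 1L; b <- lv[i2, j2] + 1L
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  px <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:Ng) mu <- mu + (i - 1) * px[i]
  sig2 <- 0; for (i in 1:Ng) sig2 <- sig2 + (i - 1 - mu)^2 * px[i]
  energy <- 0; entropy <- 0; inertia <- 0; hom <- 0; dis <- 0; cij <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    inertia <- inertia + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2)
    dis <- dis + abs(i - j) * p
    cij <- cij + (i - 1) * (j - 1) * p
  }
  corr <- if (sig2 == 0) 0 else (cij - mu^2) / sig2
  c(energy = energy, inertia = inertia, correlation = corr, entropy = entropy,
    glcm_mean = mu, glcm_variance = sig2, glcm_sd = sqrt(sig2),
    homogeneity = hom, dissimilarity = dis)
}

# runs scanned pixel-by-pixel along each line of one direction
oracle_glrlm_runs <- function(lv, mask, direction) {
  nr <- nrow(lv); nc <- ncol(lv)
  step <- -oracle_offset(direction)   # traverse each line in one fixed sense
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pi <- i - step[1L]; pj <- j - step[2L]
    if (pi < 1 || pi > nr || pj < 1 || pj > nc)
      starts[[length(starts) + 1L]] <- c(i, j)
  }
  vals <- integer(0); lens <- integer(0)
  for (s in starts) {
    i <- s[1L]; j <- s[2L]
    cur <- NA_integer_; len <- 0L
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      inside <- is.null(mask) || mask[i, j]
      v <- if (inside) lv[i, j] else NA_integer_
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) { vals <- c(vals, cur); lens <- c(lens, len) }
        cur <- v; len <- if (is.na(v)) 0L else 1L
      }
      i <- i + step[1L]; j <- j + step[2L]
    }
    if (!is.na(cur)) { vals <- c(vals, cur); lens <- c(lens, len) }
  }
  list(values = vals, lengths = lens)
}

oracle_glrlm_features <- function(runs) {
  Nr <- length(runs$lengths); Np <- sum(runs$lengths)
  sre <- 0; lre <- 0
  for (l in runs$lengths) { sre <- sre + 1 / l^2; lre <- lre + l^2 }
  gln <- 0
  for (v in unique(runs$values)) gln <- gln + sum(runs$values == v)^2
  c(lre = lre / Nr, sre = sre / Nr, gln = gln / Nr, rp = Nr / Np)
}

# all 25 features with the package's default settings (Ng 16, d 1, four
# angles / directions, feature-level averaging), via the oracles only
oracle_extract <- function(region, Ng = 16L, d = 1L) {
  lv <- oracle_quantize(region$pixels, Ng, region$bit_depth)
  mask <- region$mask
  values <- if (is.null(mask)) as.numeric(lv) else as.numeric(lv[mask])
  mom <- oracle_moments(values)
  dirs <- c(0, 45, 90, 135)
  rl <- rowMeans(sapply(dirs, function(dd)
    oracle_glrlm_features(oracle_glrlm_runs(lv, mask, dd))))
  co <- rowMeans(sapply(dirs, function(ang)
    oracle_glcm_features(oracle_glcm(lv, mask, Ng, d, ang))))
  out <- c(mom, rl, co)
  names(out) <- feature_names()
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    v <- 0
    for (i in seq_len(n)) if (bitwAnd(m, bitwShiftL(1L, i - 1L)) != 0) v <- v + r[i]
    vs[m + 1L] <- v
  }
  eps <- 1e-9
  p_le <- mean(vs <= v_obs + eps)
  p_ge <- mean(vs >= v_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

oracle_auc <- function(scores, labels) {
  pos <- which(labels == "lesion"); neg <- which(labels == "control")
  wins <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# deterministic random test region (uniform integer gray levels)
random_region <- function(height, width, seed, bit_depth = 8L, with_mask = FALSE) {
  withr::with_seed(seed, {
    px <- matrix(sample.int(2^bit_depth, height * width, replace = TRUE) - 1L,
                 height, width)
    mask <- NULL
    if (with_mask) {
      repeat {
        mask <- matrix(runif(height * width) > 0.25, height, width)
        if (sum(mask) >= 8) break
      }
    }
    gray_region(px, mask = mask, bit_depth = bit_depth)
  })
}

mean_silhouette <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  labels <- as.character(labels)
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
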