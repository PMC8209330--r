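test_that("quantization is fixed-range linear binning", {
  r <- gray_region(matrix(c(0L, 16L, 255L, 128L), 2, 2))
  q <- quantize(r, Ng = 16)
  expect_equal(sort(as.vector(q$pixels)), c(0L, 1L, 8L, 15L))
  expect_error(quantize(r, Ng = 1), "Ng")
  expect_error(quantize(r, Ng = 512), "Ng")
  qc <- quantize(gray_region(matrix(7L, 4, 4)), 16)
  expect_true(all(qc$pixels == qc$pixels[1, 1]))
  # mask passes through unchanged
  m <- matrix(c(TRUE, TRUE, TRUE, TRUE), 2, 2)
  expect_identical(quantize(gray_region(matrix(0L, 2, 2), mask = m), 4)$mask, m)
})

test_that("step2 fixture reproduces all hand-computed feature values", {
  q <- quantize(fixture_images()$step2, Ng = 2)

  mom <- histogram_moments(q)
  expect_equal(unname(mom), c(0.5, 0.5, 0.5, 0.5,
                              0, 0.25, 0, 0.0625,
                              0.5, 0.25, 0.125, 0.0625))

  P0 <- glcm(q, d = 1, angles = 0)
  expect_equal(P0$P, rbind(c(0.5, 0), c(0, 0.5)))
  f0 <- glcm_features(P0)
  expect_equal(unname(f0[c("energy", "entropy", "inertia", "dissimilarity",
                           "homogeneity", "glcm_mean", "glcm_variance",
                           "glcm_sd", "correlation")]),
               c(0.5, 1, 0, 0, 1, 0.5, 0.25, 0.5, 1))

  P90 <- glcm(q, d = 1, angles = 90)
  expect_equal(P90$P, rbind(c(0, 0.5), c(0.5, 0)))
  f90 <- glcm_features(P90)
  expect_equal(unname(f90[c("inertia", "correlation", "homogeneity")]),
               c(1, -1, 0.5))

  r0 <- glrlm(q, direction = 0)
  expect_equal(r0$Nr, 2L)
  expect_equal(r0$Np, 4L)
  expect_equal(unname(glrlm_features(r0)), c(4, 0.25, 1, 0.5))
})

test_that("constant and checkerboard fixtures hit the degenerate limits", {
  qk <- quantize(fixture_images()$const4, Ng = 16)
  fk <- glcm_features(glcm(qk, 1, 0))
  expect_equal(unname(fk[c("energy", "entropy", "inertia", "glcm_variance",
                           "correlation")]),
               c(1, 0, 0, 0, 0))
  expect_true(isTRUE(attr(fk, "degenerate_correlation")))
  mk <- histogram_moments(qk)
  expect_equal(unname(mk[c("m1", "c2", "c3", "c4")]), c(0, 0, 0, 0))
  rk <- glrlm(qk, 0)
  expect_equal(unname(glrlm_features(rk)), c(16, 1 / 16, 4, 0.25))

  qc <- quantize(fixture_images()$checker4, Ng = 2)
  rc <- glrlm(qc, 0)
  expect_equal(rc$Nr, 16L)
  fc <- glrlm_features(rc)
  expect_equal(unname(fc[c("lre", "sre", "rp")]), c(1, 1, 1))
})

test_that("every feature matches the brute-force oracle on random regions", {
  for (s in 1:20) {
    r <- random_region(16, 16, seed = s, with_mask = s > 14)
    got <- extract_features(r)
    want <- oracle_extract(r)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("moments depend only on the histogram and shift as moments should", {
  r <- random_region(8, 8, seed = 3)
  q <- quantize(r, 256)    # identity binning at full bit depth
  base <- histogram_moments(q)
  # permutation invariance
  qp <- q
  qp$pixels <- matrix(withr::with_seed(1, sample(as.vector(q$pixels))), 8, 8)
  expect_equal(histogram_moments(qp), base)
  # central and absolute moments are shift invariant
  qs <- q
  qs$pixels <- q$pixels - min(q$pixels)
  shifted <- histogram_moments(qs)
  expect_equal(shifted[5:12], base[5:12])
  # identities: c1 = 0, c2 = a2, c4 = a4, a3 >= |c3|
  for (s in 4:9) {
    m <- histogram_moments(quantize(random_region(6, 7, seed = s), 16))
    expect_equal(unname(m["c1"]), 0)
    expect_equal(m[["c2"]], m[["a2"]])
    expect_equal(m[["c4"]], m[["a4"]])
    expect_gte(m[["a3"]], abs(m[["c3"]]))
  }
  expect_error(histogram_moments(structure(list(pixels = matrix(1, 2, 2),
                                                mask = matrix(FALSE, 2, 2)),
                                           class = "quantized_region")),
               "empty")
})

test_that("co-occurrence matrices satisfy their structural contracts", {
  for (s in 1:6) {
    q <- quantize(random_region(10, 12, seed = 100 + s, with_mask = s > 3), 16)
    M <- glcm(q, d = 1 + s %% 2, angles = c(0, 45, 90, 135))
    expect_equal(sum(M$P), 1, tolerance = 1e-12)
    expect_equal(M$P, t(M$P))
    expect_equal(rowSums(M$P), colSums(M$P))
    f <- glcm_features(M)
    if (f[["glcm_variance"]] > 0) expect_lte(abs(f[["correlation"]]), 1 + 1e-12)
    expect_gt(f[["energy"]], 0)
    expect_lte(f[["energy"]], 1)
    expect_gte(f[["entropy"]], 0)
  }
  # pairs crossing the mask are excluded
  m <- matrix(TRUE, 2, 3); m[1, 2] <- FALSE
  q <- quantize(gray_region(rbind(c(0L, 1L, 0L), c(1L, 1L, 1L)),
                            mask = m, bit_depth = 1), 2)
  M <- glcm(q, 1, 0)
  # masked row 1 leaves no horizontal pair in row 1; row 2 has 2 pairs (1,1)
  expect_equal(M$P[2, 2], 1)
  # unnormalized input is rejected
  bad <- structure(list(P = matrix(0.3, 2, 2), normalized = TRUE),
                   class = "glcm_matrix")
  expect_error(glcm_features(bad), "normalized")
  # no valid pairs -> degenerate region
  iso <- matrix(FALSE, 5, 5); iso[cbind(c(1, 1, 5, 5), c(1, 5, 1, 5))] <- TRUE
  qiso <- quantize(gray_region(matrix(0L, 5, 5), mask = iso, bit_depth = 1), 2)
  expect_error(glcm(qiso, 1, 0), "degenerate")
})

test_that("run-length matrices cover every pixel exactly once per direction", {
  for (s in 1:6) {
    q <- quantize(random_region(9, 11, seed = 200 + s, with_mask = s > 3), 16)
    np_mask <- if (is.null(q$mask)) length(q$pixels) else sum(q$mask)
    for (dir in c(0, 45, 90, 135)) {
      R <- glrlm(q, dir)
      expect_equal(sum(R$R %*% seq_len(ncol(R$R))), np_mask)
      expect_equal(sum(R$R), R$Nr)
      f <- glrlm_features(R)
      expect_gt(f[["rp"]], 0)
      expect_lte(f[["rp"]], 1)
      if (ncol(R$R) > 1 && sum(R$R[, -1]) > 0) {
        expect_lte(f[["sre"]], 1)
        expect_gte(f[["lre"]], 1)
      }
    }
  }
})

test_that("extract_features returns the named finite 25-vector", {
  cfg <- feature_config()
  for (s in 1:4) {
    f <- extract_features(random_region(12, 12, seed = 300 + s), cfg)
    expect_named(f, feature_names())
    expect_true(all(is.finite(f)))
  }
  # single-angle configuration reproduces the per-angle fixture values
  f <- extract_features(fixture_images()$step2,
                        feature_config(Ng = 2, angles = 0, run_directions = 0))
  expect_equal(unname(f[c("energy", "entropy", "correlation")]), c(0.5, 1, 1))
  expect_equal(unname(f[c("lre", "sre", "gln", "rp")]), c(4, 0.25, 1, 0.5))
  expect_equal(unname(f[c("m1", "c2", "a3")]), c(0.5, 0.25, 0.125))
})
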