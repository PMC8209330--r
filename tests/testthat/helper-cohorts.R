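# Shared cohort shortcuts for the test suite.  Unit tests use 16 x 16
# patches to keep the suite fast; the acceptance tests use the package
# defaults where the property under test concerns the default conditions.

small_patch <- function(mean_intensity = 100, sd_intensity = 20,
                        smooth_len = 2) {
  patch_spec(height = 16L, width = 16L, mean_intensity = mean_intensity,
             sd_intensity = sd_intensity, smooth_len = smooth_len)
}

small_cohort_spec <- function(n_pairs = 40L, n_null_pairs = 7L, seed = 1L,
                              null_cohort = FALSE) {
  lesion <- if (null_cohort) small_patch() else small_patch(120, 40)
  cohort_spec(n_pairs = n_pairs, lesion_spec = lesion,
              control_spec = small_patch(), n_null_pairs = n_null_pairs,
              seed = seed)
}

# add a class shift of `effect` pooled SDs to the lesion rows of the named
# feature columns (feature-level planting for recovery experiments)
plant_feature_shift <- function(x, lesion_rows, features, effect = 1.6) {
  for (f in features)
    x[lesion_rows, f] <- x[lesion_rows, f] + effect * stats::sd(x[, f])
  x
}
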