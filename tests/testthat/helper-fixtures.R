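# Small-scale fixtures and a memoized copy of the default-pipeline artifacts
# shared by several test files.

tiny_synth_params <- function(n_geo = 8L, n_non = 8L, n_points = 600L,
                              class_ratio = 1.5, seed = 42L) {
  p <- default_synth_params()
  synth_params(n_geo = n_geo, n_non = n_non, axis_range = p$axis_range,
               n_points = n_points, peaks = p$peaks,
               sugar_region = p$sugar_region, class_ratio = class_ratio,
               intensity_cv = p$intensity_cv, noise_sd = p$noise_sd,
               solvent_peaks = p$solvent_peaks, solvent_cv = p$solvent_cv,
               seed = seed)
}

tiny_render <- function() render_spec(width = 160L, height = 100L)

tiny_dataset <- function(...) generate_dataset(tiny_synth_params(...))

# linear ramp spectrum on a descending ppm axis
ramp_spectrum <- function(n = 50L, lo = 0.5, hi = 9.5) {
  structure(list(sample_id = "ramp", ppm = seq(hi, lo, length.out = n),
                 intensity = seq_len(n) / n, label = "geo_authentic"),
            class = "nmr_spectrum")
}

flat_spectrum <- function(n = 30L, value = 0) {
  structure(list(sample_id = "flat", ppm = seq(9.5, 0.5, length.out = n),
                 intensity = rep(value, n), label = "geo_authentic"),
            class = "nmr_spectrum")
}

# sugar-region integral (rectangle rule on the shared axis)
sugar_integral <- function(dataset, region = c(3.5, 6.0)) {
  keep <- dataset$ppm >= region[1] & dataset$ppm <= region[2]
  step <- abs(mean(diff(dataset$ppm)))
  colSums(dataset$intensities[keep, , drop = FALSE]) * step
}

# memoized default-scale pipeline artifacts (computed at most once per run)
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$dataset)) {
    .pipeline_cache$dataset <- generate_dataset(default_synth_params())
    pp <- preprocess_apply(default_preprocess_spec(2L),
                           .pipeline_cache$dataset)
    .pipeline_cache$features_exp3 <- lbp_features(
      rasterize_dataset(pp, render_spec()))
  }
  .pipeline_cache
}

# independent riu2 oracle: bit vector of k (little-endian), transitions
# counted on the closed circular sequence
oracle_riu2 <- function(k, p = 8L) {
  bits <- as.integer(intToBits(k))[seq_len(p)]
  transitions <- sum(diff(c(bits, bits[1])) != 0)
  if (transitions <= 2L) sum(bits) else p + 1L
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

default_exp3_svm_report <- function() {
  if (is.null(.pipeline_cache$report_exp3_svm)) {
    .pipeline_cache$report_exp3_svm <- run_experiment(
      default_pipeline()$dataset, "exp3_lbp", classifier_spec("svm"),
      k = 5L, seed = 1L)
  }
  .pipeline_cache$report_exp3_svm
}
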