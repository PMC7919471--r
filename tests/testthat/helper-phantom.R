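# Shared fixtures: small grids and undegraded acquisition settings keep the
# unit tests fast; full-size defaults are exercised in the acceptance tests.

quiet_motion <- function(...) {
  motion_spec(amplitude_mm = c(0, 0, 0), psf_fwhm_mm = 0, noise_cv = 0, ...)
}

small_grid <- function(n = 24, sp = 4) grid_spec(dim = rep(n, 3), spacing = rep(sp, 3))

flat_lesion <- function(...) lesion_spec(blob_amplitude = 0, ...)

# Synthetic long feature table for the screening stage: per patient, K phase
# values from `phase_fun(patient)`, a pre3d value from `pre_fun(patient,
# phase_values)` and a post3d value. No images involved.
synth_table <- function(n_patients, K, feature_name, phase_fun, pre_fun,
                        post_fun = function(i, ph, pre) pre) {
  rows <- list()
  for (i in seq_len(n_patients)) {
    id <- sprintf("P%03d", i)
    ph <- phase_fun(i)
    stopifnot(length(ph) == K)
    pre <- pre_fun(i, ph)
    post <- post_fun(i, ph, pre)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = id,
      scan_role = c("pre3d", "post3d", sprintf("pre4d_phase_%d", seq_len(K))),
      segmentation = "manual", feature_name = feature_name,
      value = c(pre, post, ph), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Values whose Shapiro-Wilk verdict is deterministic: ideal normal quantiles
# always pass; a two-point mass always fails.
sw_passing_values <- function(K) qnorm((seq_len(K) - 0.5) / K)
sw_failing_values <- function(K) rep(c(0, 10), length.out = K)
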