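# Shared fixtures and independent oracles.

# A minimal valid setup-record tibble; shifts default to zero.
make_records <- function(n = 1, treatment_id = sprintf("T%02d", seq_len(n)),
                         patient_id = treatment_id, fraction = rep(1L, n),
                         stage = rep("XC", n),
                         lat = 0, long = 0, vert = 0,
                         pitch = 0, roll = 0, yaw = 0) {
  tibble::tibble(
    patient_id = rep_len(patient_id, n), treatment_id = rep_len(treatment_id, n),
    fraction = rep_len(fraction, n), stage = rep_len(stage, n),
    lat_mm = rep_len(lat, n), long_mm = rep_len(long, n), vert_mm = rep_len(vert, n),
    pitch_deg = rep_len(pitch, n), roll_deg = rep_len(roll, n), yaw_deg = rep_len(yaw, n))
}

# Independent oracle for the one-sample location test: sign-flip resampling.
# Under H0 the distribution of each observation is symmetric about 0, so
# randomly flipping signs regenerates the null; the p-value is the fraction
# of flipped samples whose |mean| reaches the observed |mean|.
sign_flip_p <- function(values, n_resamples = 1e5, seed = 42) {
  withr::local_seed(seed)
  n <- length(values)
  obs <- abs(mean(values))
  signs <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE), ncol = n)
  null_means <- abs(signs %*% abs(values)) / n
  mean(null_means >= obs - 1e-12)
}

# Truth object small enough for fast unit tests.
small_truth <- function(...) {
  cohort_truth(n_treatments = 6L,
               fractions_per_treatment = c(1L, 3L, 5L, 5L, 3L, 5L),
               n_patients = 5L, seed = 11L, ...)
}
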