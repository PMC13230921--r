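# Cheap in-memory cohorts for metadata-level tests (no phantom rendering).

toy_image <- function(side = 32, value = NULL) {
  if (is.null(value)) {
    array(stats::runif(side * side * 3), c(side, side, 3))
  } else {
    array(value, c(side, side, 3))
  }
}

# n_patients_per_class patients per class, eyes_per_patient eyes each.
make_toy_cohort <- function(n_patients_per_class = 5, classes = c("autosomal", "x_linked"),
                            eyes_per_patient = 2, side = 32, seed = 42,
                            scheme = "binary") {
  set.seed(seed)
  records <- list()
  pid <- 0
  for (lab in classes) {
    for (i in seq_len(n_patients_per_class)) {
      pid <- pid + 1
      patient <- sprintf("T%03d", pid)
      for (e in seq_len(eyes_per_patient)) {
        eye <- c("OD", "OS")[e]
        records[[length(records) + 1]] <- latentmix::image_record(
          image = toy_image(side), patient_id = patient, eye = eye,
          label = lab, acquisition_date = "2024-03-01",
          age_years = 40 + pid, record_id = paste(patient, eye, sep = "_"))
      }
    }
  }
  latentmix::cohort(records, scheme)
}

# Write a toy cohort (PNG + CSV) into a fresh temp dir; returns the dir.
write_toy_cohort_dir <- function(...) {
  ch <- make_toy_cohort(...)
  dir <- tempfile("cohort")
  latentmix::save_cohort(ch, dir)
  dir
}

# A deterministic linear codec (fixed random projection) implementing the
# encode/decode/latent_dim contract; cheap enough for count/property tests
# where a trained VAE is irrelevant.
make_linear_codec <- function(image_side = 32, d = 8, seed = 123) {
  latentmix::linear_codec(image_side = image_side, latent_dim = d, seed = seed)
}
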