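# Cohort I/O, preprocessing, label schemes, balancing and grouped splitting.

make_csv_cohort <- function(rows, dir = tempfile("csv")) {
  dir.create(dir)
  set.seed(7)
  for (i in seq_len(nrow(rows))) {
    png::writePNG(toy_image(32), file.path(dir, rows$image_path[i]))
  }
  path <- file.path(dir, "metadata.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    image_path = sprintf("img%d.png", 1:4),
    eye = c("OD", "OS", "OD", "OS"),
    label = c("AD", "AD", "XR", "XR"),
    acquisition_date = rep("2024-05-01", 4),
    age_years = c(50, 50, 22, 22),
    symptom_duration_years = c(20, 20, 10, 10),
    stringsAsFactors = FALSE
  )
}

test_that("load_cohort keeps only each patient's most recent date and validates input", {
  rows <- base_rows()
  # P1 has an older extra visit that must be dropped
  extra <- rows[1, ]; extra$image_path <- "img_old.png"; extra$acquisition_date <- "2020-01-01"
  path <- make_csv_cohort(rbind(rows, extra))
  expect_message(ch <- load_cohort(path, image_side = 32), "dropped 1")
  expect_equal(length(ch), 4)
  md <- cohort_metadata(ch)
  expect_setequal(unique(md$patient_id), c("P1", "P2"))
  expect_true(all(md$acquisition_date == "2024-05-01"))
  # shape/range contract
  expect_equal(dim(ch$records[[1]]$image), c(32, 32, 3))
  expect_true(all(vapply(ch$records, function(r) max(r$image) <= 1 && min(r$image) >= 0, TRUE)))

  # empty table -> empty cohort with warning
  empty <- make_csv_cohort(base_rows()[0, ])
  expect_warning(ch0 <- load_cohort(empty), "empty")
  expect_equal(length(ch0), 0)

  # schema / label errors
  bad <- base_rows(); bad$label <- NULL
  dirb <- tempfile("csv"); dir.create(dirb)
  pathb <- file.path(dirb, "metadata.csv"); utils::write.csv(bad, pathb, row.names = FALSE)
  expect_error(load_cohort(pathb), class = "latentmix_schema_error")
  badlab <- base_rows(); badlab$label[1] <- "BOGUS"
  expect_error(load_cohort(make_csv_cohort(badlab)), class = "latentmix_validation_error")
  # unreadable image names the path
  rows2 <- base_rows()
  path2 <- make_csv_cohort(rows2)
  file.remove(file.path(dirname(path2), "img2.png"))
  expect_error(load_cohort(path2), "img2.png", class = "latentmix_io_error")
})

test_that("cohort save/load round-trips metadata and images", {
  ch <- make_toy_cohort(n_patients_per_class = 2, scheme = "binary")
  dir <- tempfile("rt")
  save_cohort(ch, dir)
  ch2 <- load_cohort(file.path(dir, "metadata.csv"), image_side = 32,
                     label_scheme = "binary")
  md1 <- cohort_metadata(ch); md2 <- cohort_metadata(ch2)
  expect_equal(nrow(md2), nrow(md1))
  expect_equal(md2$patient_id, md1$patient_id)
  expect_equal(md2$label, md1$label)
  expect_equal(md2$eye, md1$eye)
  expect_equal(md2$age_years, md1$age_years)
  # 8-bit PNG round trip: pixels agree to 1/255
  expect_lt(max(abs(ch2$records[[1]]$image - ch$records[[1]]$image)), 1 / 254)
})

test_that("normalize_laterality mirrors OD only, preserves eye, and is idempotent", {
  img <- toy_image(32, value = 0.2)
  img[5, 1, ] <- 1 # bright pixel at column 1
  od <- image_record(img, "P1", "OD", "AD")
  os <- image_record(img, "P1", "OS", "AD")

  os2 <- normalize_laterality(os)
  expect_identical(os2$image, os$image)

  od2 <- normalize_laterality(od)
  expect_equal(od2$eye, "OD")
  expect_equal(od2$image[5, 32, 1], 1)
  expect_equal(od2$image[5, 1, 1], 0.2)

  od3 <- normalize_laterality(od2)
  expect_identical(od3$image, od2$image)
})

test_that("map_labels implements the binary / three-class / identity schemes", {
  labs <- c("AD", "AR", "XR", "XLC")
  ch <- cohort(lapply(seq_along(labs), function(i) {
    image_record(toy_image(32), paste0("P", i), "OS", labs[i])
  }))
  bin <- map_labels(ch, "binary")
  expect_equal(vapply(bin$records, `[[`, "", "label"),
               c("autosomal", "autosomal", "x_linked", "x_linked"))

  same <- map_labels(ch, "four_class")
  expect_equal(vapply(same$records, `[[`, "", "label"), labs)

  ch3 <- cohort(lapply(c("NORMAL", "AD", "XR"), function(l) {
    image_record(toy_image(32), paste0("Q", l), "OS", l)
  }))
  three <- map_labels(ch3, "three_class")
  expect_equal(vapply(three$records, `[[`, "", "label"),
               c("NORMAL", "autosomal", "x_linked"))

  chn <- cohort(list(image_record(toy_image(32), "N1", "OS", "NORMAL")))
  expect_error(map_labels(chn, "binary"), class = "latentmix_validation_error")
})

test_that("balance_classes undersamples whole patients deterministically", {
  # already balanced -> unchanged
  ch <- make_toy_cohort(n_patients_per_class = 5)
  expect_equal(length(balance_classes(ch, 1)), length(ch))

  # 20 vs 10 single-eye patients -> 10 vs 10
  big <- make_toy_cohort(n_patients_per_class = 20, classes = "autosomal",
                         eyes_per_patient = 1, scheme = "binary")
  small <- make_toy_cohort(n_patients_per_class = 10, classes = "x_linked",
                           eyes_per_patient = 1, scheme = "binary", seed = 43)
  # make patient ids distinct across the two constructions
  small$records <- lapply(small$records, function(r) {
    r$patient_id <- paste0("S", r$patient_id); r
  })
  both <- cohort(c(big$records, small$records), "binary")
  bal <- balance_classes(both, seed = 5)
  counts <- table(cohort_metadata(bal)$label)
  expect_equal(as.integer(counts[["autosomal"]]), 10L)
  expect_equal(as.integer(counts[["x_linked"]]), 10L)

  # determinism and patient-preservation invariants
  bal2 <- balance_classes(both, seed = 5)
  expect_identical(cohort_metadata(bal)$record_id, cohort_metadata(bal2)$record_id)
  md <- cohort_metadata(both)
  for (s in 1:5) {
    b <- balance_classes(both, seed = s)
    mb <- cohort_metadata(b)
    expect_true(all(table(mb$label) <= table(md$label)[names(table(mb$label))]))
    # no patient partially dropped
    for (p in unique(mb$patient_id)) {
      expect_equal(sum(mb$patient_id == p), sum(md$patient_id == p))
    }
  }

  emptyc <- cohort(list())
  expect_error(balance_classes(emptyc, 1), class = "latentmix_validation_error")
})

test_that("grouped_split assigns whole patients with per-class round-half-up counts", {
  ch <- make_toy_cohort(n_patients_per_class = 5) # 10 patients total
  plan <- grouped_split(ch, 0.8, seed = 1)
  expect_s3_class(plan, "split_plan")
  expect_equal(sum(plan$assignments == "train"), 8)
  expect_equal(sum(plan$assignments == "test"), 2)

  # 5 patients, fraction 0.8 -> 4/1
  ch5 <- make_toy_cohort(n_patients_per_class = 5, classes = "autosomal")
  plan5 <- grouped_split(ch5, 0.8, seed = 2)
  expect_equal(sum(plan5$assignments == "train"), 4)
  expect_equal(sum(plan5$assignments == "test"), 1)

  # single-patient class -> warning, forced to train
  one <- make_toy_cohort(n_patients_per_class = 1, classes = "x_linked", seed = 9)
  one$records <- lapply(one$records, function(r) { r$patient_id <- "LONE"; r })
  mix <- cohort(c(ch5$records, one$records), "binary")
  expect_warning(pw <- grouped_split(mix, 0.8, seed = 3), "single patient")
  expect_equal(unname(pw$assignments[["LONE"]]), "train")

  # both eyes always co-assigned: guaranteed by patient-keyed assignment
  split <- apply_split(ch, plan)
  tr <- unique(cohort_metadata(split$train)$patient_id)
  te <- unique(cohort_metadata(split$test)$patient_id)
  expect_length(intersect(tr, te), 0)

  expect_error(grouped_split(ch, 1.2, 1), class = "latentmix_validation_error")
})

test_that("repeated resampling produces k deterministic grouped plans", {
  ch <- make_toy_cohort(n_patients_per_class = 5)
  plans <- repeated_resampling_folds(ch, k = 5, train_fraction = 0.8, seed = 11)
  expect_length(plans, 5)
  for (p in plans) expect_equal(sum(p$assignments == "train"), 8)
  plans2 <- repeated_resampling_folds(ch, k = 5, train_fraction = 0.8, seed = 11)
  expect_identical(plans, plans2)
  # resampling, not a partition: plans are not all identical
  expect_true(length(unique(lapply(plans, function(p) sort(names(p$assignments[p$assignments == "test"]))))) > 1)
  expect_error(repeated_resampling_folds(ch, k = 1), class = "latentmix_validation_error")
})

test_that("split plans serialize to JSON and back", {
  ch <- make_toy_cohort(n_patients_per_class = 3)
  plan <- grouped_split(ch, 0.8, seed = 4)
  path <- tempfile(fileext = ".json")
  write_split_plan(plan, path)
  plan2 <- read_split_plan(path)
  expect_equal(plan2$seed, plan$seed)
  expect_equal(plan2$train_fraction, plan$train_fraction)
  expect_equal(plan2$assignments[names(plan$assignments)], plan$assignments)
})
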