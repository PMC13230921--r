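# Cohort representation, metadata/image I/O, preprocessing and
# patient-grouped splitting.

REQUIRED_COLUMNS <- c("patient_id", "image_path", "eye", "label",
                      "acquisition_date", "age_years", "symptom_duration_years")
FOUR_CLASS_LABELS <- c("AD", "AR", "XR", "XLC", "NORMAL")

#' Construct a single image record
#'
#' An `image_record` bundles one photograph with its clinical metadata. Pixels
#' live in `[0,1]` as an `H x W x 3` array; real records carry no provenance,
#' synthetic ones record how they were made (scheme, parents, parameters).
#'
#' @param image numeric `H x W x 3` array with values in `[0,1]`.
#' @param patient_id character scalar grouping key; all splits operate on it.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param label class label (e.g. inheritance mode `AD`, `AR`, `XR`, `XLC`,
#'   `NORMAL`, or a merged label after [map_labels()]).
#' @param acquisition_date ISO `YYYY-MM-DD` date string.
#' @param age_years,symptom_duration_years non-negative reals or `NA`.
#' @param is_synthetic logical; synthetic records must carry `provenance`.
#' @param provenance `NULL` for real records, otherwise a list describing the
#'   generating scheme (see [gen1_expand()], [gen2_expand()]).
#' @param record_id unique id; defaults to `patientid_eye_date`.
#' @return an object of class `image_record`.
#' @export
image_record <- function(image, patient_id, eye, label,
                         acquisition_date = NA_character_,
                         age_years = NA_real_,
                         symptom_duration_years = NA_real_,
                         is_synthetic = FALSE, provenance = NULL,
                         record_id = NULL) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_validation("image must be an H x W x 3 array")
  }
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop_validation("pixel values must lie in [0,1]")
  }
  if (!eye %in% c("OD", "OS")) stop_validation("eye must be 'OD' or 'OS', got '%s'", eye)
  if (!is_synthetic && !is.null(provenance)) {
    stop_validation("real records must have empty provenance")
  }
  if (is_synthetic && is.null(provenance)) {
    stop_validation("synthetic records must carry provenance")
  }
  rec <- list(
    image = image, patient_id = as.character(patient_id), eye = eye,
    label = as.character(label), acquisition_date = as.character(acquisition_date),
    age_years = as.numeric(age_years),
    symptom_duration_years = as.numeric(symptom_duration_years),
    is_synthetic = isTRUE(is_synthetic), provenance = provenance,
    laterality_normalized = FALSE,
    record_id = record_id %||% paste(patient_id, eye, acquisition_date, sep = "_")
  )
  class(rec) <- "image_record"
  rec
}

#' Construct a cohort of image records
#'
#' @param records list of [image_record()] objects.
#' @param label_scheme one of `"four_class"`, `"binary"`, `"three_class"`.
#' @return an object of class `cohort`.
#' @export
cohort <- function(records, label_scheme = "four_class") {
  stopifnot(label_scheme %in% c("four_class", "binary", "three_class"))
  structure(list(records = records, label_scheme = label_scheme),
            class = "cohort")
}

#' @export
length.cohort <- function(x) length(x$records)

#' @export
print.cohort <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<cohort> %d records, %d patients, scheme=%s\n",
              length(x), length(unique(md$patient_id)), x$label_scheme))
  if (nrow(md)) print(table(md$label))
  invisible(x)
}

#' Metadata table of a cohort
#'
#' @param x a [cohort()].
#' @return data.frame with one row per record (no pixel data).
#' @export
cohort_metadata <- function(x) {
  if (length(x$records) == 0) {
    return(data.frame(record_id = character(), patient_id = character(),
                      eye = character(), label = character(),
                      acquisition_date = character(), age_years = numeric(),
                      symptom_duration_years = numeric(),
                      is_synthetic = logical()))
  }
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(record_id = r$record_id, patient_id = r$patient_id,
               eye = r$eye, label = r$label,
               acquisition_date = r$acquisition_date,
               age_years = r$age_years,
               symptom_duration_years = r$symptom_duration_years,
               is_synthetic = r$is_synthetic, stringsAsFactors = FALSE)
  }))
}

read_rgb_image <- function(path) {
  if (!file.exists(path)) stop_io("image file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    tryCatch(png::readPNG(path), error = function(e)
      stop_io("cannot decode PNG %s: %s", path, conditionMessage(e)))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_io("reading JPEG (%s) requires the EBImage package", path)
    }
    x <- tryCatch(EBImage::readImage(path), error = function(e)
      stop_io("cannot decode JPEG %s: %s", path, conditionMessage(e)))
    aperm(EBImage::imageData(x), c(2, 1, 3))  # EBImage stores x,y,c
  } else {
    stop_io("unsupported image format '%s' for %s", ext, path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  clamp01(img)
}

#' Load a cohort from a metadata CSV and an image directory
#'
#' Reads the metadata table, keeps only each patient's most recent acquisition
#' date (ties on the same date keep all files of that date), loads each image,
#' rescales pixels to `[0,1]` and resizes to `image_side`.
#'
#' @param metadata_path path to a UTF-8 CSV with header columns
#'   `patient_id,image_path,eye,label,acquisition_date,age_years,symptom_duration_years`.
#' @param image_dir directory against which relative `image_path`s resolve.
#' @param image_side target square side length in pixels (default 64).
#' @param label_scheme label scheme tag for the returned cohort.
#' @return a [cohort()]; the number of records dropped by the latest-date rule
#'   is reported via `message()`.
#' @export
load_cohort <- function(metadata_path, image_dir = dirname(metadata_path),
                        image_side = 64L, label_scheme = "four_class") {
  if (!file.exists(metadata_path)) stop_io("metadata file not found: %s", metadata_path)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(md))
  if (length(missing_cols)) {
    stop_schema("metadata is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(md) == 0) {
    warning("empty metadata table: returning empty cohort")
    return(cohort(list(), label_scheme))
  }
  # accept raw inheritance modes as well as already-merged labels
  known_labels <- c(FOUR_CLASS_LABELS, "autosomal", "x_linked")
  bad <- setdiff(unique(md$label), known_labels)
  if (length(bad)) stop_validation("unknown label token(s): %s", paste(bad, collapse = ", "))

  dates <- as.Date(md$acquisition_date)
  if (anyNA(dates)) stop_validation("unparseable acquisition_date value(s)")
  keep <- unlist(lapply(split(seq_len(nrow(md)), md$patient_id), function(idx) {
    idx[dates[idx] == max(dates[idx])]
  }))
  n_drop <- nrow(md) - length(keep)
  if (n_drop > 0) {
    message(sprintf("load_cohort: dropped %d record(s) from non-latest acquisition dates", n_drop))
  }
  md <- md[sort(keep), , drop = FALSE]

  records <- lapply(seq_len(nrow(md)), function(i) {
    path <- md$image_path[i]
    if (!file.exists(path)) path <- file.path(image_dir, md$image_path[i])
    img <- resize_image(read_rgb_image(path), image_side)
    image_record(
      image = img, patient_id = md$patient_id[i], eye = md$eye[i],
      label = md$label[i], acquisition_date = md$acquisition_date[i],
      age_years = suppressWarnings(as.numeric(md$age_years[i])),
      symptom_duration_years = suppressWarnings(as.numeric(md$symptom_duration_years[i])),
      record_id = paste(md$patient_id[i], md$eye[i], i, sep = "_")
    )
  })
  cohort(records, label_scheme)
}

#' Write a cohort to disk as PNG images plus a metadata CSV
#'
#' @param x a [cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata CSV path.
#' @export
save_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- cohort_metadata(x)
  md$image_path <- paste0(md$record_id, ".png")
  for (i in seq_along(x$records)) {
    png::writePNG(clamp01(x$records[[i]]$image), file.path(dir, md$image_path[i]))
  }
  out <- md[, c("patient_id", "image_path", "eye", "label", "acquisition_date",
                "age_years", "symptom_duration_years")]
  csv <- file.path(dir, "metadata.csv")
  utils::write.csv(out, csv, row.names = FALSE)
  invisible(csv)
}

#' Normalize image laterality (mirror right eyes onto left-eye orientation)
#'
#' Right-eye (OD) images are flipped along the vertical axis so both eyes share
#' one orientation; left-eye (OS) images pass through unchanged. Applying the
#' function twice is a no-op (a flag records that a record was normalized).
#'
#' @param x an [image_record()] or a [cohort()].
#' @return object of the same class with OD images mirrored.
#' @export
normalize_laterality <- function(x) {
  if (inherits(x, "cohort")) {
    x$records <- lapply(x$records, normalize_laterality)
    return(x)
  }
  stopifnot(inherits(x, "image_record"))
  if (x$eye == "OD" && !isTRUE(x$laterality_normalized)) {
    w <- dim(x$image)[2]
    x$image <- x$image[, w:1, , drop = FALSE]
  }
  x$laterality_normalized <- TRUE
  x
}

#' Map inheritance-mode labels onto a classification scheme
#'
#' `binary` merges `AD`/`AR` into `autosomal` and `XR`/`XLC` into `x_linked`
#' (normal controls are rejected); `three_class` keeps `NORMAL` alongside the
#' merged disease classes; `four_class` is the identity.
#'
#' @param x a [cohort()].
#' @param scheme `"four_class"`, `"binary"` or `"three_class"`.
#' @return a relabelled [cohort()].
#' @export
map_labels <- function(x, scheme) {
  stopifnot(inherits(x, "cohort"))
  if (!scheme %in% c("four_class", "binary", "three_class")) {
    stop_validation("unknown label scheme '%s'", scheme)
  }
  if (scheme == "four_class") { x$label_scheme <- scheme; return(x) }
  map_one <- function(lab) {
    if (lab %in% c("AD", "AR")) "autosomal"
    else if (lab %in% c("XR", "XLC")) "x_linked"
    else lab # NORMAL or already-merged labels pass through
  }
  labs <- vapply(x$records, `[[`, "", "label")
  if (scheme == "binary" && any(labs == "NORMAL")) {
    stop_validation("NORMAL records are not allowed under the binary scheme")
  }
  x$records <- lapply(x$records, function(r) { r$label <- map_one(r$label); r })
  x$label_scheme <- scheme
  x
}

patient_table <- function(x) {
  md <- cohort_metadata(x)
  md <- md[!md$is_synthetic, , drop = FALSE]
  stats::aggregate(record_id ~ patient_id + label, md, length)
}

#' Balance class sizes by patient-preserving undersampling
#'
#' Whole patients are removed (seeded, at random) from majority classes until
#' every class's image count is within one patient's image count of the
#' minority class. A patient's fellow eyes are never split across kept and
#' dropped sets.
#'
#' @param x a [cohort()].
#' @param seed integer seed; the same seed always selects the same records.
#' @return a balanced [cohort()].
#' @export
balance_classes <- function(x, seed) {
  stopifnot(inherits(x, "cohort"))
  md <- cohort_metadata(x)
  if (nrow(md) == 0 || any(table(md$label) == 0)) {
    stop_validation("every class must contain at least one record")
  }
  counts <- table(md$label)
  target <- min(counts)
  drop_patients <- character(0)
  with_seed(seed, {
    for (lab in names(counts)) {
      pts <- unique(md$patient_id[md$label == lab])
      pts <- sample(pts)
      cnt <- counts[[lab]]
      for (p in pts) {
        np <- sum(md$label == lab & md$patient_id == p)
        if (cnt - np >= target) {
          drop_patients <- c(drop_patients, p)
          cnt <- cnt - np
        }
        if (cnt <= target) break
      }
    }
  })
  keep <- !(md$patient_id %in% drop_patients)
  x$records <- x$records[keep]
  x
}

#' Patient-grouped stratified train/test split
#'
#' Patients (never individual images) are shuffled under `seed`, stratified by
#' class, and assigned to train or test so that the train patient fraction per
#' class rounds (half-up) to `train_fraction`. Both eyes of a patient always
#' land on the same side by construction.
#'
#' @param x a [cohort()].
#' @param train_fraction real in (0,1); the protocol default is 0.8.
#' @param seed integer seed.
#' @param stratify stratify by class at patient level (default TRUE).
#' @return an object of class `split_plan` with fields `assignments`
#'   (named character vector patient_id -> "train"/"test"), `seed`,
#'   `train_fraction`.
#' @export
grouped_split <- function(x, train_fraction = 0.8, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(x, "cohort"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_validation("train_fraction must be in (0,1)")
  }
  pt <- patient_table(x)
  if (length(unique(pt$patient_id)) < 2) stop_validation("need at least 2 patients")
  assignments <- character(0)
  groups <- if (stratify) split(pt, pt$label) else list(all = pt)
  with_seed(seed, {
    for (g in groups) {
      pts <- sample(unique(g$patient_id))
      n <- length(pts)
      if (n == 1) {
        warning(sprintf("class '%s' has a single patient; forced to train", g$label[1]))
        n_train <- 1L
      } else {
        n_train <- min(n, max(1L, round_half_up(train_fraction * n)))
        if (n_train == n) n_train <- n - 1L  # keep at least one test patient
      }
      a <- c(rep("train", n_train), rep("test", n - n_train))
      names(a) <- pts
      assignments <- c(assignments, a)
    }
  })
  structure(list(assignments = assignments, seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "split_plan")
}

#' Repeated grouped resampling splits
#'
#' Cross-validation by resampling: `k` independent patient-grouped stratified
#' splits with derived seeds `seed + 0 ... seed + k - 1`. Test sets may overlap
#' across resamples (this is repeated resampling, not a k-way partition).
#'
#' @inheritParams grouped_split
#' @param k number of resamples (>= 2); the protocol default is 5.
#' @return list of `split_plan` objects.
#' @export
repeated_resampling_folds <- function(x, k = 5L, train_fraction = 0.8,
                                      seed = 1L, stratify = TRUE) {
  if (k < 2) stop_validation("k must be >= 2")
  lapply(seq_len(k) - 1L, function(i) {
    grouped_split(x, train_fraction, seed = as.integer(seed) + i,
                  stratify = stratify)
  })
}

#' Split cohort records according to a plan
#'
#' @param x a [cohort()] of real records.
#' @param plan a `split_plan`.
#' @return list with cohorts `train` and `test`.
#' @export
apply_split <- function(x, plan) {
  stopifnot(inherits(plan, "split_plan"))
  side <- plan$assignments[vapply(x$records, `[[`, "", "patient_id")]
  if (anyNA(side)) stop_validation("plan does not cover all patients")
  list(train = cohort(x$records[side == "train"], x$label_scheme),
       test = cohort(x$records[side == "test"], x$label_scheme))
}

#' Serialize / read a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(seed = plan$seed, train_fraction = plan$train_fraction,
                            assignments = as.list(plan$assignments)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(assignments = unlist(x$assignments), seed = as.integer(x$seed),
                 train_fraction = as.numeric(x$train_fraction)),
            class = "split_plan")
}
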