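# Synthetic fundus-like phantom cohorts: class-conditional retinal appearance
# with patient-level correlation between fellow eyes, so the whole expansion
# and evaluation workflow is testable without patient data.

#' Phantom cohort configuration
#'
#' The generator renders a circular fundus field (optic disc, macula, branching
#' vessels) and carries the class signal in two peripheral features chosen as
#' analogues of retinitis-pigmentosa correlates: dark peripheral speckle (a
#' bone-spicule stand-in) and mid-peripheral ring attenuation. Their
#' class-conditional means are separated by `effect_size`; at `effect_size = 0`
#' all classes are identical in distribution.
#'
#' @param n_patients_per_class patients per class; each contributes two eyes.
#' @param classes character vector of class labels.
#' @param image_side square image side in pixels (>= 32).
#' @param effect_size non-negative separation between class feature means
#'   (in latent-feature SD units; default 1 = moderately separable).
#' @param nuisance list with `illumination_range` (multiplicative),
#'   `rotation_range` (degrees) and `vignette_strength`.
#' @param fellow_eye_correlation correlation in `[0,1]` between the feature
#'   latents of a patient's two eyes.
#' @param seed master seed for the cohort.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients_per_class = 10L,
                           classes = c("autosomal", "x_linked"),
                           image_side = 64L, effect_size = 1,
                           nuisance = list(illumination_range = c(0.85, 1.15),
                                           rotation_range = c(-10, 10),
                                           vignette_strength = 0.25),
                           fellow_eye_correlation = 0.8, seed = 1L) {
  if (image_side < 32) stop_validation("image_side must be >= 32")
  if (effect_size < 0) stop_validation("effect_size must be >= 0")
  if (fellow_eye_correlation < 0 || fellow_eye_correlation > 1) {
    stop_validation("fellow_eye_correlation must be in [0,1]")
  }
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 classes = classes, image_side = as.integer(image_side),
                 effect_size = effect_size, nuisance = nuisance,
                 fellow_eye_correlation = fellow_eye_correlation,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Class-conditional age distributions (years): X-linked patients present
# younger, mirroring the known earlier onset of X-linked disease.
PHANTOM_AGE_TABLE <- list(
  AD = c(53, 16), AR = c(49, 17), XR = c(26, 19), XLC = c(26, 19),
  autosomal = c(51, 16), x_linked = c(26, 19), NORMAL = c(40, 18)
)

phantom_age_params <- function(label) {
  PHANTOM_AGE_TABLE[[label]] %||% c(45, 15)
}

#' Render one phantom fundus image
#'
#' Deterministic given `(class_label, patient_latent, eye, config, seed)`.
#' OD images are rendered pre-flip, i.e. with the optic disc mirrored relative
#' to OS, so [normalize_laterality()] has real work to do.
#'
#' @param class_label one of `config$classes`.
#' @param patient_latent numeric vector (length >= 6) of patient-level feature
#'   noise; fellow eyes of one patient share it.
#' @param eye `"OD"` or `"OS"`.
#' @param config a [phantom_config()].
#' @param seed integer seed for the per-eye draws.
#' @return an [image_record()] (metadata fields other than eye/label unset).
#' @export
generate_phantom_image <- function(class_label, patient_latent, eye, config,
                                   seed) {
  if (!class_label %in% config$classes) {
    stop_validation("class '%s' not in config$classes", class_label)
  }
  s <- config$image_side
  k <- length(config$classes)
  ci <- match(class_label, config$classes) - (k + 1) / 2  # centered class index
  rho <- config$fellow_eye_correlation

  img <- with_seed(seed, {
    el <- rho * patient_latent[1:6] + sqrt(1 - rho^2) * stats::rnorm(6)
    ill <- stats::runif(1, config$nuisance$illumination_range[1],
                        config$nuisance$illumination_range[2])
    rot <- stats::runif(1, config$nuisance$rotation_range[1],
                        config$nuisance$rotation_range[2]) * pi / 180

    xs <- seq(-1, 1, length.out = s)
    X <- matrix(xs, s, s, byrow = TRUE)   # column -> x
    Y <- matrix(xs, s, s)                 # row -> y
    rr <- sqrt(X^2 + Y^2)
    field <- rr <= 0.95

    # patient-level fundus pigmentation and tint (class-independent)
    pig <- 1 + 0.30 * tanh(0.8 * el[1])
    tint <- c(1, 1 - 0.15 * tanh(0.5 * el[2]), 1)
    base <- c(0.74, 0.33, 0.11) * ill * pig * tint
    mottle <- 0.02 * (sin(3 * X + el[1]) + cos(3 * Y + el[2]))
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- base[ch] + mottle

    rotate <- function(p) c(cos(rot) * p[1] - sin(rot) * p[2],
                            sin(rot) * p[1] + cos(rot) * p[2])
    side_sign <- if (eye == "OS") 1 else -1
    disc <- rotate(c(0.55 * side_sign, 0.05 * el[3]))
    mac <- rotate(c(-0.18 * side_sign, 0.02))

    # optic disc: bright ellipse with smooth falloff
    g <- exp(-(((X - disc[1]) / 0.15)^2 + ((Y - disc[2]) / 0.12)^2))
    disc_col <- c(0.95, 0.82, 0.50)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + (disc_col[ch] - img[, , ch]) * pmin(1.1 * g, 1)

    # macula: dark disc
    gm <- exp(-((X - mac[1])^2 + (Y - mac[2])^2) / 0.12^2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.35 * gm)

    # branching vessels: arcs leaving the disc
    vmask <- matrix(0, s, s)
    angles <- c(0.5, -0.5, 2.6, -2.6) + 0.15 * el[4]
    for (vi in seq_along(angles)) {
      th <- angles[vi] + rot
      curv <- 0.8 * sin(el[5] + vi)
      tseq <- seq(0, 1.5, by = 2 / s)
      ths <- th + curv * tseq
      px <- disc[1] + cumsum(c(0, diff(tseq)) * cos(ths))
      py <- disc[2] + cumsum(c(0, diff(tseq)) * sin(ths))
      ix <- round((px + 1) / 2 * (s - 1)) + 1
      iy <- round((py + 1) / 2 * (s - 1)) + 1
      ok <- ix >= 2 & ix <= s - 1 & iy >= 2 & iy <= s - 1
      for (dd in list(c(0, 0), c(0, 1), c(1, 0))) {
        vmask[cbind(iy[ok] + dd[1], ix[ok] + dd[2])] <- 1
      }
    }
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.55 * vmask * c(0.9, 1, 1)[ch])

    # class signal 1: peripheral dark speckle (bone-spicule analogue)
    lambda <- exp(log(18) + 0.9 * config$effect_size * ci + 0.25 * el[6])
    nspk <- stats::rpois(1, lambda)
    if (nspk > 0) {
      rad <- sqrt(stats::runif(nspk, 0.60^2, 0.90^2))
      ang <- stats::runif(nspk, 0, 2 * pi)
      sx <- rad * cos(ang); sy <- rad * sin(ang)
      ixc <- round((sx + 1) / 2 * (s - 1)) + 1
      iyc <- round((sy + 1) / 2 * (s - 1)) + 1
      rs <- max(1L, round(s / 32))  # spot radius scales with resolution
      for (j in seq_len(nspk)) {
        for (dy in -rs:rs) for (dx in -rs:rs) {
          yy <- iyc[j] + dy; xx <- ixc[j] + dx
          if (yy >= 1 && yy <= s && xx >= 1 && xx <= s &&
              abs(dy) + abs(dx) <= rs) {
            img[yy, xx, ] <- img[yy, xx, ] * 0.35
          }
        }
      }
    }

    # class signal 2: mid-peripheral ring attenuation
    att <- stats::plogis(-0.4 + 1.0 * config$effect_size * ci + 0.3 * el[6])
    band <- exp(-((rr - 0.72) / 0.14)^2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.6 * att * band)

    # vignette and circular field mask
    vig <- 1 - config$nuisance$vignette_strength * rr^2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vig * field
    clamp01(img)
  })

  image_record(image = img, patient_id = "phantom", eye = eye,
               label = class_label, acquisition_date = "2024-01-15",
               record_id = paste("phantom", class_label, eye, seed, sep = "_"))
}

#' Generate a phantom cohort
#'
#' `n_patients_per_class` patients per class, each with two eyes sharing a
#' patient-level feature latent. Simulated ages are drawn class-conditionally
#' (X-linked younger) but never influence rendering except through the class,
#' so age-matched subgroup analyses can isolate image signal.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory; if given, PNGs, `metadata.csv` and a
#'   `manifest.json` recording the exact seeds are written there.
#' @return a [cohort()].
#' @export
generate_phantom_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  records <- list()
  manifest <- list()
  pid <- 0L
  for (ki in seq_along(config$classes)) {
    lab <- config$classes[ki]
    agep <- phantom_age_params(lab)
    for (pi in seq_len(config$n_patients_per_class)) {
      pid <- pid + 1L
      patient_id <- sprintf("P%03d", pid)
      pseed <- derive_seed(config$seed, pid)
      latent <- with_seed(pseed, stats::rnorm(6))
      age <- with_seed(derive_seed(pseed, 1L),
                       min(max(stats::rnorm(1, agep[1], agep[2]), 5), 90))
      dur <- with_seed(derive_seed(pseed, 2L),
                       max(stats::rnorm(1, 24, 15), 0))
      for (ei in 1:2) {
        eye <- c("OD", "OS")[ei]
        eseed <- derive_seed(pseed, 10L + ei)
        rec <- generate_phantom_image(lab, latent, eye, config, eseed)
        rec$patient_id <- patient_id
        rec$age_years <- age
        rec$symptom_duration_years <- dur
        rec$record_id <- paste(patient_id, eye, sep = "_")
        records[[length(records) + 1L]] <- rec
        manifest[[length(manifest) + 1L]] <- list(record_id = rec$record_id,
                                                  class = lab, seed = eseed)
      }
    }
  }
  scheme <- if (setequal(config$classes, c("NORMAL", "autosomal", "x_linked")))
    "three_class"
  else if (all(config$classes %in% FOUR_CLASS_LABELS)) "four_class"
  else "binary"
  ch <- cohort(records, scheme)
  if (!is.null(out_dir)) {
    save_cohort(ch, out_dir)
    jsonlite::write_json(list(master_seed = config$seed, records = manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ch
}

#' Mean peripheral darkness of a fundus image
#'
#' Simple pixel statistic (1 minus mean intensity over the annulus between 55%
#' and 92% of the field radius) that separates phantom classes; used for
#' generator calibration checks.
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @return scalar in `[0,1]`.
#' @export
peripheral_darkness <- function(image) {
  s <- dim(image)[1]
  xs <- seq(-1, 1, length.out = s)
  X <- matrix(xs, s, s, byrow = TRUE)
  Y <- matrix(xs, s, s)
  rr <- sqrt(X^2 + Y^2)
  sel <- rr > 0.55 & rr < 0.92
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  1 - mean(lum[sel])
}
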