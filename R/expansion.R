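# Latent-space data expansion: Gen 1 random-noise perturbation of per-image
# embeddings and Gen 2 pairwise combinatorial mixing of same-label image
# pairs, with provenance tracking and a hard train/test leakage guard.

NOISE_KINDS <- c("constant", "gaussian", "uniform", "sinusoidal")

#' Expansion configuration
#'
#' @param scheme `"gen1"` (per-image noise perturbation), `"gen2"` (pairwise
#'   latent mixing) or `"gan"` (DCGAN sampling baseline).
#' @param noise_kinds subset of `constant`, `gaussian`, `uniform`,
#'   `sinusoidal` (Gen 1 only; nonempty).
#' @param strength_range `c(s_min, s_max)` with `s_min > 0`; a Gen-1 strength
#'   is drawn uniformly from this range per image (default `c(0.05, 1)`).
#' @param ratio_set mixing ratios strictly inside (0,1); default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param pair_mode `"all_ratios"` decodes every ratio for every pair
#'   (`|R| * C(n,2)` synthetics per class); `"one_ratio_per_pair"` draws one
#'   seeded ratio per pair (`C(n,2)` per class).
#' @param seed integer seed.
#' @return object of class `expansion_config`.
#' @export
expansion_config <- function(scheme = "gen2", noise_kinds = NOISE_KINDS,
                             strength_range = c(0.05, 1),
                             ratio_set = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             pair_mode = "all_ratios", seed = 1L) {
  if (!scheme %in% c("gen1", "gen2", "gan")) stop_validation("unknown scheme '%s'", scheme)
  if (scheme == "gen1" && length(noise_kinds) == 0) {
    stop_validation("gen1 requires a nonempty noise_kinds set")
  }
  if (!all(noise_kinds %in% NOISE_KINDS)) {
    stop_validation("unknown noise kind(s): %s",
                    paste(setdiff(noise_kinds, NOISE_KINDS), collapse = ", "))
  }
  if (strength_range[1] <= 0 || strength_range[2] < strength_range[1]) {
    stop_validation("strength_range must satisfy 0 < s_min <= s_max")
  }
  if (any(ratio_set <= 0 | ratio_set >= 1)) {
    stop_validation("mixing ratios must lie strictly in (0,1)")
  }
  if (!pair_mode %in% c("all_ratios", "one_ratio_per_pair")) {
    stop_validation("unknown pair_mode '%s'", pair_mode)
  }
  structure(list(scheme = scheme, noise_kinds = noise_kinds,
                 strength_range = strength_range, ratio_set = ratio_set,
                 pair_mode = pair_mode, seed = as.integer(seed)),
            class = "expansion_config")
}

#' Draw a latent noise vector
#'
#' * `constant`: every component equals `s * c` with one shared sign
#'   `c ~ Uniform{-1, +1}`.
#' * `gaussian`: `s * N(0, I)`.
#' * `uniform`: `s * Uniform(-1, 1)` per component.
#' * `sinusoidal`: component `i` is `s * sin(2 pi f i / d + phi)` with seeded
#'   integer frequency `f` in 1..4 and phase `phi` in `[0, 2 pi)`.
#'
#' The constant and sinusoidal families are declared conventions of this
#' package (with seeded free parameters); the noise-family set itself follows
#' the Gen 1 scheme.
#'
#' @param kind one of the four noise kinds.
#' @param strength positive scale `s`.
#' @param dim latent dimension `d`.
#' @param seed integer seed.
#' @return numeric vector of length `dim`.
#' @export
make_noise_vector <- function(kind, strength, dim, seed) {
  if (!kind %in% NOISE_KINDS) stop_validation("unknown noise kind '%s'", kind)
  if (strength <= 0) stop_validation("strength must be > 0")
  with_seed(seed, switch(kind,
    constant = rep(strength * sample(c(-1, 1), 1), dim),
    gaussian = strength * stats::rnorm(dim),
    uniform = strength * stats::runif(dim, -1, 1),
    sinusoidal = {
      f <- sample(1:4, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      strength * sin(2 * pi * f * seq_len(dim) / dim + phi)
    }))
}

new_synthetic_record <- function(image, parent, provenance, id) {
  rec <- image_record(image = clamp01(image), patient_id = parent$patient_id,
                      eye = parent$eye, label = parent$label,
                      acquisition_date = parent$acquisition_date,
                      age_years = parent$age_years,
                      symptom_duration_years = parent$symptom_duration_years,
                      is_synthetic = TRUE, provenance = provenance,
                      record_id = id)
  rec$laterality_normalized <- TRUE
  rec
}

#' Gen 1 expansion: per-image latent noise perturbation
#'
#' For each real training record, one noise kind is drawn uniformly from
#' `config$noise_kinds` and a strength `s ~ Uniform(s_min, s_max)`; the
#' perturbed latent mean `encode(x)$mu + noise` is decoded into exactly one
#' synthetic record, so appending the output doubles the training pool
#' (two-fold expansion).
#'
#' @param train_records list of real [image_record()]s (or a [cohort()]).
#' @param codec trained codec.
#' @param config an [expansion_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of synthetic [image_record()]s with filled provenance.
#' @export
gen1_expand <- function(train_records, codec, config = expansion_config("gen1"),
                        seed = config$seed) {
  recs <- records_only_real(train_records)
  d <- latent_dim(codec)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rseed <- derive_seed(seed, i)
    draw <- with_seed(rseed, list(
      kind = sample(config$noise_kinds, 1),
      s = stats::runif(1, config$strength_range[1], config$strength_range[2])
    ))
    mu <- encode(codec, recs[[i]]$image)$mu
    noise <- make_noise_vector(draw$kind, draw$s, d, derive_seed(rseed, 1L))
    z <- mu + noise
    img <- decode(codec, z)
    prov <- list(scheme = "gen1", parent_ids = recs[[i]]$record_id,
                 noise_kind = draw$kind, strength = draw$s,
                 codec_id = codec$id %||% "codec", seed = rseed,
                 latent = as.numeric(z))
    out[[i]] <- new_synthetic_record(img, recs[[i]], prov,
                                     paste0(recs[[i]]$record_id, "_g1_", i))
  }
  out
}

#' Enumerate unordered same-label record pairs
#'
#' All `C(n, 2)` unordered pairs without self-pairs, in deterministic order
#' (records sorted by id).
#'
#' @param records list of real [image_record()]s sharing one label.
#' @return list of length-2 lists of records.
#' @export
enumerate_pairs <- function(records) {
  records <- records_only_real(records)
  labs <- unique(vapply(records, `[[`, "", "label"))
  if (length(labs) > 1) {
    stop_validation("enumerate_pairs requires a single label, got: %s",
                    paste(labs, collapse = ", "))
  }
  if (length(records) < 2) return(list())
  ord <- order(vapply(records, `[[`, "", "record_id"))
  records <- records[ord]
  idx <- utils::combn(length(records), 2)
  lapply(seq_len(ncol(idx)), function(j) {
    list(records[[idx[1, j]]], records[[idx[2, j]]])
  })
}

#' Mix two latent vectors at ratio r
#'
#' `z = r * zA + (1 - r) * zB`, so `r` is the relative contribution of the
#' first image's latent.
#'
#' @param zA,zB numeric vectors of equal length.
#' @param ratio mixing ratio in `[0,1]`.
#' @return mixed latent vector.
#' @export
mix_latents <- function(zA, zB, ratio) {
  if (length(zA) != length(zB)) stop_validation("latent length mismatch")
  if (ratio < 0 || ratio > 1) stop_validation("ratio must be in [0,1]")
  ratio * zA + (1 - ratio) * zB
}

#' Gen 2 expansion: pairwise combinatorial latent mixing
#'
#' Per label class, every unordered pair of training images is encoded and
#' their latent means mixed: with `pair_mode = "all_ratios"` every ratio in
#' `config$ratio_set` is decoded (`|R| * C(n,2)` synthetics per class); with
#' `"one_ratio_per_pair"` one seeded ratio per pair (`C(n,2)` per class).
#' Mixing operates on the latent mean `mu` (deterministic synthesis). Classes
#' with fewer than two records are skipped with a warning.
#'
#' @inheritParams gen1_expand
#' @return list of synthetic [image_record()]s; each provenance records both
#'   parent ids (sharing the synthetic's label) and the ratio used.
#' @export
gen2_expand <- function(train_records, codec, config = expansion_config("gen2"),
                        seed = config$seed) {
  recs <- records_only_real(train_records)
  labs <- vapply(recs, `[[`, "", "label")
  out <- list()
  for (lab in unique(labs)) {
    class_recs <- recs[labs == lab]
    if (length(class_recs) < 2) {
      warning(sprintf("class '%s' has fewer than 2 records; skipped", lab))
      next
    }
    pairs <- enumerate_pairs(class_recs)
    mus <- lapply(class_recs, function(r) encode(codec, r$image)$mu)
    names(mus) <- vapply(class_recs, `[[`, "", "record_id")
    for (j in seq_along(pairs)) {
      a <- pairs[[j]][[1]]; b <- pairs[[j]][[2]]
      ratios <- if (config$pair_mode == "all_ratios") config$ratio_set
      else with_seed(derive_seed(seed, j + 7919L * match(lab, unique(labs))),
                     sample(config$ratio_set, 1))
      for (r in ratios) {
        z <- mix_latents(mus[[a$record_id]], mus[[b$record_id]], r)
        img <- decode(codec, z)
        prov <- list(scheme = "gen2",
                     parent_ids = c(a$record_id, b$record_id), ratio = r,
                     codec_id = codec$id %||% "codec", seed = seed,
                     latent = as.numeric(z))
        id <- paste0(a$record_id, "_x_", b$record_id, "_r", r)
        out[[length(out) + 1L]] <- new_synthetic_record(img, a, prov, id)
      }
    }
  }
  out
}

#' Attach synthetic records to a split (with a hard leakage guard)
#'
#' The training side becomes real train images plus synthetics; the test side
#' is real test images only. Any synthetic whose parent record belongs to a
#' test-side patient triggers a leakage error (a hard failure, never a
#' warning).
#'
#' @param plan a `split_plan`.
#' @param x the real [cohort()] the plan covers.
#' @param synthetics list of synthetic records (possibly empty).
#' @return list with cohorts `train` (reals + synthetics) and `test` (reals).
#' @export
attach_synthetic <- function(plan, x, synthetics = list()) {
  split <- apply_split(x, plan)
  real_ids <- vapply(x$records, `[[`, "", "record_id")
  train_ids <- vapply(split$train$records, `[[`, "", "record_id")
  for (s in synthetics) {
    if (!isTRUE(s$is_synthetic)) stop_validation("attach_synthetic expects synthetic records")
    parents <- s$provenance$parent_ids
    if (length(parents) > 0) {
      if (!all(parents %in% real_ids)) {
        stop_validation("synthetic %s has unresolvable parent id(s)", s$record_id)
      }
      if (!all(parents %in% train_ids)) {
        stop_leakage("synthetic %s derives from test-side parent(s): %s",
                     s$record_id,
                     paste(setdiff(parents, train_ids), collapse = ", "))
      }
    }
  }
  list(train = cohort(c(split$train$records, synthetics), x$label_scheme),
       test = split$test)
}
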