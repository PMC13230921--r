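# Experiment orchestration: the full protocol (grouped split -> class
# balancing on the training side -> codec training on training reals ->
# arm-specific expansion -> leakage-guarded attachment -> classifier training
# -> out-of-fold prediction) over repeated resampling splits, with pooled AUC
# across resamples and a manifest recording every seed and count.

#' Experiment configuration
#'
#' @param phantom a [phantom_config()] used to generate the cohort, or `NULL`
#'   when `cohort_path` is given.
#' @param cohort_path optional directory containing `metadata.csv` + images.
#' @param label_scheme label scheme applied to the cohort.
#' @param arms named list of arms, each `list(expansion = NULL |`
#'   [expansion_config()]`, arch = "conv_residual" | "transformer")`. An arm
#'   with `expansion = NULL` trains on real images only.
#' @param k number of resampling splits.
#' @param train_fraction patient-level training fraction.
#' @param vae a [vae_config()] for the codec (retrained per resample on that
#'   resample's training reals, so the codec never sees test patients).
#' @param gan a [gan_config()] for `"gan"` arms.
#' @param classifier a [classifier_config()]; the arm's `arch` overrides its
#'   `arch` field.
#' @param balance balance class sizes on the training side (default TRUE).
#' @param master_seed master seed; every stochastic stage derives its own
#'   seed from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              cohort_path = NULL,
                              label_scheme = "binary",
                              arms = list(
                                base = list(expansion = NULL, arch = "conv_residual"),
                                gen2 = list(expansion = expansion_config("gen2"),
                                            arch = "conv_residual")),
                              k = 5L, train_fraction = 0.8,
                              vae = vae_config(), gan = gan_config(),
                              classifier = classifier_config(),
                              balance = TRUE, master_seed = 1L) {
  if (length(arms) < 1) stop_validation("need at least one arm")
  for (a in arms) {
    if (!is.null(a$expansion) && !inherits(a$expansion, "expansion_config")) {
      stop_validation("arm expansion must be NULL or an expansion_config")
    }
    if (!a$arch %in% c("transformer", "conv_residual")) {
      stop_validation("unknown arm architecture '%s'", a$arch)
    }
  }
  structure(list(phantom = phantom, cohort_path = cohort_path,
                 label_scheme = label_scheme, arms = arms, k = as.integer(k),
                 train_fraction = train_fraction, vae = vae, gan = gan,
                 classifier = classifier, balance = balance,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

load_experiment_cohort <- function(config) {
  ch <- if (!is.null(config$cohort_path)) {
    load_cohort(file.path(config$cohort_path, "metadata.csv"),
                image_side = config$classifier$image_side,
                label_scheme = "four_class")
  } else {
    generate_phantom_cohort(config$phantom)
  }
  ch <- normalize_laterality(ch)
  if (!identical(ch$label_scheme, config$label_scheme)) {
    labs <- unique(cohort_metadata(ch)$label)
    if (any(labs %in% FOUR_CLASS_LABELS[1:4])) {
      ch <- map_labels(ch, config$label_scheme)
    } else {
      ch$label_scheme <- config$label_scheme
    }
  }
  ch
}

arm_synthetics <- function(arm, train_recs, codec, config, seed) {
  if (is.null(arm$expansion)) return(list())
  scheme <- arm$expansion$scheme
  if (scheme == "gen1") {
    gen1_expand(train_recs, codec, arm$expansion, seed)
  } else if (scheme == "gen2") {
    gen2_expand(train_recs, codec, arm$expansion, seed)
  } else {
    gan_synthetics(train_recs, config$gan, seed)
  }
}

# Class-conditional DCGAN sampling: one generator per class, sampled to the
# class's real training count (a two-fold expansion, mirroring gen1's size).
gan_synthetics <- function(train_recs, gcfg, seed) {
  labs <- vapply(train_recs, `[[`, "", "label")
  out <- list()
  for (lab in unique(labs)) {
    class_recs <- train_recs[labs == lab]
    gcfg_lab <- gcfg
    gcfg_lab$seed <- derive_seed(seed, match(lab, unique(labs)))
    g <- train_dcgan(class_recs, gcfg_lab)
    imgs <- sample_dcgan(g, length(class_recs), derive_seed(seed, 50L))
    for (i in seq_along(imgs)) {
      prov <- list(scheme = "gan", parent_ids = character(0),
                   codec_id = g$id, seed = gcfg_lab$seed)
      out[[length(out) + 1L]] <- new_synthetic_record(
        imgs[[i]], class_recs[[i]], prov,
        sprintf("gan_%s_%d_%d", lab, gcfg_lab$seed, i))
    }
  }
  out
}

fold_metrics <- function(pred) {
  pos <- pred$positive_class
  truth01 <- as.integer(pred$truth == pos)
  scores <- pred$scores[, pos]
  cm <- confusion_metrics(pred$truth, scores, threshold = 0.5,
                          positive_class = pos)
  c(cm$metrics, auc = roc_auc(truth01, scores))
}

#' Run the experiment grid
#'
#' Per resample and arm: patient-grouped split, class balancing on the
#' training side, codec training on the training reals, arm-specific
#' expansion, leakage-guarded attachment, classifier training, and prediction
#' on the real test images. Any leakage aborts the run with a hard error.
#'
#' @param config an [experiment_config()].
#' @return list with `reports` (per arm: per-fold metrics, mean and SD,
#'   pooled AUC, fold predictions, positive class) and `manifest` (seeds and
#'   counts for every stage).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ch <- load_experiment_cohort(config)
  plans <- repeated_resampling_folds(ch, k = config$k,
                                     train_fraction = config$train_fraction,
                                     seed = derive_seed(config$master_seed, 1L))
  arm_folds <- lapply(config$arms, function(a) list())
  manifest <- list(master_seed = config$master_seed, k = config$k,
                   resamples = list())
  first_codec <- NULL
  first_train <- NULL
  for (i in seq_len(config$k)) {
    plan <- plans[[i]]
    split <- apply_split(ch, plan)
    train_real <- if (config$balance) {
      balance_classes(split$train, seed = derive_seed(config$master_seed, 200L + i))
    } else split$train
    vcfg <- config$vae
    vcfg$seed <- derive_seed(config$master_seed, 300L + i)
    codec <- train_vae(train_real, vcfg)
    if (i == 1L) { first_codec <- codec; first_train <- train_real }
    res_manifest <- list(resample = i, split_seed = plan$seed,
                         vae_seed = vcfg$seed,
                         n_train_real = length(train_real),
                         n_test = length(split$test), arms = list())
    # the leakage guard below operates on exactly the records used this fold
    fold_cohort <- cohort(c(train_real$records, split$test$records),
                          ch$label_scheme)
    for (an in names(config$arms)) {
      arm <- config$arms[[an]]
      syn <- arm_synthetics(arm, train_real$records, codec, config,
                            derive_seed(config$master_seed, 400L + i))
      sets <- attach_synthetic(plan, fold_cohort, syn)
      ccfg <- config$classifier
      ccfg$arch <- arm$arch
      ccfg$seed <- derive_seed(config$master_seed, 500L + i)
      model <- train_classifier(sets$train, ccfg)
      pred <- predict_scores(model, sets$test)
      arm_folds[[an]] <- c(arm_folds[[an]], list(pred))
      res_manifest$arms[[an]] <- list(n_synthetic = length(syn),
                                      n_train_total = length(sets$train),
                                      classifier_seed = ccfg$seed)
    }
    manifest$resamples[[i]] <- res_manifest
  }
  reports <- lapply(names(config$arms), function(an) {
    folds <- arm_folds[[an]]
    fm <- t(vapply(folds, fold_metrics, numeric(6)))
    pooled <- pooled_auc(lapply(folds, function(p) {
      list(truth = as.integer(p$truth == p$positive_class),
           scores = p$scores[, p$positive_class])
    }))
    list(arm = an, fold_metrics = as.data.frame(fm),
         mean = colMeans(fm, na.rm = TRUE),
         sd = apply(fm, 2, stats::sd, na.rm = TRUE),
         pooled_auc = pooled, folds = folds,
         positive_class = folds[[1]]$positive_class)
  })
  names(reports) <- names(config$arms)
  list(reports = reports, manifest = manifest,
       codec = first_codec, train_real = first_train)
}

#' Scaled-down direction-of-effect benchmark configuration
#'
#' The phantom benchmark used to check that the expansion schemes move
#' classification performance in the expected direction at desk scale:
#' 2 classes x 12 patients (two eyes each), 64 px images, a small VAE codec,
#' a compact conv-residual classifier, and k = 5 resampling splits. Gen 2
#' runs in `one_ratio_per_pair` mode so the synthetic pool stays proportional
#' to C(n,2).
#'
#' @param master_seed master seed for one benchmark replicate.
#' @param n_patients_per_class patients per class (default 12).
#' @param image_side image side (default 64).
#' @param k resamples (default 5).
#' @return an [experiment_config()].
#' @export
benchmark_config <- function(master_seed, n_patients_per_class = 12L,
                             image_side = 64L, k = 5L) {
  experiment_config(
    phantom = phantom_config(n_patients_per_class = n_patients_per_class,
                             image_side = image_side,
                             seed = derive_seed(master_seed, 9000L)),
    label_scheme = "binary",
    arms = list(
      base = list(expansion = NULL, arch = "conv_residual"),
      gen1 = list(expansion = expansion_config("gen1"), arch = "conv_residual"),
      gen2 = list(expansion = expansion_config("gen2",
                                               pair_mode = "one_ratio_per_pair"),
                  arch = "conv_residual")),
    k = k, train_fraction = 0.8,
    vae = vae_config(latent_dim = 48, image_side = image_side,
                     channels = c(8), kl_weight = 1e-4, epochs = 24,
                     batch_size = 8, learning_rate = 3e-3, weight_decay = 0,
                     seed = 1),
    gan = gan_config(gan_latent_dim = 64, output_side = image_side,
                     epochs = 6, batch_size = 8, seed = 1),
    classifier = classifier_config("conv_residual", image_side = image_side,
                                   channels = c(4, 8, 16), epochs = 16,
                                   learning_rate = 5e-3, batch_size = 8,
                                   augmentation = list(crop_scale = c(0.85, 1),
                                                       flip_prob = 0.5),
                                   seed = 1),
    master_seed = master_seed)
}

#' Run the direction-of-effect benchmark over several master seeds
#'
#' For each master seed: runs the base / Gen 1 / Gen 2 arms of
#' [benchmark_config()] and, on one additional grouped split, compares Gen 2
#' against a DCGAN baseline by latent-distribution overlap and feature
#' Frechet distance.
#'
#' @param master_seeds integer vector of master seeds.
#' @param ... passed to [benchmark_config()].
#' @return data.frame with one row per master seed: pooled AUC per arm,
#'   latent overlap for Gen 2 and DCGAN samples, and their Frechet distances.
#' @export
run_direction_benchmark <- function(master_seeds = 1:5, ...) {
  rows <- lapply(master_seeds, function(ms) {
    cfg <- benchmark_config(ms, ...)
    out <- run_experiment(cfg)
    # Fig-6 / Table-3 style comparison on the first resample's codec and
    # balanced training reals (no extra codec training)
    codec <- out$codec
    train_recs <- out$train_real$records
    real_imgs <- lapply(train_recs, `[[`, "image")
    extractor <- random_projection_extractor(image_side = dim(real_imgs[[1]])[1])
    real_feat <- embed_features(real_imgs, extractor)
    real_mu <- encode(codec, real_imgs)$mu
    syn <- list(
      gen1 = gen1_expand(train_recs, codec, expansion_config("gen1"),
                         derive_seed(ms, 600L)),
      gen2 = gen2_expand(train_recs, codec,
                         expansion_config("gen2",
                                          pair_mode = "one_ratio_per_pair"),
                         derive_seed(ms, 601L)))
    gcfg <- cfg$gan
    gcfg$seed <- derive_seed(ms, 602L)
    g <- train_dcgan(train_recs, gcfg)
    syn$gan <- sample_dcgan(g, length(train_recs), derive_seed(ms, 603L))
    stats <- lapply(syn, function(s) {
      recs <- inherits(s[[1]], "image_record")
      imgs <- if (recs) lapply(s, `[[`, "image") else s
      # synthetic latents: the constructed latent for the VAE schemes (where
      # each sample lives by construction), encoder embeddings for the GAN
      z_syn <- if (recs) {
        do.call(rbind, lapply(s, function(r) r$provenance$latent))
      } else {
        encode(codec, imgs)$mu
      }
      list(fid = frechet_distance(real_feat, embed_features(imgs, extractor),
                                  extractor_id = extractor$id)$fid,
           overlap = latent_overlap(real_mu, z_syn)$overlap)
    })
    data.frame(
      master_seed = ms,
      auc_base = out$reports$base$pooled_auc,
      auc_gen1 = out$reports$gen1$pooled_auc,
      auc_gen2 = out$reports$gen2$pooled_auc,
      overlap_gen2 = stats$gen2$overlap,
      overlap_gan = stats$gan$overlap,
      fid_gen1 = stats$gen1$fid,
      fid_gen2 = stats$gen2$fid,
      fid_gan = stats$gan$fid)
  })
  do.call(rbind, rows)
}

#' Compare expansion strategies by feature realism and latent overlap
#'
#' On a single grouped split: trains the codec on the training reals, builds
#' each requested scheme's synthetics, and reports the Frechet distance
#' between real-train and synthetic feature distributions together with the
#' latent-distribution overlap, sorted by distance (most realistic first).
#'
#' @param config an [experiment_config()].
#' @param schemes character vector of generation schemes (`"gen1"`, `"gen2"`,
#'   `"gan"`; `"copy"` duplicates real images and serves as an identity
#'   control).
#' @return list with `table` (data.frame: scheme, fid, overlap, n_synthetic,
#'   sorted by fid) and `details` (per scheme FID/overlap objects).
#' @export
compare_expansions <- function(config, schemes = c("gen1", "gen2", "gan")) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(schemes) < 1) stop_validation("need at least one scheme")
  ch <- load_experiment_cohort(config)
  plan <- grouped_split(ch, config$train_fraction,
                        seed = derive_seed(config$master_seed, 1L))
  split <- apply_split(ch, plan)
  train_real <- if (config$balance) {
    balance_classes(split$train, seed = derive_seed(config$master_seed, 2L))
  } else split$train
  vcfg <- config$vae
  vcfg$seed <- derive_seed(config$master_seed, 3L)
  codec <- train_vae(train_real, vcfg)
  real_imgs <- lapply(train_real$records, `[[`, "image")
  extractor <- random_projection_extractor(image_side = dim(real_imgs[[1]])[1])
  real_feat <- embed_features(real_imgs, extractor)
  real_mu <- encode(codec, real_imgs)$mu
  rows <- list(); details <- list()
  for (sc in schemes) {
    syn <- if (sc == "copy") {
      lapply(seq_along(train_real$records), function(i) {
        r <- train_real$records[[i]]
        new_synthetic_record(r$image, r,
                             list(scheme = "copy", parent_ids = r$record_id,
                                  codec_id = "identity",
                                  seed = config$master_seed),
                             paste0(r$record_id, "_copy"))
      })
    } else {
      arm_synthetics(list(expansion = expansion_config(sc)),
                     train_real$records, codec, config,
                     derive_seed(config$master_seed, 4L + match(sc, schemes)))
    }
    if (length(syn) == 0) {
      warning(sprintf("scheme '%s' produced no synthetics; omitted", sc))
      next
    }
    syn_imgs <- lapply(syn, `[[`, "image")
    fid <- frechet_distance(real_feat, embed_features(syn_imgs, extractor),
                            extractor_id = extractor$id)
    ov <- latent_overlap(real_mu, encode(codec, syn_imgs)$mu)
    rows[[length(rows) + 1L]] <- data.frame(scheme = sc, fid = fid$fid,
                                            overlap = ov$overlap,
                                            n_synthetic = length(syn))
    details[[sc]] <- list(fid = fid, overlap = ov)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$fid), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, details = details, codec = codec)
}
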