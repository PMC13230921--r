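# Image classifiers under the training protocol: a compact vision-transformer
# and a compact convolutional-residual network, trained from scratch with
# AdamW, a linear learning-rate decay and crop/flip augmentation. Both
# architectures satisfy identical contracts, so architecture comparisons are a
# configuration change only.

#' Classifier configuration
#'
#' Defaults follow the training protocol (30 epochs, AdamW, learning rate
#' 5e-5 with linear decay, random resized crop + horizontal flip); batch size
#' and crop-scale bounds are package conventions since the protocol leaves
#' them open.
#'
#' @param arch `"transformer"` (patch embedding + self-attention blocks) or
#'   `"conv_residual"` (strided convolutions + identity-skip blocks).
#' @param image_side input side length.
#' @param patch_size transformer patch side; must divide `image_side`.
#' @param embed_dim,n_blocks,n_heads transformer width, depth, heads.
#' @param channels conv-residual stage widths (one strided conv + one residual
#'   block per stage).
#' @param epochs,learning_rate,weight_decay,batch_size AdamW settings.
#' @param augmentation list with `crop_scale = c(lo, hi)` (area fraction of
#'   the random resized crop) and `flip_prob`.
#' @param seed integer seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(arch = "conv_residual", image_side = 64L,
                              patch_size = 8L, embed_dim = 32L, n_blocks = 4L,
                              n_heads = 2L, channels = c(8L, 16L, 32L),
                              epochs = 30L, learning_rate = 5e-5,
                              weight_decay = 0.01, batch_size = 16L,
                              augmentation = list(crop_scale = c(0.7, 1.0),
                                                  flip_prob = 0.5),
                              seed = 1L) {
  if (!arch %in% c("transformer", "conv_residual")) {
    stop_validation("unknown architecture '%s'", arch)
  }
  if (epochs < 0) stop_validation("epochs must be >= 0")
  if (arch == "transformer" && image_side %% patch_size != 0) {
    stop_validation("patch_size must divide image_side")
  }
  structure(list(arch = arch, image_side = as.integer(image_side),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 channels = as.integer(channels), epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), augmentation = augmentation,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

build_classifier_net <- function(config, n_classes) {
  if (config$arch == "transformer") {
    p <- config$patch_size
    t <- (config$image_side %/% p)^2
    d <- config$embed_dim
    net <- list(nn_patchify(p))
    # patch embedding: dense layer applied tokenwise
    net <- c(net, list(nn_layer("tokens_linear",
                                inner = nn_linear(p * p * 3L, d))))
    net <- c(net, list(nn_posemb(t, d)))
    for (i in seq_len(config$n_blocks)) {
      net <- c(net, list(nn_tblock(d, config$n_heads)))
    }
    c(net, list(nn_layernorm(d), nn_meanpool_tokens(), nn_linear(d, n_classes)))
  } else {
    ch <- config$channels
    net <- list()
    prev <- 3L
    for (c_out in ch) {
      net <- c(net, list(nn_conv(prev, c_out, stride = 2), nn_act("relu"),
                         nn_resblock(c_out)))
      prev <- c_out
    }
    c(net, list(nn_gap(), nn_linear(prev, n_classes)))
  }
}

#' Seeded training-time image augmentation
#'
#' A randomized resized crop (area fraction drawn from
#' `config$augmentation$crop_scale`, aspect jitter in 3/4..4/3, bilinear
#' resize back to the configured side) followed by a randomized horizontal
#' flip. Applied only at training time; inference never augments.
#'
#' @param image `H x W x 3` array.
#' @param config a [classifier_config()].
#' @param seed integer seed.
#' @return augmented image of the configured side.
#' @export
augment_image <- function(image, config, seed) {
  side <- config$image_side
  aug <- config$augmentation
  with_seed(seed, {
    h <- dim(image)[1]; w <- dim(image)[2]
    scale <- stats::runif(1, aug$crop_scale[1], aug$crop_scale[2])
    aspect <- exp(stats::runif(1, log(3 / 4), log(4 / 3)))
    ch <- min(h, max(4L, round(h * sqrt(scale) * sqrt(aspect))))
    cw <- min(w, max(4L, round(w * sqrt(scale) / sqrt(aspect))))
    if (scale >= 1 && aug$crop_scale[1] >= 1) { ch <- h; cw <- w }
    top <- sample.int(h - ch + 1L, 1)
    left <- sample.int(w - cw + 1L, 1)
    img <- image[top:(top + ch - 1L), left:(left + cw - 1L), , drop = FALSE]
    img <- resize_image(img, side)
    if (stats::runif(1) < aug$flip_prob) img <- img[, side:1, , drop = FALSE]
    img
  })
}

rebuild_classifier <- function(cfg, extra) {
  config <- do.call(classifier_config, cfg[setdiff(names(cfg), "classes")])
  m <- new.env(parent = emptyenv())
  m$net <- build_classifier_net(config, length(extra$classes))
  m$config <- config
  m$classes <- unlist(extra$classes)
  m$trained <- FALSE
  class(m) <- "classifier_model"
  m
}

#' Train an image classifier
#'
#' Seeded cross-entropy training with AdamW, a linear learning-rate decay to
#' zero and crop/flip augmentation. Deterministic given
#' `(seed, config, data)`.
#'
#' @param train_records list of [image_record()]s (real and/or synthetic) or a
#'   [cohort()]; at least two classes must be present.
#' @param config a [classifier_config()].
#' @return a `classifier_model` (with `classes`, training `trace`, and the
#'   positive-class declaration used by [predict_scores()]).
#' @export
train_classifier <- function(train_records, config = classifier_config()) {
  recs <- if (inherits(train_records, "cohort")) train_records$records else train_records
  if (length(recs) < 2) stop_validation("need >= 2 training records")
  labels <- vapply(recs, `[[`, "", "label")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_validation("training requires >= 2 classes")
  y <- match(labels, classes)
  n <- length(recs)
  with_seed(config$seed, {
    m <- new.env(parent = emptyenv())
    m$net <- build_classifier_net(config, length(classes))
    m$config <- config
    m$classes <- classes
    m$extra <- list(classes = classes)
    class(m) <- "classifier_model"
    trace <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
    if (config$epochs > 0) {
      bs <- min(config$batch_size, n)
      nb <- ceiling(n / bs)
      opt <- adamw_new(nn_params(list(m$net)), lr = config$learning_rate,
                       weight_decay = config$weight_decay,
                       total_steps = config$epochs * nb)
      step <- 0L
      for (ep in seq_len(config$epochs)) {
        ord <- sample(n)
        ep_loss <- 0; ep_acc <- 0
        for (b in seq_len(nb)) {
          step <- step + 1L
          idx <- ord[((b - 1) * bs + 1):min(b * bs, n)]
          xb <- stack_images(lapply(seq_along(idx), function(k) {
            augment_image(recs[[idx[k]]]$image, config,
                          derive_seed(config$seed, step * 1000L + k))
          }))
          res <- softmax_xent(nn_forward(m$net, xb), y[idx])
          if (!is.finite(res$loss)) stop_training("non-finite classifier loss at epoch %d", ep)
          nn_zero_grads(list(m$net))
          nn_backward(m$net, res$dlogits)
          adamw_step(opt)
          ep_loss <- ep_loss + res$loss / nb
          ep_acc <- ep_acc + mean(max.col(res$probs) == y[idx]) / nb
        }
        trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss, accuracy = ep_acc))
      }
      m$trained <- TRUE
    } else {
      m$trained <- FALSE
    }
    m$trace <- trace
    m
  })
}

#' Predict class scores for records
#'
#' Deterministic forward pass without augmentation. Softmax scores sum to one
#' per row. The positive class for binary reporting is `x_linked` when
#' present, otherwise the last class level; it is declared in the result.
#'
#' @param model a trained `classifier_model`.
#' @param records list of [image_record()]s or a [cohort()].
#' @return object of class `prediction_set` with `record_ids`, `truth`,
#'   `scores` (matrix with class columns) and `positive_class`.
#' @export
predict_scores <- function(model, records) {
  stopifnot(inherits(model, "classifier_model"))
  if (!model$trained) stop_state("classifier is untrained")
  recs <- if (inherits(records, "cohort")) records$records else records
  side <- model$config$image_side
  for (r in recs) {
    if (dim(r$image)[1] != side) {
      stop_validation("record %s has side %d, model expects %d",
                      r$record_id, dim(r$image)[1], side)
    }
  }
  xb <- stack_images(lapply(recs, `[[`, "image"))
  logits <- nn_forward(model$net, xb)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  colnames(probs) <- model$classes
  pos <- if ("x_linked" %in% model$classes) "x_linked"
         else model$classes[length(model$classes)]
  structure(list(record_ids = vapply(recs, `[[`, "", "record_id"),
                 truth = vapply(recs, `[[`, "", "label"),
                 scores = probs, positive_class = pos),
            class = "prediction_set")
}
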