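# DCGAN baseline generator: standard adversarial training with binary
# cross-entropy and alternating generator/discriminator updates.

#' DCGAN configuration
#'
#' @param gan_latent_dim generator input dimension (paper-parity 100).
#' @param output_side output image side; must reduce to a 4-7 px base by
#'   repeated halving (64 and 224 both qualify).
#' @param epochs,batch_size,learning_rate,seed training settings.
#' @return object of class `gan_config`.
#' @export
gan_config <- function(gan_latent_dim = 100L, output_side = 64L,
                       epochs = 20L, batch_size = 16L, learning_rate = 2e-4,
                       seed = 1L) {
  if (gan_latent_dim < 1) stop_validation("gan_latent_dim must be >= 1")
  nup <- 0L; base <- as.integer(output_side)
  while (base %% 2L == 0L && base / 2L >= 4L) { base <- base %/% 2L; nup <- nup + 1L }
  if (base > 7L) stop_validation("output_side %d cannot be built from a 4-7 px base", output_side)
  structure(list(gan_latent_dim = as.integer(gan_latent_dim),
                 output_side = as.integer(output_side), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 seed = as.integer(seed), n_up = nup, base_side = base),
            class = "gan_config")
}

build_dcgan <- function(config) {
  nup <- config$n_up; base <- config$base_side
  widths <- pmin(32L, 4L * 2L^((nup - 1):0))  # halve channel width per upsample
  gen <- list(nn_linear(config$gan_latent_dim, base * base * widths[1]),
              nn_act("relu"), nn_reshape(base, base, widths[1]))
  prev <- widths[1]
  for (i in seq_len(nup)) {
    w <- if (i == nup) 3L else widths[i + 1]
    act <- if (i == nup) nn_act("sigmoid") else nn_act("relu")
    gen <- c(gen, list(nn_upsample2(), nn_conv(prev, w, stride = 1), act))
    prev <- w
  }
  disc <- list(nn_conv(3, 8, stride = 2), nn_act("lrelu"),
               nn_conv(8, 16, stride = 2), nn_act("lrelu"),
               nn_conv(16, 32, stride = 2), nn_act("lrelu"),
               nn_gap(), nn_linear(32, 1))
  m <- new.env(parent = emptyenv())
  m$gen <- gen; m$disc <- disc; m$config <- config; m$trained <- FALSE
  class(m) <- "dcgan_model"
  m
}

#' Train the DCGAN baseline
#'
#' Alternating discriminator/generator updates with binary cross-entropy (the
#' generator uses the non-saturating objective). Training aborts with a
#' training error naming the epoch if a loss becomes non-finite.
#'
#' @param x a [cohort()] or list of real [image_record()]s (>= 2).
#' @param config a [gan_config()].
#' @return a `dcgan_model` with a per-epoch `trace` (generator and
#'   discriminator losses) attached.
#' @export
train_dcgan <- function(x, config = gan_config()) {
  recs <- records_only_real(x)
  if (length(recs) < 2) stop_validation("need >= 2 real training images")
  imgs <- stack_images(lapply(recs, function(r) {
    if (dim(r$image)[1] != config$output_side) {
      resize_image(r$image, config$output_side)
    } else r$image
  }))
  n <- dim(imgs)[1]
  zd <- config$gan_latent_dim
  with_seed(config$seed, {
    model <- build_dcgan(config)
    bs <- min(config$batch_size, n)
    nb <- ceiling(n / bs)
    total_steps <- max(1L, config$epochs * nb)
    opt_g <- adamw_new(nn_params(list(model$gen)), lr = config$learning_rate,
                       weight_decay = 0, total_steps = total_steps, beta1 = 0.5)
    opt_d <- adamw_new(nn_params(list(model$disc)), lr = config$learning_rate,
                       weight_decay = 0, total_steps = total_steps, beta1 = 0.5)
    trace <- data.frame(epoch = integer(), g_loss = numeric(), d_loss = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_g <- 0; ep_d <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * bs + 1):min(b * bs, n)]
        xr <- imgs[idx, , , , drop = FALSE]
        m <- length(idx)
        z <- matrix(stats::rnorm(m * zd), m, zd)
        xf <- nn_forward(model$gen, z)

        # discriminator step (generator weights frozen)
        nn_zero_grads(list(model$disc))
        lr_real <- bce_logits(as.numeric(nn_forward(model$disc, xr)), 1)
        nn_backward(model$disc, matrix(lr_real$dlogits, m, 1))
        lr_fake <- bce_logits(as.numeric(nn_forward(model$disc, xf)), 0)
        nn_backward(model$disc, matrix(lr_fake$dlogits, m, 1))
        d_loss <- lr_real$loss + lr_fake$loss
        adamw_step(opt_d)

        # generator step (non-saturating loss through updated discriminator)
        nn_zero_grads(list(model$gen, model$disc))
        logits <- as.numeric(nn_forward(model$disc, xf))
        lg <- bce_logits(logits, 1)
        dxf <- nn_backward(model$disc, matrix(lg$dlogits, m, 1))
        nn_zero_grads(list(model$disc))  # discard disc grads from G pass
        nn_backward(model$gen, dxf)
        adamw_step(opt_g)

        if (!is.finite(d_loss) || !is.finite(lg$loss)) {
          stop_training("DCGAN diverged (non-finite loss) at epoch %d", ep)
        }
        ep_g <- ep_g + lg$loss / nb
        ep_d <- ep_d + d_loss / nb
      }
      trace <- rbind(trace, data.frame(epoch = ep, g_loss = ep_g, d_loss = ep_d))
    }
    model$trained <- config$epochs > 0
    model$trace <- trace
    model$id <- sprintf("dcgan(zd=%d,side=%d,seed=%d)", zd, config$output_side,
                        config$seed)
    model
  })
}

#' Sample images from a trained DCGAN generator
#'
#' Draws `z ~ N(0, I)` of the configured latent dimension and decodes.
#'
#' @param model a `dcgan_model`.
#' @param n number of images.
#' @param seed integer seed for the latent draws.
#' @return list of `side x side x 3` images in `[0,1]`.
#' @export
sample_dcgan <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "dcgan_model"))
  zd <- model$config$gan_latent_dim
  z <- with_seed(seed, matrix(stats::rnorm(n * zd), n, zd))
  out <- clamp01(nn_forward(model$gen, z))
  lapply(seq_len(n), function(i) array(out[i, , , ], dim(out)[-1]))
}
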