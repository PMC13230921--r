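# Compact convolutional VAE: encoder, reparameterization, decoder, ELBO
# training. The VAE implements the codec contract (encode / decode /
# latent_dim) that the expansion schemes operate on, so pretrained backbones
# can be swapped in behind the same surface.

LOGVAR_CLAMP <- 20 # |log sigma^2| clamped for numeric safety

#' VAE configuration
#'
#' @param latent_dim latent dimension `d` (>= 2; default 32).
#' @param image_side input/output square side; must be divisible by
#'   `2^length(channels)`.
#' @param channels encoder channel widths per downsampling level (each level
#'   halves the side; the decoder mirrors them).
#' @param kl_weight weight `beta` of the KL term in the ELBO (default 1e-3).
#' @param epochs,batch_size,learning_rate,weight_decay AdamW training settings.
#' @param seed integer seed controlling initialization, batching and sampling.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 32L, image_side = 64L,
                       channels = c(8L, 16L, 32L), kl_weight = 1e-3,
                       epochs = 30L, batch_size = 16L, learning_rate = 1e-3,
                       weight_decay = 0.01, seed = 1L) {
  if (latent_dim < 2) stop_validation("latent_dim must be >= 2")
  if (kl_weight <= 0) stop_validation("kl_weight must be > 0")
  if (image_side %% (2^length(channels)) != 0) {
    stop_validation("image_side must be divisible by 2^length(channels)")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 image_side = as.integer(image_side),
                 channels = as.integer(channels), kl_weight = kl_weight,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "vae_config")
}

build_vae <- function(config) {
  ch <- config$channels
  side <- config$image_side
  fs <- side / 2^length(ch)           # spatial side at the bottleneck
  cl <- ch[length(ch)]
  enc <- list()
  prev <- 3L
  for (c_out in ch) {
    enc <- c(enc, list(nn_conv(prev, c_out, stride = 2), nn_act("relu")))
    prev <- c_out
  }
  enc <- c(enc, list(nn_flatten(), nn_linear(fs * fs * cl, 2L * config$latent_dim)))
  dec <- list(nn_linear(config$latent_dim, fs * fs * cl), nn_act("relu"),
              nn_reshape(fs, fs, cl))
  widths <- c(rev(ch)[-1], 3L)
  prev <- cl
  for (i in seq_along(widths)) {
    act <- if (i == length(widths)) nn_act("sigmoid") else nn_act("relu")
    dec <- c(dec, list(nn_upsample2(), nn_conv(prev, widths[i], stride = 1), act))
    prev <- widths[i]
  }
  m <- new.env(parent = emptyenv())
  m$enc <- enc; m$dec <- dec; m$config <- config; m$trained <- FALSE
  class(m) <- c("vae_model", "codec")
  m
}

#' Latent code of an image
#'
#' @param mu,logvar numeric vectors (or `n x d` matrices) of the posterior
#'   mean and log-variance.
#' @param z optional sampled latent (present only after [reparameterize()]).
#' @return object of class `latent_code`.
#' @export
latent_code <- function(mu, logvar, z = NULL) {
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop_numeric("latent code must be finite")
  }
  structure(list(mu = mu, logvar = logvar, z = z), class = "latent_code")
}

#' Encode / decode through a codec
#'
#' `encode()` maps an image (or list/batch of images) to its posterior
#' `latent_code`; it is deterministic given the codec weights. `decode()` maps
#' a latent vector (or `n x d` matrix) back to image space; outputs lie in
#' `[0,1]`. `latent_dim()` reports the codec's latent dimension.
#'
#' @param codec a trained codec (e.g. a VAE from [train_vae()] or a
#'   [linear_codec()]).
#' @param x image array `H x W x 3`, list of images, or `(N,H,W,3)` batch.
#' @param z numeric latent vector of length `latent_dim(codec)` or a matrix
#'   with that many columns.
#' @param ... passed to methods.
#' @return `encode()`: a `latent_code` (matrices when the input is a batch);
#'   `decode()`: an image array, or a list of images for matrix input.
#' @export
encode <- function(codec, x, ...) UseMethod("encode")

#' @rdname encode
#' @export
decode <- function(codec, z, ...) UseMethod("decode")

#' @rdname encode
#' @export
latent_dim <- function(codec) UseMethod("latent_dim")

as_batch <- function(x, side) {
  b <- if (is.list(x)) stack_images(lapply(x, function(r) {
    if (inherits(r, "image_record")) r$image else r
  })) else if (length(dim(x)) == 3) array(x, c(1, dim(x)))
  else x
  if (dim(b)[2] != side || dim(b)[3] != side) {
    stop_validation("image side %d does not match codec side %d", dim(b)[2], side)
  }
  b
}

#' @export
encode.vae_model <- function(codec, x, ...) {
  if (!codec$trained) stop_state("codec is untrained; call train_vae() first")
  single <- !is.list(x) && length(dim(x)) == 3
  b <- as_batch(x, codec$config$image_side)
  out <- nn_forward(codec$enc, b)
  d <- codec$config$latent_dim
  mu <- out[, 1:d, drop = FALSE]
  logvar <- pmin(pmax(out[, (d + 1):(2 * d), drop = FALSE], -LOGVAR_CLAMP), LOGVAR_CLAMP)
  if (single) latent_code(mu[1, ], logvar[1, ]) else latent_code(mu, logvar)
}

#' @export
decode.vae_model <- function(codec, z, ...) {
  if (!codec$trained) stop_state("codec is untrained; call train_vae() first")
  d <- codec$config$latent_dim
  single <- is.null(dim(z))
  zm <- if (single) matrix(z, 1) else as.matrix(z)
  if (ncol(zm) != d) stop_validation("latent vector length %d, expected %d", ncol(zm), d)
  out <- nn_forward(codec$dec, zm)
  out <- clamp01(out)
  if (single) array(out[1, , , ], dim(out)[-1])
  else lapply(seq_len(nrow(zm)), function(i) array(out[i, , , ], dim(out)[-1]))
}

#' @export
latent_dim.vae_model <- function(codec) codec$config$latent_dim

#' Reparameterization trick
#'
#' Draws `z = mu + exp(logvar / 2) * eps`, `eps ~ N(0, I)`, under a fixed
#' seed. `logvar` is clamped to `[-20, 20]`, so the zero-variance limit
#' returns `z` numerically equal to `mu`.
#'
#' @param code a [latent_code()].
#' @param seed integer seed for the Gaussian draw.
#' @return the `latent_code` with `z` filled in.
#' @export
reparameterize <- function(code, seed) {
  stopifnot(inherits(code, "latent_code"))
  lv <- pmin(pmax(code$logvar, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  eps <- with_seed(seed, stats::rnorm(length(code$mu)))
  if (!is.null(dim(code$mu))) eps <- array(eps, dim(code$mu))
  code$z <- code$mu + exp(lv / 2) * eps
  code
}

#' Evidence lower bound (ELBO) loss
#'
#' Reconstruction term: pixel-wise mean squared error. KL term (closed form
#' against a standard normal prior): `0.5 * sum(mu^2 + sigma^2 - 1 - logvar)`,
#' averaged over the batch when inputs are matrices.
#'
#' @param image,reconstruction image arrays (or batches) of matching shape.
#' @param code the [latent_code()] of `image`.
#' @param beta KL weight.
#' @return list with `recon`, `kl`, `total = recon + beta * kl`.
#' @export
elbo_loss <- function(image, reconstruction, code, beta = 1e-3) {
  if (!identical(dim(image), dim(reconstruction))) stop_validation("shape mismatch")
  if (any(!is.finite(image)) || any(!is.finite(reconstruction))) {
    stop_numeric("non-finite inputs to elbo_loss")
  }
  recon <- mean((image - reconstruction)^2)
  kl <- kl_closed_form(code$mu, code$logvar)
  list(recon = recon, kl = kl, total = recon + beta * kl)
}

# 0.5 * sum(mu^2 + exp(logvar) - 1 - logvar) per sample, mean over batch.
kl_closed_form <- function(mu, logvar) {
  per <- 0.5 * (mu^2 + exp(logvar) - 1 - logvar)
  if (is.null(dim(mu))) sum(per) else mean(rowSums(per))
}

records_only_real <- function(x) {
  recs <- if (inherits(x, "cohort")) x$records else x
  if (any(vapply(recs, `[[`, TRUE, "is_synthetic"))) {
    stop_validation("training requires real records only (is_synthetic = FALSE)")
  }
  recs
}

#' Train the convolutional VAE
#'
#' Seeded AdamW optimization of the ELBO with a linear learning-rate decay;
#' identical `(seed, config, data)` always yields identical weights. With
#' `epochs = 0` the returned model is at initialization with an empty trace
#' (and is not usable as a codec).
#'
#' @param x a [cohort()] or list of real [image_record()]s (>= 2 images).
#' @param config a [vae_config()].
#' @return a `vae_model` with a `trace` data.frame (per-epoch reconstruction
#'   loss, KL term and total loss) attached.
#' @export
train_vae <- function(x, config = vae_config()) {
  recs <- records_only_real(x)
  if (length(recs) < 2) stop_validation("need >= 2 training images")
  imgs <- stack_images(lapply(recs, `[[`, "image"))
  if (dim(imgs)[2] != config$image_side) {
    stop_validation("cohort image side %d does not match config side %d",
                    dim(imgs)[2], config$image_side)
  }
  n <- dim(imgs)[1]
  d <- config$latent_dim
  beta <- config$kl_weight
  with_seed(config$seed, {
    model <- build_vae(config)
    nets <- list(model$enc, model$dec)
    bs <- min(config$batch_size, n)
    nb <- ceiling(n / bs)
    trace <- data.frame(epoch = integer(), recon = numeric(), kl = numeric(),
                        total = numeric())
    if (config$epochs > 0) {
      opt <- adamw_new(nn_params(nets), lr = config$learning_rate,
                       weight_decay = config$weight_decay,
                       total_steps = config$epochs * nb)
      for (ep in seq_len(config$epochs)) {
        ord <- sample(n)
        ep_loss <- c(recon = 0, kl = 0, total = 0)
        for (b in seq_len(nb)) {
          idx <- ord[((b - 1) * bs + 1):min(b * bs, n)]
          xb <- imgs[idx, , , , drop = FALSE]
          m <- length(idx)
          enc_out <- nn_forward(model$enc, xb)
          mu <- enc_out[, 1:d, drop = FALSE]
          lv_raw <- enc_out[, (d + 1):(2 * d), drop = FALSE]
          lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
          eps <- matrix(stats::rnorm(m * d), m, d)
          z <- mu + exp(lv / 2) * eps
          xhat <- nn_forward(model$dec, z)
          recon <- mean((xhat - xb)^2)
          kl <- kl_closed_form(mu, lv)
          total <- recon + beta * kl
          if (!is.finite(total)) stop_training("non-finite VAE loss at epoch %d", ep)
          ep_loss <- ep_loss + c(recon, kl, total) / nb

          nn_zero_grads(nets)
          dxhat <- 2 * (xhat - xb) / length(xb)
          dz <- nn_backward(model$dec, dxhat)
          dmu <- dz + beta * mu / m
          dlv <- dz * eps * 0.5 * exp(lv / 2) + beta * 0.5 * (exp(lv) - 1) / m
          dlv <- dlv * (lv_raw > -LOGVAR_CLAMP & lv_raw < LOGVAR_CLAMP)
          nn_backward(model$enc, cbind(dmu, dlv))
          adamw_step(opt)
        }
        trace <- rbind(trace, data.frame(epoch = ep, recon = ep_loss[1],
                                         kl = ep_loss[2], total = ep_loss[3]))
      }
      model$trained <- TRUE
    }
    model$trace <- trace
    model$id <- sprintf("vae(d=%d,side=%d,seed=%d)", d, config$image_side,
                        config$seed)
    model
  })
}

#' Deterministic linear codec (random-projection baseline)
#'
#' A fixed random orthogonal projection of centred pixels serves as `mu`
#' (with constant small `logvar`); decoding is the transposed projection.
#' Useful as a fast stand-in codec in tests and count checks where a trained
#' VAE is irrelevant.
#'
#' @param image_side image side length.
#' @param latent_dim latent dimension.
#' @param seed projection seed.
#' @return object of class `linear_codec` implementing the codec contract.
#' @export
linear_codec <- function(image_side = 32L, latent_dim = 8L, seed = 1L) {
  npix <- image_side * image_side * 3
  P <- with_seed(seed, {
    m <- matrix(stats::rnorm(npix * latent_dim), npix, latent_dim)
    qr.Q(qr(m))
  })
  m <- new.env(parent = emptyenv())
  m$P <- P; m$image_side <- as.integer(image_side)
  m$latent_dim <- as.integer(latent_dim)
  m$trained <- TRUE
  m$id <- sprintf("linear_codec(d=%d,seed=%d)", latent_dim, seed)
  class(m) <- c("linear_codec", "codec")
  m
}

#' @export
encode.linear_codec <- function(codec, x, ...) {
  single <- !is.list(x) && length(dim(x)) == 3
  b <- as_batch(x, codec$image_side)
  xm <- matrix(b, dim(b)[1], prod(dim(b)[-1])) - 0.5
  mu <- xm %*% codec$P
  lv <- matrix(-6, nrow(mu), ncol(mu))
  if (single) latent_code(mu[1, ], lv[1, ]) else latent_code(mu, lv)
}

#' @export
decode.linear_codec <- function(codec, z, ...) {
  single <- is.null(dim(z))
  zm <- if (single) matrix(z, 1) else as.matrix(z)
  if (ncol(zm) != codec$latent_dim) {
    stop_validation("latent vector length %d, expected %d", ncol(zm), codec$latent_dim)
  }
  xm <- clamp01(zm %*% t(codec$P) + 0.5)
  s <- codec$image_side
  out <- array(xm, c(nrow(zm), s, s, 3))
  if (single) array(out[1, , , ], c(s, s, 3))
  else lapply(seq_len(nrow(zm)), function(i) array(out[i, , , ], c(s, s, 3)))
}

#' @export
latent_dim.linear_codec <- function(codec) codec$latent_dim

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding a version tag, the configuration
#' serialized as JSON, and the weight arrays.
#'
#' @param model a `vae_model`, `dcgan_model` or `classifier_model`.
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  type <- class(model)[1]
  payload <- list(
    version = "latentmix-ckpt-1",
    type = type,
    config_json = as.character(jsonlite::toJSON(unclass(model$config),
                                                auto_unbox = TRUE, digits = NA)),
    trained = model$trained,
    extra = model$extra %||% NULL,
    weights = switch(type,
      vae_model = nn_get_weights(list(model$enc, model$dec)),
      dcgan_model = nn_get_weights(list(model$gen, model$disc)),
      classifier_model = nn_get_weights(list(model$net)),
      stop_validation("cannot checkpoint object of class %s", type))
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  if (!identical(p$version, "latentmix-ckpt-1")) {
    stop_io("unrecognized checkpoint version in %s", path)
  }
  cfg <- jsonlite::fromJSON(p$config_json)
  model <- switch(p$type,
    vae_model = build_vae(do.call(vae_config, cfg)),
    dcgan_model = build_dcgan(do.call(gan_config, cfg)),
    classifier_model = rebuild_classifier(cfg, p$extra),
    stop_io("unknown checkpoint type %s", p$type))
  switch(p$type,
    vae_model = nn_set_weights(list(model$enc, model$dec), p$weights),
    dcgan_model = nn_set_weights(list(model$gen, model$disc), p$weights),
    classifier_model = nn_set_weights(list(model$net), p$weights))
  model$trained <- p$trained
  model
}
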