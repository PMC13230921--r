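# VAE codec: closed-form KL, reparameterization, encode/decode contracts and
# training behaviour on phantom cohorts.

# One moderately trained VAE shared by the fidelity tests below.
vae_fixture <- local({
  cfg <- phantom_config(n_patients_per_class = 13, image_side = 32, seed = 2)
  ch <- normalize_laterality(generate_phantom_cohort(cfg))
  vcfg <- vae_config(latent_dim = 64, image_side = 32, channels = c(8, 16),
                     kl_weight = 1e-4, epochs = 100, batch_size = 4,
                     learning_rate = 5e-3, weight_decay = 0, seed = 3)
  list(cohort = ch, model = train_vae(ch, vcfg))
})

test_that("KL closed form matches hand values and is non-negative with equality iff prior", {
  expect_equal(elbo_loss(array(0, c(2, 2, 3)), array(0, c(2, 2, 3)),
                         latent_code(rep(0, 4), rep(0, 4)))$kl, 0)
  # d = 1, mu = 1, logvar = 0 -> 0.5 * (1 + 1 - 1 - 0) = 0.5
  expect_equal(elbo_loss(array(0, c(2, 2, 3)), array(0, c(2, 2, 3)),
                         latent_code(1, 0))$kl, 0.5)
  set.seed(20)
  for (i in 1:25) {
    mu <- rnorm(6); lv <- rnorm(6)
    kl <- elbo_loss(array(0, c(1, 1, 3)), array(0, c(1, 1, 3)),
                    latent_code(mu, lv))$kl
    expect_gte(kl, 0)
    if (any(mu != 0) || any(lv != 0)) expect_gt(kl, 0)
  }
  # total combines the pieces
  x <- array(runif(12), c(2, 2, 3)); y <- array(runif(12), c(2, 2, 3))
  l <- elbo_loss(x, y, latent_code(rnorm(3), rnorm(3)), beta = 0.5)
  expect_equal(l$total, l$recon + 0.5 * l$kl)
  expect_equal(l$recon, mean((x - y)^2))
  xb <- x; xb[1] <- NaN
  expect_error(elbo_loss(xb, y, latent_code(0, 0)), class = "latentmix_numeric_error")
})

test_that("KL closed form agrees with a Monte-Carlo estimate within 3 SE", {
  set.seed(21)
  for (i in 1:5) {
    mu <- rnorm(3); lv <- runif(3, -1.5, 1.5)
    n <- 2e4
    z <- matrix(rnorm(3 * n, mean = rep(mu, each = n),
                      sd = rep(exp(lv / 2), each = n)), n, 3)
    logq <- sapply(1:3, function(j) dnorm(z[, j], mu[j], exp(lv[j] / 2), log = TRUE))
    logp <- sapply(1:3, function(j) dnorm(z[, j], 0, 1, log = TRUE))
    samples <- rowSums(logq - logp)
    se <- sd(samples) / sqrt(n)
    kl <- elbo_loss(array(0, c(1, 1, 3)), array(0, c(1, 1, 3)),
                    latent_code(mu, lv))$kl
    expect_lt(abs(kl - mean(samples)), 3 * se + 1e-9)
  }
})

test_that("reparameterization is seeded, unbiased and collapses to mu at zero variance", {
  code <- latent_code(c(1, -2, 0.5), c(0.3, -0.4, 0))
  z1 <- reparameterize(code, 5)$z
  z2 <- reparameterize(code, 5)$z
  expect_identical(z1, z2)
  expect_false(identical(z1, reparameterize(code, 6)$z))

  # zero-variance limit: logvar below the clamp returns z ~= mu
  frozen <- latent_code(c(1, -2, 0.5), rep(-1e9, 3))
  expect_lt(max(abs(reparameterize(frozen, 1)$z - frozen$mu)), 1e-4)

  # Monte-Carlo mean of z within 3 SE of mu, componentwise
  mu <- c(0.8, -1.2, 0.1, 2)
  lv <- c(0.5, 0, -0.5, 0.2)
  code <- latent_code(mu, lv)
  n <- 1e4
  zs <- t(vapply(seq_len(n), function(s) reparameterize(code, s)$z, numeric(4)))
  se <- exp(lv / 2) / sqrt(n)
  expect_true(all(abs(colMeans(zs) - mu) < 3 * se))
})

test_that("encode obeys shape and determinism contracts and requires training", {
  m <- vae_fixture$model
  img <- vae_fixture$cohort$records[[1]]$image
  code <- encode(m, img)
  expect_s3_class(code, "latent_code")
  expect_length(code$mu, 64)
  expect_length(code$logvar, 64)
  expect_null(code$z)
  expect_identical(code$mu, encode(m, img)$mu)

  untrained <- train_vae(vae_fixture$cohort,
                         vae_config(latent_dim = 8, image_side = 32,
                                    channels = c(4, 8), epochs = 0, seed = 1))
  expect_equal(nrow(untrained$trace), 0)
  expect_error(encode(untrained, img), class = "latentmix_state_error")
  expect_error(encode(m, toy_image(16)), class = "latentmix_validation_error")
})

test_that("same-patient renders land closer in latent space than different patients", {
  m <- vae_fixture$model
  ch <- vae_fixture$cohort
  md <- cohort_metadata(ch)
  mus <- t(vapply(ch$records, function(r) encode(m, r$image)$mu, numeric(64)))
  set.seed(30)
  pats <- sample(unique(md$patient_id), 20)
  same <- numeric(0); diff <- numeric(0)
  for (p in pats) {
    idx <- which(md$patient_id == p)
    k <- sample(which(md$patient_id != p), 1)
    same <- c(same, sqrt(sum((mus[idx[1], ] - mus[idx[2], ])^2)))
    diff <- c(diff, sqrt(sum((mus[idx[1], ] - mus[k, ])^2)))
  }
  expect_lt(mean(same), mean(diff))
})

test_that("decode stays in [0,1], is deterministic, and reconstructions are image-specific", {
  m <- vae_fixture$model
  set.seed(31)
  for (i in 1:10) {
    z <- rnorm(64, sd = 2)
    img <- decode(m, z)
    expect_equal(dim(img), c(32, 32, 3))
    expect_true(min(img) >= 0 && max(img) <= 1)
  }
  z <- rnorm(64)
  expect_identical(decode(m, z), decode(m, z))
  expect_error(decode(m, rnorm(10)), class = "latentmix_validation_error")

  # decode(encode(x)$mu) closer to x than to an unrelated image for >= 90% of 50
  imgs <- lapply(vae_fixture$cohort$records, `[[`, "image")
  set.seed(1)
  hits <- 0
  for (i in 1:50) {
    rec <- decode(m, encode(m, imgs[[i]])$mu)
    j <- sample(setdiff(seq_along(imgs), i), 1)
    hits <- hits + (mean((rec - imgs[[i]])^2) < mean((rec - imgs[[j]])^2))
  }
  expect_gte(hits, 45)
})

test_that("gen2 synthetics decoded through the trained codec retain the class signal", {
  m <- vae_fixture$model
  ch <- vae_fixture$cohort
  syn <- gen2_expand(ch$records, m,
                     expansion_config("gen2", pair_mode = "one_ratio_per_pair"),
                     seed = 9)
  st <- vapply(syn, function(s) peripheral_darkness(s$image), 0)
  labs <- vapply(syn, `[[`, "", "label")
  auc_syn <- roc_auc(as.integer(labs == "x_linked"), st)
  # mixing same-class latents averages patient nuisance, so the synthetic
  # classes separate at least as well as a moderate real-image baseline
  expect_gt(auc_syn, 0.65)
})

test_that("VAE training reduces the loss, is reproducible, and validates its inputs", {
  small <- cohort(vae_fixture$cohort$records[1:20], "binary")
  vcfg <- vae_config(latent_dim = 8, image_side = 32, channels = c(4, 8),
                     epochs = 15, batch_size = 8, seed = 7)
  m1 <- train_vae(small, vcfg)
  expect_equal(nrow(m1$trace), 15)
  expect_lt(m1$trace$total[15], m1$trace$total[1])
  expect_true(all(is.finite(m1$trace$total)))
  m2 <- train_vae(small, vcfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(encode(m1, small$records[[1]]$image)$mu,
                   encode(m2, small$records[[1]]$image)$mu)

  expect_error(train_vae(cohort(list()), vcfg), class = "latentmix_validation_error")
  synth <- small$records[[1]]
  synth$is_synthetic <- TRUE
  synth$provenance <- list(scheme = "gen1")
  expect_error(train_vae(cohort(c(small$records[1:3], list(synth))), vcfg),
               class = "latentmix_validation_error")
  expect_error(vae_config(latent_dim = 1), class = "latentmix_validation_error")
})

test_that("checkpoints round-trip the codec bit-exactly", {
  m <- vae_fixture$model
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  img <- vae_fixture$cohort$records[[3]]$image
  expect_identical(encode(m, img)$mu, encode(m2, img)$mu)
  expect_identical(decode(m, encode(m, img)$mu), decode(m2, encode(m2, img)$mu))
})

test_that("the linear codec satisfies the codec contract", {
  lc <- linear_codec(image_side = 32, latent_dim = 8, seed = 4)
  expect_equal(latent_dim(lc), 8)
  img <- toy_image(32)
  code <- encode(lc, img)
  expect_length(code$mu, 8)
  out <- decode(lc, code$mu)
  expect_equal(dim(out), c(32, 32, 3))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_identical(encode(lc, img)$mu, encode(lc, img)$mu)
})
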