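# Evaluation metrics against independent oracles: brute-force Mann-Whitney
# pair counting for AUC, analytic Gaussian closed forms for the Frechet
# distance, and a direct histogram-min computation for latent overlap.

# Brute-force AUC oracle: count positive-negative pairs, ties worth 1/2.
brute_force_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

test_that("confusion metrics match hand-counted tables and report undefined ratios as NA", {
  # perfect predictions
  cm <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(cm$metrics[c("accuracy", "recall", "specificity")]),
               c(1, 1, 1))

  # labels (1,1,0,0), predictions (1,0,0,0): TP=1 FN=1 TN=2 FP=0
  cm2 <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.1, 0.2, 0.3))
  expect_equal(unname(cm2$metrics["recall"]), 0.5)
  expect_equal(unname(cm2$metrics["specificity"]), 1.0)
  expect_equal(unname(cm2$metrics["precision"]), 1.0)
  expect_equal(unname(cm2$metrics["f1"]), 2 / 3)

  # all-negative predictions: precision undefined (NA), specificity 1
  cm3 <- confusion_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.3, 0.4))
  expect_true(is.na(cm3$metrics["precision"]))
  expect_equal(unname(cm3$metrics["specificity"]), 1.0)

  # character labels with declared positive class
  cm4 <- confusion_metrics(c("x_linked", "autosomal"), c(0.8, 0.2),
                           positive_class = "x_linked")
  expect_equal(unname(cm4$metrics["accuracy"]), 1.0)

  # multiclass argmax with one-vs-rest per-class metrics
  sc <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.6, 0.2))
  colnames(sc) <- c("a", "b", "c")
  cm5 <- confusion_metrics(c("a", "b", "c"), sc)
  expect_equal(unname(cm5$metrics["accuracy"]), 2 / 3)
  expect_equal(cm5$per_class$recall[cm5$per_class$class == "a"], 1.0)
  expect_equal(cm5$per_class$recall[cm5$per_class$class == "c"], 0.0)
})

test_that("roc_auc equals the Mann-Whitney pair count on trivial and random cases", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), class = "latentmix_validation_error")

  # 50 random small instances with ties, matched to 1e-12
  set.seed(100)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(truth, scores), brute_force_auc(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with the pROC reference implementation", {
  set.seed(110)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(truth, scores), ref, tolerance = 1e-12)
  }
})

test_that("roc_auc of negated scores complements to 1 for tie-free scores", {
  set.seed(101)
  for (i in 1:10) {
    truth <- c(0, 1, sample(0:1, 18, replace = TRUE))
    scores <- sample(seq_len(1000), 20) / 1000 # distinct
    expect_equal(roc_auc(truth, scores) + roc_auc(truth, -scores), 1)
  }
})

test_that("pooled_auc concatenates folds and is fold-order invariant", {
  set.seed(102)
  f1 <- list(truth = c(1, 0, 1), scores = c(0.9, 0.3, 0.6))
  expect_equal(pooled_auc(list(f1)), roc_auc(f1$truth, f1$scores))
  # duplicating a fold leaves the AUC unchanged
  expect_equal(pooled_auc(list(f1, f1)), roc_auc(f1$truth, f1$scores))

  folds <- lapply(1:5, function(i) {
    n <- 10
    list(truth = c(0, 1, sample(0:1, n - 2, replace = TRUE)),
         scores = round(runif(n), 2))
  })
  pooled <- pooled_auc(folds)
  expect_equal(pooled,
               brute_force_auc(unlist(lapply(folds, `[[`, "truth")),
                               unlist(lapply(folds, `[[`, "scores"))),
               tolerance = 1e-12)
  expect_equal(pooled, pooled_auc(rev(folds)))
  expect_equal(pooled, pooled_auc(folds[c(3, 1, 5, 2, 4)]))
})

test_that("frechet_gaussian reproduces analytic closed forms", {
  # identical distributions
  expect_lt(abs(frechet_gaussian(c(0, 0), diag(2), c(0, 0), diag(2))), 1e-10)
  # 1-D mean shift: N(0,1) vs N(1,1) -> 1
  expect_equal(frechet_gaussian(0, 1, 1, 1), 1, tolerance = 1e-6)
  # 1-D variance change: N(0,1) vs N(0,4) -> 1 + 4 - 2*2 = 1
  expect_equal(frechet_gaussian(0, 1, 0, 4), 1, tolerance = 1e-6)
  # symmetry
  set.seed(103)
  a <- crossprod(matrix(rnorm(9), 3)); b <- crossprod(matrix(rnorm(9), 3))
  m1 <- rnorm(3); m2 <- rnorm(3)
  expect_equal(frechet_gaussian(m1, a, m2, b), frechet_gaussian(m2, b, m1, a),
               tolerance = 1e-6)
  # quadratic scaling: features scaled by c -> distance scaled by c^2
  cc <- 2.5
  expect_equal(frechet_gaussian(cc * m1, cc^2 * a, cc * m2, cc^2 * b),
               cc^2 * frechet_gaussian(m1, a, m2, b), tolerance = 1e-6)
})

test_that("frechet_distance on samples: X vs X is 0 and results carry metadata", {
  set.seed(104)
  x <- matrix(rnorm(200 * 4), 200, 4)
  r <- frechet_distance(x, x)
  expect_s3_class(r, "fid_result")
  expect_lt(abs(r$fid), 1e-6)
  expect_equal(r$n_real, 200)
  expect_equal(r$dim, 4)
  y <- matrix(rnorm(200 * 4, mean = 3), 200, 4)
  expect_gt(frechet_distance(x, y)$fid, 1)
  expect_error(frechet_distance(x, matrix(rnorm(10 * 3), 10, 3)),
               class = "latentmix_validation_error")
  xb <- x; xb[1, 1] <- NaN
  expect_error(frechet_distance(xb, y), class = "latentmix_numeric_error")
})

test_that("feature extractor is deterministic and shape-checked", {
  set.seed(105)
  imgs <- lapply(1:3, function(i) toy_image(32))
  ex <- random_projection_extractor(image_side = 32)
  f1 <- embed_features(imgs, ex)
  f2 <- embed_features(imgs, ex)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(3, 32))
  # identical images give identical rows
  f3 <- embed_features(list(imgs[[1]], imgs[[1]]), ex)
  expect_equal(f3[1, ], f3[2, ])
  expect_error(embed_features(list(toy_image(16)), ex),
               class = "latentmix_validation_error")
})

test_that("latent_overlap matches a direct histogram-min oracle", {
  set.seed(106)
  z <- matrix(rnorm(300 * 2), 300, 2)
  expect_equal(latent_overlap(z, z)$overlap, 1.0)
  far <- sweep(z, 2, c(1e3, 1e3), "+")
  expect_equal(latent_overlap(z, far)$overlap, 0.0)

  # independent oracle: explicit projection + histogram min-sum
  zs <- matrix(rnorm(250 * 2, mean = 0.8), 250, 2)
  res <- latent_overlap(z, zs, bins = 32)
  ctr <- colMeans(z)
  ax <- prcomp(z, center = TRUE, scale. = FALSE)$rotation[, 1]
  pr <- as.numeric(sweep(z, 2, ctr) %*% ax)
  ps <- as.numeric(sweep(zs, 2, ctr) %*% ax)
  brk <- seq(min(c(pr, ps)), max(c(pr, ps)), length.out = 33)
  h1 <- hist(pr, breaks = brk, plot = FALSE)$counts / length(pr)
  h2 <- hist(ps, breaks = brk, plot = FALSE)$counts / length(ps)
  expect_equal(res$overlap, sum(pmin(h1, h2)), tolerance = 1e-10)

  expect_error(latent_overlap(matrix(1, 5, 2), zs),
               class = "latentmix_validation_error")
})

test_that("subgroup metrics restrict to age bins and flag degenerate bins", {
  # hand-built 6-record bin with one false positive
  pred <- structure(list(
    record_ids = sprintf("r%d", 1:8),
    truth = c(rep("autosomal", 3), rep("x_linked", 3), "autosomal", "x_linked"),
    scores = {
      s <- rbind(
        c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7),  # one autosomal misread as x_linked
        c(0.2, 0.8), c(0.1, 0.9), c(0.3, 0.7),
        c(0.9, 0.1), c(0.2, 0.8))
      colnames(s) <- c("autosomal", "x_linked"); s
    },
    positive_class = "x_linked"), class = "prediction_set")
  md <- data.frame(record_id = sprintf("r%d", 1:8),
                   age_years = c(15, 15, 15, 15, 15, 15, 55, 55))
  tab <- subgroup_metrics(pred, md, age_bins = list(c(10, 20), c(50, 60)))
  b1 <- tab[tab$bin == "10-20", ]
  # in the 10-20 bin: x_linked TP=3 FP=1 -> precision 3/4; autosomal 2/2 -> 1
  expect_equal(b1$precision[b1$class == "x_linked"], 0.75)
  expect_equal(b1$precision[b1$class == "autosomal"], 1.0)
  # F1 for autosomal: precision 1, recall 2/3 -> 0.8
  expect_equal(b1$f1[b1$class == "autosomal"], 0.8)
  expect_false(any(b1$single_class))

  # a bin holding a single class is flagged, not silently perfect
  md2 <- data.frame(record_id = sprintf("r%d", 1:8),
                    age_years = c(15, 15, 15, 55, 55, 55, 30, 30))
  tab2 <- subgroup_metrics(pred, md2, age_bins = list(c(10, 20)))
  expect_true(all(tab2$single_class))

  expect_warning(subgroup_metrics(pred, md, age_bins = list(c(80, 90))),
                 "empty")
})
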