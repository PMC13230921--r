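# Evaluation protocol: confusion-derived metrics, per-fold and pooled ROC AUC,
# Frechet distance between feature distributions, latent-distribution overlap,
# and age-binned subgroup metrics.

#' Confusion matrix and derived classification metrics
#'
#' Binary mode (numeric `scores` vector): predictions are `score >= threshold`
#' for the declared positive class; recall is the true-positive rate on that
#' class and specificity the true-negative rate on the other. Multiclass mode
#' (`scores` matrix with class columns): argmax predictions with one-vs-rest
#' per-class metrics. Ratios with a zero denominator are reported as `NA`
#' (missing), never silently as 0.
#'
#' @param truth vector of true labels (character/factor, or 0/1 in binary mode
#'   when `positive_class` is omitted).
#' @param scores numeric vector of positive-class scores, or an `n x K` matrix
#'   with `colnames` naming the classes.
#' @param threshold binary decision threshold in `[0,1]` (default 0.5).
#' @param positive_class label counted as positive in binary mode.
#' @return list with `confusion` (table), `metrics` (named numeric vector with
#'   accuracy, recall, specificity, precision, f1) and, in multiclass mode,
#'   `per_class` (data.frame of one-vs-rest metrics).
#' @export
confusion_metrics <- function(truth, scores, threshold = 0.5,
                              positive_class = NULL) {
  if (is.matrix(scores)) {
    if (length(truth) != nrow(scores)) stop_validation("length mismatch")
    classes <- colnames(scores)
    pred <- classes[max.col(scores, ties.method = "first")]
    truth <- as.character(truth)
    conf <- table(factor(truth, classes), factor(pred, classes),
                  dnn = c("truth", "pred"))
    acc <- sum(diag(conf)) / sum(conf)
    per <- do.call(rbind, lapply(classes, function(k) {
      tp <- sum(truth == k & pred == k); fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k); tn <- sum(truth != k & pred != k)
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else NA_real_
      data.frame(class = k, recall = rec, specificity = spec,
                 precision = prec, f1 = f1)
    }))
    metrics <- c(accuracy = acc,
                 recall = mean(per$recall, na.rm = TRUE),
                 specificity = mean(per$specificity, na.rm = TRUE),
                 precision = mean(per$precision, na.rm = TRUE),
                 f1 = mean(per$f1, na.rm = TRUE))
    return(list(confusion = conf, metrics = metrics, per_class = per))
  }
  if (length(truth) != length(scores)) stop_validation("length mismatch")
  if (threshold < 0 || threshold > 1) stop_validation("threshold must be in [0,1]")
  pos <- if (is.null(positive_class)) as.integer(truth) == 1L
         else as.character(truth) == positive_class
  pred <- scores >= threshold
  tp <- sum(pos & pred); fp <- sum(!pos & pred)
  fn <- sum(pos & !pred); tn <- sum(!pos & !pred)
  conf <- as.table(matrix(c(tp, fp, fn, tn), 2, 2,
                          dimnames = list(truth = c("pos", "neg"),
                                          pred = c("pos", "neg"))))
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(confusion = conf,
       metrics = c(accuracy = (tp + tn) / length(truth), recall = rec,
                   specificity = spec, precision = prec, f1 = f1))
}

#' ROC AUC via the Mann-Whitney statistic (ties counted one half)
#'
#' @param truth 0/1 vector (1 = positive) or logical.
#' @param scores numeric scores; higher means more positive.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(as.logical(as.integer(truth)))
  if (length(truth) != length(scores)) stop_validation("length mismatch")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop_validation("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled AUC over cross-validation folds
#'
#' Out-of-fold labels and scores are concatenated across all folds and a single
#' ROC AUC is computed on the pooled vectors.
#'
#' @param folds list of `list(truth = , scores = )` pairs on one score scale.
#' @return pooled AUC.
#' @export
pooled_auc <- function(folds) {
  if (length(folds) < 1) stop_validation("need at least one fold")
  roc_auc(unlist(lapply(folds, `[[`, "truth")),
          unlist(lapply(folds, `[[`, "scores")))
}

#' Fixed-seed random convolutional feature extractor
#'
#' Default extractor for Frechet-distance computations: two strided random
#' convolutions with ReLU, followed by per-channel mean and standard-deviation
#' pooling. Weights are drawn once from the given seed, so features are fully
#' reproducible. Absolute distances from this extractor are not comparable to
#' values computed with pretrained ImageNet features; only within-run rankings
#' are meaningful. Any object with fields `transform`, `id`, `dim`,
#' `image_side` satisfies the extractor contract, so a pretrained backbone can
#' be plugged in.
#'
#' @param image_side expected input side.
#' @param seed weight seed (fixed default so the extractor is a constant).
#' @return object of class `feature_extractor`.
#' @export
random_projection_extractor <- function(image_side = 64, seed = 760613L) {
  layers <- with_seed(seed, list(
    nn_conv(3, 8, stride = 2), nn_act("relu"),
    nn_conv(8, 16, stride = 2), nn_act("relu")
  ))
  transform <- function(images) {
    x <- if (is.list(images)) stack_images(images) else images
    if (length(dim(x)) == 3) x <- array(x, c(1, dim(x)))
    if (dim(x)[2] != image_side || dim(x)[3] != image_side) {
      stop_validation("extractor expects side %d, got %d", image_side, dim(x)[2])
    }
    h <- nn_forward(layers, x)
    n <- dim(h)[1]; ck <- dim(h)[4]
    feat <- matrix(0, n, 2 * ck)
    for (i in seq_len(n)) {
      m <- apply(h[i, , , , drop = FALSE], 4, mean)
      s <- apply(h[i, , , , drop = FALSE], 4, stats::sd)
      feat[i, ] <- c(m, s)
    }
    feat
  }
  structure(list(transform = transform,
                 id = sprintf("random_conv_projection(seed=%d)", seed),
                 dim = 32L, image_side = as.integer(image_side)),
            class = "feature_extractor")
}

#' Embed images as feature vectors
#'
#' @param images list of `H x W x 3` arrays (or an `(N,H,W,3)` batch array).
#' @param extractor a `feature_extractor` (default: the fixed-seed random
#'   convolutional projection).
#' @return `n x p` feature matrix.
#' @export
embed_features <- function(images, extractor = NULL) {
  if (is.null(extractor)) {
    side <- if (is.list(images)) dim(images[[1]])[1] else dim(images)[2]
    extractor <- random_projection_extractor(image_side = side)
  }
  extractor$transform(images)
}

#' Frechet distance between two Gaussians
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))`, computed through the
#' symmetric form `Tr sqrt(S1^(1/2) S2 S1^(1/2))` with an eigenvalue floor at
#' zero.
#'
#' @param mu1,mu2 mean vectors.
#' @param s1,s2 covariance matrices (scalars allowed in 1-D).
#' @return non-negative scalar distance.
#' @export
frechet_gaussian <- function(mu1, s1, mu2, s2) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  if (any(!is.finite(c(mu1, mu2, s1, s2)))) stop_numeric("non-finite Gaussian parameters")
  sym_sqrt <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    v <- pmax(e$values, 0)
    e$vectors %*% (sqrt(v) * t(e$vectors))
  }
  h <- sym_sqrt(s1)
  cross <- sym_sqrt(h %*% s2 %*% h)
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(diag(cross))
}

#' Frechet distance between two feature samples (FID-style)
#'
#' Fits a Gaussian (sample mean, `n - 1` covariance) to each feature matrix
#' and evaluates [frechet_gaussian()]. A small diagonal jitter is added if a
#' covariance is numerically singular.
#'
#' @param features_real,features_syn `n x p` feature matrices (>= 2 rows each).
#' @param extractor_id optional id string recorded in the result.
#' @return object of class `fid_result` with fields `fid`, `extractor_id`,
#'   `n_real`, `n_synthetic`, `dim`.
#' @export
frechet_distance <- function(features_real, features_syn, extractor_id = "unspecified") {
  fr <- as.matrix(features_real); fs <- as.matrix(features_syn)
  if (ncol(fr) != ncol(fs)) stop_validation("feature dimension mismatch")
  if (nrow(fr) < 2 || nrow(fs) < 2) stop_validation("need >= 2 rows per sample")
  if (any(!is.finite(fr)) || any(!is.finite(fs))) stop_numeric("non-finite features")
  jit <- 1e-8 * diag(ncol(fr))
  fid <- frechet_gaussian(colMeans(fr), stats::cov(fr) + jit,
                          colMeans(fs), stats::cov(fs) + jit)
  structure(list(fid = max(fid, -1e-8), extractor_id = extractor_id,
                 n_real = nrow(fr), n_synthetic = nrow(fs), dim = ncol(fr)),
            class = "fid_result")
}

#' Overlap between real and synthetic latent distributions
#'
#' Both latent sets are projected onto the first principal axis of the real
#' set; the overlap coefficient is `sum(min(p_i, q_i))` over a shared histogram
#' (default 32 bins spanning the pooled range). 1 means identical binned
#' densities, 0 disjoint supports.
#'
#' @param z_real,z_syn `n x d` latent matrices with matching `d`.
#' @param bins number of histogram bins.
#' @return object of class `overlap_result` with fields `overlap`,
#'   `projection`, `n_real`, `n_syn`.
#' @export
latent_overlap <- function(z_real, z_syn, bins = 32L) {
  zr <- as.matrix(z_real); zs <- as.matrix(z_syn)
  if (ncol(zr) != ncol(zs)) stop_validation("latent dimension mismatch")
  ctr <- colMeans(zr)
  zc <- sweep(zr, 2, ctr)
  sv <- La.svd(zc, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12) stop_validation("degenerate (zero-variance) real latent set")
  axis <- as.numeric(sv$vt[1, ])
  pr <- zc %*% axis
  ps <- sweep(zs, 2, ctr) %*% axis
  rng <- range(c(pr, ps))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  p <- tabulate(findInterval(pr, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(pr)
  q <- tabulate(findInterval(ps, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(ps)
  structure(list(overlap = sum(pmin(p, q)),
                 projection = "first principal axis of real set",
                 n_real = nrow(zr), n_syn = nrow(zs), bins = bins),
            class = "overlap_result")
}

#' Age-binned subgroup metrics
#'
#' Restricts predictions to records inside each age bin `[lo, hi)` and reports
#' per-class precision and F1. Bins containing a single class are flagged, not
#' silently reported as perfect; empty bins are omitted with a warning.
#'
#' @param pred a `prediction_set` (see [predict_scores()]).
#' @param metadata data.frame with `record_id` and `age_years`.
#' @param age_bins list of `c(lo, hi)` bin edges in years; defaults to the
#'   10-20 and 50-60 bins used in the evaluation protocol.
#' @return data.frame with columns `bin`, `class`, `n`, `precision`, `f1`,
#'   `single_class`.
#' @export
subgroup_metrics <- function(pred, metadata,
                             age_bins = list(c(10, 20), c(50, 60))) {
  stopifnot(inherits(pred, "prediction_set"))
  ages <- metadata$age_years[match(pred$record_ids, metadata$record_id)]
  out <- list()
  for (b in age_bins) {
    sel <- !is.na(ages) & ages >= b[1] & ages < b[2]
    bin_name <- sprintf("%g-%g", b[1], b[2])
    if (!any(sel)) {
      warning(sprintf("age bin %s is empty; omitted", bin_name))
      next
    }
    truth <- pred$truth[sel]
    sc <- pred$scores[sel, , drop = FALSE]
    cm <- confusion_metrics(truth, sc)
    pc <- cm$per_class
    pc <- pc[pc$class %in% unique(truth) | !is.na(pc$precision), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      bin = bin_name, class = pc$class, n = as.integer(sum(sel)),
      precision = pc$precision, f1 = pc$f1,
      single_class = length(unique(truth)) < 2)
  }
  if (!length(out)) return(data.frame(bin = character(), class = character(),
                                      n = integer(), precision = numeric(),
                                      f1 = numeric(), single_class = logical()))
  do.call(rbind, out)
}
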