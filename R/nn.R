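# Minimal neural-network layer library (internal).
#
# Layers are environments holding parameter arrays and (after a backward pass)
# gradient arrays named "g_<param>". Networks are plain lists of layers run by
# nn_forward()/nn_backward(). Convolutions use the shift-and-matmul
# decomposition of a 3x3 kernel (nine strided slices, one matmul each), which
# keeps everything in BLAS-backed matrix products. Every layer's backward pass
# is checked against numerical gradients in the test suite.
#
# Tensor conventions:
#   image batches  (N, H, W, C) arrays
#   feature rows   (N, D) matrices
#   token batches  (N, T, D) arrays

nn_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

nn_linear <- function(d_in, d_out, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / d_in)
  nn_layer("linear",
           W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
           b = numeric(d_out))
}

nn_conv <- function(c_in, c_out, stride = 1L, k = 3L, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / (k * k * c_in))
  nn_layer("conv",
           W = array(stats::rnorm(k * k * c_in * c_out, sd = sd), c(k, k, c_in, c_out)),
           b = numeric(c_out), stride = as.integer(stride), k = as.integer(k),
           pad = as.integer((k - 1L) / 2L))
}

nn_act <- function(kind) nn_layer(kind)        # relu / lrelu / sigmoid / tanh / gelu
nn_upsample2 <- function() nn_layer("upsample2")
nn_flatten <- function() nn_layer("flatten")
nn_reshape <- function(h, w, c) nn_layer("reshape", h = h, w = w, c = c)
nn_gap <- function() nn_layer("gap")           # global average pool (N,H,W,C)->(N,C)

nn_layernorm <- function(d) {
  nn_layer("layernorm", gamma = rep(1, d), beta = rep(0, d), eps = 1e-5)
}

nn_attention <- function(d, heads) {
  stopifnot(d %% heads == 0)
  sd <- 1 / sqrt(d)
  m <- function() matrix(stats::rnorm(d * d, sd = sd), d, d)
  nn_layer("attention", Wq = m(), Wk = m(), Wv = m(), Wo = m(), heads = heads)
}

nn_meanpool_tokens <- function() nn_layer("meanpool_tokens")

# Two 3x3 convolutions with identity skip: y = relu(x + c2(relu(c1(x)))).
nn_resblock <- function(ch) {
  nn_layer("resblock", c1 = nn_conv(ch, ch, stride = 1), c2 = nn_conv(ch, ch, stride = 1))
}

# (N,H,W,3) -> (N, T, p*p*3) token grid of non-overlapping p x p patches.
nn_patchify <- function(p) nn_layer("patchify", p = as.integer(p))

# Learned additive positional embedding for (N,T,D) tokens.
nn_posemb <- function(t, d) {
  nn_layer("posemb", P = matrix(stats::rnorm(t * d, sd = 0.02), t, d))
}

# Pre-norm transformer block: x + att(ln1(x)), then + mlp(ln2(.)).
nn_tblock <- function(d, heads, mlp_mult = 4L) {
  nn_layer("tblock",
           ln1 = nn_layernorm(d), att = nn_attention(d, heads),
           ln2 = nn_layernorm(d),
           fc1 = nn_linear(d, mlp_mult * d), fc2 = nn_linear(mlp_mult * d, d))
}

layer_children <- function(l) {
  switch(l$type,
    resblock = list(l$c1, l$c2),
    tblock = list(l$ln1, l$att, l$ln2, l$fc1, l$fc2),
    tokens_linear = list(l$inner),
    list()
  )
}

pad_nhwc <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

# ---- forward ---------------------------------------------------------------

layer_fwd <- function(l, x) {
  switch(l$type,
    linear = {
      l$cache_x <- x
      sweep(x %*% l$W, 2, l$b, "+")
    },
    conv = {
      d <- dim(x)
      k <- l$k; s <- l$stride; p <- l$pad
      oh <- (d[2] + 2 * p - k) %/% s + 1L
      ow <- (d[3] + 2 * p - k) %/% s + 1L
      cout <- dim(l$W)[4]
      cols <- im2col_cpp(x, k, s, p)
      l$cache_cols <- cols
      l$cache_dims <- c(d, oh, ow)
      ym <- sweep(cols %*% matrix(l$W, k * k * d[4], cout), 2, l$b, "+")
      array(ym, c(d[1], oh, ow, cout))
    },
    relu = { l$cache_x <- x; x * (x > 0) },
    lrelu = { l$cache_x <- x; ifelse(x > 0, x, 0.2 * x) },
    sigmoid = { y <- 1 / (1 + exp(-x)); l$cache_y <- y; y },
    tanh = { y <- tanh(x); l$cache_y <- y; y },
    gelu = { l$cache_x <- x; x * stats::pnorm(x) },
    upsample2 = {
      d <- dim(x); l$cache_dims <- d
      x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
    },
    flatten = {
      d <- dim(x); l$cache_dims <- d
      matrix(x, d[1], prod(d[-1]))
    },
    reshape = {
      l$cache_n <- nrow(x)
      array(x, c(nrow(x), l$h, l$w, l$c))
    },
    gap = {
      d <- dim(x); l$cache_dims <- d
      apply(x, c(1, 4), mean)
    },
    layernorm = {
      d <- dim(x); l$cache_dims <- d
      xm <- if (length(d) == 3) matrix(x, d[1] * d[2], d[3]) else x
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc * xc)
      inv <- 1 / sqrt(v + l$eps)
      xhat <- xc * inv
      l$cache_xhat <- xhat; l$cache_inv <- inv
      ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      if (length(d) == 3) array(ym, d) else ym
    },
    attention = attention_fwd(l, x),
    meanpool_tokens = {
      d <- dim(x); l$cache_dims <- d
      apply(x, c(1, 3), mean)
    },
    resblock = {
      h1 <- layer_fwd(l$c1, x)
      a1 <- h1 * (h1 > 0)
      h2 <- layer_fwd(l$c2, a1)
      pre <- x + h2
      l$cache_m1 <- h1 > 0; l$cache_mout <- pre > 0
      pre * (pre > 0)
    },
    patchify = {
      d <- dim(x); p <- l$p
      nt <- (d[2] %/% p) * (d[3] %/% p)
      l$cache_dims <- d
      tok <- array(0, c(d[1], nt, p * p * d[4]))
      t <- 0L
      for (ti in seq_len(d[2] %/% p)) for (tj in seq_len(d[3] %/% p)) {
        t <- t + 1L
        patch <- x[, ((ti - 1) * p + 1):(ti * p), ((tj - 1) * p + 1):(tj * p), ,
                   drop = FALSE]
        tok[, t, ] <- matrix(patch, d[1], p * p * d[4])
      }
      tok
    },
    posemb = {
      d <- dim(x); l$cache_dims <- d
      for (i in seq_len(d[1])) x[i, , ] <- x[i, , ] + l$P
      x
    },
    tblock = {
      h <- layer_fwd(l$ln1, x)
      a <- x + layer_fwd(l$att, h)
      d <- dim(a)
      g <- layer_fwd(l$ln2, a)
      gm <- matrix(g, d[1] * d[2], d[3])
      u <- layer_fwd(l$fc1, gm)
      ug <- u * stats::pnorm(u)
      l$cache_u <- u
      v <- layer_fwd(l$fc2, ug)
      a + array(v, d)
    },
    tokens_linear = {
      d <- dim(x); l$cache_dims <- d
      ym <- layer_fwd(l$inner, matrix(x, d[1] * d[2], d[3]))
      array(ym, c(d[1], d[2], ncol(ym)))
    },
    stop("unknown layer type ", l$type)
  )
}

attention_fwd <- function(l, x) {
  d <- dim(x); n <- d[1]; tt <- d[2]; dd <- d[3]
  h <- l$heads; dh <- dd %/% h
  y <- array(0, d)
  cache <- vector("list", n)
  for (i in seq_len(n)) {
    xn <- matrix(x[i, , ], tt, dd)
    q <- xn %*% l$Wq; kk <- xn %*% l$Wk; v <- xn %*% l$Wv
    o <- matrix(0, tt, dd)
    ps <- vector("list", h)
    for (j in seq_len(h)) {
      idx <- ((j - 1) * dh + 1):(j * dh)
      s <- (q[, idx, drop = FALSE] %*% t(kk[, idx, drop = FALSE])) / sqrt(dh)
      s <- s - apply(s, 1, max)
      p <- exp(s); p <- p / rowSums(p)
      ps[[j]] <- p
      o[, idx] <- p %*% v[, idx, drop = FALSE]
    }
    y[i, , ] <- o %*% l$Wo
    cache[[i]] <- list(xn = xn, q = q, k = kk, v = v, p = ps, o = o)
  }
  l$cache <- cache
  l$cache_dims <- d
  y
}

# ---- backward --------------------------------------------------------------

acc_grad <- function(l, name, g) {
  gname <- paste0("g_", name)
  if (is.null(l[[gname]])) assign(gname, g, envir = l)
  else assign(gname, l[[gname]] + g, envir = l)
}

layer_bwd <- function(l, dy) {
  switch(l$type,
    linear = {
      acc_grad(l, "W", crossprod(l$cache_x, dy))
      acc_grad(l, "b", colSums(dy))
      dy %*% t(l$W)
    },
    conv = {
      cd <- l$cache_dims
      k <- l$k; cin <- cd[4]; cout <- dim(l$W)[4]
      dym <- matrix(dy, cd[1] * cd[5] * cd[6], cout)
      acc_grad(l, "W", array(crossprod(l$cache_cols, dym), dim(l$W)))
      acc_grad(l, "b", colSums(dym))
      dcols <- dym %*% t(matrix(l$W, k * k * cin, cout))
      l$cache_cols <- NULL
      col2im_cpp(dcols, cd[1], cd[2], cd[3], cin, k, l$stride, l$pad)
    },
    relu = dy * (l$cache_x > 0),
    lrelu = dy * ifelse(l$cache_x > 0, 1, 0.2),
    sigmoid = dy * l$cache_y * (1 - l$cache_y),
    tanh = dy * (1 - l$cache_y^2),
    gelu = dy * (stats::pnorm(l$cache_x) + l$cache_x * stats::dnorm(l$cache_x)),
    upsample2 = {
      d <- l$cache_dims
      dy[, seq.int(1, 2 * d[2], 2), seq.int(1, 2 * d[3], 2), , drop = FALSE] +
      dy[, seq.int(2, 2 * d[2], 2), seq.int(1, 2 * d[3], 2), , drop = FALSE] +
      dy[, seq.int(1, 2 * d[2], 2), seq.int(2, 2 * d[3], 2), , drop = FALSE] +
      dy[, seq.int(2, 2 * d[2], 2), seq.int(2, 2 * d[3], 2), , drop = FALSE]
    },
    flatten = array(dy, l$cache_dims),
    reshape = matrix(dy, l$cache_n, l$h * l$w * l$c),
    gap = {
      d <- l$cache_dims
      scale <- 1 / (d[2] * d[3])
      out <- array(0, d)
      for (ci in seq_len(d[4])) {
        out[, , , ci] <- array(rep(dy[, ci], d[2] * d[3]), d[1:3]) * scale
      }
      out
    },
    layernorm = {
      d <- l$cache_dims
      dym <- if (length(d) == 3) matrix(dy, d[1] * d[2], d[3]) else dy
      xhat <- l$cache_xhat; inv <- l$cache_inv
      acc_grad(l, "gamma", colSums(dym * xhat))
      acc_grad(l, "beta", colSums(dym))
      dxhat <- sweep(dym, 2, l$gamma, "*")
      dxm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
      if (length(d) == 3) array(dxm, d) else dxm
    },
    attention = attention_bwd(l, dy),
    meanpool_tokens = {
      d <- l$cache_dims
      out <- array(0, d)
      for (di in seq_len(d[3])) {
        out[, , di] <- matrix(rep(dy[, di], d[2]), d[1], d[2]) / d[2]
      }
      out
    },
    resblock = {
      dpre <- dy * l$cache_mout
      da1 <- layer_bwd(l$c2, dpre)
      dh1 <- da1 * l$cache_m1
      layer_bwd(l$c1, dh1) + dpre
    },
    patchify = {
      d <- l$cache_dims; p <- l$p
      dx <- array(0, d)
      t <- 0L
      for (ti in seq_len(d[2] %/% p)) for (tj in seq_len(d[3] %/% p)) {
        t <- t + 1L
        dx[, ((ti - 1) * p + 1):(ti * p), ((tj - 1) * p + 1):(tj * p), ] <-
          array(dy[, t, ], c(d[1], p, p, d[4]))
      }
      dx
    },
    posemb = {
      d <- l$cache_dims
      dP <- matrix(0, d[2], d[3])
      for (i in seq_len(d[1])) dP <- dP + matrix(dy[i, , ], d[2], d[3])
      acc_grad(l, "P", dP)
      dy
    },
    tblock = {
      d <- dim(dy)
      dym <- matrix(dy, d[1] * d[2], d[3])
      dug <- layer_bwd(l$fc2, dym)
      u <- l$cache_u
      du <- dug * (stats::pnorm(u) + u * stats::dnorm(u))
      dgm <- layer_bwd(l$fc1, du)
      da <- dy + layer_bwd(l$ln2, array(dgm, d))
      dh <- layer_bwd(l$att, da)
      layer_bwd(l$ln1, dh) + da
    },
    tokens_linear = {
      d <- l$cache_dims
      dxm <- layer_bwd(l$inner, matrix(dy, d[1] * d[2], prod(dim(dy)) / (d[1] * d[2])))
      array(dxm, d)
    },
    stop("unknown layer type ", l$type)
  )
}

attention_bwd <- function(l, dy) {
  d <- l$cache_dims; n <- d[1]; tt <- d[2]; dd <- d[3]
  h <- l$heads; dh <- dd %/% h
  dx <- array(0, d)
  dWq <- matrix(0, dd, dd); dWk <- dWq; dWv <- dWq; dWo <- dWq
  for (i in seq_len(n)) {
    cc <- l$cache[[i]]
    dyn <- matrix(dy[i, , ], tt, dd)
    dWo <- dWo + crossprod(cc$o, dyn)
    do <- dyn %*% t(l$Wo)
    dq <- matrix(0, tt, dd); dk <- dq; dv <- dq
    for (j in seq_len(h)) {
      idx <- ((j - 1) * dh + 1):(j * dh)
      p <- cc$p[[j]]
      doh <- do[, idx, drop = FALSE]
      dp <- doh %*% t(cc$v[, idx, drop = FALSE])
      dv[, idx] <- crossprod(p, doh)
      ds <- p * (dp - rowSums(dp * p))
      dq[, idx] <- ds %*% cc$k[, idx, drop = FALSE] / sqrt(dh)
      dk[, idx] <- crossprod(ds, cc$q[, idx, drop = FALSE]) / sqrt(dh)
    }
    dWq <- dWq + crossprod(cc$xn, dq)
    dWk <- dWk + crossprod(cc$xn, dk)
    dWv <- dWv + crossprod(cc$xn, dv)
    dx[i, , ] <- dq %*% t(l$Wq) + dk %*% t(l$Wk) + dv %*% t(l$Wv)
  }
  acc_grad(l, "Wq", dWq); acc_grad(l, "Wk", dWk)
  acc_grad(l, "Wv", dWv); acc_grad(l, "Wo", dWo)
  l$cache <- NULL
  dx
}

# ---- network-level helpers -------------------------------------------------

nn_forward <- function(net, x) {
  for (l in net) x <- layer_fwd(l, x)
  x
}

nn_backward <- function(net, dy) {
  for (l in rev(net)) dy <- layer_bwd(l, dy)
  dy
}

layer_param_names <- function(l) {
  switch(l$type,
    linear = c("W", "b"),
    conv = c("W", "b"),
    layernorm = c("gamma", "beta"),
    attention = c("Wq", "Wk", "Wv", "Wo"),
    posemb = "P",
    character(0)
  )
}

# Flatten a layer and its composite children into a single layer list.
flatten_layers <- function(net) {
  out <- list()
  for (l in net) {
    out <- c(out, list(l), flatten_layers(layer_children(l)))
  }
  out
}

nn_params <- function(nets) {
  # nets: a list of layer lists (composite layers contribute their children)
  out <- list()
  for (net in nets) {
    for (l in flatten_layers(net)) {
      for (nm in layer_param_names(l)) {
        out[[length(out) + 1L]] <- list(layer = l, name = nm)
      }
    }
  }
  out
}

nn_zero_grads <- function(nets) {
  for (net in nets) {
    for (l in flatten_layers(net)) {
      for (nm in layer_param_names(l)) assign(paste0("g_", nm), NULL, envir = l)
    }
  }
  invisible(NULL)
}

# Serialize / restore parameter values (checkpoints hold plain arrays).
nn_get_weights <- function(nets) {
  lapply(nets, function(net) lapply(flatten_layers(net), function(l) {
    w <- lapply(layer_param_names(l), function(nm) l[[nm]])
    names(w) <- layer_param_names(l)
    w
  }))
}

nn_set_weights <- function(nets, weights) {
  for (i in seq_along(nets)) {
    fl <- flatten_layers(nets[[i]])
    for (j in seq_along(fl)) {
      w <- weights[[i]][[j]]
      for (nm in names(w)) assign(nm, w[[nm]], envir = fl[[j]])
    }
  }
  invisible(NULL)
}

# ---- AdamW with linear learning-rate decay ---------------------------------

adamw_new <- function(params, lr, weight_decay = 0.01, total_steps = 1L,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$wd <- weight_decay
  st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$total <- max(1L, as.integer(total_steps))
  zeros <- function() lapply(params, function(p) {
    array(0, dim(as.array(p$layer[[p$name]])))
  })
  st$m <- zeros()
  st$v <- zeros()  # distinct allocations: the update kernel mutates in place
  st
}

adamw_step <- function(st) {
  st$t <- st$t + 1L
  # linear decay to zero over the scheduled number of steps (no warmup)
  lr_t <- st$lr * max(0, (st$total - st$t + 1) / st$total)
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$layer[[paste0("g_", p$name)]]
    if (is.null(g)) next
    w <- p$layer[[p$name]]
    # m and v are private optimizer state, updated in place by the kernel
    upd <- adamw_update_cpp(g, st$m[[i]], st$v[[i]], st$b1, st$b2, st$eps, st$t)
    neww <- w - lr_t * (upd + st$wd * w)
    if (!is.null(dim(w))) dim(neww) <- dim(w)
    assign(p$name, neww, envir = p$layer)
  }
  invisible(lr_t)
}

# ---- fused losses ----------------------------------------------------------

# Softmax cross-entropy from logits. y: integer class index per row (1-based).
# Returns list(loss, dlogits, probs).
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  picked <- probs[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- probs
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dl / n, probs = probs)
}

# Binary cross-entropy from logits against constant target in {0,1}.
bce_logits <- function(logits, target) {
  n <- length(logits)
  # softplus(x) - t*x, numerically stable
  sp <- ifelse(logits > 0, logits + log1p(exp(-logits)), log1p(exp(logits)))
  loss <- mean(sp - target * logits)
  dl <- (1 / (1 + exp(-logits)) - target) / n
  list(loss = loss, dlogits = dl)
}
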