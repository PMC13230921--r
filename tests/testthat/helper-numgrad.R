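# Central-difference numerical gradients used to verify every layer's
# analytic backward pass.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  xv <- as.vector(x)
  for (i in seq_along(xv)) {
    xp <- xv; xp[i] <- xp[i] + eps
    xm <- xv; xm[i] <- xm[i] - eps
    dx <- dim(x)
    a1 <- if (is.null(dx)) xp else array(xp, dx)
    a2 <- if (is.null(dx)) xm else array(xm, dx)
    g[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  if (is.null(dim(x))) as.vector(g) else g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Scalar loss used in layer checks: weighted sum of outputs with a fixed
# random weight tensor, so gradients exercise every output element.
weighted_sum_loss <- function(out, wts) sum(out * wts)
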