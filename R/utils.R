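# Internal helpers: seeded evaluation, classed conditions, small numerics.

#' Evaluate an expression under a fixed RNG seed, restoring the stream after
#'
#' All stochastic operations in the package funnel through this helper so that
#' every result is reproducible from the seeds recorded in run manifests.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministically derive a child seed from a master seed and a stage offset.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %% 2147483587)
}

# Classed conditions so callers (and tests) can distinguish failure modes.
lm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "latentmix_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) lm_stop("latentmix_validation_error", msg, ...)
stop_schema     <- function(msg, ...) lm_stop("latentmix_schema_error", msg, ...)
stop_io         <- function(msg, ...) lm_stop("latentmix_io_error", msg, ...)
stop_state      <- function(msg, ...) lm_stop("latentmix_state_error", msg, ...)
stop_leakage    <- function(msg, ...) lm_stop("latentmix_leakage_error", msg, ...)
stop_numeric    <- function(msg, ...) lm_stop("latentmix_numeric_error", msg, ...)
stop_training   <- function(msg, ...) lm_stop("latentmix_training_error", msg, ...)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Round-half-up (0.5 always rounds toward +Inf), used for patient counts.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Stack a list of H x W x 3 images into an (N, H, W, 3) batch array.
stack_images <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1]])
  n <- length(images)
  out <- array(0, c(n, d[1], d[2], d[3]))
  for (i in seq_len(n)) out[i, , , ] <- images[[i]]
  out
}

# Bilinear resize of an H x W x C image to side x side.
resize_image <- function(img, side) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  # sample positions in source coordinates (align-corners = FALSE convention)
  sy <- (seq_len(side) - 0.5) * d[1] / side + 0.5
  sx <- (seq_len(side) - 0.5) * d[2] / side + 0.5
  y0 <- pmin(pmax(floor(sy), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(sx), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(side, side, d[3]))
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    cc <- ch[y1, x0, drop = FALSE]; dd <- ch[y1, x1, drop = FALSE]
    W <- outer(1 - wy, 1 - wx)
    out[, , c] <- a * outer(1 - wy, 1 - wx) + b * outer(1 - wy, wx) +
      cc * outer(wy, 1 - wx) + dd * outer(wy, wx)
  }
  out
}
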