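# Low-level neural network primitives: forward passes return the output plus
# whatever the matching backward pass needs. Tensors with a time axis are 3-d
# arrays (batch, time, channels); column-major reshaping to (batch*time,
# channels) merges the first two axes without copying semantics we rely on.

as_2d <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L])
  x
}

as_3d <- function(x, b, l) {
  dim(x) <- c(b, l, ncol(x))
  x
}

init_mat <- function(nr, nc, scale) {
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

# PyTorch-style fan-in uniform initialization for an affine map.
init_dense <- function(fan_in, fan_out) {
  s <- 1 / sqrt(fan_in)
  list(W = init_mat(fan_in, fan_out, s), b = runif(fan_out, -s, s))
}

dense_fwd <- function(x, W, b) {
  sweep(x %*% W, 2L, b, "+")
}

dense_bwd <- function(x, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

relu_fwd <- function(x) {
  x * (x > 0)
}

relu_bwd <- function(x, dout) {
  dout * (x > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 1-d convolution over the time axis of a (b, L, Cin) array.
# W is (k, Cin, Cout). pad = "causal" left-pads with (k-1)*dilation zeros so
# the output at position t only sees inputs at or before t; pad = "valid"
# shortens the sequence to L - (k-1)*dilation.
conv1d_fwd <- function(x, W, b, dilation = 1L, pad = c("causal", "valid")) {
  pad <- match.arg(pad)
  d <- dim(x)
  bsz <- d[1L]; l <- d[2L]; cin <- d[3L]
  k <- dim(W)[1L]; cout <- dim(W)[3L]
  span <- (k - 1L) * dilation
  if (pad == "causal") {
    xp <- array(0, c(bsz, l + span, cin))
    xp[, span + seq_len(l), ] <- x
    lout <- l
  } else {
    if (l <= span) stop("input too short for valid convolution")
    xp <- x
    lout <- l - span
  }
  out2 <- matrix(rep(b, each = bsz * lout), bsz * lout, cout)
  for (j in seq_len(k)) {
    tap <- xp[, (j - 1L) * dilation + seq_len(lout), , drop = FALSE]
    dim(tap) <- c(bsz * lout, cin)
    out2 <- out2 + tap %*% matrix(W[j, , ], cin, cout)
  }
  list(out = as_3d(out2, bsz, lout), xp = xp, lout = lout)
}

conv1d_bwd <- function(cache, W, dilation, pad, dout) {
  xp <- cache$xp
  dp <- dim(xp)
  bsz <- dp[1L]; cin <- dp[3L]
  k <- dim(W)[1L]; cout <- dim(W)[3L]
  lout <- cache$lout
  span <- (k - 1L) * dilation
  dout2 <- dout
  dim(dout2) <- c(bsz * lout, cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dp)
  for (j in seq_len(k)) {
    idx <- (j - 1L) * dilation + seq_len(lout)
    tap <- xp[, idx, , drop = FALSE]
    dim(tap) <- c(bsz * lout, cin)
    dW[j, , ] <- crossprod(tap, dout2)
    dtap <- dout2 %*% t(matrix(W[j, , ], cin, cout))
    dim(dtap) <- c(bsz, lout, cin)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + dtap
  }
  dx <- if (pad == "causal") dxp[, span + seq_len(dp[2L] - span), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = colSums(dout2))
}

# Non-overlapping width-2 max pooling over time; odd trailing step dropped.
maxpool2_fwd <- function(x) {
  l <- dim(x)[2L]
  lo <- l %/% 2L
  a <- x[, 2L * seq_len(lo) - 1L, , drop = FALSE]
  b <- x[, 2L * seq_len(lo), , drop = FALSE]
  takea <- a >= b
  list(out = a * takea + b * !takea, takea = takea, l_in = l)
}

maxpool2_bwd <- function(cache, dout) {
  lo <- dim(dout)[2L]
  dx <- array(0, c(dim(dout)[1L], cache$l_in, dim(dout)[3L]))
  dx[, 2L * seq_len(lo) - 1L, ] <- dout * cache$takea
  dx[, 2L * seq_len(lo), ] <- dout * !cache$takea
  dx
}

# Layer normalization over the channel axis of a 2-d (rows, channels) matrix.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat * rep(g, each = nrow(x)), 2L, b, "+")
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dout) {
  xhat <- cache$xhat
  inv <- cache$inv
  n <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(g, each = nrow(dout))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

softmax_rows_bwd <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

# Flatten a nested list of numeric arrays to one vector and back; used by the
# optimizer and by finite-difference gradient checks.
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      lapply(node, walk)
    } else {
      n <- length(node)
      out <- vec[pos + seq_len(n)]
      pos <<- pos + n
      dim(out) <- dim(node)
      out
    }
  }
  walk(skeleton)
}

map_params <- function(f, ...) {
  args <- list(...)
  walk <- function(...) {
    nodes <- list(...)
    if (is.list(nodes[[1L]])) {
      out <- vector("list", length(nodes[[1L]]))
      names(out) <- names(nodes[[1L]])
      for (i in seq_along(out)) {
        out[[i]] <- do.call(walk, lapply(nodes, `[[`, i))
      }
      out
    } else {
      do.call(f, nodes)
    }
  }
  do.call(walk, args)
}

zeros_like <- function(p) {
  map_params(function(x) {
    z <- numeric(length(x))
    dim(z) <- dim(x)
    z
  }, p)
}
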