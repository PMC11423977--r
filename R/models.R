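#' Architecture specification at the benchmark's optimal configuration
#'
#' Returns the fixed configuration of one of the five benchmarked
#' architectures. Defaults are the optimal values selected by grid search in
#' the underlying benchmark: FFN with two hidden layers of 32 and 64 neurons
#' applied per timestep; CNN with two 1-d convolutional layers of 32 and 64
#' channels followed by a 64-32-1 fully connected head; TCN with four
#' residual blocks of 16, 32, 64 and 64 channels and dilations 1, 2, 4, 8;
#' LSTM with two stacked layers of 30 hidden units; SAN (self-attention
#' network) with 3 encoder layers, 4 heads, model width 128 and feed-forward
#' width 512. All optimal configurations use dropout 0.
#'
#' @param architecture one of `"FFN"`, `"CNN"`, `"TCN"`, `"LSTM"`, `"SAN"`.
#' @param input_length history length L in 5-minute steps (default 24 = 2 h).
#' @param ... architecture fields to override (e.g. `hidden` for FFN,
#'   `hidden_units` for LSTM, `d_model`/`n_heads`/`n_layers`/`d_ff` for SAN,
#'   `channels`/`kernel`/`dilations` for TCN, `conv_channels`/`fc` for CNN).
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' spec <- model_spec("LSTM")
#' count_parameters(build_model(spec, seed = 1))
model_spec <- function(architecture = c("FFN", "CNN", "TCN", "LSTM", "SAN"),
                       input_length = 24L, ...) {
  architecture <- match.arg(architecture)
  stopifnot(input_length >= 1)
  base <- switch(architecture,
    FFN = list(hidden = c(32L, 64L)),
    CNN = list(conv_channels = c(32L, 64L), kernel = 3L, fc = c(64L, 32L)),
    TCN = list(channels = c(16L, 32L, 64L, 64L), kernel = 3L,
               dilations = c(1L, 2L, 4L, 8L)),
    LSTM = list(hidden_units = c(30L, 30L)),
    SAN = list(d_model = 128L, n_heads = 4L, n_layers = 3L, d_ff = 512L)
  )
  spec <- modifyList(c(base, list(dropout = 0)), list(...))
  spec$architecture <- architecture
  spec$input_length <- as.integer(input_length)
  if (spec$dropout != 0) {
    stop("all optimal configurations use dropout 0; nonzero dropout is not supported")
  }
  if (architecture == "TCN" && length(spec$channels) != length(spec$dilations)) {
    stop("TCN needs one dilation per block")
  }
  if (architecture == "SAN" && spec$d_model %% spec$n_heads != 0) {
    stop("SAN model width must be divisible by the number of heads")
  }
  structure(spec, class = "model_spec")
}

#' Build a model instance with deterministic seeded initialization
#'
#' @param spec a [model_spec()].
#' @param seed integer seed controlling the parameter initialization.
#' @return an object of class `cgm_model` holding the parameter arrays.
#' @export
build_model <- function(spec, seed) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  set.seed(seed)
  params <- switch(spec$architecture,
    FFN = init_ffn(spec),
    CNN = init_cnn(spec),
    TCN = init_tcn(spec),
    LSTM = init_lstm(spec),
    SAN = init_san(spec)
  )
  structure(list(spec = spec, params = params, seed = seed),
            class = "cgm_model")
}

#' @export
print.cgm_model <- function(x, ...) {
  cat(sprintf("<cgm_model> %s, L = %d, %d parameters\n",
              x$spec$architecture, x$spec$input_length, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable weight and bias elements of a built model,
#' matching the parameter-accounting conventions of the benchmark: the FFN
#' (1-32-64-1 per-timestep stack) has 2241, the two-layer 30-unit LSTM with
#' separate input-side and recurrent-side biases has 11431, and the SAN with
#' sinusoidal positions and a final layer normalization has 595457.
#'
#' @param model a `cgm_model` or trained model.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  sum(unlist(map_params(length, p)))
}

# ---- FFN: affine stack 1 -> 32 -> 64 -> 1 applied per timestep, with the
# forecast read off the final timestep. Only the last timestep influences the
# output, so the forward pass evaluates the stack there.

init_ffn <- function(spec) {
  dims <- c(1L, spec$hidden, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) layers[[i]] <- init_dense(dims[i], dims[i + 1L])
  names(layers) <- paste0("fc", seq_along(layers))
  layers
}

ffn_fwd <- function(params, x) {
  h <- x[, ncol(x), drop = FALSE]
  acts <- list(h)
  nl <- length(params)
  for (i in seq_len(nl)) {
    h <- dense_fwd(h, params[[i]]$W, params[[i]]$b)
    if (i < nl) h <- relu_fwd(h)
    acts[[i + 1L]] <- h
  }
  list(yhat = drop(acts[[nl + 1L]]), cache = acts)
}

ffn_bwd <- function(params, cache, x, dy) {
  nl <- length(params)
  grads <- vector("list", nl)
  names(grads) <- names(params)
  d <- matrix(dy, ncol = 1L)
  for (i in rev(seq_len(nl))) {
    if (i < nl) d <- relu_bwd(cache[[i + 1L]], d)
    g <- dense_bwd(cache[[i]], params[[i]]$W, d)
    grads[[i]] <- list(W = g$dW, b = g$db)
    d <- g$dx
  }
  grads
}

# ---- CNN: valid 1-d convolutions (kernel 3) of 32 then 64 channels with a
# width-2 max pool between them, global average pooling over time, and a
# 64 -> 32 -> 1 fully connected head.

init_cnn <- function(spec) {
  k <- spec$kernel
  ch <- spec$conv_channels
  list(
    conv1 = list(W = array(runif(k * ch[1], -1, 1) / sqrt(k), c(k, 1L, ch[1])),
                 b = runif(ch[1], -1, 1) / sqrt(k)),
    conv2 = list(W = array(runif(k * ch[1] * ch[2], -1, 1) / sqrt(k * ch[1]),
                           c(k, ch[1], ch[2])),
                 b = runif(ch[2], -1, 1) / sqrt(k * ch[1])),
    fc1 = init_dense(spec$fc[1], spec$fc[2]),
    fc2 = init_dense(spec$fc[2], 1L)
  )
}

cnn_fwd <- function(params, x) {
  bsz <- nrow(x)
  x3 <- array(x, c(bsz, ncol(x), 1L))
  c1 <- conv1d_fwd(x3, params$conv1$W, params$conv1$b, 1L, "valid")
  r1 <- relu_fwd(c1$out)
  p1 <- maxpool2_fwd(r1)
  c2 <- conv1d_fwd(p1$out, params$conv2$W, params$conv2$b, 1L, "valid")
  r2 <- relu_fwd(c2$out)
  lpool <- dim(r2)[2L]
  gap <- apply(r2, c(1L, 3L), mean)            # (b, C2)
  h1 <- relu_fwd(dense_fwd(gap, params$fc1$W, params$fc1$b))
  y <- dense_fwd(h1, params$fc2$W, params$fc2$b)
  list(yhat = drop(y),
       cache = list(x3 = x3, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                    lpool = lpool, gap = gap, h1 = h1))
}

cnn_bwd <- function(params, cache, x, dy) {
  d <- matrix(dy, ncol = 1L)
  g2 <- dense_bwd(cache$h1, params$fc2$W, d)
  dh1 <- relu_bwd(cache$h1, g2$dx)
  g1 <- dense_bwd(cache$gap, params$fc1$W, dh1)
  lpool <- cache$lpool
  dgap <- g1$dx / lpool
  dr2 <- array(0, dim(cache$r2))
  for (t in seq_len(lpool)) dr2[, t, ] <- dgap
  dc2 <- relu_bwd(cache$c2$out, dr2)
  gc2 <- conv1d_bwd(cache$c2, params$conv2$W, 1L, "valid", dc2)
  dp1 <- maxpool2_bwd(cache$p1, gc2$dx)
  dc1 <- relu_bwd(cache$c1$out, dp1)
  gc1 <- conv1d_bwd(cache$c1, params$conv1$W, 1L, "valid", dc1)
  list(conv1 = list(W = gc1$dW, b = gc1$db),
       conv2 = list(W = gc2$dW, b = gc2$db),
       fc1 = list(W = g1$dW, b = g1$db),
       fc2 = list(W = g2$dW, b = g2$db))
}

# ---- TCN: four residual blocks of causal dilated convolutions (two
# convolutions per block, kernel 3), channels 16/32/64/64 with dilations
# 1/2/4/8, a 1x1 convolution on the residual path where channel counts
# change, and a 64 -> 1 head on the final position.

init_tcn <- function(spec) {
  k <- spec$kernel
  ch <- c(1L, spec$channels)
  blocks <- vector("list", length(spec$channels))
  for (i in seq_along(blocks)) {
    cin <- ch[i]; cout <- ch[i + 1L]
    blk <- list(
      convA = list(W = array(runif(k * cin * cout, -1, 1) / sqrt(k * cin),
                             c(k, cin, cout)),
                   b = runif(cout, -1, 1) / sqrt(k * cin)),
      convB = list(W = array(runif(k * cout * cout, -1, 1) / sqrt(k * cout),
                             c(k, cout, cout)),
                   b = runif(cout, -1, 1) / sqrt(k * cout))
    )
    if (cin != cout) blk$proj <- init_dense(cin, cout)
    blocks[[i]] <- blk
  }
  names(blocks) <- paste0("block", seq_along(blocks))
  c(blocks, list(head = init_dense(spec$channels[length(spec$channels)], 1L)))
}

tcn_fwd <- function(params, x, spec) {
  bsz <- nrow(x); l <- ncol(x)
  h <- array(x, c(bsz, l, 1L))
  nb <- length(spec$channels)
  caches <- vector("list", nb)
  for (i in seq_len(nb)) {
    blk <- params[[i]]
    d <- spec$dilations[i]
    cA <- conv1d_fwd(h, blk$convA$W, blk$convA$b, d, "causal")
    rA <- relu_fwd(cA$out)
    cB <- conv1d_fwd(rA, blk$convB$W, blk$convB$b, d, "causal")
    if (!is.null(blk$proj)) {
      h2 <- as_2d(h)
      res <- as_3d(dense_fwd(h2, blk$proj$W, blk$proj$b), bsz, l)
    } else {
      h2 <- NULL
      res <- h
    }
    pre <- cB$out + res
    out <- relu_fwd(pre)
    caches[[i]] <- list(h = h, h2 = h2, cA = cA, rA = rA, cB = cB, pre = pre)
    h <- out
  }
  hl <- h[, l, ]                                # (b, C)
  if (is.null(dim(hl))) hl <- matrix(hl, nrow = bsz)
  y <- dense_fwd(hl, params$head$W, params$head$b)
  list(yhat = drop(y), cache = list(blocks = caches, hl = hl, h_final = h))
}

tcn_bwd <- function(params, cache, x, dy, spec) {
  bsz <- length(dy); l <- ncol(x)
  gh <- dense_bwd(cache$hl, params$head$W, matrix(dy, ncol = 1L))
  dh <- array(0, dim(cache$h_final))
  dh[, l, ] <- gh$dx
  nb <- length(spec$channels)
  grads <- vector("list", nb + 1L)
  names(grads) <- names(params)
  grads$head <- list(W = gh$dW, b = gh$db)
  for (i in rev(seq_len(nb))) {
    blk <- params[[i]]
    cc <- cache$blocks[[i]]
    d <- spec$dilations[i]
    dpre <- relu_bwd(cc$pre, dh)
    gB <- conv1d_bwd(cc$cB, blk$convB$W, d, "causal", dpre)
    drA <- relu_bwd(cc$cA$out, gB$dx)
    gA <- conv1d_bwd(cc$cA, blk$convA$W, d, "causal", drA)
    dh_in <- gA$dx
    g <- list(convA = list(W = gA$dW, b = gA$db),
              convB = list(W = gB$dW, b = gB$db))
    if (!is.null(blk$proj)) {
      dpre2 <- as_2d(dpre)
      gp <- dense_bwd(cc$h2, blk$proj$W, dpre2)
      g$proj <- list(W = gp$dW, b = gp$db)
      dh_in <- dh_in + as_3d(gp$dx, bsz, l)
    } else {
      dh_in <- dh_in + dpre
    }
    grads[[i]] <- g
    dh <- dh_in
  }
  grads
}

# ---- LSTM: two stacked layers of 30 hidden units on the univariate input,
# separate input-side and recurrent-side bias vectors per gate (the
# convention under which the two-layer 30-unit network has 11431
# parameters), and an affine 30 -> 1 head on the final hidden state.
# The numeric core lives in src/ (see lstm_forward / lstm_backward).

init_lstm <- function(spec) {
  hs <- spec$hidden_units
  ins <- c(1L, hs[-length(hs)])
  layers <- vector("list", length(hs))
  for (i in seq_along(hs)) {
    h <- hs[i]; s <- 1 / sqrt(h)
    layers[[i]] <- list(
      Wi = init_mat(ins[i], 4L * h, s),
      Wh = init_mat(h, 4L * h, s),
      bi = runif(4L * h, -s, s),
      bh = runif(4L * h, -s, s)
    )
  }
  names(layers) <- paste0("layer", seq_along(hs))
  c(layers, list(head = init_dense(hs[length(hs)], 1L)))
}

lstm_fwd <- function(params, x, spec) {
  nlay <- length(spec$hidden_units)
  h <- array(x, c(nrow(x), ncol(x), 1L))
  caches <- vector("list", nlay)
  for (i in seq_len(nlay)) {
    lay <- params[[i]]
    res <- lstm_layer_forward(h, lay$Wi, lay$Wh, lay$bi + lay$bh)
    caches[[i]] <- res
    h <- res$H
  }
  hl <- h[, dim(h)[2L], ]
  if (is.null(dim(hl))) hl <- matrix(hl, nrow = nrow(x))
  y <- dense_fwd(hl, params$head$W, params$head$b)
  list(yhat = drop(y), cache = list(layers = caches, hl = hl))
}

lstm_bwd <- function(params, cache, x, dy, spec) {
  nlay <- length(spec$hidden_units)
  gh <- dense_bwd(cache$hl, params$head$W, matrix(dy, ncol = 1L))
  dH <- array(0, dim(cache$layers[[nlay]]$H))
  dH[, dim(dH)[2L], ] <- gh$dx
  grads <- vector("list", nlay + 1L)
  names(grads) <- names(params)
  grads$head <- list(W = gh$dW, b = gh$db)
  for (i in rev(seq_len(nlay))) {
    lay <- params[[i]]
    xin <- if (i == 1L) array(x, c(nrow(x), ncol(x), 1L)) else cache$layers[[i - 1L]]$H
    g <- lstm_layer_backward(xin, lay$Wi, lay$Wh, cache$layers[[i]], dH)
    grads[[i]] <- list(Wi = g$dWi, Wh = g$dWh, bi = drop(g$db),
                       bh = drop(g$db))
    dH <- g$dX
  }
  grads
}

# ---- SAN: affine input projection to width 128, parameter-free sinusoidal
# position encoding, three pre-norm transformer encoder blocks (4-head
# self-attention with fused query/key/value projection, feed-forward
# 128 -> 512 -> 128), a final layer normalization and an affine head on the
# last position.

init_san <- function(spec) {
  d <- spec$d_model
  blocks <- vector("list", spec$n_layers)
  for (i in seq_len(spec$n_layers)) {
    blocks[[i]] <- list(
      ln1 = list(g = rep(1, d), b = rep(0, d)),
      qkv = init_dense(d, 3L * d),
      out = init_dense(d, d),
      ln2 = list(g = rep(1, d), b = rep(0, d)),
      ff1 = init_dense(d, spec$d_ff),
      ff2 = init_dense(spec$d_ff, d)
    )
  }
  names(blocks) <- paste0("block", seq_len(spec$n_layers))
  c(list(inproj = init_dense(1L, d)), blocks,
    list(lnf = list(g = rep(1, d), b = rep(0, d)), head = init_dense(d, 1L)))
}

sinusoidal_pe <- function(l, d) {
  pos <- matrix(0, l, d)
  t <- seq_len(l) - 1
  for (i in seq_len(d %/% 2)) {
    w <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2L * i - 1L] <- sin(t * w)
    pos[, 2L * i] <- cos(t * w)
  }
  pos
}

attn_fwd <- function(h2, blk, bsz, l, nh, dh) {
  d <- ncol(h2)
  qkv <- dense_fwd(h2, blk$qkv$W, blk$qkv$b)     # (b*l, 3d)
  qkv3 <- as_3d(qkv, bsz, l)
  o3 <- array(0, c(bsz, l, d))
  P <- vector("list", bsz)
  scl <- 1 / sqrt(dh)
  for (ib in seq_len(bsz)) {
    Pi <- vector("list", nh)
    for (m in seq_len(nh)) {
      cols <- (m - 1L) * dh + seq_len(dh)
      Q <- matrix(qkv3[ib, , cols], l, dh)
      K <- matrix(qkv3[ib, , d + cols], l, dh)
      V <- matrix(qkv3[ib, , 2L * d + cols], l, dh)
      p <- softmax_rows(tcrossprod(Q, K) * scl)
      o3[ib, , cols] <- p %*% V
      Pi[[m]] <- p
    }
    P[[ib]] <- Pi
  }
  o2 <- as_2d(o3)
  out <- dense_fwd(o2, blk$out$W, blk$out$b)
  list(out = out, qkv3 = qkv3, P = P, o2 = o2)
}

attn_bwd <- function(cache, blk, h2, dout, bsz, l, nh, dh) {
  d <- ncol(h2)
  go <- dense_bwd(cache$o2, blk$out$W, dout)
  do3 <- as_3d(go$dx, bsz, l)
  dqkv3 <- array(0, c(bsz, l, 3L * d))
  scl <- 1 / sqrt(dh)
  for (ib in seq_len(bsz)) {
    for (m in seq_len(nh)) {
      cols <- (m - 1L) * dh + seq_len(dh)
      Q <- matrix(cache$qkv3[ib, , cols], l, dh)
      K <- matrix(cache$qkv3[ib, , d + cols], l, dh)
      V <- matrix(cache$qkv3[ib, , 2L * d + cols], l, dh)
      p <- cache$P[[ib]][[m]]
      dO <- matrix(do3[ib, , cols], l, dh)
      dV <- crossprod(p, dO)
      dp <- tcrossprod(dO, V)
      ds <- softmax_rows_bwd(p, dp) * scl
      dqkv3[ib, , cols] <- ds %*% K
      dqkv3[ib, , d + cols] <- crossprod(ds, Q)
      dqkv3[ib, , 2L * d + cols] <- dV
    }
  }
  gq <- dense_bwd(h2, blk$qkv$W, as_2d(dqkv3))
  list(dh2 = gq$dx,
       g = list(qkv = list(W = gq$dW, b = gq$db),
                out = list(W = go$dW, b = go$db)))
}

san_fwd <- function(params, x, spec) {
  bsz <- nrow(x); l <- ncol(x)
  d <- spec$d_model; nh <- spec$n_heads; dh <- d %/% nh
  x2 <- matrix(as.numeric(x), bsz * l, 1L)
  h0 <- dense_fwd(x2, params$inproj$W, params$inproj$b)
  pe <- sinusoidal_pe(l, d)
  h <- h0 + pe[rep(seq_len(l), each = bsz), ]
  blocks <- vector("list", spec$n_layers)
  for (i in seq_len(spec$n_layers)) {
    blk <- params[[paste0("block", i)]]
    ln1 <- layernorm_fwd(h, blk$ln1$g, blk$ln1$b)
    at <- attn_fwd(ln1$out, blk, bsz, l, nh, dh)
    h1 <- h + at$out
    ln2 <- layernorm_fwd(h1, blk$ln2$g, blk$ln2$b)
    f1 <- relu_fwd(dense_fwd(ln2$out, blk$ff1$W, blk$ff1$b))
    f2 <- dense_fwd(f1, blk$ff2$W, blk$ff2$b)
    blocks[[i]] <- list(h_in = h, ln1 = ln1, at = at, h1 = h1, ln2 = ln2, f1 = f1)
    h <- h1 + f2
  }
  lnf <- layernorm_fwd(h, params$lnf$g, params$lnf$b)
  hf <- as_3d(lnf$out, bsz, l)
  hl <- matrix(hf[, l, ], nrow = bsz)
  y <- dense_fwd(hl, params$head$W, params$head$b)
  list(yhat = drop(y),
       cache = list(blocks = blocks, lnf = lnf, hl = hl, bsz = bsz, l = l))
}

san_bwd <- function(params, cache, x, dy, spec) {
  bsz <- cache$bsz; l <- cache$l
  d <- spec$d_model; nh <- spec$n_heads; dh <- d %/% nh
  ghead <- dense_bwd(cache$hl, params$head$W, matrix(dy, ncol = 1L))
  dlnf_out <- matrix(0, bsz * l, d)
  dlnf_out[(l - 1L) * bsz + seq_len(bsz), ] <- ghead$dx
  glnf <- layernorm_bwd(cache$lnf, params$lnf$g, dlnf_out)
  dcur <- glnf$dx
  grads <- list(head = list(W = ghead$dW, b = ghead$db),
                lnf = list(g = glnf$dg, b = glnf$db))
  for (i in rev(seq_len(spec$n_layers))) {
    blk <- params[[paste0("block", i)]]
    cc <- cache$blocks[[i]]
    gf2 <- dense_bwd(cc$f1, blk$ff2$W, dcur)
    df1 <- relu_bwd(cc$f1, gf2$dx)
    gf1 <- dense_bwd(cc$ln2$out, blk$ff1$W, df1)
    gln2 <- layernorm_bwd(cc$ln2, blk$ln2$g, gf1$dx)
    dh1 <- dcur + gln2$dx
    gat <- attn_bwd(cc$at, blk, cc$ln1$out, dh1, bsz, l, nh, dh)
    gln1 <- layernorm_bwd(cc$ln1, blk$ln1$g, gat$dh2)
    grads[[paste0("block", i)]] <- c(
      list(ln1 = list(g = gln1$dg, b = gln1$db)),
      gat$g,
      list(ln2 = list(g = gln2$dg, b = gln2$db),
           ff1 = list(W = gf1$dW, b = gf1$db),
           ff2 = list(W = gf2$dW, b = gf2$db))
    )
    dcur <- dh1 + gln1$dx
  }
  ginp <- dense_bwd(matrix(as.numeric(x), bsz * l, 1L), params$inproj$W, dcur)
  grads$inproj <- list(W = ginp$dW, b = ginp$db)
  grads[names(params)]
}

# Dispatch table used by the training loop.
model_forward <- function(model, x) {
  switch(model$spec$architecture,
    FFN = ffn_fwd(model$params, x),
    CNN = cnn_fwd(model$params, x),
    TCN = tcn_fwd(model$params, x, model$spec),
    LSTM = lstm_fwd(model$params, x, model$spec),
    SAN = san_fwd(model$params, x, model$spec)
  )
}

model_backward <- function(model, cache, x, dy) {
  switch(model$spec$architecture,
    FFN = ffn_bwd(model$params, cache, x, dy),
    CNN = cnn_bwd(model$params, cache, x, dy),
    TCN = tcn_bwd(model$params, cache, x, dy, model$spec),
    LSTM = lstm_bwd(model$params, cache, x, dy, model$spec),
    SAN = san_bwd(model$params, cache, x, dy, model$spec)
  )
}

#' Analytic floating-point operation count for one inference
#'
#' Counts 2 x (multiply-accumulate) operations over all affine,
#' convolutional, recurrent and attention contractions for a single forward
#' pass on one window. Convolutions are counted at one kernel application
#' per timestep (padded-length convention) so the sequence-processing cost
#' is linear in the input length; pooling, activations and normalizations
#' contribute no multiply-accumulates. An affine map with `fi` inputs and
#' `fo` outputs costs `2 * fi * fo` (so a 24 to 1 map costs 48).
#'
#' @param model a built `cgm_model`.
#' @param input_length history length in steps; defaults to the spec's.
#' @return total FLOP count, with a `breakdown` attribute separating the
#'   length-dependent sequence cost from the fixed head cost.
#' @export
estimate_flops <- function(model, input_length = NULL) {
  spec <- model$spec
  l <- if (is.null(input_length)) spec$input_length else as.integer(input_length)
  mac <- function(fi, fo) fi * fo
  seq_macs <- 0; head_macs <- 0
  if (spec$architecture == "FFN") {
    dims <- c(1L, spec$hidden, 1L)
    seq_macs <- l * sum(dims[-length(dims)] * dims[-1L])
  } else if (spec$architecture == "CNN") {
    k <- spec$kernel; ch <- c(1L, spec$conv_channels)
    seq_macs <- l * k * ch[1] * ch[2] + (l %/% 2L) * k * ch[2] * ch[3]
    head_macs <- mac(spec$fc[1], spec$fc[2]) + mac(spec$fc[2], 1L)
  } else if (spec$architecture == "TCN") {
    k <- spec$kernel; ch <- c(1L, spec$channels)
    for (i in seq_along(spec$channels)) {
      seq_macs <- seq_macs + l * k * ch[i] * ch[i + 1L] + l * k * ch[i + 1L]^2
      if (ch[i] != ch[i + 1L]) seq_macs <- seq_macs + l * ch[i] * ch[i + 1L]
    }
    head_macs <- mac(spec$channels[length(spec$channels)], 1L)
  } else if (spec$architecture == "LSTM") {
    hs <- spec$hidden_units
    ins <- c(1L, hs[-length(hs)])
    seq_macs <- sum(l * 4 * hs * (ins + hs))
    head_macs <- mac(hs[length(hs)], 1L)
  } else if (spec$architecture == "SAN") {
    d <- spec$d_model
    per_block <- l * d * 3 * d + 2 * l * l * d + l * d * d +
      l * (d * spec$d_ff + spec$d_ff * d)
    seq_macs <- l * d + spec$n_layers * per_block
    head_macs <- mac(d, 1L)
  }
  structure(2 * (seq_macs + head_macs),
            breakdown = c(sequence = 2 * seq_macs, head = 2 * head_macs))
}

# ---- fused C++ path for the stacked LSTM (training hot path): one call
# computes forward, RMSE loss and all gradients without marshalling
# per-timestep caches through R.

lstm_pack_layers <- function(params, nlay) {
  lapply(seq_len(nlay), function(i) {
    lay <- params[[i]]
    list(Wi = lay$Wi, Wh = lay$Wh, b = lay$bi + lay$bh)
  })
}

lstm_net_step <- function(model, x, y = NULL) {
  nlay <- length(model$spec$hidden_units)
  res <- lstm_net_cpp(x, lstm_pack_layers(model$params, nlay),
                      model$params$head$W, model$params$head$b[1L], y)
  if (is.null(y)) return(list(yhat = drop(res$yhat)))
  grads <- vector("list", nlay + 1L)
  names(grads) <- names(model$params)
  for (i in seq_len(nlay)) {
    g <- res$layers[[i]]
    grads[[i]] <- list(Wi = g$dWi, Wh = g$dWh, bi = drop(g$db),
                       bh = drop(g$db))
  }
  grads$head <- list(W = res$dWhead, b = res$dbhead)
  list(yhat = drop(res$yhat), loss = res$loss, grads = grads)
}
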