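test_that("parameter counts match the architecture-determined values", {
  expect_identical(count_parameters(build_model(model_spec("FFN"), 1)), 2241L)
  expect_identical(count_parameters(build_model(model_spec("LSTM"), 1)), 11431L)
  expect_identical(count_parameters(build_model(model_spec("SAN"), 1)), 595457L)
  expect_gt(count_parameters(build_model(model_spec("CNN"), 1)), 0)
  expect_gt(count_parameters(build_model(model_spec("TCN"), 1)), 0)
})

test_that("initialization is deterministic given the seed", {
  for (a in c("FFN", "CNN", "TCN", "LSTM", "SAN")) {
    m1 <- build_model(model_spec(a), seed = 7)
    m2 <- build_model(model_spec(a), seed = 7)
    expect_identical(m1$params, m2$params)
    m3 <- build_model(model_spec(a), seed = 8)
    expect_false(identical(m1$params, m3$params))
  }
})

test_that("forward pass maps (b, L) input to length-b output", {
  set.seed(2)
  x <- matrix(rnorm(5 * 24), 5, 24)
  for (a in c("FFN", "CNN", "TCN", "LSTM", "SAN")) {
    y <- cgmbench:::model_forward(build_model(model_spec(a), 3), x)$yhat
    expect_length(y, 5)
    expect_true(all(is.finite(y)))
  }
})

test_that("zero-initialized FFN maps the zero window to zero", {
  m <- build_model(model_spec("FFN"), 1)
  m$params <- cgmbench:::map_params(function(p) p * 0, m$params)
  y <- cgmbench:::model_forward(m, matrix(0, 2, 24))$yhat
  expect_equal(y, c(0, 0))
})

test_that("unknown architectures and invalid specs are rejected", {
  expect_error(model_spec("GRU"))
  expect_error(model_spec("LSTM", dropout = 0.5), "dropout 0")
  expect_error(model_spec("SAN", d_model = 10, n_heads = 4), "divisible")
})

test_that("causal dilated convolutions never see the future", {
  set.seed(4)
  x <- array(rnorm(2 * 20 * 3), c(2, 20, 3))
  W <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  b <- rnorm(4)
  base <- cgmbench:::conv1d_fwd(x, W, b, dilation = 2L, pad = "causal")$out
  x2 <- x
  x2[, 11:20, ] <- x2[, 11:20, ] + 5   # perturb strictly after t = 10
  pert <- cgmbench:::conv1d_fwd(x2, W, b, dilation = 2L, pad = "causal")$out
  expect_equal(pert[, 1:10, ], base[, 1:10, ])
  expect_false(isTRUE(all.equal(pert[, 11:20, ], base[, 11:20, ])))

  # whole TCN: hidden state at position t is invariant to later inputs
  m <- build_model(model_spec("TCN", input_length = 24), 5)
  xm <- matrix(rnorm(3 * 24), 3, 24)
  h1 <- cgmbench:::model_forward(m, xm)$cache$h_final
  xm2 <- xm; xm2[, 15:24] <- 0
  h2 <- cgmbench:::model_forward(m, xm2)$cache$h_final
  expect_equal(h1[, 1:14, ], h2[, 1:14, ])
})

test_that("analytic gradients match finite differences for every architecture", {
  gradcheck <- function(spec, b = 3, n_checks = 40, tol = 1e-4) {
    m <- build_model(spec, seed = 3)
    L <- spec$input_length
    set.seed(9)
    x <- matrix(rnorm(b * L), b, L)
    y <- rnorm(b)
    lossf <- function(pv) {
      m2 <- m
      m2$params <- cgmbench:::unflatten_params(pv, m$params)
      yh <- cgmbench:::model_forward(m2, x)$yhat
      sqrt(mean((yh - y)^2))
    }
    fw <- cgmbench:::model_forward(m, x)
    err <- fw$yhat - y
    loss <- sqrt(mean(err^2))
    dy <- err / (length(err) * loss)
    gr <- cgmbench:::model_backward(m, fw$cache, x, dy)
    gv <- cgmbench:::flatten_params(gr[names(m$params)])
    pv <- cgmbench:::flatten_params(m$params)
    set.seed(11)
    idx <- sample(length(pv), min(n_checks, length(pv)))
    h <- 1e-6
    num <- vapply(idx, function(i) {
      p1 <- pv; p1[i] <- p1[i] + h
      p2 <- pv; p2[i] <- p2[i] - h
      (lossf(p1) - lossf(p2)) / (2 * h)
    }, 0)
    max(abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx])))
  }
  expect_lt(gradcheck(model_spec("FFN")), 1e-4)
  expect_lt(gradcheck(model_spec("CNN", conv_channels = c(4L, 6L),
                                 fc = c(6L, 5L), input_length = 12L)), 1e-4)
  expect_lt(gradcheck(model_spec("TCN", channels = c(3L, 4L, 5L),
                                 dilations = c(1L, 2L, 4L),
                                 input_length = 12L)), 1e-4)
  expect_lt(gradcheck(model_spec("LSTM", hidden_units = c(5L, 4L),
                                 input_length = 10L)), 1e-3)
  expect_lt(gradcheck(model_spec("SAN", d_model = 8L, n_heads = 2L,
                                 n_layers = 2L, d_ff = 12L,
                                 input_length = 8L)), 1e-4)
})

test_that("fused LSTM kernel agrees with the layer-by-layer path", {
  m <- build_model(model_spec("LSTM"), seed = 5)
  set.seed(1)
  x <- matrix(rnorm(7 * 24), 7, 24)
  y <- rnorm(7)
  layered <- cgmbench:::model_forward(m, x)
  fused <- cgmbench:::lstm_net_step(m, x, y)
  expect_equal(fused$yhat, layered$yhat, tolerance = 1e-12)
  err <- layered$yhat - y
  loss <- sqrt(mean(err^2))
  gr <- cgmbench:::model_backward(m, layered$cache, x,
                                  err / (length(err) * loss))
  expect_equal(fused$grads, gr[names(m$params)], tolerance = 1e-10)
  expect_equal(fused$loss, loss, tolerance = 1e-12)
})

test_that("one optimizer step reduces the batch loss for every architecture", {
  set.seed(6)
  x <- matrix(rnorm(8 * 24), 8, 24)
  y <- rnorm(8)
  for (a in c("FFN", "CNN", "TCN", "LSTM", "SAN")) {
    m <- build_model(model_spec(a), seed = 12)
    fw <- cgmbench:::model_forward(m, x)
    err <- fw$yhat - y
    loss0 <- sqrt(mean(err^2))
    gr <- cgmbench:::model_backward(m, fw$cache, x, err / (length(err) * loss0))
    gv <- cgmbench:::flatten_params(gr[names(m$params)])
    pv <- cgmbench:::flatten_params(m$params)
    m$params <- cgmbench:::unflatten_params(pv - 1e-3 * gv, m$params)
    loss1 <- sqrt(mean((cgmbench:::model_forward(m, x)$yhat - y)^2))
    expect_lt(loss1, loss0)
  }
})

test_that("FLOP estimates follow the documented per-layer formulas", {
  ffn <- build_model(model_spec("FFN"), 1)
  # per-timestep stack 1-32-64-1 over 24 steps: 24 * 2 * (32 + 2048 + 64)
  expect_equal(as.numeric(estimate_flops(ffn)), 102912)
  lstm <- build_model(model_spec("LSTM"), 1)
  bd <- attr(estimate_flops(lstm), "breakdown")
  expect_equal(unname(bd["head"]), 2 * 30)  # affine 30 -> 1
  # doubling input length doubles sequence cost, not the head cost
  for (a in c("CNN", "TCN", "LSTM")) {
    m <- build_model(model_spec(a), 1)
    f1 <- attr(estimate_flops(m, 24), "breakdown")
    f2 <- attr(estimate_flops(m, 48), "breakdown")
    expect_equal(unname(f2["sequence"]), 2 * unname(f1["sequence"]))
    expect_equal(unname(f2["head"]), unname(f1["head"]))
  }
})
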