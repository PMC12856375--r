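# The compiled convolution/pooling kernels are checked against independent
# R oracles (direct triple-loop convolution, plain R pooling) on tiny
# inputs, and the full backward pass is checked by finite differences.

# direct 3-D convolution oracle: valid region of a zero-padded input
conv3d_oracle <- function(vol4, W, b, k, pad) {
  cin <- dim(vol4)[4]
  d <- dim(vol4)[1:3] + 2L * pad
  padded <- array(0, c(d, cin))
  padded[pad + seq_len(dim(vol4)[1]), pad + seq_len(dim(vol4)[2]),
         pad + seq_len(dim(vol4)[3]), ] <- vol4
  od <- d - k + 1L
  cout <- nrow(W)
  out <- array(0, c(od, cout))
  for (co_i in seq_len(cout)) {
    Wk <- array(W[co_i, ], c(k, k, k, cin))
    for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (l in seq_len(od[3])) {
      patch <- padded[i:(i + k - 1), j:(j + k - 1), l:(l + k - 1), ]
      out[i, j, l, co_i] <- sum(patch * Wk) + b[co_i]
    }
  }
  out
}

test_that("compiled convolution matches the direct-loop oracle", {
  set.seed(5)
  for (case in list(list(k = 2L, pad = 0L, cin = 2L, cout = 3L, g = 4L),
                    list(k = 3L, pad = 1L, cin = 3L, cout = 2L, g = 5L))) {
    layer <- dmnfuse:::layer_conv3d(case$cin, case$cout, case$k, case$pad)
    vol <- array(rnorm(case$g^3 * case$cin), c(rep(case$g, 3), case$cin))
    x <- matrix(as.vector(vol), ncol = 1)
    attr(x, "dim_in") <- rep(case$g, 3L)
    got <- layer$fwd(x, training = FALSE)
    want <- conv3d_oracle(vol, layer$W, layer$b, case$k, case$pad)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-10)
  }
})

test_that("compiled max-pool matches a plain R oracle", {
  set.seed(6)
  g <- 7L
  vol <- array(rnorm(g^3 * 2), c(g, g, g, 2))
  layer <- dmnfuse:::layer_maxpool3d(3L, 2L)
  x <- matrix(as.vector(vol), ncol = 1)
  attr(x, "dim_in") <- rep(g, 3L)
  got <- layer$fwd(x, training = FALSE)
  od <- (g - 3L) %/% 2L + 1L
  want <- array(0, c(od, od, od, 2))
  for (c_i in 1:2) for (i in seq_len(od)) for (j in seq_len(od)) for (l in seq_len(od)) {
    want[i, j, l, c_i] <- max(vol[(2 * i - 1):(2 * i + 1),
                                  (2 * j - 1):(2 * j + 1),
                                  (2 * l - 1):(2 * l + 1), c_i])
  }
  expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
})

test_that("pooling on a grid smaller than the window passes through", {
  layer <- dmnfuse:::layer_maxpool3d(3L, 2L)
  x <- matrix(rnorm(2^3 * 3), ncol = 1)
  attr(x, "dim_in") <- c(2L, 2L, 2L)
  out <- layer$fwd(x, training = TRUE)
  expect_equal(as.vector(out), as.vector(x))
  expect_equal(as.vector(layer$bwd(out)), as.vector(out))
})

test_that("backward pass agrees with finite differences through the whole net", {
  set.seed(42)
  grid <- c(12, 12, 12); B <- 2
  x <- matrix(rnorm(prod(grid) * 4 * B), prod(grid) * 4, B)
  attr(x, "dim_in") <- grid
  cl <- matrix(runif(6 * B), 6, B)
  y <- c(1, 0)
  m <- build_model(model_config(dropout = 0), seed = 9)  # deterministic loss
  p <- model_forward(m, x, cl, training = TRUE)
  dz <- matrix((p - y) / length(y), nrow = 1)
  dh <- dmnfuse:::seq_backward(m$head, dz, need_input_grad = TRUE)
  dmnfuse:::seq_backward(m$extractor, dh[1:64, , drop = FALSE],
                         need_input_grad = FALSE)
  learn <- dmnfuse:::collect_learnable(c(m$extractor, m$head))
  eps <- 1e-5
  for (l in learn) {
    gv <- l$grads()[[1]]
    ix <- order(-abs(gv))[1]   # strongest-gradient entry of each layer
    pl <- l$params()
    pl[[1]][ix] <- pl[[1]][ix] + eps; l$set_params(pl)
    lp <- bce_loss(model_forward(m, x, cl, training = TRUE), y)
    pl[[1]][ix] <- pl[[1]][ix] - 2 * eps; l$set_params(pl)
    lm <- bce_loss(model_forward(m, x, cl, training = TRUE), y)
    pl[[1]][ix] <- pl[[1]][ix] + eps; l$set_params(pl)
    g_num <- (lp - lm) / (2 * eps)
    expect_equal(gv[ix], g_num, tolerance = 1e-4)
  }
})

test_that("adam reduces the loss on a separable toy batch", {
  set.seed(3)
  lin <- dmnfuse:::layer_linear(4L, 1L)
  x <- matrix(rnorm(4 * 40), 4, 40)
  y <- as.numeric(x[1, ] > 0)
  opt <- dmnfuse:::adam_state(list(lin), lr = 0.05)
  loss_at <- function() {
    p <- 1 / (1 + exp(-as.vector(lin$fwd(x, TRUE))))
    bce_loss(p, y)
  }
  l0 <- loss_at()
  for (i in 1:100) {
    p <- 1 / (1 + exp(-as.vector(lin$fwd(x, TRUE))))
    lin$bwd(matrix((p - y) / length(y), 1), need_dx = FALSE)
    opt <- dmnfuse:::adam_step(opt)
  }
  expect_lt(loss_at(), l0 / 2)
})
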