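# Native neural-network primitives.
#
# No deep-learning framework is available to the package, so the 3D CNN is
# built directly on BLAS: convolutions are im2col gathers followed by a GEMM,
# their input gradient is a sparse col2im scatter (Matrix), and every layer
# carries an explicit backward pass. Tensors use one fixed layout throughout:
# a sample volume is vec(array(D, H, W, C)) — voxel-fastest, channels blocked
# — and a batch is a matrix with one sample per column. Feature vectors are
# (features x batch) matrices.

# ---- layout helpers --------------------------------------------------------

# channel-first (C,D,H,W) array -> flat sample vector in internal layout
stack_to_input <- function(stack) {
  as.vector(aperm(stack, c(2, 3, 4, 1)))
}

input_to_stack <- function(x, dim_in, channels) {
  aperm(array(x, c(dim_in, channels)), c(4, 1, 2, 3))
}

# patch offsets within a padded flat volume for a k^3 window over Cin channels
.conv_offsets <- function(pdim, cin, k) {
  kd <- seq_len(k) - 1L
  spatial <- as.vector(outer(outer(kd, kd * pdim[1], "+"),
                             kd * pdim[1] * pdim[2], "+"))
  chan <- (seq_len(cin) - 1L) * prod(pdim)
  as.vector(outer(spatial, chan, "+"))
}

# flat base index of each output position in the padded input volume
.conv_bases <- function(pdim, odim, stride = 1L) {
  od <- (seq_len(odim[1]) - 1L) * stride
  oh <- (seq_len(odim[2]) - 1L) * stride * pdim[1]
  ow <- (seq_len(odim[3]) - 1L) * stride * pdim[1] * pdim[2]
  as.vector(outer(outer(od, oh, "+"), ow, "+"))
}

# ---- layers ----------------------------------------------------------------
# Each layer is an environment with fwd(x, training), bwd(dy, need_dx),
# and optional params()/set_params() for learnables.

layer_conv3d <- function(cin, cout, k, pad = 0L) {
  self <- new.env(parent = emptyenv())
  self$type <- "conv3d"
  self$cin <- cin; self$cout <- cout; self$k <- as.integer(k)
  self$pad <- as.integer(pad)
  fan_in <- cin * k^3
  bound <- 1 / sqrt(fan_in)
  self$W <- matrix(runif(cout * fan_in, -bound, bound), cout, fan_in)
  self$b <- runif(cout, -bound, bound)
  self$cache <- NULL
  self$geom <- NULL   # per-input-shape gather geometry

  self$prepare <- function(dim_in) {
    key <- paste(dim_in, collapse = "x")
    if (!is.null(self$geom) && identical(self$geom$key, key)) return(self$geom)
    pdim <- dim_in + 2L * self$pad
    odim <- pdim - self$k + 1L
    if (any(odim < 1L)) {
      .err("dmnfuse_shape_error", "conv input ", paste(dim_in, collapse = "x"),
           " smaller than kernel ", self$k, " (minimum spatial size ",
           self$k - 2L * self$pad, ")")
    }
    inner <- NULL
    if (self$pad > 0L) {
      keep <- array(FALSE, c(pdim, self$cin))
      keep[(self$pad + 1):(self$pad + dim_in[1]),
           (self$pad + 1):(self$pad + dim_in[2]),
           (self$pad + 1):(self$pad + dim_in[3]), ] <- TRUE
      inner <- which(keep)
    }
    self$geom <- list(key = key, dim_in = dim_in, pdim = pdim, odim = odim,
                      npad = as.integer(prod(pdim) * self$cin),
                      nout = prod(odim),
                      off = as.integer(.conv_offsets(pdim, self$cin, self$k)),
                      base = as.integer(.conv_bases(pdim, odim)),
                      inner = inner)
    self$geom
  }

  self$fwd <- function(x, training) {
    g <- self$prepare(attr(x, "dim_in"))
    B <- ncol(x)
    xp <- if (self$pad > 0L) {
      tmp <- matrix(0, g$npad, B); tmp[g$inner, ] <- x; tmp
    } else x
    out <- cpp_conv_fwd(xp, self$W, self$b, g$off, g$base)
    self$cache <- if (training) list(xp = xp) else NULL
    attr(out, "dim_in") <- g$odim
    out
  }

  self$bwd <- function(dy, need_dx = TRUE) {
    g <- self$geom; cc <- self$cache
    res <- cpp_conv_bwd(cc$xp, dy, self$W, g$off, g$base, need_dx)
    self$dW <- res$dW
    self$db <- as.vector(res$db)
    if (!need_dx) return(NULL)
    dx <- if (self$pad > 0L) res$dxp[g$inner, , drop = FALSE] else res$dxp
    attr(dx, "dim_in") <- g$dim_in
    dx
  }

  self$params <- function() list(W = self$W, b = self$b)
  self$grads <- function() list(W = self$dW, b = self$db)
  self$set_params <- function(p) { self$W <- p$W; self$b <- p$b }
  self
}

layer_maxpool3d <- function(k = 3L, stride = 2L) {
  self <- new.env(parent = emptyenv())
  self$type <- "maxpool3d"
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$fwd <- function(x, training) {
    dim_in <- attr(x, "dim_in")
    chans <- nrow(x) / prod(dim_in)
    if (any(dim_in < self$k)) {
      # grid too small for the pool window: pass through unchanged
      self$cache <- list(skip = TRUE)
      return(x)
    }
    key <- paste(c(dim_in, chans), collapse = "x")
    if (is.null(self$geom) || !identical(self$geom$key, key)) {
      odim <- (dim_in - self$k) %/% self$stride + 1L
      kd <- seq_len(self$k) - 1L
      off <- as.vector(outer(outer(kd, kd * dim_in[1], "+"),
                             kd * dim_in[1] * dim_in[2], "+"))
      sp_base <- .conv_bases(dim_in, odim, self$stride)
      base <- as.vector(outer(sp_base, (seq_len(chans) - 1L) * prod(dim_in),
                              "+"))
      self$geom <- list(key = key, odim = odim,
                        off = as.integer(off), base = as.integer(base))
    }
    g <- self$geom
    res <- cpp_maxpool_fwd(x, g$off, g$base)
    self$cache <- list(skip = FALSE, wm = res$wm, n_in = nrow(x))
    out <- res$y
    attr(out, "dim_in") <- g$odim
    out
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    cc <- self$cache
    if (cc$skip) return(dy)
    cpp_maxpool_bwd(dy, cc$wm, self$geom$off, self$geom$base, cc$n_in)
  }
  self
}

layer_globalmaxpool <- function() {
  self <- new.env(parent = emptyenv())
  self$type <- "globalmaxpool"
  self$fwd <- function(x, training) {
    dim_in <- attr(x, "dim_in")
    nvox <- prod(dim_in)
    chans <- nrow(x) / nvox
    res <- cpp_globalmax_fwd(x, nvox, chans)
    self$cache <- list(wm = res$wm, nvox = nvox, chans = chans)
    res$y    # feature matrix: one 64-vector per column
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    cc <- self$cache
    cpp_globalmax_bwd(dy, cc$wm, cc$nvox, cc$chans)
  }
  self
}

layer_relu <- function() {
  self <- new.env(parent = emptyenv())
  self$type <- "relu"
  self$fwd <- function(x, training) {
    self$cache <- x > 0
    y <- x * self$cache
    attr(y, "dim_in") <- attr(x, "dim_in")
    y
  }
  self$bwd <- function(dy, need_dx = TRUE) dy * self$cache
  self
}

layer_linear <- function(n_in, n_out) {
  self <- new.env(parent = emptyenv())
  self$type <- "linear"
  bound <- 1 / sqrt(n_in)
  self$W <- matrix(runif(n_out * n_in, -bound, bound), n_out, n_in)
  self$b <- runif(n_out, -bound, bound)
  self$fwd <- function(x, training) {
    self$cache <- x
    self$W %*% x + self$b
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    self$dW <- tcrossprod(dy, self$cache)
    self$db <- rowSums(dy)
    if (need_dx) crossprod(self$W, dy) else NULL
  }
  self$params <- function() list(W = self$W, b = self$b)
  self$grads <- function() list(W = self$dW, b = self$db)
  self$set_params <- function(p) { self$W <- p$W; self$b <- p$b }
  self
}

layer_batchnorm <- function(n, momentum = 0.1, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$type <- "batchnorm"
  self$gamma <- rep(1, n); self$beta <- rep(0, n)
  self$r_mean <- rep(0, n); self$r_var <- rep(1, n)
  self$momentum <- momentum; self$eps <- eps
  self$fwd <- function(x, training) {
    if (training && ncol(x) > 1L) {
      mu <- rowMeans(x)
      v <- rowMeans((x - mu)^2)
      self$r_mean <- (1 - self$momentum) * self$r_mean + self$momentum * mu
      self$r_var <- (1 - self$momentum) * self$r_var + self$momentum * v
      inv <- 1 / sqrt(v + self$eps)
      xhat <- (x - mu) * inv
      self$cache <- list(xhat = xhat, inv = inv)
      self$gamma * xhat + self$beta
    } else {
      xhat <- (x - self$r_mean) / sqrt(self$r_var + self$eps)
      self$cache <- list(xhat = xhat, inv = 1 / sqrt(self$r_var + self$eps))
      self$gamma * xhat + self$beta
    }
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    cc <- self$cache
    self$dgamma <- rowSums(dy * cc$xhat)
    self$dbeta <- rowSums(dy)
    if (!need_dx) return(NULL)
    dxhat <- dy * self$gamma
    cc$inv * (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
  }
  self$params <- function() list(gamma = self$gamma, beta = self$beta)
  self$grads <- function() list(gamma = self$dgamma, beta = self$dbeta)
  self$set_params <- function(p) { self$gamma <- p$gamma; self$beta <- p$beta }
  self
}

layer_dropout <- function(p) {
  self <- new.env(parent = emptyenv())
  self$type <- "dropout"
  self$p <- p
  self$fwd <- function(x, training) {
    if (!training || self$p == 0) { self$cache <- NULL; return(x) }
    mask <- (matrix(runif(length(x)), nrow(x)) >= self$p) / (1 - self$p)
    self$cache <- mask
    x * mask
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    if (is.null(self$cache)) dy else dy * self$cache
  }
  self
}

# ---- sequential plumbing ---------------------------------------------------

seq_forward <- function(layers, x, training) {
  for (l in layers) x <- l$fwd(x, training)
  x
}

seq_backward <- function(layers, dy, need_input_grad = FALSE) {
  n <- length(layers)
  for (i in rev(seq_len(n))) {
    need <- need_input_grad || i > 1L
    dy <- layers[[i]]$bwd(dy, need_dx = need)
  }
  dy
}

collect_learnable <- function(layers) {
  Filter(function(l) !is.null(l$params), layers)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(layers, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  learn <- collect_learnable(layers)
  st <- lapply(learn, function(l) lapply(l$params(), function(p) {
    list(m = p * 0, v = p * 0)
  }))
  list(layers = learn, state = st, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    ps <- l$params(); gs <- l$grads()
    for (nm in names(ps)) {
      s <- opt$state[[i]][[nm]]
      s$m <- opt$beta1 * s$m + (1 - opt$beta1) * gs[[nm]]
      s$v <- opt$beta2 * s$v + (1 - opt$beta2) * gs[[nm]]^2
      ps[[nm]] <- ps[[nm]] - opt$lr * (s$m / bc1) / (sqrt(s$v / bc2) + opt$eps)
      opt$state[[i]][[nm]] <- s
    }
    l$set_params(ps)
  }
  opt
}
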