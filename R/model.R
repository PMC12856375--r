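#' Model architecture configuration
#'
#' The network splits into a convolutional feature extractor and a linear
#' classification head. The extractor chains six 3-D convolutions
#' (4->8->16->24->24->32->64 channels; first kernel 6^3 unpadded, the rest
#' 3^3 with padding 1, all stride 1) with ReLU activations and 3^3/stride-2
#' max-pools after convolutions 1-5; a pool is skipped whenever the spatial
#' grid has shrunk below the pool window, and a final global max-pool
#' collapses any remaining grid so the extractor always emits exactly
#' `feature_dim = 64` values. In multimodal mode the 6 normalized clinical
#' scores are concatenated to these 64 features, giving the head's first
#' linear layer 70 inputs (64 in unimodal mode); the head is
#' linear -> batch-norm -> ReLU -> dropout -> linear -> sigmoid.
#'
#' @param mode `"multimodal"` (images + clinical) or `"unimodal"` (images
#'   only).
#' @param n_channels image channels, one per ROI.
#' @param clinical_dim number of clinical scores fused in multimodal mode.
#' @param conv_channels output channels of the six convolution layers.
#' @param kernels per-layer kernel sizes.
#' @param pads per-layer symmetric zero-padding.
#' @param pool_after indices of conv layers followed by a max-pool.
#' @param hidden_dim width of the head's hidden linear layer.
#' @param dropout dropout probability on the head's hidden activations.
#' @return Object of class `dmn_model_config`.
#' @export
model_config <- function(mode = c("multimodal", "unimodal"),
                         n_channels = 4L,
                         clinical_dim = 6L,
                         conv_channels = c(8L, 16L, 24L, 24L, 32L, 64L),
                         kernels = c(6L, 3L, 3L, 3L, 3L, 3L),
                         pads = c(0L, 1L, 1L, 1L, 1L, 1L),
                         pool_after = 1:5,
                         hidden_dim = 32L,
                         dropout = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(conv_channels) == length(kernels),
            length(kernels) == length(pads),
            dropout >= 0, dropout < 1)
  structure(list(mode = mode, n_channels = as.integer(n_channels),
                 clinical_dim = as.integer(clinical_dim),
                 conv_channels = as.integer(conv_channels),
                 kernels = as.integer(kernels), pads = as.integer(pads),
                 pool_after = as.integer(pool_after),
                 feature_dim = as.integer(conv_channels[length(conv_channels)]),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout),
            class = "dmn_model_config")
}

#' Head input width implied by a model configuration
#'
#' 64 extracted image features plus, in multimodal mode, the clinical
#' scores: 70 by default.
#'
#' @param config a `dmn_model_config`.
#' @return Integer input width of the first linear layer.
#' @export
head_input_dim <- function(config) {
  config$feature_dim +
    if (config$mode == "multimodal") config$clinical_dim else 0L
}

#' Instantiate a model with seeded fan-in initialization
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return Object of class `dmn_model` holding the extractor and head layer
#'   stacks.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    extractor <- list()
    cin <- config$n_channels
    for (i in seq_along(config$conv_channels)) {
      extractor <- c(extractor,
                     list(layer_conv3d(cin, config$conv_channels[i],
                                       config$kernels[i], config$pads[i]),
                          layer_relu()))
      if (i %in% config$pool_after) {
        extractor <- c(extractor, list(layer_maxpool3d(3L, 2L)))
      }
      cin <- config$conv_channels[i]
    }
    extractor <- c(extractor, list(layer_globalmaxpool()))
    head <- list(layer_linear(head_input_dim(config), config$hidden_dim),
                 layer_batchnorm(config$hidden_dim),
                 layer_relu(),
                 layer_dropout(config$dropout),
                 layer_linear(config$hidden_dim, 1L))
    structure(list(config = config, extractor = extractor, head = head),
              class = "dmn_model")
  })
}

#' Extract the 64 image features for a batch
#'
#' Runs the convolutional extractor only. Output dimensionality is fixed at
#' `feature_dim` (64) by the global pooling stage for any input grid the
#' first convolution accepts.
#'
#' @param model a `dmn_model`.
#' @param x input matrix (flattened volumes x batch) carrying a `dim_in`
#'   attribute, as produced by [batch_images()].
#' @param training logical; enables caching for backprop.
#' @return `feature_dim` x batch matrix.
#' @export
extract_features <- function(model, x, training = FALSE) {
  seq_forward(model$extractor, x, training)
}

#' Assemble a batch matrix from bundles
#'
#' @param bundles list of `dmn_bundle`s sharing one grid shape.
#' @return List with `x` (flattened image matrix with `dim_in` attribute),
#'   `clinical` (clinical_dim x batch matrix) and `y` (0/1 labels).
#' @export
batch_images <- function(bundles) {
  d <- dim(bundles[[1]]$image_stack)
  x <- vapply(bundles, function(b) {
    if (!identical(dim(b$image_stack), d)) {
      .err("dmnfuse_shape_error", "bundles differ in image shape")
    }
    stack_to_input(b$image_stack)
  }, numeric(prod(d)))
  dim(x) <- c(prod(d), length(bundles))
  attr(x, "dim_in") <- d[2:4]
  cl <- vapply(bundles, function(b) as.numeric(b$clinical),
               numeric(length(bundles[[1]]$clinical)))
  dim(cl) <- c(length(bundles[[1]]$clinical), length(bundles))
  list(x = x, clinical = cl,
       y = vapply(bundles, function(b) as.numeric(b$label), numeric(1)))
}

#' Forward pass: probability of AD
#'
#' Extracts image features, concatenates the normalized clinical scores in
#' multimodal mode, and applies the linear head with a sigmoid output.
#'
#' @param model a `dmn_model`.
#' @param x flattened image batch (see [batch_images()]).
#' @param clinical clinical_dim x batch matrix; ignored in unimodal mode.
#' @param training logical; training-mode batch-norm/dropout and gradient
#'   caching.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
model_forward <- function(model, x, clinical = NULL, training = FALSE) {
  feats <- seq_forward(model$extractor, x, training)
  if (model$config$mode == "multimodal") {
    if (is.null(clinical) || nrow(clinical) != model$config$clinical_dim) {
      .err("dmnfuse_shape_error", "multimodal mode needs a ",
           model$config$clinical_dim, "-row clinical matrix")
    }
    h <- rbind(feats, clinical)
  } else {
    h <- feats
  }
  z <- seq_forward(model$head, h, training)
  1 / (1 + exp(-as.vector(z)))
}

#' Forward a single bundle in evaluation mode
#'
#' @param model a `dmn_model`.
#' @param bundle a `dmn_bundle`.
#' @return Scalar probability of AD.
#' @export
predict_bundle <- function(model, bundle) {
  bt <- batch_images(list(bundle))
  model_forward(model, bt$x, bt$clinical, training = FALSE)
}

#' Binary cross-entropy loss
#'
#' `-[y log p + (1 - y) log(1 - p)]`, with probabilities clamped to
#' `[1e-7, 1 - 1e-7]` so the loss stays finite; mean over the batch.
#'
#' @param prob numeric probabilities in (0, 1).
#' @param label 0/1 labels.
#' @return Scalar mean loss.
#' @export
bce_loss <- function(prob, label) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  mean(-(label * log(p) + (1 - label) * log(1 - p)))
}

#' Calibrate batch-norm statistics on the training set
#'
#' With few optimization steps the exponentially averaged running statistics
#' of the batch-norm layers are still dominated by their initialization, so
#' held-out evaluation would normalize with the wrong moments. This runs one
#' forward pass over the (unaugmented) training batch and sets the running
#' statistics to that batch's exact moments — the population statistics the
#' evaluation-mode layer is meant to estimate. Dropout is disabled for the
#' pass and no RNG is consumed.
#'
#' @param model a trained `dmn_model`.
#' @param x,clinical the training batch (see [batch_images()]).
#' @return The model, invisibly (layers are environments, updated in
#'   place).
#' @export
calibrate_batchnorm <- function(model, x, clinical = NULL) {
  layers <- c(model$extractor, model$head)
  bn <- Filter(function(l) identical(l$type, "batchnorm"), layers)
  drop <- Filter(function(l) identical(l$type, "dropout"), layers)
  old_p <- lapply(drop, function(l) l$p)
  old_mom <- lapply(bn, function(l) l$momentum)
  for (l in drop) l$p <- 0
  for (l in bn) l$momentum <- 1
  model_forward(model, x, clinical, training = TRUE)
  for (i in seq_along(drop)) drop[[i]]$p <- old_p[[i]]
  for (i in seq_along(bn)) bn[[i]]$momentum <- old_mom[[i]]
  invisible(model)
}

# one optimization step on a batch; returns the batch loss.
# gradient of mean BCE wrt the pre-sigmoid logit is (p - y)/B.
train_step <- function(model, opt, x, clinical, y) {
  p <- model_forward(model, x, clinical, training = TRUE)
  loss <- bce_loss(p, y)
  dz <- matrix((p - y) / length(y), nrow = 1)
  dh <- seq_backward(model$head, dz, need_input_grad = TRUE)
  dfeat <- dh[seq_len(model$config$feature_dim), , drop = FALSE]
  seq_backward(model$extractor, dfeat, need_input_grad = FALSE)
  list(opt = adam_step(opt), loss = loss)
}

#' Number of learnable parameters
#'
#' @param model a `dmn_model`.
#' @return Integer count over extractor and head.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_learnable(c(model$extractor, model$head)),
             function(l) sum(lengths(l$params())), numeric(1)))
}
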