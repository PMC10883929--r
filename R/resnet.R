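# Residual-network feature branch with the classification head removed.
#
# Each residual block computes H_i = H_{i-1} + F(H_{i-1}) where F is a
# small stack of convolutions with batch normalisation (projection shortcut
# when width or stride changes). The stem follows the hyperparameter table:
# 3x3 stride-1 convolution, 64 initial filters, 3x3 stride-2 max pooling.
# Features are the global-average-pooled channel vector; no dense layer
# follows.

#' Residual branch configuration
#'
#' `depth = 18` selects basic blocks (2,2,2,2) with widths 64/128/256/512
#' (feature dimension 512); `depth = 50` selects bottleneck blocks
#' (3,4,6,3) with output widths 256/512/1024/2048 (feature dimension 2048).
#' `blocks_per_stage` and `stage_channels` override both for reduced
#' desk-scale builds.
#'
#' @param depth 18 or 50
#' @param initial_filters stem width (default 64)
#' @param blocks_per_stage,stage_channels explicit stage layout (optional)
#' @param block `"basic"` or `"bottleneck"`
#' @param in_channels input image channels
#' @param input_size input image side length
#' @param bn_momentum,bn_epsilon batch-norm hyperparameters
#' @param dropout dropout rate used before the optional standalone
#'   classifier (midpoint of the 0.2-0.5 range)
#' @param weight_decay default L2 regularisation strength
#' @export
resnet_config <- function(depth = 18L, initial_filters = 64L,
                          blocks_per_stage = NULL, stage_channels = NULL,
                          block = NULL, in_channels = 3L, input_size = 224L,
                          bn_momentum = 0.1, bn_epsilon = 1e-5,
                          dropout = 0.35, weight_decay = 1e-4) {
  if (is.null(blocks_per_stage)) {
    if (depth == 18L) {
      blocks_per_stage <- c(2L, 2L, 2L, 2L)
      stage_channels <- c(64L, 128L, 256L, 512L)
      block <- "basic"
    } else if (depth == 50L) {
      blocks_per_stage <- c(3L, 4L, 6L, 3L)
      stage_channels <- c(256L, 512L, 1024L, 2048L)
      block <- "bottleneck"
    } else {
      stop("depth must be 18 or 50 unless blocks_per_stage is given")
    }
  }
  if (is.null(block)) block <- "basic"
  stopifnot(length(blocks_per_stage) == length(stage_channels))
  structure(list(depth = depth, initial_filters = as.integer(initial_filters),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 stage_channels = as.integer(stage_channels),
                 block = block, in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 bn_momentum = bn_momentum, bn_epsilon = bn_epsilon,
                 dropout = dropout, weight_decay = weight_decay,
                 feature_dim = stage_channels[length(stage_channels)]),
            class = "resnet_config")
}

nn_resblock <- function(in_ch, out_ch, stride = 1L, block = "basic",
                        bn_momentum = 0.1, bn_eps = 1e-5) {
  bn <- function(c) nn_batchnorm2d(c, bn_momentum, bn_eps)
  if (block == "basic") {
    fpath <- nn_seq(nn_conv2d(in_ch, out_ch, 3L, stride), bn(out_ch),
                    nn_relu(),
                    nn_conv2d(out_ch, out_ch, 3L, 1L), bn(out_ch))
  } else {
    mid <- max(1L, out_ch %/% 4L)
    fpath <- nn_seq(nn_conv2d(in_ch, mid, 1L, 1L), bn(mid), nn_relu(),
                    nn_conv2d(mid, mid, 3L, stride), bn(mid), nn_relu(),
                    nn_conv2d(mid, out_ch, 1L, 1L), bn(out_ch))
  }
  proj <- if (stride != 1L || in_ch != out_ch) {
    nn_seq(nn_conv2d(in_ch, out_ch, 1L, stride, bias = FALSE), bn(out_ch))
  }
  children <- c(list(fpath), if (!is.null(proj)) list(proj))
  self <- environment()
  forward <- function(x, train = FALSE) {
    fx <- fpath$forward(x, train)
    idn <- if (is.null(proj)) x else proj$forward(x, train)
    fx + idn
  }
  backward <- function(dout) {
    dx <- fpath$backward(dout)
    dx + if (is.null(proj)) dout else proj$backward(dout)
  }
  nn_finalize(self, "nn_resblock")
}

#' Build the residual feature branch
#'
#' Stem (3x3 stride-1 convolution, batch norm, ReLU, 3x3 stride-2 max
#' pool), the configured residual stages (first block of each later stage
#' downsamples with a projection shortcut), and a global average pool.
#' There is no classification layer: the output is the feature vector.
#'
#' @param cfg a [resnet_config()]
#' @return an nn module; use [resnet_features()] to run it
#' @export
build_resnet <- function(cfg = resnet_config()) {
  stem <- nn_seq(nn_conv2d(cfg$in_channels, cfg$initial_filters, 3L, 1L),
                 nn_batchnorm2d(cfg$initial_filters, cfg$bn_momentum,
                                cfg$bn_epsilon),
                 nn_relu(),
                 nn_maxpool2d(3L, 2L, 1L))
  blocks <- list()
  in_ch <- cfg$initial_filters
  for (s in seq_along(cfg$stage_channels)) {
    out_ch <- cfg$stage_channels[s]
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[length(blocks) + 1L]] <-
        nn_resblock(in_ch, out_ch, stride, cfg$block,
                    cfg$bn_momentum, cfg$bn_epsilon)
      in_ch <- out_ch
    }
  }
  pool <- nn_gap()
  children <- c(list(stem), blocks, list(pool))
  feature_dim <- cfg$feature_dim
  self <- environment()
  forward <- function(x, train = FALSE) {
    x <- stem$forward(x, train)
    for (b in blocks) x <- b$forward(x, train)
    pool$forward(x, train)
  }
  backward <- function(dout) {
    dout <- pool$backward(dout)
    for (b in rev(blocks)) dout <- b$backward(dout)
    stem$backward(dout)
  }
  nn_finalize(self, "resnet_branch")
}

#' Run one residual block
#' @param x `[H, W, C]` feature map
#' @param block an `nn_resblock`
#' @export
residual_block_forward <- function(x, block) {
  .internal_to_hwc(block$forward(.hwc_to_internal(x)))
}

#' Residual-branch feature vector for an image
#'
#' Stem, residual stages, global average pool, flatten; no classifier.
#' @param image `[H, W, C]` image tensor
#' @param net output of [build_resnet()]
#' @return feature vector of length `cfg$feature_dim`
#' @export
resnet_features <- function(image, net) {
  as.vector(net$forward(.hwc_to_internal(image)))
}
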