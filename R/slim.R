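# The "slim" convolutional patch-embedding stem: four multibranch stages
# with squeeze-and-excitation channel attention, then a pointwise
# channel-expansion convolution. Each stage computes
#
#   O(x) = F_s2(x) + L_s2(x)                    (stride-2 3x3 and 1x1 branches)
#   H(x) = SE[ F_s1(O) + L_s1(O) + O ]          (stride-1 branches + identity)
#
# so the spatial size halves exactly once per stage: 224 -> 112 -> 56 ->
# 28 -> 14 at the default configuration, with stage channels 48/96/192/384
# and a final 1x1 expansion to 768.

#' Slim stem configuration
#'
#' @param stage_channels output channels of the four stages
#' @param final_channels channels after the final 1x1 expansion (the
#'   transformer embedding width)
#' @param input_size input image side length; must be divisible by 16
#' @param in_channels input image channels
#' @param se_reduction squeeze-and-excitation bottleneck ratio r
#' @export
slim_config <- function(stage_channels = c(48L, 96L, 192L, 384L),
                        final_channels = 768L, input_size = 224L,
                        in_channels = 3L, se_reduction = 16L) {
  stopifnot(length(stage_channels) == 4L,
            input_size %% 2L^length(stage_channels) == 0L,
            se_reduction >= 1L)
  structure(list(stage_channels = as.integer(stage_channels),
                 final_channels = as.integer(final_channels),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 se_reduction = as.integer(se_reduction)),
            class = "slim_config")
}

# squeeze-and-excitation: global average pool -> bottleneck dense pair ->
# sigmoid gates -> channelwise rescale
nn_se <- function(ch, reduction = 16L) {
  mid <- max(1L, ch %/% reduction)
  fc1 <- nn_dense(ch, mid)
  fc2 <- nn_dense(mid, ch)
  children <- list(fc1, fc2)
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    d <- dim(x)                      # C, H, W, N
    hw <- d[2] * d[3]
    z <- .spatial_mean(x, d)
    dim(x) <- d
    a1 <- fc1$forward(z, train)
    r1 <- a1 * (a1 > 0)
    g <- 1 / (1 + exp(-fc2$forward(r1, train)))
    gv <- .rep_spatial(g, hw)
    dim(gv) <- d
    if (train) cache <<- list(x = x, g = g, gv = gv, a1 = a1, hw = hw, d = d)
    x * gv
  }
  backward <- function(dout) {
    cc <- cache
    d <- cc$d
    dx <- dout * cc$gv
    dg <- .spatial_mean(dout * cc$x, d) * cc$hw   # channelwise spatial sum
    da2 <- dg * cc$g * (1 - cc$g)
    dr1 <- fc2$backward(da2)
    dz <- fc1$backward(dr1 * (cc$a1 > 0))
    dz_sp <- .rep_spatial(dz / cc$hw, cc$hw)
    dim(dz_sp) <- d
    dx + dz_sp
  }
  nn_finalize(self, "nn_se")
}

# conv -> BN -> ReLU branch
.cbr <- function(in_ch, out_ch, kernel, stride) {
  nn_seq(nn_conv2d(in_ch, out_ch, kernel, stride),
         nn_batchnorm2d(out_ch),
         nn_relu())
}

nn_slim_stage <- function(in_ch, out_ch, se_reduction = 16L) {
  f2 <- .cbr(in_ch, out_ch, 3L, 2L)
  l2 <- .cbr(in_ch, out_ch, 1L, 2L)
  f1 <- .cbr(out_ch, out_ch, 3L, 1L)
  l1 <- .cbr(out_ch, out_ch, 1L, 1L)
  se <- nn_se(out_ch, se_reduction)
  children <- list(f2, l2, f1, l1, se)
  self <- environment()
  forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
      stop("stage input spatial size must be even, got ", d[2], "x", d[3])
    }
    O <- f2$forward(x, train) + l2$forward(x, train)
    se$forward(f1$forward(O, train) + l1$forward(O, train) + O, train)
  }
  backward <- function(dout) {
    dS <- se$backward(dout)
    dO <- f1$backward(dS) + l1$backward(dS) + dS
    f2$backward(dO) + l2$backward(dO)
  }
  nn_finalize(self, "nn_slim_stage")
}

#' Build the slim patch-embedding stem
#'
#' Four multibranch SE stages followed by the 1x1 channel expansion to
#' `final_channels`. Weights are randomly initialised from the current RNG
#' state.
#' @param cfg a [slim_config()]
#' @return an nn module; use [slim_forward()] to run it
#' @export
build_slim_stem <- function(cfg = slim_config()) {
  chans <- c(cfg$in_channels, cfg$stage_channels)
  stages <- lapply(seq_len(4L), function(i) {
    nn_slim_stage(chans[i], chans[i + 1L], cfg$se_reduction)
  })
  final <- .cbr(cfg$stage_channels[4L], cfg$final_channels, 1L, 1L)
  children <- c(stages, list(final))
  self <- environment()
  forward <- function(x, train = FALSE) {
    for (st in stages) x <- st$forward(x, train)
    final$forward(x, train)
  }
  backward <- function(dout) {
    dout <- final$backward(dout)
    for (st in rev(stages)) dout <- st$backward(dout)
    dout
  }
  nn_finalize(self, "slim_stem")
}

# public feature maps are [H, W, C]; internally channel-major [C, H, W, N]
.hwc_to_internal <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(3, 1, 2))
  dim(y) <- c(d[3], d[1], d[2], 1L)
  y
}

.internal_to_hwc <- function(y) {
  d <- dim(y)
  aperm(array(y, d[1:3]), c(2, 3, 1))
}

#' Run the squeeze-and-excitation block on a feature map
#' @param x `[H, W, C]` feature map
#' @param se an `nn_se` module (e.g. `stage$se`)
#' @export
se_forward <- function(x, se) {
  .internal_to_hwc(se$forward(.hwc_to_internal(x)))
}

#' Run one slim stage on a feature map
#' @param x `[H, W, C]` feature map with even spatial size
#' @param stage an `nn_slim_stage` module
#' @export
stage_forward <- function(x, stage) {
  .internal_to_hwc(stage$forward(.hwc_to_internal(x)))
}

#' Run the full slim stem
#'
#' Maps a `input_size x input_size` image to the
#' `input_size/16 x input_size/16 x final_channels` embedding map
#' (14 x 14 x 768 at the defaults).
#' @param image `[H, W, C]` image tensor
#' @param stem output of [build_slim_stem()]
#' @export
slim_forward <- function(image, stem) {
  d <- dim(image)
  if (d[1] != d[2]) stop("input must be square, got ", d[1], "x", d[2])
  .internal_to_hwc(stem$forward(.hwc_to_internal(image)))
}

#' Parameter count of a slim-stem configuration
#'
#' Deterministic arithmetic over the configuration (convolution kernels,
#' biases, batch-norm affine pairs and SE bottleneck weights); agrees with
#' the parameter count of a built stem.
#' @param cfg a [slim_config()]
#' @export
count_slim_parameters <- function(cfg = slim_config()) {
  conv_p <- function(ci, co, k) k * k * ci * co + co
  bn_p <- function(c) 2L * c
  total <- 0L
  chans <- c(cfg$in_channels, cfg$stage_channels)
  for (i in seq_len(4L)) {
    ci <- chans[i]; co <- chans[i + 1L]
    total <- total +
      conv_p(ci, co, 3L) + bn_p(co) +   # F_s2
      conv_p(ci, co, 1L) + bn_p(co) +   # L_s2
      conv_p(co, co, 3L) + bn_p(co) +   # F_s1
      conv_p(co, co, 1L) + bn_p(co)     # L_s1
    mid <- max(1L, co %/% cfg$se_reduction)
    total <- total + (co * mid + mid) + (mid * co + co)  # SE dense pair
  }
  total + conv_p(cfg$stage_channels[4L], cfg$final_channels, 1L) +
    bn_p(cfg$final_channels)
}
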