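# Reduced-depth vision-transformer encoder over the slim-stem embedding.
#
# The grid of embedding vectors becomes a token sequence (row-major), a
# learned classification token is prepended and learned positional
# embeddings are added. The encoder is the standard pre-norm stack
# (LayerNorm -> multi-head self-attention -> residual, LayerNorm -> GELU
# MLP -> residual) at a depth two lower than the reference model, so the
# default is 10 layers against the 12-layer reference. The last hidden
# states minus the classification token feed a dense map that matches the
# residual-branch feature width.

#' Encoder configuration
#'
#' @param reference_depth depth of the reference transformer (ViT-Base: 12);
#'   the built encoder always has `reference_depth - 2` layers
#' @param embed_dim token width; must match the slim stem's final channels
#' @param heads attention heads (must divide `embed_dim`)
#' @param mlp_ratio MLP hidden width as a multiple of `embed_dim`
#' @param dropout dropout probability inside blocks
#' @param n_patches number of grid tokens (196 for a 14 x 14 map)
#' @export
encoder_config <- function(reference_depth = 12L, embed_dim = 768L,
                           heads = 12L, mlp_ratio = 4, dropout = 0,
                           n_patches = 196L) {
  stopifnot(reference_depth >= 2L, embed_dim %% heads == 0L,
            dropout >= 0, dropout < 1)
  grid <- sqrt(n_patches)
  if (grid != round(grid)) stop("n_patches must be a perfect square")
  structure(list(reference_depth = as.integer(reference_depth),
                 depth = as.integer(reference_depth) - 2L,
                 embed_dim = as.integer(embed_dim), heads = as.integer(heads),
                 mlp_ratio = mlp_ratio, dropout = dropout,
                 n_patches = as.integer(n_patches),
                 grid = as.integer(grid)),
            class = "encoder_config")
}

# learned class token + positional embeddings as a parameter leaf
nn_token_embed <- function(embed_dim, n_tokens) {
  cls <- stats::rnorm(embed_dim, sd = 0.02)
  pos <- matrix(stats::rnorm(embed_dim * n_tokens, sd = 0.02),
                embed_dim, n_tokens)
  gcls <- cls * 0
  gpos <- pos * 0
  cache <- NULL
  self <- environment()
  forward <- function(x, train = FALSE) {
    # x: [D, T-1, N] grid tokens; prepend cls, add positions
    d <- dim(x)
    N <- d[3]
    y <- array(0, c(d[1], d[2] + 1L, N))
    y[, 1L, ] <- cls
    y[, -1L, ] <- x
    y <- y + rep(as.vector(pos), N)
    if (train) cache <<- list(d = d, N = N)
    y
  }
  backward <- function(dout) {
    N <- cache$N
    gpos <<- gpos + matrix(rowSums(matrix(dout, ncol = N)), nrow(pos))
    gcls <<- gcls + rowSums(matrix(dout[, 1L, ], ncol = N))
    dout[, -1L, , drop = FALSE]
  }
  param_names <- c("cls", "pos")
  decay_names <- character()
  nn_finalize(self, "nn_token_embed")
}

nn_vit_block <- function(embed_dim, heads, mlp_ratio = 4, dropout = 0) {
  ln1 <- nn_layernorm(embed_dim)
  attn <- nn_mhsa(embed_dim, heads)
  drop1 <- nn_dropout(dropout)
  ln2 <- nn_layernorm(embed_dim)
  hidden <- as.integer(round(embed_dim * mlp_ratio))
  fc1 <- nn_dense(embed_dim, hidden, sd = 0.02)
  act <- nn_gelu()
  fc2 <- nn_dense(hidden, embed_dim, sd = 0.02)
  drop2 <- nn_dropout(dropout)
  children <- list(ln1, attn, drop1, ln2, fc1, act, fc2, drop2)
  cache <- NULL
  self <- environment()
  mlp_fwd <- function(x, train) {
    d <- dim(x)
    y <- fc2$forward(act$forward(fc1$forward(matrix(x, d[1]), train), train),
                     train)
    dim(y) <- d
    drop2$forward(y, train)
  }
  mlp_bwd <- function(dout) {
    d <- dim(dout)
    dy <- drop2$backward(dout)
    dx <- fc1$backward(act$backward(fc2$backward(matrix(dy, d[1]))))
    dim(dx) <- d
    dx
  }
  forward <- function(x, train = FALSE) {
    x <- x + drop1$forward(attn$forward(ln1$forward(x, train), train), train)
    x + mlp_fwd(ln2$forward(x, train), train)
  }
  backward <- function(dout) {
    dx <- dout + ln2$backward(mlp_bwd(dout))
    dx + ln1$backward(attn$backward(drop1$backward(dx)))
  }
  nn_finalize(self, "nn_vit_block")
}

#' Build the reduced-depth transformer encoder
#'
#' @param cfg an [encoder_config()]
#' @return an nn module with fields `embed` (token/position parameters),
#'   `blocks` (list of `cfg$depth` encoder layers) and `cfg`
#' @export
build_encoder <- function(cfg = encoder_config()) {
  embed <- nn_token_embed(cfg$embed_dim, cfg$n_patches + 1L)
  blocks <- lapply(seq_len(cfg$depth), function(i) {
    nn_vit_block(cfg$embed_dim, cfg$heads, cfg$mlp_ratio, cfg$dropout)
  })
  children <- c(list(embed), blocks)
  self <- environment()
  # x: [D, T-1, N] grid tokens -> hidden states [D, T-1, N] (cls stripped)
  forward <- function(x, train = FALSE) {
    x <- embed$forward(x, train)
    for (b in blocks) x <- b$forward(x, train)
    if (any(!is.finite(x))) stop("non-finite values in encoder output")
    x[, -1L, , drop = FALSE]
  }
  backward <- function(dout) {
    d <- dim(dout)
    dfull <- array(0, c(d[1], d[2] + 1L, d[3]))
    dfull[, -1L, ] <- dout
    for (b in rev(blocks)) dfull <- b$backward(dfull)
    embed$backward(dfull)
  }
  nn_finalize(self, "hvit_encoder")
}

# row-major grid flatten: token t = (row-1)*grid + col.
# Internal maps are channel-major [C, H, W, N]; token order needs the grid
# column (w) to vary fastest, so swap the two spatial axes.
.grid_to_tokens <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2, 4)), d[1])  # D x (T*N)
}

.tokens_to_grid <- function(tok, H, W, N) {
  D <- nrow(tok)
  aperm(array(tok, c(D, W, H, N)), c(1, 3, 2, 4))
}

#' Turn an embedding map into a transformer token sequence
#'
#' The `grid x grid` map is flattened row-major into `n_patches` tokens,
#' the classification token is prepended and learned positional embeddings
#' are added.
#'
#' @param fmap `[H, W, C]` feature map with `H == W == cfg$grid` and
#'   `C == cfg$embed_dim`
#' @param encoder output of [build_encoder()]
#' @return `(n_patches + 1) x embed_dim` token matrix (tokens as rows,
#'   classification token first)
#' @export
tokenize <- function(fmap, encoder) {
  cfg <- encoder$cfg
  d <- dim(fmap)
  if (d[1] != cfg$grid || d[2] != cfg$grid) {
    stop("feature map is ", d[1], "x", d[2], " but the encoder expects ",
         cfg$grid, "x", cfg$grid)
  }
  if (d[3] != cfg$embed_dim) stop("channel count does not match embed_dim")
  tok <- encoder$embed$forward(array(.grid_to_tokens(.hwc_to_internal(fmap)),
                                     c(d[3], cfg$n_patches, 1L)))
  t(matrix(tok, cfg$embed_dim))
}

#' Run the encoder over a token sequence
#'
#' Standard pre-norm multi-head self-attention and MLP blocks at depth
#' `reference_depth - 2`; returns the last layer's hidden states with the
#' classification token removed.
#'
#' @param tokens `(n_patches + 1) x embed_dim` matrix from [tokenize()]
#' @param encoder output of [build_encoder()]
#' @return `n_patches x embed_dim` hidden-state matrix
#' @export
encode <- function(tokens, encoder) {
  cfg <- encoder$cfg
  stopifnot(nrow(tokens) == cfg$n_patches + 1L, ncol(tokens) == cfg$embed_dim)
  x <- array(t(tokens), c(cfg$embed_dim, cfg$n_patches + 1L, 1L))
  for (b in encoder$blocks) x <- b$forward(x)
  if (any(!is.finite(x))) stop("non-finite values in encoder output")
  t(matrix(x[, -1L, , drop = FALSE], cfg$embed_dim))
}

#' Build the transformer feature head
#'
#' Dense map from the flattened hidden states (`n_patches * embed_dim`) to
#' the residual-branch feature width, enforcing feature-dimension parity at
#' construction.
#' @param cfg an [encoder_config()]
#' @param d_out residual-branch feature dimension
#' @export
build_vit_head <- function(cfg, d_out) {
  nn_dense(cfg$n_patches * cfg$embed_dim, as.integer(d_out),
           sd = sqrt(1 / (cfg$n_patches * cfg$embed_dim)))
}

#' Transformer feature vector from hidden states
#'
#' `F = W_f . flatten(H) + b_f` with H flattened row-major (token-major:
#' token 1's embedding first).
#' @param h `n_patches x embed_dim` hidden-state matrix from [encode()]
#' @param head output of [build_vit_head()]
#' @return numeric feature vector of length `d_out`
#' @export
vit_features <- function(h, head) {
  flat <- as.vector(t(h))
  if (length(flat) != ncol(head$W)) {
    stop("hidden-state size ", length(flat),
         " does not match the head input ", ncol(head$W))
  }
  as.vector(head$forward(matrix(flat, ncol = 1L)))
}
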