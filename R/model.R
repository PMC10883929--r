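# The fused classifier: residual branch and transformer branch run on the
# same beat image, their equal-length feature vectors are concatenated and
# passed through a dense prediction head. Training is joint end-to-end
# with Adam and categorical cross-entropy.

#' Fusion head configuration
#'
#' @param hidden_sizes widths of the dense layers between the concatenated
#'   features and the softmax (default one layer of 256)
#' @param dropout dropout before the classifier
#' @param n_classes number of output classes
#' @export
fusion_config <- function(hidden_sizes = c(256L), dropout = 0.35,
                          n_classes = 12L) {
  structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "fusion_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001)
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param seed RNG seed; recorded in the history so every run is
#'   reproducible
#' @param weight_decay decoupled L2 strength on weight matrices
#' @param freeze_resnet train only the transformer branch and the heads,
#'   keeping the residual branch fixed
#' @export
train_config <- function(learning_rate = 0.001, epochs = 30L,
                         batch_size = 32L, seed = 0L, weight_decay = 1e-4,
                         freeze_resnet = FALSE) {
  stopifnot(learning_rate >= 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 weight_decay = weight_decay, freeze_resnet = freeze_resnet),
            class = "train_config")
}

.build_fusion_head <- function(d_in, cfg) {
  layers <- list()
  prev <- d_in
  for (h in cfg$hidden_sizes) {
    layers <- c(layers, list(nn_dense(prev, h), nn_relu(),
                             nn_dropout(cfg$dropout)))
    prev <- h
  }
  layers <- c(layers, list(nn_dense(prev, cfg$n_classes)))
  nn_seq(layers)
}

.softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' Build the fused two-branch classifier
#'
#' Residual branch and slim-stem + encoder + feature-head transformer
#' branch over the same input, concatenation fusion, dense prediction
#' head. Feature-dimension parity between the branches is enforced at
#' construction: the transformer head maps to the residual feature width.
#' The slim stem's output grid must match the encoder's patch grid and its
#' channel width the embedding dimension.
#'
#' @param slim_cfg a [slim_config()]
#' @param enc_cfg an [encoder_config()]
#' @param res_cfg a [resnet_config()]
#' @param fus_cfg a [fusion_config()]
#' @return an nn module with `$forward(x, train)` returning class logits
#'   `[K, N]`, plus the sub-modules (`resnet`, `slim`, `encoder`,
#'   `vit_head`, `fusion`) as fields
#' @export
build_mi_model <- function(slim_cfg = slim_config(),
                           enc_cfg = encoder_config(),
                           res_cfg = resnet_config(),
                           fus_cfg = fusion_config()) {
  grid <- slim_cfg$input_size %/% 16L
  if (grid != enc_cfg$grid) {
    stop("slim stem emits a ", grid, "x", grid, " grid but the encoder",
         " expects ", enc_cfg$grid, "x", enc_cfg$grid)
  }
  if (slim_cfg$final_channels != enc_cfg$embed_dim) {
    stop("slim final_channels must equal the encoder embed_dim")
  }
  if (slim_cfg$input_size != res_cfg$input_size ||
      slim_cfg$in_channels != res_cfg$in_channels) {
    stop("branch input sizes disagree")
  }
  d_res <- res_cfg$feature_dim
  resnet <- build_resnet(res_cfg)
  slim <- build_slim_stem(slim_cfg)
  encoder <- build_encoder(enc_cfg)
  vit_head <- build_vit_head(enc_cfg, d_res)
  fusion <- .build_fusion_head(2L * d_res, fus_cfg)
  children <- list(resnet, slim, encoder, vit_head, fusion)
  n_classes <- fus_cfg$n_classes
  self <- environment()

  forward <- function(x, train = FALSE) {
    N <- dim(x)[4]
    f_res <- resnet$forward(x, train)                 # D x N
    fmap <- slim$forward(x, train)                    # g x g x D_e x N
    tok <- array(.grid_to_tokens(fmap),
                 c(enc_cfg$embed_dim, enc_cfg$n_patches, N))
    h <- encoder$forward(tok, train)                  # D_e x T x N
    flat <- matrix(h, enc_cfg$embed_dim * enc_cfg$n_patches, N)
    f_vit <- vit_head$forward(flat, train)            # D x N
    fusion$forward(rbind(f_res, f_vit), train)        # K x N
  }

  backward <- function(dlogits) {
    dfused <- fusion$backward(dlogits)
    dres <- dfused[seq_len(d_res), , drop = FALSE]
    dvit <- dfused[d_res + seq_len(d_res), , drop = FALSE]
    N <- ncol(dres)
    dflat <- vit_head$backward(dvit)
    dh <- array(dflat, c(enc_cfg$embed_dim, enc_cfg$n_patches, N))
    dtok <- encoder$backward(dh)
    dfmap <- .tokens_to_grid(matrix(dtok, enc_cfg$embed_dim),
                             enc_cfg$grid, enc_cfg$grid, N)
    dx1 <- slim$backward(dfmap)
    dx2 <- resnet$backward(dres)
    dx1 + dx2
  }
  nn_finalize(self, "mi_model")
}

#' Desk-scale reduced model configuration
#'
#' A narrow build of the same architecture for fast CPU training:
#' 64 x 64 grayscale input, slim channels 4/8/16/32 expanding to 32, a
#' 2-layer encoder (reference depth 4) with 2 heads, a 2-stage residual
#' branch of width 8/16, and a 32-unit fusion layer. Used by the test and
#' evaluation harnesses; the default configurations retain the full-scale
#' architecture.
#'
#' @param input_size input side length (multiple of 16)
#' @param n_classes output classes
#' @export
reduced_model_config <- function(input_size = 64L, n_classes = 12L) {
  grid <- input_size %/% 16L
  list(
    slim = slim_config(stage_channels = c(4L, 8L, 16L, 32L),
                       final_channels = 32L, input_size = input_size,
                       in_channels = 1L, se_reduction = 4L),
    encoder = encoder_config(reference_depth = 4L, embed_dim = 32L,
                             heads = 2L, mlp_ratio = 2,
                             n_patches = grid * grid),
    resnet = resnet_config(blocks_per_stage = c(1L, 1L),
                           stage_channels = c(8L, 16L),
                           initial_filters = 8L, in_channels = 1L,
                           input_size = input_size, block = "basic"),
    fusion = fusion_config(hidden_sizes = c(32L), dropout = 0.35,
                           n_classes = n_classes)
  )
}

#' Build the reduced desk-scale model
#' @param input_size input side length
#' @param n_classes output classes
#' @export
build_reduced_model <- function(input_size = 64L, n_classes = 12L) {
  cfgs <- reduced_model_config(input_size, n_classes)
  build_mi_model(cfgs$slim, cfgs$encoder, cfgs$resnet, cfgs$fusion)
}

#' Class probabilities from a pair of branch feature vectors
#'
#' Concatenates the residual-branch and transformer-branch features (equal
#' lengths enforced) and applies the fusion head followed by softmax.
#' @param f_res,f_vit equal-length feature vectors
#' @param head a fusion head module (e.g. `model$fusion`)
#' @return probability vector summing to 1
#' @export
fuse_predict <- function(f_res, f_vit, head) {
  if (length(f_res) != length(f_vit)) {
    stop("branch features must have equal length (got ", length(f_res),
         " and ", length(f_vit), "): feature parity is a build-time contract")
  }
  z <- head$forward(matrix(c(f_res, f_vit), ncol = 1L))
  as.vector(.softmax_cols(z))
}

.images_to_batch <- function(images, idx) {
  # [n, H, W, C] -> channel-major [C, H, W, |idx|]
  aperm(images[idx, , , , drop = FALSE], c(4, 2, 3, 1))
}

#' Predict class probabilities for an image set
#' @param model output of [build_mi_model()]
#' @param images `[n, H, W, C]` image array
#' @param batch_size evaluation batch size
#' @return `n x K` probability matrix
#' @export
predict_model <- function(model, images, batch_size = 64L) {
  n <- dim(images)[1]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    p <- t(.softmax_cols(model$forward(.images_to_batch(images, idx))))
    out <- rbind(out, p)
  }
  out
}

#' Train the fused classifier
#'
#' Joint end-to-end minibatch training with Adam and categorical
#' cross-entropy. Fully reproducible from `cfg$seed` (shuffling and
#' dropout included).
#'
#' @param model output of [build_mi_model()]
#' @param dataset a `labeled_image_set`
#' @param cfg a [train_config()]
#' @return history: data frame of per-epoch `loss` and `accuracy`
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  images <- dataset$images
  labels <- dataset$labels
  n <- dim(images)[1]
  if (n == 0L) stop("empty dataset")
  if (length(unique(labels)) < 2L) stop("training needs at least 2 classes")
  K <- model$n_classes
  if (max(labels) > K) stop("label outside the model's class range")
  set.seed(cfg$seed)
  trainable <- if (cfg$freeze_resnet) {
    mods <- list(model$slim, model$encoder, model$vit_head, model$fusion)
    structure(list(children = mods), class = "nn_module")
  } else model
  opt <- nn_adam(trainable, lr = cfg$learning_rate,
                 weight_decay = cfg$weight_decay)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      x <- .images_to_batch(images, idx)
      y <- labels[idx]
      logits <- model$forward(x, train = TRUE)
      probs <- .softmax_cols(logits)
      m <- length(idx)
      py <- probs[cbind(y, seq_len(m))]
      loss <- -mean(log(pmax(py, 1e-12)))
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      onehot <- matrix(0, K, m)
      onehot[cbind(y, seq_len(m))] <- 1
      nn_zero_grads(model)
      model$backward((probs - onehot) / m)
      opt$step()
      tot_loss <- tot_loss + loss * m
      tot_correct <- tot_correct + sum(apply(logits, 2, which.max) == y)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / n,
                                         accuracy = tot_correct / n))
  }
  history
}

#' Stratified k-fold evaluation
#'
#' Builds a stratified fold plan, re-initialises the model for every fold
#' via `model_builder`, trains on the k-1 training folds and evaluates the
#' held-out fold. Alongside the per-fold metric reports, the per-class
#' one-vs-rest accuracies are tabulated class x fold.
#'
#' @param dataset a `labeled_image_set`
#' @param model_builder zero-argument function returning a fresh model
#' @param cfg a [train_config()]
#' @param k number of folds (default 10)
#' @param seed seed for the fold plan
#' @return list: `reports` (one `metrics_report` per fold),
#'   `accuracy_table` (class x fold one-vs-rest accuracies), `plan`,
#'   `mean_accuracy` (mean over folds of overall fold accuracy)
#' @export
kfold_evaluate <- function(dataset, model_builder, cfg = train_config(),
                           k = 10L, seed = 1L) {
  labels <- dataset$labels
  plan <- fold_plan(dataset$class_names[labels], k = k, seed = seed)
  K <- length(dataset$class_names)
  reports <- vector("list", k)
  acc_tab <- matrix(NA_real_, K, k,
                    dimnames = list(dataset$class_names, paste0("fold", 1:k)))
  for (fold in seq_len(k)) {
    test_idx <- which(plan$assignments == fold)
    train_idx <- setdiff(seq_along(labels), test_idx)
    tr <- labeled_image_set(dataset$images[train_idx, , , , drop = FALSE],
                            labels[train_idx], dataset$class_names)
    set.seed(seed * 10000L + fold)
    model <- model_builder()
    train_model(model, tr, cfg)
    probs <- predict_model(model, dataset$images[test_idx, , , , drop = FALSE])
    pred <- apply(probs, 1, which.max)
    rep <- compute_metrics(labels[test_idx], pred, probs,
                           class_names = dataset$class_names)
    reports[[fold]] <- rep
    acc_tab[, fold] <- rep$per_class$accuracy
  }
  list(reports = reports, accuracy_table = acc_tab, plan = plan,
       mean_accuracy = mean(vapply(reports, function(r) r$accuracy, 0)))
}

#' Extract all trainable parameters of a model as a plain list
#'
#' The list follows the module tree's leaf order and can be re-applied to
#' any model built from the same configuration, which is how checkpoints
#' (including externally trained branch weights) are loaded.
#' @param model an nn module
#' @export
model_weights <- function(model) {
  lapply(nn_leaves(model), function(l) {
    stats::setNames(lapply(l$param_names, function(nm) l[[nm]]),
                    l$param_names)
  })
}

#' Load parameters produced by [model_weights()] into a model
#' @param model an nn module built from the same configuration
#' @param weights output of [model_weights()]
#' @export
set_model_weights <- function(model, weights) {
  leaves <- nn_leaves(model)
  if (length(leaves) != length(weights)) {
    stop("weight list does not match the model structure (",
         length(weights), " vs ", length(leaves), " parameter groups)")
  }
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    for (nm in l$param_names) {
      w <- weights[[i]][[nm]]
      if (is.null(w) || length(w) != length(l[[nm]])) {
        stop("shape mismatch for parameter '", nm, "' in group ", i)
      }
      dim(w) <- dim(l[[nm]])
      l[[nm]] <- w
    }
  }
  invisible(model)
}

#' Save model weights to an RDS checkpoint
#' @param model an nn module
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model_weights(model), path)
  invisible(path)
}

#' Load an RDS checkpoint into a model
#' @param model an nn module built from the same configuration
#' @param path checkpoint file from [save_checkpoint()]
#' @export
load_checkpoint <- function(model, path) {
  set_model_weights(model, readRDS(path))
}
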