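# End-to-end gradients, training reproducibility and checkpoints.

tiny_model <- function() {
  build_mi_model(
    slim_config(stage_channels = c(2L, 2L, 3L, 3L), final_channels = 4L,
                input_size = 16L, in_channels = 1L, se_reduction = 2L),
    encoder_config(reference_depth = 3L, embed_dim = 4L, heads = 2L,
                   mlp_ratio = 2, n_patches = 1L),
    resnet_config(blocks_per_stage = c(1L), stage_channels = c(3L),
                  initial_filters = 2L, in_channels = 1L, input_size = 16L),
    fusion_config(hidden_sizes = 4L, dropout = 0, n_classes = 3L)
  )
}

test_that("the full fused model backpropagates exact gradients", {
  set.seed(23)
  model <- tiny_model()
  x <- array(rnorm(16 * 16 * 2), c(1, 16, 16, 2))
  y <- c(1L, 3L)
  loss_of <- function(xx) {
    logits <- model$forward(xx, train = TRUE)
    probs <- ecghvit:::.softmax_cols(logits)
    -mean(log(probs[cbind(y, 1:2)]))
  }
  logits <- model$forward(x, train = TRUE)
  probs <- ecghvit:::.softmax_cols(logits)
  onehot <- matrix(0, 3, 2)
  onehot[cbind(y, 1:2)] <- 1
  ecghvit:::nn_zero_grads(model)
  dx <- model$backward((probs - onehot) / 2)
  ng <- fd_grad(loss_of, x, eps = 1e-5)
  expect_lt(max(abs(dx - ng)), 1e-6)
  # a few parameter gradients, spread across both branches
  for (l in list(ecghvit:::nn_leaves(model$resnet)[[1]],
                 ecghvit:::nn_leaves(model$slim)[[3]],
                 ecghvit:::nn_leaves(model$encoder)[[2]],
                 model$vit_head)) {
    nm <- l$param_names[1]
    p0 <- l[[nm]]
    idx <- seq_len(min(4, length(p0)))
    ng <- numeric(length(idx))
    for (i in idx) {
      l[[nm]][i] <- p0[i] + 1e-5; fp <- loss_of(x)
      l[[nm]][i] <- p0[i] - 1e-5; fm <- loss_of(x)
      l[[nm]][i] <- p0[i]
      ng[i] <- (fp - fm) / 2e-5
    }
    model$forward(x, train = TRUE)
    ecghvit:::nn_zero_grads(model)
    model$backward((probs - onehot) / 2)
    expect_lt(max(abs(l[[paste0("g", nm)]][idx] - ng)), 1e-6)
  }
})

test_that("zero learning rate leaves parameters untouched", {
  set.seed(24)
  model <- tiny_model()
  before <- model_weights(model)
  imgs <- array(runif(6 * 16 * 16), c(6, 16, 16, 1))
  ds <- ecghvit:::labeled_image_set(imgs, rep(1:3, 2), c("a", "b", "c"))
  # full-batch so batch-norm statistics are identical across epochs
  h <- train_model(model, ds, train_config(learning_rate = 0,
                                           epochs = 2, weight_decay = 0,
                                           batch_size = 6, seed = 1))
  after <- model_weights(model)
  expect_equal(after, before, tolerance = 1e-14)
  expect_equal(h$loss[1], h$loss[2], tolerance = 1e-9)
})

test_that("training is reproducible given the seed", {
  imgs <- array(runif(12 * 16 * 16), c(12, 16, 16, 1))
  labs <- rep(1:3, 4)
  ds <- ecghvit:::labeled_image_set(imgs, labs, c("a", "b", "c"))
  run <- function() {
    set.seed(77)
    m <- tiny_model()
    train_model(m, ds, train_config(epochs = 3, batch_size = 4, seed = 5))
  }
  h1 <- run()
  h2 <- run()
  expect_identical(h1, h2)
  expect_error(train_model(tiny_model(),
                           ecghvit:::labeled_image_set(imgs, rep(1L, 12),
                                                       c("a", "b", "c")),
                           train_config(epochs = 1)),
               "2 classes")
})

test_that("loss decreases on a small separable problem", {
  set.seed(25)
  imgs <- array(0, c(16, 16, 16, 1))
  labs <- rep(1:2, each = 8)
  imgs[labs == 1, 4:6, , 1] <- 1
  imgs[labs == 2, 10:12, , 1] <- 1
  imgs <- imgs + array(runif(length(imgs)) * 0.05, dim(imgs))
  ds <- ecghvit:::labeled_image_set(imgs, labs, c("a", "b"))
  set.seed(1)
  m <- build_reduced_model(16L, 2L)
  h <- train_model(m, ds, train_config(epochs = 25, batch_size = 8, seed = 2))
  expect_lt(mean(tail(h$loss, 3)), mean(head(h$loss, 3)))
  expect_gte(tail(h$accuracy, 1), 0.75)
})

test_that("checkpoints round trip and freezing keeps the branch fixed", {
  dir <- withr::local_tempdir()
  set.seed(26)
  m1 <- tiny_model()
  p <- file.path(dir, "w.rds")
  save_checkpoint(m1, p)
  set.seed(99)
  m2 <- tiny_model()
  expect_false(isTRUE(all.equal(model_weights(m2), model_weights(m1))))
  load_checkpoint(m2, p)
  expect_equal(model_weights(m2), model_weights(m1))
  # frozen residual branch stays at its checkpointed weights
  imgs <- array(runif(8 * 16 * 16), c(8, 16, 16, 1))
  ds <- ecghvit:::labeled_image_set(imgs, rep(1:2, 4), c("a", "b"))
  res_before <- model_weights(m2$resnet)
  train_model(m2, ds, train_config(epochs = 2, batch_size = 4, seed = 3,
                                   freeze_resnet = TRUE))
  expect_equal(model_weights(m2$resnet), res_before)
  expect_false(isTRUE(all.equal(m2$vit_head$W, m1$vit_head$W)))
})
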