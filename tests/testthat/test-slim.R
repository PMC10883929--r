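# Slim patch-embedding stem: SE attention, stage algebra, shape contract.

test_that("SE forward equals a hand-coded pool/dense/sigmoid/scale chain", {
  set.seed(42)
  se <- ecghvit:::nn_se(8L, reduction = 2L)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  got <- se_forward(x, se)
  # independent composition over the same weights
  z <- apply(x, 3, mean)
  a1 <- pmax(se$fc1$W %*% z + se$fc1$b, 0)
  g <- 1 / (1 + exp(-(se$fc2$W %*% a1 + se$fc2$b)))
  want <- sweep(x, 3, as.vector(g), "*")
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("SE gate limits give identity and annihilation", {
  set.seed(1)
  se <- ecghvit:::nn_se(6L, reduction = 2L)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  se$fc2$b[] <- 1e3                       # gates -> 1
  expect_equal(se_forward(x, se), x)
  se$fc2$b[] <- -1e3                      # gates -> 0
  expect_equal(se_forward(x, se), x * 0)
  # gating is always a channelwise contraction
  se2 <- ecghvit:::nn_se(6L, reduction = 2L)
  y <- se_forward(x, se2)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
})

test_that("a stage with zeroed stride-1 branches and unit gates is O(x)", {
  set.seed(2)
  st <- ecghvit:::nn_slim_stage(3L, 5L, 2L)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  for (br in list(st$f1, st$l1)) {
    cv <- br$children[[1]]
    cv$W[] <- 0; cv$b[] <- 0
    bn <- br$children[[2]]
    bn$beta[] <- 0
  }
  st$se$fc2$b[] <- 1e3
  got <- stage_forward(x, st)
  # O(x) recomputed from the stride-2 branches alone
  xi <- ecghvit:::.hwc_to_internal(x)
  O <- st$f2$forward(xi) + st$l2$forward(xi)
  expect_equal(got, ecghvit:::.internal_to_hwc(O), tolerance = 1e-12)
})

test_that("stage shapes follow the architecture table", {
  set.seed(0)
  st1 <- ecghvit:::nn_slim_stage(3L, 48L)
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3))
  y <- stage_forward(x, st1)
  expect_equal(dim(y), c(112L, 112L, 48L))
  expect_error(stage_forward(array(0, c(7, 7, 3)), st1), "even")
})

test_that("a stage agrees with direct convolution arithmetic on all-ones", {
  st <- ecghvit:::nn_slim_stage(1L, 1L, 1L)
  # unit kernels, no bias shifts, neutral BN, unit SE gates
  for (br in list(st$f2, st$l2, st$f1, st$l1)) {
    br$children[[1]]$W[] <- 1
    br$children[[1]]$b[] <- 0
    br$children[[2]]$run_mean[] <- 0
    br$children[[2]]$run_var[] <- 1 - 1e-5  # istd exactly 1
  }
  st$se$fc2$W[] <- 0; st$se$fc2$b[] <- 1e3
  x <- array(1, c(4, 4, 1))
  y <- stage_forward(x, st)
  # F_s2 on an all-ones 4x4 with 3x3 unit kernels, stride 2, zero padding:
  # window sums are 4 (corner) and 6 (edge); L_s2 contributes 1 everywhere
  O <- matrix(c(5, 7, 7, 10), 2, 2)  # [ (4+1) (6+1); (6+1) (9+1) ] at stride-2 taps
  O_true <- matrix(0, 2, 2)
  for (oh in 1:2) for (ow in 1:2) {
    rows <- (2 * oh - 2):(2 * oh)
    cols <- (2 * ow - 2):(2 * ow)
    rows <- rows[rows >= 1 & rows <= 4]
    cols <- cols[cols >= 1 & cols <= 4]
    O_true[oh, ow] <- length(rows) * length(cols) + 1
  }
  H_true <- O_true
  for (oh in 1:2) for (ow in 1:2) {
    rows <- intersect((oh - 1):(oh + 1), 1:2)
    cols <- intersect((ow - 1):(ow + 1), 1:2)
    H_true[oh, ow] <- sum(O_true[rows, cols]) + O_true[oh, ow] + O_true[oh, ow]
  }
  expect_equal(y[, , 1], H_true, tolerance = 1e-9)
})

test_that("the full stem maps 224x224x3 to 14x14x768 through the stage chain", {
  set.seed(3)
  stem <- build_slim_stem()
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3))
  xi <- ecghvit:::.hwc_to_internal(x)
  shapes <- list()
  for (i in 1:4) {
    xi <- stem$stages[[i]]$forward(xi)
    shapes[[i]] <- dim(xi)
  }
  expect_equal(shapes[[1]][2:3], c(112L, 112L))
  expect_equal(shapes[[1]][1], 48L)
  expect_equal(shapes[[2]][1], 96L)
  expect_equal(shapes[[3]][2:3], c(28L, 28L))
  expect_equal(shapes[[3]][1], 192L)
  expect_equal(shapes[[4]][2:3], c(14L, 14L))
  expect_equal(shapes[[4]][1], 384L)
  out <- stem$final$forward(xi)
  expect_equal(dim(out)[1:3], c(768L, 14L, 14L))
  expect_error(slim_forward(array(0, c(224, 112, 3)), stem), "square")
})

test_that("zero input with neutral parameters produces zero output", {
  set.seed(4)
  cfg <- slim_config(stage_channels = c(2L, 4L, 8L, 8L), final_channels = 8L,
                     input_size = 32L, in_channels = 1L, se_reduction = 2L)
  stem <- build_slim_stem(cfg)
  y <- slim_forward(array(0, c(32, 32, 1)), stem)
  expect_equal(dim(y), c(2L, 2L, 8L))
  expect_equal(max(abs(y)), 0)
})

test_that("parameter counting matches a built stem and scales with r", {
  cfg <- slim_config(stage_channels = c(4L, 8L, 16L, 32L),
                     final_channels = 32L, input_size = 64L,
                     in_channels = 1L, se_reduction = 4L)
  stem <- build_slim_stem(cfg)
  expect_equal(count_slim_parameters(cfg), ecghvit:::nn_n_params(stem))
  expect_equal(count_slim_parameters(slim_config()),
               ecghvit:::nn_n_params(build_slim_stem(slim_config())))
  # doubling the reduction shrinks only the SE bottleneck
  c2 <- slim_config(stage_channels = c(4L, 8L, 16L, 32L),
                    final_channels = 32L, input_size = 64L,
                    in_channels = 1L, se_reduction = 8L)
  expect_lt(count_slim_parameters(c2), count_slim_parameters(cfg))
})
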