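# Metric identities, confusion views, ROC and fold planning.

test_that("perfect predictions give perfect metrics", {
  y <- rep(1:3, each = 4)
  m <- compute_metrics(y, y, class_names = c("a", "b", "c"))
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$fpr == 0))
  expect_true(all(m$per_class$fnr == 0))
  expect_equal(unname(diag(m$confusion)), rep(4L, 3))
  expect_true(all(m$confusion[upper.tri(m$confusion)] == 0))
})

test_that("per-class tallies match a hand count on a 3-class toy", {
  # confusion [[5,1,0],[0,4,2],[1,0,7]]
  y_true <- rep(1:3, times = c(6, 6, 8))
  y_pred <- c(rep(1, 5), 2, rep(2, 4), 3, 3, 1, rep(3, 7))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(unname(as.vector(t(m$confusion))), c(5, 1, 0, 0, 4, 2, 1, 0, 7))
  expect_equal(m$per_class$precision, c(5 / 6, 4 / 5, 7 / 9))
  expect_equal(m$per_class$recall, c(5 / 6, 4 / 6, 7 / 8))
  expect_equal(m$per_class$specificity, c(1 - 1 / 14, 1 - 1 / 14, 1 - 2 / 12))
  expect_equal(m$accuracy, 16 / 20)
  expect_equal(m$per_class$accuracy[1], (5 + 13) / 20)
})

test_that("metric identities hold to numerical precision", {
  set.seed(18)
  y_true <- sample(1:4, 300, replace = TRUE)
  y_pred <- ifelse(runif(300) < 0.7, y_true, sample(1:4, 300, replace = TRUE))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$per_class$fnr, 1 - m$per_class$sensitivity, tolerance = 1e-9)
  expect_equal(m$per_class$fpr, 1 - m$per_class$specificity, tolerance = 1e-9)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
  expect_equal(unname(rowSums(m$confusion_percent)), rep(100, 4),
               tolerance = 0.01)
  expect_equal(sum(m$confusion), 300L)
})

test_that("ROC is monotone with the expected extremes", {
  # perfectly separated scores
  r1 <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1)
  # constant scores carry no information
  r2 <- roc_curve(rep(0.5, 20), rep(c(TRUE, FALSE), 10))
  expect_equal(r2$auc, 0.5)
  set.seed(19)
  r3 <- roc_curve(runif(200), runif(200) < 0.4)
  expect_true(all(diff(r3$points$fpr) >= 0))
  expect_true(all(diff(r3$points$tpr) >= 0))
  expect_gte(r3$auc, 0)
  expect_lte(r3$auc, 1)
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  scores <- c(rnorm(60, 1), rnorm(90, 0))
  pos <- rep(c(TRUE, FALSE), c(60, 90))
  ours <- roc_curve(scores, pos)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                           predictor = scores,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("probability metrics attach one ROC per class", {
  set.seed(21)
  y <- rep(1:3, each = 10)
  probs <- matrix(runif(90), 30, 3)
  probs <- probs / rowSums(probs)
  pred <- apply(probs, 1, which.max)
  m <- compute_metrics(y, pred, probs, class_names = c("x", "y", "z"))
  expect_named(m$roc, c("x", "y", "z"))
  expect_true(all(vapply(m$roc, function(r) r$auc, 0) >= 0))
  expect_error(compute_metrics(c(1, 5), c(1, 1), class_names = c("a", "b")),
               "outside")
  expect_error(compute_metrics(integer(), integer()), "empty")
})

test_that("stratified folds are disjoint, covering and balanced", {
  labels <- rep(mi_classes(), each = 20)
  plan <- fold_plan(labels, k = 10, seed = 3)
  expect_length(plan$assignments, 240)
  # disjoint + covering is automatic for an assignment vector; check balance
  for (cls in mi_classes()) {
    tab <- table(plan$assignments[labels == cls])
    expect_equal(length(tab), 10L)
    expect_lte(diff(range(tab)), 1)
  }
  # per-fold totals balanced within one per class
  expect_true(all(table(plan$assignments) == 24))
  # determinism
  plan2 <- fold_plan(labels, k = 10, seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
  plan3 <- fold_plan(labels, k = 10, seed = 4)
  expect_false(identical(plan$assignments, plan3$assignments))
  expect_error(fold_plan(rep(c("a", "b"), c(5, 40)), k = 10),
               "fewer than k")
})

test_that("balanced 120-sample plan puts one sample per class in each fold", {
  labels <- rep(mi_classes(), each = 10)
  plan <- fold_plan(labels, k = 10, seed = 1)
  for (f in 1:10) {
    expect_equal(sort(labels[plan$assignments == f]), sort(mi_classes()))
  }
})

test_that("fusion head with zero weights yields uniform probabilities", {
  cfgs <- reduced_model_config(48L)
  model <- build_mi_model(cfgs$slim, cfgs$encoder, cfgs$resnet, cfgs$fusion)
  for (l in ecghvit:::nn_leaves(model$fusion)) {
    for (nm in l$param_names) l[[nm]][] <- 0
  }
  p <- fuse_predict(rnorm(16), rnorm(16), model$fusion)
  expect_equal(p, rep(1 / 12, 12))
  expect_error(fuse_predict(rnorm(3), rnorm(4), model$fusion), "parity")
})

test_that("a hand-set two-class toy head matches manual softmax", {
  head <- ecghvit:::.build_fusion_head(2L, fusion_config(hidden_sizes = integer(),
                                                         n_classes = 2L))
  lin <- head$children[[1]]
  lin$W <- matrix(c(1, -1, 0.5, 2), 2, 2)
  lin$b <- c(0.1, -0.2)
  p <- fuse_predict(0.3, -0.4, head)
  z <- lin$W %*% c(0.3, -0.4) + lin$b
  expect_equal(p, as.vector(exp(z) / sum(exp(z))))
})

test_that("swapping branch order with matching weights leaves output fixed", {
  set.seed(22)
  head <- ecghvit:::.build_fusion_head(4L, fusion_config(hidden_sizes = 3L,
                                                         n_classes = 2L))
  f_res <- rnorm(2); f_vit <- rnorm(2)
  p1 <- fuse_predict(f_res, f_vit, head)
  lin <- head$children[[1]]
  lin$W <- lin$W[, c(3, 4, 1, 2)]
  p2 <- fuse_predict(f_vit, f_res, head)
  expect_equal(p1, p2, tolerance = 1e-12)
})
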