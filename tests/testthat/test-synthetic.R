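# Class-conditional synthetic ECG generation and beat-image rendering.

test_that("healthy control records carry no ST displacement", {
  sr <- generate_record("Healthy Control", n_beats = 10, seed = 31)
  expect_length(sr$truth_r_peaks, 10)
  segs <- segment_beats(sr$record, sr$truth_r_peaks)
  st <- st_level(segs[[3]], 360)
  expect_true(all(abs(st) <= 0.02))
})

test_that("inferior records express the configured ST pattern", {
  sr <- generate_record("Inferior", n_beats = 10, seed = 32)
  segs <- segment_beats(sr$record, sr$truth_r_peaks)
  st <- st_level(segs[[4]], 360)
  elev <- c("II", "III", "aVF")
  depr <- c("I", "aVL", "V1", "V2", "V3")
  expect_true(all(st[elev] > 0.15))
  expect_true(all(st[depr] < -0.15))
  expect_true(all(abs(st[c("V4", "V5", "V6")]) < 0.05))
})

test_that("every MI class modifies at least one lead; healthy none", {
  sigs <- class_signatures()
  expect_named(sigs, mi_classes())
  hc <- sigs[["Healthy Control"]]
  expect_length(hc$st, 0)
  expect_length(hc$q_leads, 0)
  for (cls in setdiff(mi_classes(), "Healthy Control")) {
    s <- sigs[[cls]]
    expect_gt(length(s$st) + length(s$q_leads) + length(s$tall_r), 0)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_record("Posterior", n_beats = 5, noise_snr_db = 10, seed = 7)
  b <- generate_record("Posterior", n_beats = 5, noise_snr_db = 10, seed = 7)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$truth_r_peaks, b$truth_r_peaks)
  c <- generate_record("Posterior", n_beats = 5, noise_snr_db = 10, seed = 8)
  expect_false(identical(a$record$signal, c$record$signal))
  expect_error(generate_record("NotAClass"), "unknown class")
})

test_that("truth peaks coincide with clean-reference R maxima", {
  for (cls in c("Healthy Control", "Anterior", "Posterior")) {
    sr <- generate_record(cls, n_beats = 8, seed = 41)
    lead <- sr$clean_reference[, "II"]
    for (p in sr$truth_r_peaks) {
      win <- max(1, p - 20):min(length(lead), p + 20)
      expect_lte(abs(win[which.max(lead[win])] - p), 2)
    }
  }
})

test_that("rendering is deterministic and localises per-lead changes", {
  sr <- generate_record("Healthy Control", n_beats = 4, seed = 51)
  segs <- segment_beats(sr$record, sr$truth_r_peaks)
  b <- segs[[2]]
  img1 <- render_beat_image(b, size = 96)
  img2 <- render_beat_image(b, size = 96)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  # zero beat -> one horizontal line per lead lane
  zero <- b
  zero$values[] <- 0
  zi <- render_beat_image(zero, size = 96)
  dark_rows <- which(apply(zi, 1, min) <= 0.5)
  lanes <- split(dark_rows, cumsum(c(1, diff(dark_rows) > 1)))
  expect_equal(length(lanes), 12)
  # boosting one lead only changes that lead's lane rows
  mod <- b
  mod$values[, 5] <- mod$values[, 5] * 3
  dimg <- abs(render_beat_image(mod, size = 96) - img1)
  changed <- which(rowSums(dimg) > 0)
  lane5 <- (round(96 / 12 * 4) - 1):(round(96 / 12 * 5) + 1)
  expect_true(all(changed %in% lane5))
})

test_that("grid layout renders one panel per lead", {
  sr <- generate_record("Healthy Control", n_beats = 4, seed = 52)
  segs <- segment_beats(sr$record, sr$truth_r_peaks)
  img <- render_beat_image(segs[[1]], size = 96, layout = "single-lead-grid")
  expect_equal(dim(img), c(96L, 96L))
  expect_lt(min(img), 0.5)
})

test_that("make_dataset yields a balanced labelled image set", {
  res <- make_dataset(3, classes = mi_classes()[c(1, 6, 10)],
                      image_size = 48, seed = 9)
  expect_equal(dim(res$images$images), c(9L, 48L, 48L, 1L))
  expect_equal(as.vector(table(res$images$labels)), c(3L, 3L, 3L))
  expect_equal(nrow(res$manifest$entries), 9L)
  expect_equal(res$manifest$created_with_seed, 9L)
  expect_true(all(file.exists(res$manifest$entries$path)))
  res2 <- make_dataset(3, classes = mi_classes()[c(1, 6, 10)],
                       image_size = 48, seed = 10)
  expect_false(identical(res$images$images, res2$images$images))
  expect_equal(dim(res2$images$images), dim(res$images$images))
})

test_that("a linear probe on ST-window means separates the twelve classes", {
  skip_if_not_installed("nnet")
  set.seed(61)
  feats <- NULL
  labs <- integer()
  for (ci in seq_along(mi_classes())) {
    for (r in 1:3) {
      sr <- generate_record(mi_classes()[ci], n_beats = 6, noise_snr_db = 20,
                            seed = 6000 + ci * 13 + r)
      segs <- segment_beats(sr$record, sr$truth_r_peaks)
      for (s in segs) {
        feats <- rbind(feats, st_level(s, 360))
        labs <- c(labs, ci)
      }
    }
  }
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(labs), feats),
                        trace = FALSE, maxit = 300, MaxNWts = 2000)
  acc <- mean(predict(fit) == factor(labs))
  expect_gte(acc, 0.99)
})
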