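# Record, beat-archive and image-set input/output.

test_that("CSV round trip preserves values and metadata", {
  dir <- withr::local_tempdir()
  sr <- generate_record("Anterior", n_beats = 5, seed = 2)
  p <- file.path(dir, "rec.csv")
  write_record(sr$record, p)
  back <- read_record(p)
  expect_equal(back$signal, sr$record$signal, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$fs, 360)
  expect_equal(back$lead_names, sr$record$lead_names)
  expect_equal(back$record_id, sr$record$record_id)
})

test_that("reader enforces shape, finiteness and sampling rate", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "small.csv")
  write.csv(data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100)),
            p, row.names = FALSE)
  rec <- read_record(p, fs = 360)
  expect_equal(dim(rec$signal), c(100L, 3L))
  expect_error(read_record(p), "fs")
  p2 <- file.path(dir, "bad.csv")
  writeLines(c("x,y", "1,2", "NaN,3"), p2)
  expect_error(read_record(p2, fs = 360), "non-finite")
  expect_error(read_record(file.path(dir, "missing.csv"), fs = 360), "not found")
  expect_error(ecg_record(matrix(1, 5, 1), fs = 0), "fs")
})

test_that("header lead names are re-ordered to the conventional order", {
  dir <- withr::local_tempdir()
  sr <- generate_record("Healthy Control", n_beats = 3, seed = 1)
  shuffled <- sr$record$signal[, c(12:1)]
  p <- file.path(dir, "shuf.csv")
  write.csv(as.data.frame(shuffled), p, row.names = FALSE)
  rec <- read_record(p, fs = 360)
  expect_equal(rec$lead_names,
               c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6)))
  expect_equal(rec$signal[, "V6"], sr$record$signal[, "V6"],
               ignore_attr = TRUE)
})

test_that("WFDB format-16 record pairs are readable", {
  dir <- withr::local_tempdir()
  set.seed(3)
  n <- 500
  adc <- matrix(as.integer(round(rnorm(n * 2) * 200)), n, 2)
  writeBin(as.integer(t(adc)), file.path(dir, "r0.dat"), size = 2,
           endian = "little")
  writeLines(c("r0 2 250 500",
               "r0.dat 16 200 12 0 0 0 0 MLII",
               "r0.dat 16 200 12 0 0 0 0 V5"),
             file.path(dir, "r0.hea"))
  rec <- read_record(file.path(dir, "r0"), format = "wfdb")
  expect_equal(dim(rec$signal), c(500L, 2L))
  expect_equal(rec$lead_names, c("MLII", "V5"))
  expect_equal(rec$signal[, 1], adc[, 1] / 200, ignore_attr = TRUE)
})

test_that("beat archives round trip through the manifest", {
  dir <- withr::local_tempdir()
  sr <- generate_record("Inferior", n_beats = 8, seed = 4)
  peaks <- detect_r_peaks(sr$record$signal[, "II"], 360)
  segs <- segment_beats(sr$record, peaks)
  for (i in seq_along(segs)) segs[[i]]$label <- "Inferior"
  man <- write_beats(segs, file.path(dir, "beats"), seed = 4L)
  expect_s3_class(man, "dataset_manifest")
  expect_equal(nrow(man$entries), length(segs))
  expect_true(all(man$entries$label == "Inferior"))
  expect_true(all(file.exists(man$entries$path)))
  expect_equal(sum(grepl("\\.png$", man$entries$path)), 0L)
  back <- as.matrix(read.csv(gzfile(man$entries$path[1])))
  expect_equal(back, segs[[1]]$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(write_beats(list(), dir), "no segments")
  segs2 <- segs
  segs2[[2]]$values <- segs2[[2]]$values[1:100, ]
  expect_error(write_beats(segs2, dir), "heterogeneous")
})

test_that("rendered images persist at the configured size and reload", {
  dir <- withr::local_tempdir()
  sr <- generate_record("Lateral", n_beats = 6, seed = 5)
  segs <- segment_beats(sr$record,
                        detect_r_peaks(sr$record$signal[, "II"], 360))
  segs <- segs[1:2]
  for (i in 1:2) segs[[i]]$label <- "Lateral"
  man <- write_beats(segs, file.path(dir, "img"), with_images = TRUE,
                     image_size = 224L)
  expect_equal(sum(grepl("\\.png$", man$entries$path)), 2L)
  img <- png::readPNG(man$entries$path[1])
  expect_equal(dim(img)[1:2], c(224L, 224L))
  ds <- load_image_dataset(man, image_size = 224L)
  expect_equal(dim(ds$images), c(2L, 224L, 224L, 1L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_equal(ds$labels, match(c("Lateral", "Lateral"), mi_classes()))
  # downscaling on load
  ds2 <- load_image_dataset(man, image_size = 56L)
  expect_equal(dim(ds2$images)[2:3], c(56L, 56L))
})

test_that("manifests reject duplicate paths and foreign labels", {
  e <- data.frame(path = c("a.png", "a.png"), label = "Anterior",
                  split = "train")
  expect_error(dataset_manifest(e), "unique")
  e2 <- data.frame(path = c("a.png", "b.png"), label = "NotAClass",
                   split = "train")
  expect_error(dataset_manifest(e2), "vocabulary")
})
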