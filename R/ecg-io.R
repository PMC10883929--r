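# Reading and writing ECG records, beat archives, rendered beat images and
# dataset manifests. Signals travel as plain CSV (one column per lead) with a
# YAML sidecar carrying the sampling rate; beats as per-beat gzipped CSV plus
# a CSV manifest; images as 8-bit grayscale PNG.

.lead_order_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

#' The twelve diagnostic classes
#'
#' Healthy control plus the eleven myocardial-infarction localizations, in
#' canonical order.
#' @export
mi_classes <- function() {
  c("Healthy Control", "Anterior", "Anteriolateral", "Anterioseptal",
    "Anterioseptal Lateral", "Inferior", "Inferiolateral", "Inferioposterior",
    "Inferioposterior Lateral", "Lateral", "Posterior", "Posteriolateral")
}

#' Multi-lead ECG record
#'
#' @param signal samples-by-leads numeric matrix in millivolts
#' @param fs sampling rate in Hz (> 0)
#' @param lead_names lead labels; defaults to the conventional 12-lead order
#'   when there are 12 columns, else `L1, L2, ...`
#' @param record_id identifier string
#' @export
ecg_record <- function(signal, fs, lead_names = NULL, record_id = "record") {
  signal <- as.matrix(signal)
  if (ncol(signal) == 0L) stop("record has no leads")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (is.null(lead_names)) {
    lead_names <- if (ncol(signal) == 12L) .lead_order_12
                  else paste0("L", seq_len(ncol(signal)))
  }
  if (length(lead_names) != ncol(signal)) {
    stop("lead_names length does not match the number of signal columns")
  }
  colnames(signal) <- lead_names
  structure(list(signal = signal, fs = fs, lead_names = lead_names,
                 record_id = record_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples x %d leads @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}

.sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".yaml")

#' Write an ECG record as CSV plus YAML sidecar
#'
#' The CSV carries one column per lead with lead names as header; the
#' sidecar stores `fs`, `lead_names` and `record_id`.
#' @param record an [ecg_record()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.csv(as.data.frame(record$signal), path, row.names = FALSE)
  yaml::write_yaml(list(fs = record$fs, lead_names = record$lead_names,
                        record_id = record$record_id),
                   .sidecar_path(path))
  invisible(path)
}

.read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(hdr[3]) else 250
  nsamp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2:(1 + nsig)]), "\\s+")
  datfile <- sig[[1]][1]
  fmt <- sub("x.*$", "", sig[[1]][2])
  gains <- vapply(sig, function(s) {
    g <- suppressWarnings(as.numeric(sub("\\(.*$", "", s[3])))
    if (is.na(g) || g == 0) 200 else g
  }, 0)
  leads <- vapply(seq_along(sig), function(i) {
    s <- sig[[i]]
    if (length(s) >= 9) paste(s[9:length(s)], collapse = " ") else paste0("L", i)
  }, "")
  dat <- file.path(dirname(hea), datfile)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw <- readBin(dat, "raw", n = file.size(dat))
  if (fmt == "16") {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 signed = TRUE, endian = "little")
  } else if (fmt == "212") {
    b <- as.integer(raw)
    np <- (length(b) %/% 3) * 3
    b1 <- b[seq(1, np, 3)]; b2 <- b[seq(2, np, 3)]; b3 <- b[seq(3, np, 3)]
    s1 <- b1 + bitwAnd(b2, 15L) * 256L
    s2 <- b3 + bitwAnd(b2, 240L) * 16L
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
  } else {
    stop("unsupported WFDB signal format '", fmt, "' (only 16 and 212)")
  }
  nr <- length(v) %/% nsig
  if (!is.na(nsamp)) nr <- min(nr, nsamp)
  m <- matrix(v[seq_len(nr * nsig)], ncol = nsig, byrow = TRUE)
  m <- sweep(m, 2, gains, "/")  # ADC units -> physical (mV)
  ecg_record(m, fs, lead_names = leads,
             record_id = sub("\\.hea$", "", basename(hea)))
}

#' Read an ECG record
#'
#' CSV records carry one column per lead; the sampling rate comes from the
#' `fs` argument or from a YAML sidecar next to the file. When the CSV
#' header names match standard 12-lead labels the columns are re-ordered to
#' the conventional order; unnamed columns are taken positionally. WFDB
#' record pairs (`.hea` + `.dat`, formats 16 and 212) are also supported.
#'
#' @param path path to the CSV file or WFDB header/record name
#' @param fs sampling rate in Hz; required for CSV unless a sidecar exists
#' @param format `"auto"`, `"csv"` or `"wfdb"`
#' @return an [ecg_record()]
#' @export
read_record <- function(path, fs = NULL, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(hea|dat)$", path) ||
                  (!file.exists(path) && file.exists(paste0(path, ".hea")))) {
      "wfdb"
    } else "csv"
  }
  if (format == "wfdb") return(.read_wfdb(path))
  if (!file.exists(path)) stop("file not found: ", path)
  head1 <- utils::read.csv(path, nrows = 1, header = FALSE,
                           colClasses = "character")
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(head1)))))
  df <- utils::read.csv(path, header = has_header)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  if (!all(is.finite(m))) stop("signal contains non-finite values")
  lead_names <- if (has_header) colnames(df) else NULL
  record_id <- sub("\\.[^.]+$", "", basename(path))
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (is.null(fs)) fs <- meta$fs
    if (!is.null(meta$record_id)) record_id <- meta$record_id
    if (is.null(lead_names) && !is.null(meta$lead_names)) {
      lead_names <- meta$lead_names
    }
  }
  if (is.null(fs)) stop("fs not supplied and no sidecar found for ", path)
  if (!is.null(lead_names) && all(.lead_order_12 %in% lead_names)) {
    m <- m[, match(.lead_order_12, lead_names), drop = FALSE]
    lead_names <- .lead_order_12
  }
  ecg_record(m, fs, lead_names = lead_names, record_id = record_id)
}

#' Polyphase-resample a record to a target sampling rate
#'
#' Keeps the physical duration of sample-count-based windows consistent
#' across records acquired at different rates.
#' @param record an [ecg_record()]
#' @param fs_target target rate in Hz
#' @export
resample_record <- function(record, fs_target) {
  stopifnot(inherits(record, "ecg_record"), fs_target > 0)
  if (record$fs == fs_target) return(record)
  fr <- as.integer(round(fs_target * 1000))
  to <- as.integer(round(record$fs * 1000))
  g <- .gcd(fr, to)
  sig <- apply(record$signal, 2, function(col) {
    signal::resample(col, p = fr %/% g, q = to %/% g)
  })
  ecg_record(sig, fs_target, lead_names = record$lead_names,
             record_id = record$record_id)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Dataset manifest
#' @param entries data frame with columns `path`, `label`, `split`
#' @param class_names ordered class vocabulary
#' @param seed generation seed or `NA`
#' @export
dataset_manifest <- function(entries, class_names = mi_classes(),
                             seed = NA_integer_) {
  stopifnot(all(c("path", "label", "split") %in% names(entries)))
  if (anyDuplicated(entries$path)) stop("manifest paths must be unique")
  bad <- setdiff(unique(entries$label), class_names)
  if (length(bad) > 0L) {
    stop("labels outside the class vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(list(entries = entries, class_names = class_names,
                 created_with_seed = seed),
            class = "dataset_manifest")
}

#' Persist beat segments (and optionally rendered images)
#'
#' Each beat is written as a gzipped CSV of its samples-by-leads values;
#' with `with_images = TRUE` a grayscale PNG rendering (see
#' [render_beat_image()]) is written next to it and listed in the manifest
#' instead of the CSV. A `manifest.csv` is always written in `out_dir`.
#'
#' @param segments non-empty list of [beat_segment()]s sharing one shape
#' @param out_dir output directory (created if needed)
#' @param with_images render and save 224x224 (or `image_size`) PNGs
#' @param image_size rendered image side length in pixels
#' @param layout rendering layout passed to [render_beat_image()]
#' @param class_names manifest class vocabulary
#' @param seed seed recorded in the manifest
#' @return a [dataset_manifest()]
#' @export
write_beats <- function(segments, out_dir, with_images = FALSE,
                        image_size = 224L, layout = "stacked-leads",
                        class_names = mi_classes(), seed = NA_integer_) {
  if (length(segments) == 0L) stop("no segments to write")
  shp <- vapply(segments, function(s) dim(s$values), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stop("segments have heterogeneous shapes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character(length(segments))
  labels <- character(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    base <- sprintf("beat_%05d", i)
    csvp <- file.path(out_dir, paste0(base, ".csv.gz"))
    con <- gzfile(csvp, "w")
    utils::write.csv(as.data.frame(s$values), con, row.names = FALSE)
    close(con)
    if (with_images) {
      img <- render_beat_image(s, size = image_size, layout = layout)
      pngp <- file.path(out_dir, paste0(base, ".png"))
      png::writePNG(img, pngp)
      paths[i] <- pngp
    } else {
      paths[i] <- csvp
    }
    labels[i] <- if (is.na(s$label)) class_names[1] else s$label
  }
  entries <- data.frame(path = paths, label = labels, split = "train",
                        stringsAsFactors = FALSE)
  man <- dataset_manifest(entries, class_names = class_names, seed = seed)
  utils::write.csv(entries, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  man
}

.bilinear_resize <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  if (H == h && W == w) return(m)
  ry <- (seq_len(h) - 0.5) * H / h + 0.5
  rx <- (seq_len(w) - 0.5) * W / w + 0.5
  y0 <- pmin(pmax(floor(ry), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(rx), 1L), W); x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * (1 - fy) + m[y1, x0, drop = FALSE] * fy
  b <- m[y0, x1, drop = FALSE] * (1 - fy) + m[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = h) + b * rep(fx, each = h)
}

#' Load a labelled image set from a manifest
#'
#' Reads every PNG listed in the manifest, converts to grayscale in
#' `[0, 1]`, resizes to `image_size` and encodes labels as integers
#' following the manifest's class order (1-based).
#'
#' @param manifest a [dataset_manifest()]
#' @param image_size target side length in pixels
#' @return a `labeled_image_set`: `images` array `[n, H, W, 1]`, integer
#'   `labels`, and `class_names`
#' @export
load_image_dataset <- function(manifest, image_size = 224L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  e <- manifest$entries
  n <- nrow(e)
  images <- array(0, c(n, image_size, image_size, 1L))
  labels <- match(e$label, manifest$class_names)
  if (anyNA(labels)) {
    stop("unknown label(s): ",
         paste(unique(e$label[is.na(labels)]), collapse = ", "))
  }
  for (i in seq_len(n)) {
    if (!file.exists(e$path[i])) stop("missing file: ", e$path[i])
    m <- png::readPNG(e$path[i])
    if (length(dim(m)) == 3L) m <- apply(m[, , 1:min(3, dim(m)[3])], c(1, 2), mean)
    images[i, , , 1] <- .bilinear_resize(m, image_size, image_size)
  }
  structure(list(images = images, labels = as.integer(labels),
                 class_names = manifest$class_names),
            class = "labeled_image_set")
}

#' Construct a labelled image set directly from in-memory images
#' @keywords internal
labeled_image_set <- function(images, labels, class_names) {
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names),
            class = "labeled_image_set")
}
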