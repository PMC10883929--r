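# Class-conditional synthetic 12-lead ECG with known R-peak ground truth.
#
# Beats are sums of Gaussian bumps (P, Q, R, S, T) repeated at the heart
# rate with small RR jitter; infarct classes superimpose lead-specific ST
# plateaus, pathological Q waves and tall-R modifications on the leads that
# express each territory. The generator is fully deterministic given
# (seed, configuration) and stores the noiseless reference plus true R-peak
# and T-apex indices, so the detection and evaluation stages can be scored
# against ground truth.

#' Beat morphology template
#'
#' Component waves as Gaussian bumps: amplitudes in mV, centers in seconds
#' relative to the R peak, widths as Gaussian standard deviations in
#' seconds.
#'
#' @param p_amp,q_amp,r_amp,s_amp,t_amp component amplitudes (mV)
#' @param p_c,q_c,r_c,s_c,t_c component centers (s, relative to R)
#' @param p_w,q_w,r_w,s_w,t_w component widths (s)
#' @param heart_rate beats per minute
#' @param fs sampling rate in Hz
#' @export
beat_template <- function(p_amp = 0.15, q_amp = -0.10, r_amp = 1.0,
                          s_amp = -0.15, t_amp = 0.30,
                          p_c = -0.20, q_c = -0.035, r_c = 0, s_c = 0.035,
                          t_c = 0.30,
                          p_w = 0.025, q_w = 0.010, r_w = 0.012, s_w = 0.010,
                          t_w = 0.060,
                          heart_rate = 75, fs = 360) {
  stopifnot(r_amp > abs(q_amp), r_amp > abs(s_amp),
            p_c < q_c, q_c < r_c, r_c < s_c, s_c < t_c)
  structure(list(
    amps = c(P = p_amp, Q = q_amp, R = r_amp, S = s_amp, T = t_amp),
    centers = c(P = p_c, Q = q_c, R = r_c, S = s_c, T = t_c),
    widths = c(P = p_w, Q = q_w, R = r_w, S = s_w, T = t_w),
    heart_rate = heart_rate, fs = fs
  ), class = "beat_template")
}

# Per-lead scaling of the template: conventional projections of a single
# dipole-like beat onto the 12 leads (aVR inverted).
.lead_gain <- c(I = 0.7, II = 1.0, III = 0.5, aVR = -0.6, aVL = 0.4,
                aVF = 0.7, V1 = 0.4, V2 = 0.5, V3 = 0.7, V4 = 1.1,
                V5 = 1.0, V6 = 0.8)

#' Lead-specific class signatures for the twelve diagnostic classes
#'
#' Each signature lists the leads carrying ST-segment elevation or
#' depression (signed offsets in mV), the leads carrying pathological Q
#' waves, a Q-amplitude scale (fraction of the lead's R amplitude) and any
#' tall-R leads. Healthy Control modifies nothing; reciprocal ST changes
#' are included for the inferior-territory classes.
#'
#' @param st_effect magnitude of the ST offset in mV (default 0.2)
#' @param q_scale pathological-Q depth as a fraction of the R amplitude
#' @return named list of signatures, one per class of [mi_classes()]
#' @export
class_signatures <- function(st_effect = 0.2, q_scale = 0.4) {
  el <- st_effect; de <- -st_effect
  sig <- function(st = numeric(), q = character(), qs = q_scale,
                  tall_r = character()) {
    list(st = st, q_leads = q, q_scale = qs, tall_r = tall_r)
  }
  st <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  list(
    "Healthy Control" = sig(),
    "Anterior" = sig(st(V1 = de, V2 = de, V3 = de, V4 = de, V5 = de, V6 = de),
                     q = paste0("V", 1:6)),
    "Anteriolateral" = sig(st(I = el, aVL = el, V2 = el, V3 = el, V4 = el,
                              V5 = el),
                           q = c("I", "aVL", "V2", "V3", "V4", "V5")),
    "Anterioseptal" = sig(st(V1 = el, V2 = el, V3 = el), q = c("V2", "V3")),
    "Anterioseptal Lateral" = sig(st(I = el, aVL = el),
                                  q = c("V2", "V3"), qs = 1.4 * q_scale),
    "Inferior" = sig(st(II = el, III = el, aVF = el, I = de, aVL = de,
                        V1 = de, V2 = de, V3 = de)),
    "Inferiolateral" = sig(st(II = el, III = el, aVF = el, V5 = el, V6 = el),
                           q = c("II", "III", "aVF", "V5", "V6")),
    "Inferioposterior" = sig(st(II = el, III = el, aVF = el, V1 = de, V2 = de),
                             q = c("II", "III", "aVF")),
    "Inferioposterior Lateral" = sig(st(II = el, III = el, aVF = el, V5 = el,
                                        V6 = el, V1 = de, V2 = de),
                                     q = c("II", "III", "aVF")),
    "Lateral" = sig(st(I = el, aVL = el, V5 = el, V6 = el),
                    q = c("V5", "V6")),
    "Posterior" = sig(st(V1 = de, V2 = de, V3 = de),
                      tall_r = c("V1", "V2")),
    "Posteriolateral" = sig(st(V1 = de, V2 = de, V3 = de, I = el, aVL = el,
                               V5 = el, V6 = el),
                            q = c("V5", "V6"))
  )
}

# Smooth ST plateau: raised-cosine box between `from` and `to` seconds after
# the R peak with `ramp`-second transitions.
.st_plateau <- function(tt, from = 0.06, to = 0.24, ramp = 0.02) {
  y <- numeric(length(tt))
  core <- tt >= from + ramp & tt <= to - ramp
  y[core] <- 1
  up <- tt >= from & tt < from + ramp
  y[up] <- 0.5 * (1 - cos(pi * (tt[up] - from) / ramp))
  dn <- tt > to - ramp & tt <= to
  y[dn] <- 0.5 * (1 + cos(pi * (tt[dn] - (to - ramp)) / ramp))
  y
}

#' The ST-segment measurement window in seconds after the R peak
#' @keywords internal
st_window <- function() c(0.08, 0.20)

#' Generate a class-conditional synthetic 12-lead record
#'
#' @param label one of [mi_classes()]
#' @param n_beats number of beats (>= 1)
#' @param fs sampling rate in Hz (>= 100)
#' @param noise_snr_db additive white-Gaussian-noise level per lead in dB;
#'   `Inf` disables noise
#' @param seed RNG seed; the record is fully reproducible from it
#' @param template a [beat_template()]
#' @param signatures output of [class_signatures()]
#' @param rr_jitter_sd standard deviation of the RR-interval jitter (s)
#' @param min_duration minimum record duration in seconds (tail-padded with
#'   baseline when the requested beats span less)
#' @return a `synthetic_record`: `record` ([ecg_record()]), integer
#'   `truth_r_peaks` and `truth_t_peaks`, noiseless `clean_reference`
#'   matrix, `label`, `seed`
#' @export
generate_record <- function(label, n_beats = 10L, fs = 360,
                            noise_snr_db = Inf, seed = 1L,
                            template = beat_template(fs = fs),
                            signatures = class_signatures(),
                            rr_jitter_sd = 0.02, min_duration = 0) {
  if (!label %in% names(signatures)) stop("unknown class label '", label, "'")
  stopifnot(n_beats >= 1L, fs >= 100)
  sg <- signatures[[label]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  rr <- 60 / template$heart_rate
  gaps <- rr + stats::rnorm(n_beats - 1L, 0, rr_jitter_sd)
  gaps <- pmax(gaps, 0.4)
  centers <- 0.6 + cumsum(c(0, gaps))
  dur <- max(centers[n_beats] + 0.8, min_duration)
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1L) / fs

  leads <- .lead_order_12
  clean <- matrix(0, n, 12L, dimnames = list(NULL, leads))
  amps <- template$amps; cts <- template$centers; wds <- template$widths
  for (li in seq_along(leads)) {
    ld <- leads[li]
    g <- .lead_gain[[ld]]
    a <- amps * g
    if (ld %in% sg$tall_r) a["R"] <- a["R"] * 1.6
    if (ld %in% sg$q_leads) {
      a["Q"] <- -sg$q_scale * abs(a["R"]) * sign(g)
      wq <- 0.060 / (2 * sqrt(2 * log(2)))  # 60 ms full width at half maximum
    } else wq <- wds["Q"]
    w <- wds; w["Q"] <- wq
    stoff <- if (ld %in% names(sg$st)) sg$st[[ld]] else 0
    col <- numeric(n)
    for (ck in centers) {
      dt <- tt - ck
      near <- which(dt > -0.45 & dt < 0.65)
      dn <- dt[near]
      acc <- numeric(length(near))
      for (wv in names(a)) {
        acc <- acc + a[[wv]] * exp(-((dn - cts[[wv]])^2) / (2 * w[[wv]]^2))
      }
      if (stoff != 0) acc <- acc + stoff * .st_plateau(dn)
      col[near] <- col[near] + acc
    }
    clean[, li] <- col
  }

  truth_r <- as.integer(round(centers * fs) + 1L)
  truth_t <- as.integer(round((centers + cts[["T"]]) * fs) + 1L)

  sigm <- clean
  if (is.finite(noise_snr_db)) {
    for (li in seq_len(12L)) {
      rms <- sqrt(mean(clean[, li]^2))
      sd_n <- rms * 10^(-noise_snr_db / 20)
      sigm[, li] <- clean[, li] + stats::rnorm(n, 0, sd_n)
    }
  }
  structure(list(
    record = ecg_record(sigm, fs, record_id = sprintf("syn_%s_%d",
                                                      gsub(" ", "", label), seed)),
    truth_r_peaks = truth_r, truth_t_peaks = truth_t,
    clean_reference = clean, label = label, seed = seed
  ), class = "synthetic_record")
}

#' Render a beat segment as a grayscale image
#'
#' Deterministic anti-aliased rendering: white background, dark trace, one
#' horizontal lane per lead in canonical order (`"stacked-leads"`), or a
#' 4-row by 3-column panel grid (`"single-lead-grid"`). Amplitudes use a
#' fixed +/- `amp_range` mV scale per lane so absolute displacements such
#' as ST shifts stay visible; values beyond the scale are clipped.
#'
#' @param beat a [beat_segment()] (or samples-by-leads matrix)
#' @param size output side length in pixels
#' @param layout `"stacked-leads"` or `"single-lead-grid"`
#' @param amp_range half-range of the amplitude scale in mV
#' @return `size` x `size` numeric matrix in `[0, 1]`
#' @export
render_beat_image <- function(beat, size = 224L, layout = c("stacked-leads",
                                                            "single-lead-grid"),
                              amp_range = 1.8) {
  layout <- match.arg(layout)
  vals <- if (inherits(beat, "beat_segment")) beat$values else as.matrix(beat)
  L <- ncol(vals)
  if (L < 1L) stop("beat has no leads")
  img <- matrix(1, size, size)
  draw_trace <- function(img, y_px, x0, x1, r0, r1) {
    # y_px: trace row position per pixel column (already in image coords)
    n_col <- x1 - x0 + 1L
    for (cx in seq_len(n_col)) {
      y0 <- y_px[max(1L, cx - 1L)]
      y1 <- y_px[cx]
      lo <- min(y0, y1); hi <- max(y0, y1)
      rlo <- max(r0, floor(lo - 0.5)); rhi <- min(r1, ceiling(hi + 0.5))
      if (rlo > rhi) next
      rr <- rlo:rhi
      cov <- pmin(hi + 0.5, rr + 0.5) - pmax(lo - 0.5, rr - 0.5)
      cov <- pmin(pmax(cov, 0), 1)
      col <- x0 + cx - 1L
      img[rr, col] <- pmin(img[rr, col], 1 - cov)
    }
    img
  }
  place <- function(img, v, x0, x1, r0, r1) {
    lane_h <- r1 - r0 + 1L
    yc <- (r0 + r1) / 2
    nx <- x1 - x0 + 1L
    # linear interpolation of the lead onto the pixel columns
    xi <- seq(1, length(v), length.out = nx)
    vi <- stats::approx(seq_along(v), v, xout = xi)$y
    vi <- pmin(pmax(vi, -amp_range), amp_range)
    y_px <- yc - vi / amp_range * (lane_h * 0.45)
    draw_trace(img, y_px, x0, x1, r0, r1)
  }
  if (layout == "stacked-leads") {
    bounds <- round(seq(0, size, length.out = L + 1L))
    for (j in seq_len(L)) {
      r0 <- bounds[j] + 1L; r1 <- bounds[j + 1L]
      img <- place(img, vals[, j], 1L, size, r0, r1)
    }
  } else {
    nrows <- 4L; ncols <- ceiling(L / nrows)
    rb <- round(seq(0, size, length.out = nrows + 1L))
    cb <- round(seq(0, size, length.out = ncols + 1L))
    for (j in seq_len(L)) {
      ri <- (j - 1L) %% nrows + 1L
      ci <- (j - 1L) %/% nrows + 1L
      img <- place(img, vals[, j], cb[ci] + 1L, cb[ci + 1L],
                   rb[ri] + 1L, rb[ri + 1L])
    }
  }
  img
}

#' Generate, preprocess and render a labelled synthetic dataset
#'
#' For each class: records are generated with [generate_record()], each
#' lead is wavelet-denoised, R peaks are detected on lead II with
#' Pan-Tompkins, beats are segmented with the default 250/400 window and
#' rendered to grayscale PNGs. A manifest recording the seed accompanies
#' the images.
#'
#' @param n_per_class beat images per class (>= 1)
#' @param classes class labels (default all twelve)
#' @param fs sampling rate in Hz
#' @param noise_snr_db additive noise level in dB (`Inf` = clean)
#' @param seed master seed; per-record seeds derive from it
#' @param out_dir output directory for PNGs and the manifest
#' @param image_size rendered image side length
#' @param n_beats_per_record beats generated per record before edge losses
#' @param st_effect,q_scale signature effect sizes, see [class_signatures()]
#' @return list with `manifest` ([dataset_manifest()]) and `images`
#'   (`labeled_image_set`)
#' @export
make_dataset <- function(n_per_class, classes = mi_classes(), fs = 360,
                         noise_snr_db = 20, seed = 1L,
                         out_dir = tempfile("ecgds"), image_size = 224L,
                         n_beats_per_record = 12L,
                         st_effect = 0.2, q_scale = 0.4) {
  stopifnot(n_per_class >= 1L)
  sigs <- class_signatures(st_effect = st_effect, q_scale = q_scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg_cfg <- segmentation_config()
  n_total <- n_per_class * length(classes)
  images <- array(0, c(n_total, image_size, image_size, 1L))
  labels <- integer(n_total)
  paths <- character(n_total)
  i <- 0L
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    got <- 0L
    rec_i <- 0L
    while (got < n_per_class) {
      rec_i <- rec_i + 1L
      if (rec_i > 50L) stop("could not collect enough beats for ", cls)
      sr <- generate_record(cls, n_beats = n_beats_per_record, fs = fs,
                            noise_snr_db = noise_snr_db,
                            seed = seed * 1000L + ci * 97L + rec_i,
                            signatures = sigs)
      den <- dwt_denoise(sr$record$signal)
      rec <- ecg_record(den, fs, lead_names = sr$record$lead_names,
                        record_id = sr$record$record_id)
      lead <- match("II", rec$lead_names)
      peaks <- detect_r_peaks(rec$signal[, lead], fs)
      segs <- segment_beats(rec, peaks, seg_cfg)
      for (s in segs) {
        if (got >= n_per_class) break
        got <- got + 1L; i <- i + 1L
        img <- render_beat_image(s, size = image_size)
        p <- file.path(out_dir, sprintf("%s_%03d.png",
                                        gsub(" ", "_", cls), got))
        png::writePNG(img, p)
        images[i, , , 1] <- img
        labels[i] <- ci
        paths[i] <- p
      }
    }
  }
  entries <- data.frame(path = paths, label = classes[labels],
                        split = "train", stringsAsFactors = FALSE)
  man <- dataset_manifest(entries, class_names = classes, seed = seed)
  utils::write.csv(entries, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  list(manifest = man,
       images = labeled_image_set(images, labels, classes))
}

#' Mean ST-window level per lead of a beat segment
#'
#' Measures the mean amplitude in the 80-200 ms window after the R peak on
#' every lead, relative to the isoelectric baseline estimated just before
#' the P wave. This is the linear-probe feature used to verify that the
#' synthetic class signatures are measurable.
#'
#' @param beat a [beat_segment()]
#' @param fs sampling rate in Hz
#' @return named numeric vector, one value per lead
#' @export
st_level <- function(beat, fs) {
  w <- st_window()
  r <- beat$r_index_local
  i0 <- r + round(w[1] * fs); i1 <- r + round(w[2] * fs)
  b0 <- r - round(0.30 * fs); b1 <- r - round(0.26 * fs)
  n <- nrow(beat$values)
  i0 <- min(max(i0, 1L), n); i1 <- min(max(i1, 1L), n)
  b0 <- min(max(b0, 1L), n); b1 <- min(max(b1, 1L), n)
  colMeans(beat$values[i0:i1, , drop = FALSE]) -
    colMeans(beat$values[b0:b1, , drop = FALSE])
}
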