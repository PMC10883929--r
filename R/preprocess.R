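# QRS detection (Pan-Tompkins) and fixed-window beat segmentation.

#' Pan-Tompkins detector configuration
#'
#' The canonical published constants: 5-15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, 200 ms refractory
#' period, running signal/noise peak estimates updated with factors
#' 0.125/0.25, and search-back triggered at 1.66 times the running RR
#' average.
#'
#' @param bandpass_low,bandpass_high pass-band edges in Hz
#' @param filter_order Butterworth order of the band-pass
#' @param mwi_window moving-window-integration width in seconds
#' @param refractory minimum peak separation in seconds
#' @param update_factor running-estimate update weight for regular detections
#' @param searchback_update update weight used for search-back detections
#' @param searchback logical, enable RR-gap search-back
#' @param searchback_factor multiple of the running RR average that triggers
#'   search-back
#' @param refine_window half-width (seconds) of the window used to snap each
#'   detection to the local signal maximum
#' @export
peak_config <- function(bandpass_low = 5, bandpass_high = 15,
                        filter_order = 3, mwi_window = 0.150,
                        refractory = 0.200, update_factor = 0.125,
                        searchback_update = 0.25, searchback = TRUE,
                        searchback_factor = 1.66, refine_window = 0.075) {
  stopifnot(refractory > 0, mwi_window > 0,
            bandpass_low > 0, bandpass_high > bandpass_low)
  structure(as.list(environment()), class = "peak_config")
}

.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Stages in order: band-pass filter, derivative, squaring, moving-window
#' integration, adaptive dual-threshold peak selection with search-back.
#' Detections are snapped to the local maximum of the input signal so the
#' returned indices point at R waves of `x` itself.
#'
#' @param x single-lead numeric signal
#' @param fs sampling rate in Hz (>= 100)
#' @param cfg a [peak_config()]
#' @return strictly increasing integer vector of R-peak sample indices
#' @export
detect_r_peaks <- function(x, fs, cfg = peak_config()) {
  if (fs < 100) stop("sampling rate must be at least 100 Hz")
  if (length(x) < 2 * fs) {
    stop("signal shorter than twice the 1 s learning phase")
  }
  learn <- min(2 * fs, length(x))
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)

  bp <- signal::butter(cfg$filter_order,
                       c(cfg$bandpass_low, cfg$bandpass_high) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bp, x)
  # centred five-point derivative (zero phase)
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  wlen <- max(1L, round(cfg$mwi_window * fs))
  mwi <- stats::filter(sq, rep(1 / wlen, wlen), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  cand <- .local_maxima(mwi)
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) return(integer())

  refr <- round(cfg$refractory * fs)
  spki <- max(mwi[seq_len(learn)])
  npki <- mean(mwi[seq_len(learn)])
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer()
  rr <- numeric()
  last_scanned <- 0L
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    v <- mwi[p]
    accepted <- FALSE
    if (length(qrs) == 0L || p - qrs[length(qrs)] > refr) {
      if (v > thr1) {
        # T-wave discrimination: a peak within 360 ms of the previous QRS
        # whose height is under half of it is treated as a T wave
        tw <- length(qrs) > 0L && (p - qrs[length(qrs)]) < round(0.36 * fs) &&
          v < 0.5 * mwi[qrs[length(qrs)]]
        if (!tw) {
          if (length(qrs) > 0L) rr <- c(rr, p - qrs[length(qrs)])
          qrs <- c(qrs, p)
          spki <- cfg$update_factor * v + (1 - cfg$update_factor) * spki
          accepted <- TRUE
        } else {
          npki <- cfg$update_factor * v + (1 - cfg$update_factor) * npki
        }
      } else {
        npki <- cfg$update_factor * v + (1 - cfg$update_factor) * npki
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    # search-back over a missed RR interval
    if (cfg$searchback && !accepted && length(qrs) >= 2L && length(rr) > 0L) {
      rr_avg <- mean(utils::tail(rr, 8))
      if (p - qrs[length(qrs)] > cfg$searchback_factor * rr_avg) {
        thr2 <- 0.5 * thr1
        inwin <- cand[cand > qrs[length(qrs)] + refr & cand < p & cand > last_scanned]
        inwin <- inwin[mwi[inwin] > thr2]
        if (length(inwin) > 0L) {
          pb <- inwin[which.max(mwi[inwin])]
          rr <- c(rr, pb - qrs[length(qrs)])
          qrs <- sort(c(qrs, pb))
          spki <- cfg$searchback_update * mwi[pb] +
            (1 - cfg$searchback_update) * spki
          thr1 <- npki + 0.25 * (spki - npki)
          next  # re-examine the current candidate against the new last QRS
        }
        last_scanned <- p
      }
    }
    i <- i + 1L
  }
  if (length(qrs) == 0L) return(integer())

  # snap each detection to the local maximum of the raw input
  w <- round(cfg$refine_window * fs)
  w <- as.integer(w)
  peaks <- vapply(as.integer(qrs), function(p) {
    a <- max(1L, p - w); b <- min(n, p + w)
    a + which.max(x[a:b]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) > refr)
    }
  }
  as.integer(peaks)
}

#' Beat segmentation configuration
#'
#' @param left samples kept before the R peak (default 250)
#' @param right samples kept after the R peak (default 400), giving the
#'   default segment length 651
#' @param lead_for_detection lead whose signal drives R-peak detection
#' @param boundary_policy `"drop"` discards beats whose window crosses a
#'   record boundary; `"pad-edge"` replicates the edge sample instead
#' @export
segmentation_config <- function(left = 250L, right = 400L,
                                lead_for_detection = "II",
                                boundary_policy = c("drop", "pad-edge")) {
  left <- as.integer(left); right <- as.integer(right)
  if (left < 0L || right < 0L) stop("segment offsets must be non-negative")
  structure(list(left = left, right = right,
                 lead_for_detection = lead_for_detection,
                 boundary_policy = match.arg(boundary_policy)),
            class = "segmentation_config")
}

#' One fixed-length beat window
#' @param values segment-length x leads matrix
#' @param r_index_local 1-based R-peak position inside the segment
#' @param r_index_global 1-based R-peak sample index in the source record
#' @param label class label or `NA`
#' @param source_record record identifier
#' @export
beat_segment <- function(values, r_index_local, r_index_global,
                         label = NA_character_, source_record = "") {
  values <- as.matrix(values)
  stopifnot(r_index_local >= 1L, r_index_local <= nrow(values))
  structure(list(values = values,
                 r_index_local = as.integer(r_index_local),
                 r_index_global = as.integer(r_index_global),
                 label = label, source_record = source_record),
            class = "beat_segment")
}

#' Slice fixed-length beats around R peaks
#'
#' Every segment spans `left + right + 1` samples on all leads with the R
#' peak at local position `left + 1`. Peaks whose window would cross a
#' record boundary are dropped or edge-padded according to the policy.
#'
#' @param record an [ecg_record()]
#' @param peaks integer R-peak indices
#' @param cfg a [segmentation_config()]
#' @return list of [beat_segment()]s
#' @export
segment_beats <- function(record, peaks, cfg = segmentation_config()) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$signal)
  if (length(peaks) == 0L) return(list())
  if (any(peaks < 1L | peaks > n)) stop("peaks outside record bounds")
  out <- list()
  for (p in as.integer(peaks)) {
    idx <- (p - cfg$left):(p + cfg$right)
    if (any(idx < 1L | idx > n)) {
      if (cfg$boundary_policy == "drop") next
      idx <- pmin(pmax(idx, 1L), n)
    }
    out[[length(out) + 1L]] <- beat_segment(
      values = record$signal[idx, , drop = FALSE],
      r_index_local = cfg$left + 1L,
      r_index_global = p,
      source_record = record$record_id
    )
  }
  out
}

.match_peaks <- function(truth, detected, tol) {
  if (length(truth) == 0L) {
    return(list(miss = 0, false = if (length(detected)) 1 else 0, hits = 0L))
  }
  hit <- logical(length(truth))
  false <- 0L
  for (d in detected) {
    j <- which.min(abs(truth - d))
    if (abs(truth[j] - d) <= tol && !hit[j]) hit[j] <- TRUE else false <- false + 1L
  }
  list(miss = mean(!hit), false = false / max(1L, length(detected)),
       hits = sum(hit))
}

#' Select the integration-window width by cost minimisation
#'
#' Evaluates the detection cost
#' `C(W) = miss_rate + false_rate + lambda * twave_overlap`
#' over a grid of candidate moving-window-integration widths on annotated
#' records and returns the minimiser (ties broken toward the smaller
#' width). `twave_overlap` is the fraction of detections that land closer
#' to an annotated T-wave apex than to any true R peak. The equivalent
#' dimensionless constant `k = W * fs` relating the chosen width to the
#' sampling rate is reported alongside.
#'
#' @param candidates candidate window widths in seconds
#' @param annotated list of synthetic records (see [generate_record()]) or
#'   lists with fields `record`, `truth_r_peaks` and optionally
#'   `truth_t_peaks`
#' @param lambda weight of the T-wave-overlap term (>= 0)
#' @param tol match tolerance in seconds between truth and detection
#' @return a `window_cost` list: `W`, `miss_rate`, `false_rate`,
#'   `twave_overlap`, `lambda`, `C`, `k`, `fs`, and the full cost grid
#' @export
optimize_window <- function(candidates, annotated, lambda = 1, tol = 0.05) {
  if (length(candidates) == 0L) stop("no candidate windows supplied")
  if (length(annotated) == 0L) stop("no annotated records supplied")
  stopifnot(lambda >= 0)
  candidates <- sort(candidates)
  fs <- annotated[[1]]$record$fs
  grid <- lapply(candidates, function(W) {
    miss <- fa <- tw <- 0
    for (a in annotated) {
      lead <- match("II", a$record$lead_names, nomatch = 1L)
      det <- detect_r_peaks(a$record$signal[, lead], a$record$fs,
                            peak_config(mwi_window = W))
      m <- .match_peaks(a$truth_r_peaks, det, tol * a$record$fs)
      miss <- miss + m$miss
      fa <- fa + m$false
      if (!is.null(a$truth_t_peaks) && length(det) > 0L) {
        dr <- vapply(det, function(d) min(abs(a$truth_r_peaks - d)), 0)
        dt <- vapply(det, function(d) min(abs(a$truth_t_peaks - d)), 0)
        tw <- tw + mean(dt < dr)
      }
    }
    k <- length(annotated)
    c(miss = miss / k, false = fa / k, tw = tw / k)
  })
  cost <- vapply(grid, function(g) g["miss"] + g["false"] + lambda * g["tw"], 0)
  best <- which.min(cost)  # which.min takes the first (smallest W) on ties
  g <- grid[[best]]
  structure(list(W = candidates[best], miss_rate = unname(g["miss"]),
                 false_rate = unname(g["false"]),
                 twave_overlap = unname(g["tw"]), lambda = lambda,
                 C = unname(cost[best]), k = candidates[best] * fs, fs = fs,
                 candidates = candidates, costs = unname(cost)),
            class = "window_cost")
}

#' Window width from the sampling-rate closed form
#'
#' `W = k / fs`: the window scales inversely with the sampling rate so a
#' fixed dimensionless constant `k` keeps its physical duration.
#' @param k dimensionless constant
#' @param fs sampling rate in Hz
#' @export
window_from_constant <- function(k, fs) {
  stopifnot(k > 0, fs > 0)
  k / fs
}
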