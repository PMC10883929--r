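# Periodized discrete wavelet transform and wavelet-shrinkage denoising.
#
# The transform is the orthogonal periodized DWT: circular convolution with
# the Daubechies analysis pair followed by dyadic downsampling, so each level
# halves the coefficient count exactly and the inverse (the adjoint) is a
# perfect reconstruction.

.daub_lo <- list(
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574, 0.008746094047405777,
          0.013981027917398282, -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828, -0.2840155429615469,
          -0.015829105256349306, 0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401)
)

#' Analysis filter pair for a Daubechies wavelet
#'
#' @param wavelet one of `"db2"`, `"db4"`, `"db6"`, `"db8"`
#' @return list with low-pass `lo` and high-pass `hi` decomposition filters
#' @export
dwt_filters <- function(wavelet = "db6") {
  lo <- .daub_lo[[wavelet]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.daub_lo), collapse = ", "))
  }
  L <- length(lo)
  m <- seq_len(L)
  hi <- (-1)^m * lo[L + 1L - m]
  list(lo = lo, hi = hi)
}

#' Maximum useful decomposition level for a signal length
#' @param n signal length
#' @param wavelet wavelet name
#' @export
dwt_max_level <- function(n, wavelet = "db6") {
  L <- length(dwt_filters(wavelet)$lo)
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  odd <- n %% 2L == 1L
  if (odd) { x <- c(x, x[n]); n <- n + 1L }
  L <- length(lo)
  nh <- n %/% 2L
  pos0 <- 2L * seq_len(nh) - 1L + L %/% 2L
  cA <- numeric(nh); cD <- numeric(nh)
  for (m in seq_len(L)) {
    xi <- x[((pos0 - m) %% n) + 1L]
    cA <- cA + lo[m] * xi
    cD <- cD + hi[m] * xi
  }
  list(cA = cA, cD = cD, odd = odd)
}

.idwt_step <- function(cA, cD, lo, hi, odd = FALSE) {
  nh <- length(cA)
  n <- 2L * nh
  L <- length(lo)
  pos0 <- 2L * seq_len(nh) - 1L + L %/% 2L
  x <- numeric(n)
  for (m in seq_len(L)) {
    idx <- ((pos0 - m) %% n) + 1L
    x[idx] <- x[idx] + lo[m] * cA + hi[m] * cD
  }
  if (odd) x <- x[-n]
  x
}

#' Multi-level periodized DWT decomposition
#'
#' @param x numeric vector
#' @param wavelet wavelet name
#' @param level decomposition depth
#' @return list with final approximation `a`, detail coefficient list `d`
#'   (element i is level i, finest first), and bookkeeping for [idwt()]
#' @export
dwt <- function(x, wavelet = "db6", level = 1L) {
  stopifnot(level >= 1L)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  maxl <- dwt_max_level(length(x), wavelet)
  if (level > maxl) {
    stop("level ", level, " too deep for signal of length ", length(x),
         " with ", wavelet, " (max ", maxl, ")")
  }
  f <- dwt_filters(wavelet)
  d <- vector("list", level)
  odd <- logical(level)
  a <- x
  for (j in seq_len(level)) {
    st <- .dwt_step(a, f$lo, f$hi)
    d[[j]] <- st$cD
    odd[j] <- st$odd
    a <- st$cA
  }
  structure(list(a = a, d = d, wavelet = wavelet, odd = odd, n = length(x)),
            class = "ecg_dwt")
}

#' Inverse of [dwt()]
#' @param w an `ecg_dwt` object
#' @export
idwt <- function(w) {
  f <- dwt_filters(w$wavelet)
  a <- w$a
  for (j in rev(seq_along(w$d))) {
    a <- .idwt_step(a, w$d[[j]], f$lo, f$hi, odd = w$odd[j])
  }
  a
}

#' Denoising configuration
#'
#' @param wavelet mother wavelet (the pipeline default is Daubechies-6)
#' @param level decomposition depth, or `"auto"` for
#'   `min(4, maximum permitted by the signal length)`
#' @param threshold_rule `"universal-soft"` (default) or `"universal-hard"`;
#'   the universal threshold is `sigma * sqrt(2 log N)` with `sigma`
#'   estimated from the median absolute deviation of the finest detail band
#' @param detail_levels which detail levels to threshold; `NULL` means all.
#'   An empty integer vector disables shrinkage entirely, making the
#'   transform a perfect-reconstruction identity.
#' @export
denoise_config <- function(wavelet = "db6", level = "auto",
                           threshold_rule = c("universal-soft", "universal-hard"),
                           detail_levels = NULL) {
  structure(list(wavelet = wavelet, level = level,
                 threshold_rule = match.arg(threshold_rule),
                 detail_levels = detail_levels),
            class = "denoise_config")
}

#' Wavelet-shrinkage ECG denoising
#'
#' Decomposes the signal with the periodized DWT, soft- or hard-thresholds
#' the detail coefficients at the universal threshold, and reconstructs.
#' Output length always equals input length. Matrices are denoised one
#' column (lead) at a time.
#'
#' @param x numeric vector, or a samples-by-leads matrix
#' @param cfg a [denoise_config()]
#' @return denoised signal with the same shape as `x`
#' @export
dwt_denoise <- function(x, cfg = denoise_config()) {
  if (is.matrix(x)) {
    return(apply(x, 2, dwt_denoise, cfg = cfg))
  }
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  level <- cfg$level
  if (identical(level, "auto")) level <- min(4L, dwt_max_level(n, cfg$wavelet))
  if (level < 1L) stop("signal too short to decompose with ", cfg$wavelet)
  w <- dwt(x, cfg$wavelet, level)
  which_lv <- cfg$detail_levels
  if (is.null(which_lv)) which_lv <- seq_len(level)
  if (length(which_lv) > 0L) {
    sigma <- stats::median(abs(w$d[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    for (j in intersect(which_lv, seq_len(level))) {
      dj <- w$d[[j]]
      if (cfg$threshold_rule == "universal-soft") {
        w$d[[j]] <- sign(dj) * pmax(abs(dj) - thr, 0)
      } else {
        w$d[[j]] <- dj * (abs(dj) > thr)
      }
    }
  }
  idwt(w)
}
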