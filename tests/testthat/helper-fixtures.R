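# Shared fixtures: small deterministic signals and a cached synthetic
# image set used by several test files (built once per test run).

# a clean beat train plus known white noise, for denoising SNR checks
make_noisy_beats <- function(seed = 7, snr_db = 5, n = 4096, fs = 360) {
  set.seed(seed)
  tt <- (seq_len(n) - 1) / fs
  clean <- numeric(n)
  for (ck in seq(0.5, max(tt) - 0.5, by = 0.8)) {
    clean <- clean + exp(-((tt - ck)^2) / (2 * 0.012^2)) +
      0.25 * exp(-((tt - ck - 0.3)^2) / (2 * 0.06^2))
  }
  sd_n <- sqrt(mean(clean^2)) * 10^(-snr_db / 20)
  list(clean = clean, noisy = clean + rnorm(n, 0, sd_n), fs = fs)
}

snr_db <- function(clean, x) {
  10 * log10(sum(clean^2) / sum((x - clean)^2))
}

# finite-difference gradient of a scalar-valued function
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small cached 12-class image set shared by the evaluation tests
.cache <- new.env()
tiny_image_set <- function(n_per_class = 20L, size = 48L, seed = 1L) {
  key <- paste0("ds_", n_per_class, "_", size, "_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- make_dataset(n_per_class, image_size = size,
                                  seed = seed)$images
  }
  .cache[[key]]
}
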