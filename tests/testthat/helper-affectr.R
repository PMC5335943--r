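# FFT periodogram band power, independent of the package's filter code
band_power_oracle <- function(x, fs, low, high) {
  n <- length(x)
  spec <- abs(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) / n * fs
  sum(spec[f >= low & f < high | (fs - f) >= low & (fs - f) < high])
}

# evaluate code under a local seed without touching the global stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# all permutations of a short vector, one per row
combinat_perms <- function(v) {
  if (length(v) == 1) {
    return(matrix(v, 1, 1))
  }
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], combinat_perms(v[-i]))
  }))
}

# hand-built recording with arbitrary sample content
make_rec <- function(n, fs = 128, value = NULL, data = NULL) {
  m <- emotiv_montage()
  if (is.null(data)) {
    data <- if (is.null(value)) matrix(rnorm(n * 14), n, 14) else matrix(value, n, 14)
  }
  colnames(data) <- m$channel_names
  affectr:::new_eeg_recording(data, fs, m)
}

# labeled per-band/channel Hjorth feature table from fresh synthetic data
synthetic_features <- function(epochs_per_class, seed, channels = NULL) {
  labs <- emotion_labels()
  seeds <- seed + seq_along(labs)
  do.call(rbind, lapply(seq_along(labs), function(i) {
    rec <- simulate_recording(labs[i], epochs_per_class * 1.5, seed = seeds[i])
    hjorth_features(segment_epochs(rec), channels = channels)
  }))
}

# tiny linearly separable 2-feature toy set, two classes of four points
toy_features <- function() {
  tibble::tibble(
    label = rep(c("happy", "sad"), each = 4),
    f1 = c(1, 1.2, 0.8, 1.1, -1, -1.2, -0.8, -1.1),
    f2 = c(1, 0.9, 1.1, 1.2, -1, -0.9, -1.1, -1.2)
  )
}
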