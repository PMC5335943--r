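#' Default class-conditional spectral profiles
#'
#' Per-band, per-channel gain multipliers that give each emotion class its
#' own spectral signature in the synthetic generator. These are simulation
#' fixtures chosen so the four classes are statistically separable, not
#' claims about physiology: calm elevates alpha on all channels, happy
#' elevates frontal beta, sad elevates frontal delta and theta, and scared
#' elevates theta and beta over frontal and temporal sites.
#'
#' @param montage An `eeg_montage`; defaults to [emotiv_montage()].
#' @param elevation Gain applied to a class's signature bands (baseline 1).
#' @return A tibble with columns `label`, `band`, `channel`, `gain` covering
#'   every combination of the four labels, four bands, and all channels.
#' @examples
#' profiles <- class_spectral_profiles()
#' dplyr::filter(profiles, gain > 1)
#' @export
class_spectral_profiles <- function(montage = emotiv_montage(), elevation = 2.5) {
  ch <- montage$channel_names
  frontal <- intersect(c("AF3", "F7", "F3", "FC5", "FC6", "F4", "F8", "AF4"), ch)
  temporal <- intersect(c("T7", "T8"), ch)
  grid <- tidyr::expand_grid(
    label = emotion_labels(),
    band = eeg_bands()$band,
    channel = ch
  )
  grid$gain <- 1
  up <- function(g, lab, bnd, chs, value) {
    sel <- g$label == lab & g$band %in% bnd & g$channel %in% chs
    g$gain[sel] <- value
    g
  }
  grid <- up(grid, "calm", "alpha", ch, elevation)
  grid <- up(grid, "happy", "beta", frontal, elevation)
  grid <- up(grid, "sad", c("delta", "theta"), frontal, elevation)
  grid <- up(grid, "scared", c("theta", "beta"), c(frontal, temporal), elevation)
  grid
}

#' Simulate a headset-like EEG recording
#'
#' Generates a seeded multichannel recording whose band powers follow the
#' class-conditional spectral profile of the requested emotion label. Each
#' channel is a sum of band-limited Gaussian noise components (one per band,
#' scaled by the class's gain for that band and channel) on top of a
#' 1/f-shaped broadband background, on a microvolt-like scale. Identical
#' `(label, duration, seed)` calls return bit-identical data.
#'
#' @param label One of `emotion_labels()`.
#' @param duration Recording length in seconds (> 0).
#' @param seed Integer seed controlling all randomness.
#' @param sampling_rate Samples per second (default 128).
#' @param montage An `eeg_montage` (default [emotiv_montage()]).
#' @param profiles Gain table as returned by [class_spectral_profiles()].
#' @param band_amp Standard deviation, in microvolts, of a unit-gain band
#'   component (default 6).
#' @param background_amp Standard deviation of the 1/f background
#'   (default 15, giving excursions on the order of +/- 50 microvolts).
#' @return An `eeg_recording`: a tibble with one column per channel and one
#'   row per sample, with attributes `sampling_rate`, `label`, `seed`, and
#'   `montage`.
#' @examples
#' rec <- simulate_recording("calm", duration = 3, seed = 1)
#' dim(rec) # 384 samples x 14 channels
#' @export
simulate_recording <- function(label, duration, seed,
                               sampling_rate = 128,
                               montage = emotiv_montage(),
                               profiles = class_spectral_profiles(montage),
                               band_amp = 6,
                               background_amp = 15) {
  assert_label(label)
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
    duration <= 0) {
    stop("duration must be a positive number of seconds", call. = FALSE)
  }
  n <- round(duration * sampling_rate)
  if (n < 8) stop("duration too short at this sampling rate", call. = FALSE)
  bands <- eeg_bands()
  ch <- montage$channel_names
  prof <- profiles[profiles$label == label, ]
  gain <- matrix(1, nrow(bands), length(ch),
    dimnames = list(bands$band, ch)
  )
  gain[cbind(
    match(prof$band, bands$band),
    match(prof$channel, ch)
  )] <- prof$gain
  if (any(!is.finite(gain)) || any(gain < 0)) {
    stop("spectral profile gains must be finite and non-negative", call. = FALSE)
  }

  data <- with_seed(seed, {
    vapply(seq_along(ch), function(ci) {
      bg <- background_amp * one_over_f_noise(n, sampling_rate)
      comp <- bg
      for (bi in seq_len(nrow(bands))) {
        w <- bandpass_filter(
          stats::rnorm(n), bands$low_hz[bi], bands$high_hz[bi],
          sampling_rate
        )
        comp <- comp + gain[bi, ci] * band_amp * (w / stats::sd(w))
      }
      comp
    }, numeric(n))
  })
  colnames(data) <- ch
  new_eeg_recording(data, sampling_rate, montage, label = label, seed = seed)
}

# broadband background with a 1/f amplitude spectrum, low-passed near the
# headset's 43 Hz output bandwidth, normalized to unit standard deviation
one_over_f_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  amp <- ifelse(f <= 0, 0, 1 / sqrt(pmax(f, 0.5)))
  amp <- amp / sqrt(1 + (f / 43)^8)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

new_eeg_recording <- function(data, sampling_rate, montage,
                              label = NULL, seed = NULL) {
  stopifnot(is.matrix(data), ncol(data) == length(montage$channel_names))
  if (!all(is.finite(data))) {
    stop("recording samples must all be finite", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "label") <- label
  attr(out, "seed") <- seed
  attr(out, "montage") <- montage
  class(out) <- c("eeg_recording", class(out))
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(
    "<eeg_recording> ", ncol(x), " channels x ", nrow(x), " samples @ ",
    sampling_rate(x), " Hz",
    if (!is.null(attr(x, "label"))) paste0(" [", attr(x, "label"), "]"),
    "\n",
    sep = ""
  )
  NextMethod()
}

#' Sampling rate of a recording
#'
#' @param x An `eeg_recording`.
#' @return Samples per second.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "sampling_rate")
  if (is.null(fs)) stop("object carries no sampling_rate attribute", call. = FALSE)
  fs
}

#' Write an EEG recording to CSV
#'
#' The on-disk dialect is a `# fs=<rate>` comment line, a channel-name
#' header, then one row per sample instant with `.` as the decimal mark.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording_csv()]
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s", format(sampling_rate(recording))), con)
  df <- as.data.frame(recording)
  utils::write.table(df, con,
    sep = ",", row.names = FALSE, col.names = TRUE,
    quote = FALSE
  )
  invisible(path)
}

#' Read an EEG recording from CSV
#'
#' @param path File written by [write_recording_csv()] (or hand-assembled in
#'   the same dialect).
#' @param montage Expected montage; the file's channel header must match its
#'   channel set. Pass `NULL` to accept any channel set.
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, montage = emotiv_montage()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3) {
    stop("parse error at line ", length(lines),
      ": file needs an fs header, a channel header, and data rows",
      call. = FALSE
    )
  }
  m <- regmatches(lines[1], regexec("^#\\s*fs=([0-9.]+)\\s*$", lines[1]))[[1]]
  if (length(m) != 2) {
    stop("parse error at line 1: expected '# fs=<rate>', got '", lines[1], "'",
      call. = FALSE
    )
  }
  fs <- as.numeric(m[2])
  channels <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  channels <- trimws(channels)
  if (anyDuplicated(channels)) {
    stop("parse error at line 2: duplicate channel names", call. = FALSE)
  }
  if (!is.null(montage) && !setequal(channels, montage$channel_names)) {
    stop("parse error at line 2: header lists ", length(channels),
      " channels (", paste(channels, collapse = " "),
      "); expected the ", length(montage$channel_names),
      "-channel montage",
      call. = FALSE
    )
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    stop("parse error at line 3: empty data section", call. = FALSE)
  }
  rows <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(rows)
  bad <- which(lens != length(channels))
  if (length(bad)) {
    stop("parse error at line ", bad[1] + 2, ": ", lens[bad[1]],
      " cells, expected ", length(channels),
      call. = FALSE
    )
  }
  data <- suppressWarnings(
    matrix(as.numeric(unlist(rows)),
      nrow = length(rows), byrow = TRUE,
      dimnames = list(NULL, channels)
    )
  )
  if (anyNA(data)) {
    bad_row <- which(apply(data, 1, anyNA))[1]
    stop("parse error at line ", bad_row + 2, ": non-numeric cell", call. = FALSE)
  }
  keep <- if (is.null(montage)) emotiv_montage(channels) else montage
  new_eeg_recording(data[, keep$channel_names, drop = FALSE], fs, keep)
}
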