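#' Segment a recording into fixed-length epochs
#'
#' Cuts contiguous windows of `epoch_length` samples at stride `step`
#' (non-overlapping by default); a trailing partial window is dropped. Each
#' epoch inherits the recording's label, if any.
#'
#' @param recording An `eeg_recording`.
#' @param epoch_length Window length in samples. The default, 192 samples
#'   (1.5 s at 128 Hz), makes a full 14-channel epoch hold 2688 values and
#'   lets ten non-overlapping epochs tile a 15 s decision window.
#' @param step Stride in samples (default: `epoch_length`, non-overlapping).
#' @return A tibble with one row per epoch: `epoch` (index), `start` (first
#'   sample, 1-based), `label`, and `signal` (list column of
#'   samples-by-channels matrices). Attributes `sampling_rate` and `montage`
#'   carry over. Zero rows when the recording is shorter than one epoch.
#' @examples
#' rec <- simulate_recording("happy", 15, seed = 7)
#' segment_epochs(rec) # 10 epochs
#' @export
segment_epochs <- function(recording, epoch_length = 192, step = epoch_length) {
  stopifnot(inherits(recording, "eeg_recording"))
  epoch_length <- as.integer(epoch_length)
  if (!is.numeric(step) || length(step) != 1 || step < 1) {
    stop("step must be a positive number of samples", call. = FALSE)
  }
  step <- as.integer(step)
  if (epoch_length < 1) stop("epoch_length must be positive", call. = FALSE)
  n <- nrow(recording)
  data <- as.matrix(as.data.frame(recording))
  starts <- seq.int(1L, by = step, length.out = max(0L, (n - epoch_length) %/% step + 1L))
  starts <- starts[starts + epoch_length - 1L <= n]
  out <- tibble::tibble(
    epoch = seq_along(starts),
    start = starts,
    label = rep(
      if (is.null(attr(recording, "label"))) NA_character_ else attr(recording, "label"),
      length(starts)
    ),
    signal = lapply(starts, function(s) data[s:(s + epoch_length - 1L), , drop = FALSE])
  )
  attr(out, "sampling_rate") <- sampling_rate(recording)
  attr(out, "montage") <- attr(recording, "montage")
  attr(out, "epoch_length") <- epoch_length
  out
}

epoch_attrs <- function(epochs) {
  fs <- attr(epochs, "sampling_rate")
  if (is.null(fs)) {
    stop("epochs lack a sampling_rate attribute; use segment_epochs()",
      call. = FALSE
    )
  }
  list(
    sampling_rate = fs,
    montage = attr(epochs, "montage"),
    epoch_length = attr(epochs, "epoch_length")
  )
}

#' Decompose epochs into the four frequency bands
#'
#' Applies the zero-phase band-pass of [bandpass_filter()] to every channel
#' of every epoch, once per band, adding one list column of filtered
#' matrices per band name. Filtering preserves the epoch's shape exactly.
#'
#' @param epochs Epoch tibble from [segment_epochs()].
#' @param bands Band table (default [eeg_bands()]); must be non-overlapping
#'   and lie inside (0, sampling_rate/2).
#' @param order Butterworth prototype order passed to [bandpass_filter()].
#' @return `epochs` with one additional list column per band.
#' @examples
#' rec <- simulate_recording("calm", 3, seed = 1)
#' ep <- decompose_bands(segment_epochs(rec))
#' names(ep) # epoch start label signal delta theta alpha beta
#' @export
decompose_bands <- function(epochs, bands = eeg_bands(), order = 12) {
  at <- epoch_attrs(epochs)
  validate_bands(bands, at$sampling_rate)
  for (i in seq_len(nrow(bands))) {
    epochs[[bands$band[i]]] <- lapply(
      epochs$signal, bandpass_filter,
      low_hz = bands$low_hz[i], high_hz = bands$high_hz[i],
      sampling_rate = at$sampling_rate, order = order
    )
  }
  epochs
}
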