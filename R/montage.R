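#' Default 14-channel consumer-headset montage
#'
#' The Emotiv EPOC-style montage used throughout the package: 14 data
#' channels placed per the 10/20 system. The headset's CMS/DRL reference
#' electrodes carry no signal and are recorded here only as a note.
#'
#' @param channel_names Character vector of electrode labels. Defaults to the
#'   14-channel EPOC layout.
#' @param reference_note Free-text description of the reference scheme.
#' @return An object of class `eeg_montage`: a list with `channel_names` and
#'   `reference_note`.
#' @examples
#' emotiv_montage()
#' @export
emotiv_montage <- function(channel_names = c(
                             "AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                             "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"
                           ),
                           reference_note = "CMS/DRL references at P3/P4; not recorded") {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) {
    stop("montage channel names must be unique", call. = FALSE)
  }
  if (length(channel_names) < 1) {
    stop("montage must contain at least one channel", call. = FALSE)
  }
  structure(
    list(channel_names = channel_names, reference_note = reference_note),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_names), " channels: ",
    paste(x$channel_names, collapse = " "), "\n",
    sep = ""
  )
  cat("reference: ", x$reference_note, "\n", sep = "")
  invisible(x)
}

#' The four emotion classes
#'
#' The admissible emotion labels, one per quadrant of the valence-arousal
#' plane: happy (+v,+a), calm (+v,-a), sad (-v,-a), scared (-v,+a).
#'
#' @return Character vector of the four class labels.
#' @examples
#' emotion_labels()
#' @export
emotion_labels <- function() c("happy", "calm", "sad", "scared")

#' Default frontal/central channel subset
#'
#' Six channels drawn from the frontal and central areas of the default
#' montage, used for the reduced Hjorth feature family. The montage has no
#' true central (Cz-line) electrodes, so the six most frontal-central sites
#' are used.
#'
#' @return Character vector of six channel names.
#' @examples
#' frontal_channels()
#' @export
frontal_channels <- function() c("AF3", "F3", "FC5", "FC6", "F4", "AF4")

assert_label <- function(label) {
  if (!(is.character(label) && length(label) == 1 && label %in% emotion_labels())) {
    stop(
      "label must be one of: ", paste(emotion_labels(), collapse = ", "),
      call. = FALSE
    )
  }
  label
}

# run code under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seeds below 2^31 for independent draws
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
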