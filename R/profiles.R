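#' Build a quadrant-balanced stimulus manifest
#'
#' Emulates the structure of an affective-picture training protocol: a set
#' of stimulus entries balanced across the four emotion classes, each tagged
#' with the valence/arousal quadrant of its class (happy +v +a, scared -v
#' +a, calm +v -a, sad -v -a). The default reproduces the 180-image, 45-per-
#' class protocol. Stimulus ids are synthetic; no picture content is
#' modeled.
#'
#' @param per_class Stimuli per emotion class (default 45).
#' @param seed Integer seed controlling the presentation order shuffle.
#' @param display_s Display duration per stimulus in seconds (default 3).
#' @return A tibble with columns `stimulus_id`, `label`, `valence`,
#'   `arousal` (+1/-1), and `display_s`, shuffled into presentation order.
#' @examples
#' nrow(build_manifest()) # 180
#' @export
build_manifest <- function(per_class = 45, seed = 1, display_s = 3) {
  if (!is.numeric(per_class) || length(per_class) != 1 || per_class < 1) {
    stop("per_class must be a positive integer", call. = FALSE)
  }
  per_class <- as.integer(per_class)
  quadrant <- tibble::tibble(
    label = c("happy", "scared", "calm", "sad"),
    valence = c(1L, -1L, 1L, -1L),
    arousal = c(1L, 1L, -1L, -1L)
  )
  entries <- tidyr::uncount(quadrant, per_class)
  entries$stimulus_id <- sprintf(
    "%s-%03d", entries$label,
    unlist(lapply(rle(entries$label)$lengths, seq_len))
  )
  entries$display_s <- display_s
  ord <- with_seed(seed, sample.int(nrow(entries)))
  entries[ord, c("stimulus_id", "label", "valence", "arousal", "display_s")]
}

#' Record a simulated training session
#'
#' For each manifest entry, synthesizes a recording of the entry's display
#' duration with the entry's emotion label (via [simulate_recording()]) and
#' segments it into labeled epochs. The result is the labeled epoch pool a
#' training session contributes to a user profile.
#'
#' @param manifest Tibble from [build_manifest()].
#' @param seed Integer master seed; each entry receives its own derived
#'   sub-seed, so sessions are reproducible end to end.
#' @param epoch_length Epoch length in samples (default 192).
#' @param sampling_rate Samples per second (default 128).
#' @param ... Further arguments to [simulate_recording()] (montage,
#'   profiles, amplitudes).
#' @return An epoch tibble (as from [segment_epochs()]) with an extra
#'   `stimulus_id` column; `epoch` renumbered consecutively.
#' @examples
#' m <- build_manifest(per_class = 2, seed = 1, display_s = 1.5)
#' record_training_session(m, seed = 5) # 8 labeled epochs
#' @export
record_training_session <- function(manifest, seed, epoch_length = 192,
                                    sampling_rate = 128, ...) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  sub_seeds <- derive_seeds(seed, nrow(manifest))
  pieces <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- simulate_recording(
      manifest$label[i], manifest$display_s[i],
      seed = sub_seeds[i], sampling_rate = sampling_rate, ...
    )
    ep <- segment_epochs(rec, epoch_length)
    if (nrow(ep)) ep$stimulus_id <- manifest$stimulus_id[i]
    ep
  })
  at <- attributes(pieces[[1]])
  out <- dplyr::bind_rows(pieces)
  out$epoch <- seq_len(nrow(out))
  attr(out, "sampling_rate") <- at$sampling_rate
  attr(out, "montage") <- at$montage
  attr(out, "epoch_length") <- at$epoch_length
  out
}

#' Create a user profile
#'
#' A profile stores one user's labeled training epochs and their
#' emotion-keyed treatment notes; it is the unit of persistence, one JSON
#' file per user.
#'
#' @param user_id Short identifier.
#' @param name Display name (defaults to `user_id`).
#' @return A `user_profile` object.
#' @export
new_user_profile <- function(user_id, name = user_id) {
  stopifnot(is.character(user_id), nzchar(user_id))
  structure(
    list(
      version = 1L,
      user_id = user_id,
      name = name,
      epochs = NULL,
      treatments = tibble::tibble(
        emotion = character(), text = character(),
        author = character(), timestamp = character(), entry = integer()
      )
    ),
    class = "user_profile"
  )
}

#' @export
print.user_profile <- function(x, ...) {
  n_ep <- if (is.null(x$epochs)) 0 else nrow(x$epochs)
  cat("<user_profile> ", x$user_id, ": ", n_ep, " stored epochs, ",
    nrow(x$treatments), " treatment notes\n",
    sep = ""
  )
  invisible(x)
}

#' Add labeled epochs to a profile
#'
#' Sessions accumulate: epochs from successive training sessions are
#' appended, never replaced, and a model can later be retrained on the
#' union.
#'
#' @param profile A `user_profile`.
#' @param epochs Labeled epoch tibble ([record_training_session()] output).
#' @return The updated profile.
#' @export
add_epochs <- function(profile, epochs) {
  stopifnot(inherits(profile, "user_profile"))
  if (anyNA(epochs$label) || !all(epochs$label %in% emotion_labels())) {
    stop("every stored epoch must carry one of the four emotion labels",
      call. = FALSE
    )
  }
  at <- epoch_attrs(epochs)
  if (is.null(profile$epochs)) {
    profile$epochs <- epochs
  } else {
    combined <- dplyr::bind_rows(profile$epochs, epochs)
    combined$epoch <- seq_len(nrow(combined))
    attr(combined, "sampling_rate") <- at$sampling_rate
    attr(combined, "montage") <- at$montage
    attr(combined, "epoch_length") <- at$epoch_length
    profile$epochs <- combined
  }
  profile
}

#' Add a treatment note for an emotion
#'
#' Appends an instructor note (e.g. "offer break time") under an emotion
#' key with its author and a timestamp; history is append-only.
#'
#' @param profile A `user_profile`.
#' @param emotion One of `emotion_labels()`.
#' @param text Non-empty instruction text.
#' @param author Author name (default "instructor").
#' @return The updated profile.
#' @export
add_treatment <- function(profile, emotion, text, author = "instructor") {
  stopifnot(inherits(profile, "user_profile"))
  assert_label(emotion)
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("treatment text must be a non-empty string", call. = FALSE)
  }
  profile$treatments <- dplyr::bind_rows(
    profile$treatments,
    tibble::tibble(
      emotion = emotion, text = text, author = author,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
      entry = nrow(profile$treatments) + 1L
    )
  )
  profile
}

#' Treatments stored for an emotion
#'
#' @param profile A `user_profile`.
#' @param emotion One of `emotion_labels()`.
#' @return Character vector of treatment texts in insertion order (empty if
#'   none stored).
#' @export
get_treatments <- function(profile, emotion) {
  stopifnot(inherits(profile, "user_profile"))
  assert_label(emotion)
  tr <- profile$treatments
  tr$text[tr$emotion == emotion]
}

#' Persist and restore a user profile
#'
#' Profiles are stored as versioned JSON, one file per user: epochs (with
#' labels and full-precision samples), treatment history, and naming
#' information all round-trip losslessly.
#'
#' @param profile A `user_profile`.
#' @param path JSON file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the restored `user_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "user_profile"))
  ep <- profile$epochs
  payload <- list(
    version = profile$version,
    user_id = profile$user_id,
    name = profile$name,
    treatments = profile$treatments,
    epochs = if (is.null(ep)) {
      NULL
    } else {
      list(
        sampling_rate = attr(ep, "sampling_rate"),
        epoch_length = attr(ep, "epoch_length"),
        channels = colnames(ep$signal[[1]]),
        label = ep$label,
        stimulus_id = if ("stimulus_id" %in% names(ep)) ep$stimulus_id else NULL,
        signal = lapply(ep$signal, unname)
      )
    }
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$version) || p$version != 1L) {
    stop("unsupported profile version: ", p$version %||% "<missing>",
      call. = FALSE
    )
  }
  profile <- new_user_profile(p$user_id, p$name)
  if (length(p$treatments)) {
    profile$treatments <- tibble::as_tibble(p$treatments)
  }
  if (!is.null(p$epochs) && length(p$epochs$signal)) {
    raw <- p$epochs$signal
    # jsonlite collapses a list of equal-sized matrices into one 3-d array
    if (is.array(raw) && length(dim(raw)) == 3) {
      raw <- lapply(seq_len(dim(raw)[1]), function(i) raw[i, , ])
    } else if (!is.list(raw)) {
      raw <- list(raw)
    }
    sig <- lapply(raw, function(m) {
      m <- as.matrix(m)
      colnames(m) <- p$epochs$channels
      m
    })
    ep <- tibble::tibble(
      epoch = seq_along(sig),
      start = NA_integer_,
      label = p$epochs$label,
      signal = sig
    )
    if (!is.null(p$epochs$stimulus_id)) ep$stimulus_id <- p$epochs$stimulus_id
    attr(ep, "sampling_rate") <- p$epochs$sampling_rate
    attr(ep, "montage") <- emotiv_montage(p$epochs$channels)
    attr(ep, "epoch_length") <- p$epochs$epoch_length
    profile$epochs <- ep
  }
  profile
}
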