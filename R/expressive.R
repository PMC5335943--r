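#' Majority vote over per-epoch emotion decisions
#'
#' Returns the label with the highest count. Ties break in favor of the
#' tied label that occurs latest in the sequence, so the subject's most
#' recent state wins.
#'
#' @param decisions Non-empty character vector of emotion labels in temporal
#'   order.
#' @return A single label.
#' @examples
#' majority_vote(c("happy", "happy", "sad")) # "happy"
#' majority_vote(c("happy", "sad")) # tie: most recent, "sad"
#' @export
majority_vote <- function(decisions) {
  decisions <- as.character(decisions)
  if (length(decisions) == 0) {
    stop("cannot vote over an empty decision list", call. = FALSE)
  }
  counts <- table(decisions)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) {
    return(top)
  }
  last_seen <- vapply(top, function(l) max(which(decisions == l)), numeric(1))
  top[which.max(last_seen)]
}

#' Run expressive-mode emotion feedback over a recording
#'
#' Simulates the real-time loop on a stored recording: the signal is cut
#' into epochs, each epoch is classified with the model's own feature
#' family, and every complete decision window (default 15 s, i.e. ten 1.5 s
#' epochs) is reduced to a single emotion feedback by [majority_vote()].
#' For feedback labeling an unpleasant state (sad or scared), the treatment
#' texts stored in the user profile for that emotion are attached. A
#' trailing partial window produces no feedback.
#'
#' @param recording An `eeg_recording`.
#' @param model An `emotion_model` trained on one of the package's feature
#'   families.
#' @param profile Optional `user_profile` supplying treatment notes.
#' @param window_s Decision window length in seconds (default 15).
#' @param epoch_length Epoch length in samples (default 192).
#' @return A tibble with one row per complete window: `window`, `label`,
#'   one vote-count column per class present in the model, `decisions`
#'   (list column of the per-epoch labels), and `treatments` (list column
#'   of character vectors).
#' @examples
#' \donttest{
#' rec <- simulate_recording("calm", 15, seed = 1)
#' train <- do.call(rbind, lapply(emotion_labels(), function(l) {
#'   hjorth_features(segment_epochs(simulate_recording(l, 9, seed = match(l, emotion_labels()))))
#' }))
#' model <- fit_emotion_model(train, method = "knn")
#' run_expressive(rec, model)
#' }
#' @export
run_expressive <- function(recording, model, profile = NULL,
                           window_s = 15, epoch_length = 192) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(model, "emotion_model"))
  fs <- sampling_rate(recording)
  per_window <- floor(window_s * fs / epoch_length)
  if (per_window < 1) stop("window shorter than one epoch", call. = FALSE)
  epochs <- segment_epochs(recording, epoch_length)
  n_windows <- nrow(epochs) %/% per_window
  if (n_windows == 0) {
    stop("recording shorter than one decision window (", window_s, " s)",
      call. = FALSE
    )
  }
  feats <- features_for_model(epochs, model)
  decisions <- predict(model, feats)
  unpleasant <- c("sad", "scared")
  rows <- lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1) * per_window + 1):(w * per_window)
    votes <- decisions[idx]
    lab <- majority_vote(votes)
    counts <- table(factor(votes, levels = model$classes))
    tr <- if (!is.null(profile) && lab %in% unpleasant) {
      get_treatments(profile, lab)
    } else {
      character(0)
    }
    c(
      list(window = w, label = lab),
      as.list(as.integer(counts)) |> stats::setNames(names(counts)),
      list(decisions = list(votes), treatments = list(tr))
    )
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# rebuild the model's training-time feature layout from raw epochs
features_for_model <- function(epochs, model) {
  cfg <- model$feature_config
  feats <- switch(model$family,
    filtered = filtered_features(epochs,
      low_hz = cfg$low_hz %||% 0.5,
      high_hz = cfg$high_hz %||% 30,
      order = cfg$order %||% 12
    ),
    {
      channels <- cfg$channels %||% NULL
      hjorth_features(epochs, channels = channels, order = cfg$order %||% 12)
    }
  )
  have <- setdiff(names(feats), c("epoch", "start", "label"))
  if (!identical(have, model$feature_names)) {
    stop("montage/model mismatch: model expects features ",
      paste(utils::head(model$feature_names, 3), collapse = ", "),
      ", ...; epochs produced ",
      paste(utils::head(have, 3), collapse = ", "), ", ...",
      call. = FALSE
    )
  }
  feats
}
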