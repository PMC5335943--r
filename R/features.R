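#' Hjorth parameters of a single-channel signal
#'
#' The three time-domain normalized slope descriptors of Hjorth (1970):
#' activity is the population variance of the signal; mobility is the square
#' root of the variance ratio of the first difference to the signal
#' (a dimensionless rate, in radians per sample); complexity is the mobility
#' of the first difference divided by the mobility of the signal.
#'
#' Differences are plain sample-to-sample differences, not scaled by the
#' sampling interval, so a pure sinusoid of frequency `f` at rate `fs` has
#' mobility `2 sin(pi f / fs)` and complexity 1.
#'
#' @param y Numeric vector, length at least 3.
#' @return Named numeric vector with elements `activity`, `mobility`,
#'   `complexity`.
#' @examples
#' hjorth_params(rep(c(1, -1), 100)) # activity 1, mobility 2, complexity 1
#' @export
hjorth_params <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 3) stop("signal must have at least 3 samples", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  pvar <- function(v) mean((v - mean(v))^2)
  v0 <- pvar(y)
  if (v0 == 0) {
    stop("degenerate signal: zero variance, Hjorth mobility undefined",
      call. = FALSE
    )
  }
  d1 <- diff(y)
  d2 <- diff(d1)
  v1 <- pvar(d1)
  v2 <- pvar(d2)
  mob <- sqrt(v1 / v0)
  mob_d <- if (v1 == 0) 0 else sqrt(v2 / v1)
  c(
    activity = v0,
    mobility = mob,
    complexity = if (v1 == 0) 0 else mob_d / mob
  )
}

# batch-mode variant: a flat channel must not abort a session, so it maps
# to the sentinel triple (0, 0, 0) with a warning instead of an error
hjorth_params_safe <- function(y, context = "signal") {
  tryCatch(hjorth_params(y), error = function(e) {
    warning("degenerate ", context, ": using sentinel Hjorth triple (0,0,0)",
      call. = FALSE
    )
    c(activity = 0, mobility = 0, complexity = 0)
  })
}

#' Filtered-signal feature vectors
#'
#' The first feature family: each epoch's samples, band-limited to the
#' 0.5--30 Hz envelope, concatenated channel-major into one flat vector. A
#' full default epoch (14 channels x 192 samples) yields exactly 2688
#' values.
#'
#' @param epochs Epoch tibble from [segment_epochs()].
#' @param low_hz,high_hz Envelope edges (defaults 0.5 and 30 Hz).
#' @param order Filter order, see [bandpass_filter()].
#' @return A tibble with `epoch`, `label`, and one numeric column per value,
#'   named `<channel>_t<sample>`; attribute `family = "filtered"`.
#' @examples
#' rec <- simulate_recording("sad", 3, seed = 2)
#' ff <- filtered_features(segment_epochs(rec))
#' ncol(ff) - 2 # 2688
#' @export
filtered_features <- function(epochs, low_hz = 0.5, high_hz = 30, order = 12) {
  at <- epoch_attrs(epochs)
  if (nrow(epochs) == 0) stop("no epochs to featurize", call. = FALSE)
  mat <- t(vapply(epochs$signal, function(sig) {
    filt <- bandpass_filter(sig, low_hz, high_hz, at$sampling_rate, order)
    as.numeric(filt) # column-major = channel-major concatenation
  }, numeric(nrow(epochs$signal[[1]]) * ncol(epochs$signal[[1]]))))
  if (nrow(epochs) == 1) mat <- matrix(mat, nrow = 1)
  sig1 <- epochs$signal[[1]]
  colnames(mat) <- as.vector(outer(
    sprintf("t%03d", seq_len(nrow(sig1))), colnames(sig1),
    function(t, ch) paste(ch, t, sep = "_")
  ))
  out <- dplyr::bind_cols(
    tibble::tibble(epoch = epochs$epoch, label = epochs$label),
    tibble::as_tibble(mat)
  )
  attr(out, "family") <- "filtered"
  attr(out, "feature_config") <- list(
    low_hz = low_hz, high_hz = high_hz, order = order,
    epoch_length = at$epoch_length
  )
  out
}

#' Per-band Hjorth feature vectors
#'
#' The second and third feature families: for each selected channel and each
#' frequency band, the Hjorth triple of the band-filtered signal, flattened
#' channel-major, then band, then (activity, mobility, complexity). All 14
#' channels give 168 features; the 6-channel frontal/central subset gives
#' 72.
#'
#' @param epochs Epoch tibble; band columns are added via
#'   [decompose_bands()] if not already present.
#' @param channels Channel subset (character). `NULL` uses every montage
#'   channel; [frontal_channels()] selects the reduced family.
#' @param bands Band table (default [eeg_bands()]).
#' @param order Filter order, see [bandpass_filter()].
#' @return A tibble with `epoch`, `label`, and one column per feature named
#'   `<channel>_<band>_<parameter>`; attribute `family` is `"hjorth14"` for
#'   the full montage or `"hjorth6"` for a 6-channel subset.
#' @examples
#' rec <- simulate_recording("scared", 3, seed = 3)
#' hf <- hjorth_features(segment_epochs(rec))
#' ncol(hf) - 2 # 168
#' @export
hjorth_features <- function(epochs, channels = NULL, bands = eeg_bands(),
                            order = 12) {
  at <- epoch_attrs(epochs)
  if (nrow(epochs) == 0) stop("no epochs to featurize", call. = FALSE)
  montage_ch <- colnames(epochs$signal[[1]])
  if (is.null(channels)) channels <- montage_ch
  missing_ch <- setdiff(channels, montage_ch)
  if (length(missing_ch)) {
    stop("channels not in montage: ", paste(missing_ch, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(bands$band %in% names(epochs))) {
    epochs <- decompose_bands(epochs, bands, order)
  }
  params <- c("activity", "mobility", "complexity")
  feat_names <- as.vector(vapply(
    channels,
    function(ch) as.vector(vapply(bands$band, function(b) paste(ch, b, params, sep = "_"), character(3))),
    character(length(params) * nrow(bands))
  ))
  mat <- t(vapply(seq_len(nrow(epochs)), function(i) {
    unlist(lapply(channels, function(ch) {
      unlist(lapply(bands$band, function(b) {
        hjorth_params_safe(epochs[[b]][[i]][, ch],
          context = paste0("channel ", ch, " (", b, ")")
        )
      }))
    }), use.names = FALSE)
  }, numeric(length(feat_names))))
  if (nrow(epochs) == 1) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- feat_names
  out <- dplyr::bind_cols(
    tibble::tibble(epoch = epochs$epoch, label = epochs$label),
    tibble::as_tibble(mat)
  )
  family <- if (setequal(channels, montage_ch)) {
    paste0("hjorth", length(montage_ch))
  } else {
    paste0("hjorth", length(channels))
  }
  attr(out, "family") <- family
  attr(out, "feature_config") <- list(
    channels = channels, bands = bands, order = order,
    epoch_length = at$epoch_length
  )
  out
}

feature_matrix <- function(features) {
  keep <- setdiff(names(features), c("epoch", "start", "label"))
  m <- as.matrix(as.data.frame(features)[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Rank features by mutual information with the class label
#'
#' Plug-in mutual information between each feature (discretized into
#' equal-frequency bins) and the emotion label, in bits. Features are
#' returned in decreasing order of estimated information; ties keep the
#' original column order, so uninformative constant features rank in index
#' order.
#'
#' @param features Feature tibble (from [hjorth_features()] or
#'   [filtered_features()]), or any data frame of numeric columns; a `label`
#'   column supplies the classes unless `labels` is given.
#' @param labels Optional vector of class labels overriding the `label`
#'   column.
#' @param bins Number of equal-frequency bins per feature (default 8).
#' @return A tibble with `feature`, `index` (original column position),
#'   `mi` (bits), and `rank`, ordered by rank.
#' @examples
#' ep <- segment_epochs(simulate_recording("calm", 6, seed = 4))
#' hf <- hjorth_features(ep, frontal_channels())
#' hf$label <- rep(c("calm", "sad"), length.out = nrow(hf)) # toy labels
#' mi_rank(hf, bins = 2)
#' @export
mi_rank <- function(features, labels = NULL, bins = 8) {
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      stop("supply labels or include a 'label' column", call. = FALSE)
    }
    labels <- features$label
  }
  mat <- feature_matrix(features)
  if (nrow(mat) != length(labels)) {
    stop("labels length must match the number of rows", call. = FALSE)
  }
  if (nrow(mat) < 10) {
    stop("need at least 10 samples to estimate mutual information", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; mutual information is undefined",
      call. = FALSE
    )
  }
  mi <- vapply(seq_len(ncol(mat)), function(j) {
    mutual_information_binned(mat[, j], labels, bins)
  }, numeric(1))
  ord <- order(-mi, seq_along(mi))
  tibble::tibble(
    feature = colnames(mat)[ord],
    index = ord,
    mi = mi[ord],
    rank = seq_along(ord)
  )
}

mutual_information_binned <- function(x, labels, bins) {
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
    names = FALSE, type = 7
  ))
  if (length(brk) < 2) {
    return(0) # constant feature: one bin, no information
  }
  xb <- cut(x, breaks = brk, include.lowest = TRUE)
  tab <- table(xb, labels)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}
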