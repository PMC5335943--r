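#' Pipeline run configuration
#'
#' Collects every tunable of the recognition pipeline with its default. The
#' one structural constraint is validated here: the number of per-epoch
#' decisions per feedback window times the epoch duration must equal the
#' window duration (by default 10 x 1.5 s = 15 s).
#'
#' @param sampling_rate Samples per second (default 128).
#' @param epoch_length Epoch length in samples (default 192).
#' @param window_s Decision window in seconds (default 15).
#' @param decisions_per_window Epoch decisions aggregated per feedback
#'   (default 10).
#' @param feature_family `"hjorth14"`, `"hjorth6"`, or `"filtered"`.
#' @param method Classifier, `"svm"` or `"knn"`.
#' @param filter_order Band-pass prototype order (default 12).
#' @param bands Band table (default [eeg_bands()]).
#' @param channels Channel subset for `"hjorth6"` (default
#'   [frontal_channels()]).
#' @param seed Default seed for seeded steps.
#' @return A validated list of class `run_config`.
#' @examples
#' run_config()
#' @export
run_config <- function(sampling_rate = 128, epoch_length = 192, window_s = 15,
                       decisions_per_window = 10,
                       feature_family = c("hjorth14", "hjorth6", "filtered"),
                       method = c("svm", "knn"), filter_order = 12,
                       bands = eeg_bands(), channels = frontal_channels(),
                       seed = 1) {
  feature_family <- match.arg(feature_family)
  method <- match.arg(method)
  validate_bands(bands, sampling_rate)
  if (abs(decisions_per_window * epoch_length / sampling_rate - window_s) > 1e-9) {
    stop("decisions_per_window x epoch duration must equal window_s (",
      decisions_per_window, " x ", epoch_length / sampling_rate,
      " s != ", window_s, " s)",
      call. = FALSE
    )
  }
  structure(
    list(
      sampling_rate = sampling_rate, epoch_length = epoch_length,
      window_s = window_s, decisions_per_window = decisions_per_window,
      feature_family = feature_family, method = method,
      filter_order = filter_order, bands = bands, channels = channels,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from an INI-style file
#'
#' The file holds `key = value` lines (blank lines and `#` comments
#' ignored) whose keys are scalar arguments of [run_config()]; unknown keys
#' are an error. Values given in the file override the defaults, and the
#' combined configuration is re-validated.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("config lines must be 'key = value'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  numeric_keys <- c(
    "sampling_rate", "epoch_length", "window_s",
    "decisions_per_window", "filter_order", "seed"
  )
  allowed <- c(numeric_keys, "feature_family", "method", "channels")
  bad <- setdiff(keys, allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  if ("channels" %in% keys) {
    args$channels <- strsplit(args$channels, "[ ,]+")[[1]]
  }
  do.call(run_config, args)
}
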