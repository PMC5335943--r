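#' Train an emotion classifier
#'
#' Fits an SVM (radial kernel, via e1071) or a KNN model (via caret) on a
#' feature table. Features are standardized to zero mean and unit variance
#' using statistics of the training data; the same statistics are reused at
#' prediction time, so no information leaks from test data.
#'
#' @param features Feature tibble from [hjorth_features()] or
#'   [filtered_features()] (or any data frame of numeric feature columns);
#'   classes come from its `label` column unless `labels` is given.
#' @param method `"svm"` or `"knn"`.
#' @param labels Optional class labels overriding the `label` column.
#' @param cost SVM soft-margin cost (default 1).
#' @param gamma SVM radial-kernel width; default `1 / n_features`.
#' @param k KNN neighborhood size (default 5).
#' @param seed Optional integer recorded in the model metadata.
#' @return An `emotion_model` object.
#' @examples
#' ep <- segment_epochs(simulate_recording("calm", 6, seed = 1))
#' hf <- hjorth_features(ep)
#' hf2 <- hjorth_features(segment_epochs(simulate_recording("sad", 6, seed = 2)))
#' model <- fit_emotion_model(rbind(hf, hf2), method = "knn", k = 1)
#' @export
fit_emotion_model <- function(features, method = c("svm", "knn"), labels = NULL,
                              cost = 1, gamma = NULL, k = 5, seed = NULL) {
  method <- match.arg(method)
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      stop("supply labels or include a 'label' column", call. = FALSE)
    }
    labels <- features$label
  }
  labels <- as.character(labels)
  x <- feature_matrix(features)
  if (nrow(x) != length(labels)) {
    stop("labels length (", length(labels), ") must match rows (", nrow(x), ")",
      call. = FALSE
    )
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))]
    stop("non-finite feature values in: ", paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- table(labels)
  if (length(counts) < 2) {
    stop("training data contains a single class (", names(counts), ")",
      call. = FALSE
    )
  }
  if (any(counts < 2)) {
    stop("every class needs at least 2 training samples", call. = FALSE)
  }
  classes <- sort(names(counts))
  y <- factor(labels, levels = classes)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1 # constant features carry no information; leave them at 0
  xs <- scale(x, center = center, scale = scale_)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- switch(method,
    svm = e1071::svm(
      x = xs, y = y, kernel = "radial", cost = cost,
      gamma = gamma, scale = FALSE
    ),
    knn = caret::knn3(xs, y, k = k)
  )
  structure(
    list(
      version = 1L,
      method = method,
      hyperparameters = switch(method,
        svm = list(cost = cost, gamma = gamma),
        knn = list(k = k)
      ),
      fit = fit,
      center = center,
      scale = scale_,
      feature_names = colnames(x),
      family = attr(features, "family") %||% "custom",
      feature_config = attr(features, "feature_config"),
      classes = classes,
      n_per_class = as.list(stats::setNames(as.integer(counts), names(counts)))[classes],
      seed = seed,
      trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      training = list(x = x, labels = labels)
    ),
    class = "emotion_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.emotion_model <- function(x, ...) {
  cat("<emotion_model> ", toupper(x$method), " on ", length(x$feature_names),
    " ", x$family, " features; classes: ", paste(x$classes, collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict emotion labels
#'
#' @param object An `emotion_model`.
#' @param newdata Feature tibble (feature columns matching the training
#'   layout) or a numeric matrix/vector in that layout.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.emotion_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    have <- setdiff(names(newdata), c("epoch", "start", "label"))
    if (!identical(have, object$feature_names)) {
      if (!all(object$feature_names %in% have)) {
        stop("feature mismatch: model expects ", length(object$feature_names),
          " features, received ", length(have),
          call. = FALSE
        )
      }
      newdata <- newdata[, c(intersect(names(newdata), c("epoch", "start", "label")), object$feature_names)]
    }
    x <- feature_matrix(newdata)
  } else {
    x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  }
  if (ncol(x) != length(object$feature_names)) {
    stop("feature length mismatch: expected ", length(object$feature_names),
      ", received ", ncol(x),
      call. = FALSE
    )
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  out <- switch(object$method,
    svm = as.character(stats::predict(object$fit, xs)),
    knn = {
      # pick the modal neighbor class from the vote probabilities; ties
      # break deterministically in class order
      pr <- stats::predict(object$fit, xs, type = "prob")
      colnames(pr)[max.col(pr, ties.method = "first")]
    }
  )
  unname(out)
}

#' Stratified k-fold cross-validation of an emotion classifier
#'
#' Shuffles samples within each class under the given seed, deals them into
#' `folds` folds whose sizes differ by at most one, and evaluates the chosen
#' classifier on each held-out fold with leakage-free standardization
#' (scaling statistics come from the training folds only).
#'
#' @inheritParams fit_emotion_model
#' @param folds Number of folds (default 10).
#' @param ... Passed on to [fit_emotion_model()] (e.g. `cost`, `k`).
#' @return A `cv_report`: fold accuracies, their mean, and the pooled
#'   confusion matrix (rows = truth).
#' @examples
#' eps <- lapply(emotion_labels(), function(l) {
#'   segment_epochs(simulate_recording(l, 7.5, seed = match(l, emotion_labels())))
#' })
#' feats <- do.call(rbind, lapply(eps, hjorth_features, channels = frontal_channels()))
#' cross_validate(feats, method = "knn", folds = 5, seed = 1)
#' @export
cross_validate <- function(features, method = c("svm", "knn"), labels = NULL,
                           folds = 10, seed = 1, ...) {
  method <- match.arg(method)
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      stop("supply labels or include a 'label' column", call. = FALSE)
    }
    labels <- as.character(features$label)
  } else {
    labels <- as.character(labels)
  }
  n <- length(labels)
  if (n < folds) {
    stop("cannot make ", folds, " folds from ", n, " samples", call. = FALSE)
  }
  fold_id <- make_stratified_folds(labels, folds, seed)
  x <- feature_matrix(features)
  classes <- sort(unique(labels))
  confusion <- matrix(0L, length(classes), length(classes),
    dimnames = list(truth = classes, predicted = classes)
  )
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    model <- fit_emotion_model(
      tibble::as_tibble(x[train, , drop = FALSE]),
      method = method, labels = labels[train], seed = seed, ...
    )
    pred <- predict(model, x[test, , drop = FALSE])
    fold_acc[f] <- mean(pred == labels[test])
    for (i in seq_along(test)) {
      confusion[labels[test[i]], pred[i]] <- confusion[labels[test[i]], pred[i]] + 1L
    }
  }
  structure(
    list(
      n_folds = folds,
      fold_accuracy = fold_acc,
      mean_accuracy = mean(fold_acc),
      confusion = confusion,
      n = n,
      method = method,
      seed = seed
    ),
    class = "cv_report"
  )
}

# within-class shuffle, then cyclic deal along the class-blocked order:
# per-class and overall fold sizes both differ by at most one
make_stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    ord <- unlist(lapply(
      sample(unique(labels)),
      function(cl) sample(which(labels == cl))
    ), use.names = FALSE)
    fold_id <- integer(length(labels))
    fold_id[ord] <- rep_len(seq_len(folds), length(labels))
    fold_id
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$n_folds, "-fold CV (", x$method, "), n = ", x$n,
    ": mean accuracy ", sprintf("%.3f", x$mean_accuracy), "\n",
    sep = ""
  )
  print(x$confusion)
  invisible(x)
}

#' @rdname tidy.emotion_model
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$n_folds), accuracy = x$fold_accuracy)
}

#' @rdname tidy.emotion_model
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$fold_accuracy),
    n = x$n,
    method = x$method
  )
}

#' Tidiers for fitted emotion models and CV reports
#'
#' `tidy()` on an `emotion_model` gives per-class training counts; on a
#' `cv_report`, per-fold accuracies. `glance()` gives one-row summaries.
#'
#' @param x An `emotion_model` or `cv_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.emotion_model <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    n_train = unname(unlist(x$n_per_class)[x$classes])
  )
}

#' @rdname tidy.emotion_model
#' @export
glance.emotion_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = length(x$feature_names),
    n_train = sum(unlist(x$n_per_class)),
    n_classes = length(x$classes),
    family = x$family
  )
}

#' Persist and restore an emotion model
#'
#' Models are stored as versioned JSON holding the method, hyperparameters,
#' scaling statistics, feature layout, and the full training set; loading
#' refits the (deterministic) classifier from that data, so a restored model
#' predicts identically to the original. Loading a file with an unknown
#' version is an error.
#'
#' @param model An `emotion_model`.
#' @param path File path for the JSON model.
#' @return `write_emotion_model()` returns `path` invisibly;
#'   `read_emotion_model()` returns the restored `emotion_model`.
#' @export
write_emotion_model <- function(model, path) {
  stopifnot(inherits(model, "emotion_model"))
  payload <- list(
    version = model$version,
    method = model$method,
    hyperparameters = model$hyperparameters,
    feature_names = model$feature_names,
    family = model$family,
    classes = model$classes,
    seed = model$seed,
    trained_at = model$trained_at,
    training_labels = model$training$labels,
    training_x = model$training$x
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_emotion_model
#' @export
read_emotion_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$version) || p$version != 1L) {
    stop("unsupported model version: ", p$version %||% "<missing>", call. = FALSE)
  }
  x <- p$training_x
  colnames(x) <- p$feature_names
  feats <- tibble::as_tibble(x)
  attr(feats, "family") <- p$family
  args <- c(
    list(
      features = feats, method = p$method, labels = p$training_labels,
      seed = p$seed
    ),
    p$hyperparameters
  )
  model <- do.call(fit_emotion_model, args)
  model$trained_at <- p$trained_at
  model
}
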