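# Seizure event detection: 3-class classification of Bonn-style channels.
#
# Each 4096-sample channel is cut into 16 non-overlapping 256-sample frames;
# per channel the first 10 frames train and the last 6 test (a deterministic
# positional split). Features from all channels of all three sets are pooled
# into one classifier that outputs 0 for normal (set A), 1 for ictal (set E)
# and 2 for interictal (set D).

#' Cut a channel into non-overlapping frames
#'
#' @param channel Numeric vector.
#' @param frame_length Samples per frame (default 256).
#' @return Matrix with one frame per row; a trailing remainder shorter than
#'   `frame_length` is discarded.
#' @export
segment_frames <- function(channel, frame_length = 256L) {
  channel <- as.numeric(channel)
  frame_length <- as.integer(frame_length)
  if (length(channel) < frame_length)
    stop(sprintf("channel has %d samples, shorter than one %d-sample frame",
                 length(channel), frame_length))
  n_frames <- length(channel) %/% frame_length
  matrix(channel[seq_len(n_frames * frame_length)],
         nrow = n_frames, ncol = frame_length, byrow = TRUE)
}

#' Run the three-class seizure event-detection experiment
#'
#' Per channel of each set, frames are extracted, the first `n_train` frames
#' contribute to a pooled training matrix and the following `n_test` frames
#' to the test matrix; one linear classifier is fit on the pooled features
#' and scored on held-out frames only.
#'
#' @param records Named list of sets; each set is a list of one-channel
#'   numeric vectors or `eeg_record`s. Names must cover the class map
#'   (default sets `"A"`, `"D"`, `"E"`).
#' @param class_map Named integer codes per set: normal A -> 0, ictal E -> 1,
#'   interictal D -> 2 by default.
#' @param frame_length Samples per frame (default 256).
#' @param n_train,n_test Frames per channel used for training / testing
#'   (default 10 / 6; every channel must yield at least their sum).
#' @param negative_set Set treated as negative class for specificity.
#' @param trainer,standardize Passed to [linear_classifier()].
#' @param bands,levels,extension_mode Passed to [event_feature_vector()].
#' @return An object of class `event_report`: confusion matrix (labels =
#'   class codes, with a `set` mapping), specificity, per-class
#'   sensitivities, accuracy (percent) and the configuration echo.
#' @export
run_event_experiment <- function(records,
                                 class_map = c(A = 0L, E = 1L, D = 2L),
                                 frame_length = 256L, n_train = 10L,
                                 n_test = 6L, negative_set = "A",
                                 trainer = "lda", standardize = FALSE,
                                 bands = c("D3", "D4", "A4"), levels = 4L,
                                 extension_mode = "symmetric") {
  sets <- names(class_map)
  missing_sets <- setdiff(sets, names(records))
  if (length(missing_sets))
    stop("records missing for set(s): ", paste(missing_sets, collapse = ", "))

  feat <- function(frame) event_feature_vector(frame, bands = bands,
                                               levels = levels,
                                               extension_mode = extension_mode)
  train_x <- list(); train_y <- character(0)
  test_x <- list(); test_y <- character(0)
  for (s in sets) {
    code <- as.character(class_map[[s]])
    for (chan in records[[s]]) {
      if (inherits(chan, "eeg_record")) {
        if (nrow(chan$samples) != 1L)
          stop("event experiment expects one-channel records")
        chan <- chan$samples[1L, ]
      }
      frames <- segment_frames(chan, frame_length)
      if (nrow(frames) < n_train + n_test)
        stop(sprintf("set %s: channel yields %d frames, need %d",
                     s, nrow(frames), n_train + n_test))
      fv <- t(apply(frames[seq_len(n_train + n_test), , drop = FALSE], 1, feat))
      train_x[[length(train_x) + 1L]] <- fv[seq_len(n_train), , drop = FALSE]
      test_x[[length(test_x) + 1L]] <- fv[n_train + seq_len(n_test), , drop = FALSE]
      train_y <- c(train_y, rep(code, n_train))
      test_y <- c(test_y, rep(code, n_test))
    }
  }
  train_x <- do.call(rbind, train_x)
  test_x <- do.call(rbind, test_x)

  model <- linear_classifier(train_x, train_y, method = trainer,
                             standardize = standardize)
  cm <- confusion(model, test_x, test_y)
  neg_code <- as.character(class_map[[negative_set]])
  metrics <- metrics_from_confusion(cm, negative_class = neg_code)

  code_to_set <- stats::setNames(sets, as.character(class_map))
  structure(list(confusion = cm, specificity = metrics$specificity,
                 sensitivities = metrics$sensitivity,
                 accuracy = metrics$accuracy, model = model,
                 class_map = class_map, set_of_code = code_to_set,
                 negative_set = negative_set,
                 config = list(frame_length = frame_length, n_train = n_train,
                               n_test = n_test, trainer = trainer,
                               standardize = standardize, bands = bands,
                               levels = levels,
                               extension_mode = extension_mode)),
            class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  cat("Seizure event-detection report\n")
  cm <- x$confusion
  dimnames(cm) <- lapply(dimnames(cm), function(d)
    paste0(x$set_of_code[d], " (", d, ")"))
  print(unclass(cm))
  cat(sprintf("Specificity (%s): %.1f%%\n", x$negative_set, x$specificity))
  for (k in names(x$sensitivities))
    cat(sprintf("Sensitivity (%s): %.1f%%\n", x$set_of_code[[k]],
                x$sensitivities[[k]]))
  cat(sprintf("Overall accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}
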