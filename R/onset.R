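# Seizure onset detection on multichannel records.
#
# Each record is cut into consecutive 1-second epochs; every channel of
# every epoch yields a 20-feature vector. A pooled binary classifier (one
# set of weights shared by all channels, because the voting rule consumes
# per-channel outputs) labels each channel 0/1; an epoch is declared a
# seizure when at least 60% of channels vote 1. Detected onset is the start
# of the first declared epoch at or after the annotated onset within the
# seizure; latency = detected - annotated, hence never negative. Epochs
# declared before onset count toward false detections.

#' Per-epoch per-channel feature array for a record
#'
#' Cuts the record into consecutive 1-second epochs (a trailing partial
#' second is discarded) and computes [onset_channel_features()] for every
#' channel of every epoch.
#'
#' @param record An `eeg_record` with an integer sampling rate.
#' @inheritParams onset_channel_features
#' @return Numeric array `[epoch, channel, feature]` with dimnames; 20
#'   features in the frozen order.
#' @export
epoch_matrix <- function(record, bands = c("D3", "D4", "A4"), levels = 4L,
                         filters = db2_filters(), extension_mode = "symmetric") {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate_hz
  if (fs != round(fs)) stop("epoching requires an integer sampling rate")
  fs <- as.integer(fs)
  n_epochs <- ncol(record$samples) %/% fs
  if (n_epochs < 1L) stop("record shorter than one 1-second epoch")
  n_ch <- nrow(record$samples)
  proto <- onset_channel_features(record$samples[1L, seq_len(fs)],
                                  bands = bands, levels = levels,
                                  filters = filters,
                                  extension_mode = extension_mode)
  out <- array(NA_real_, dim = c(n_epochs, n_ch, length(proto)),
               dimnames = list(NULL, record$channel_labels, names(proto)))
  for (e in seq_len(n_epochs)) {
    cols <- ((e - 1L) * fs + 1L):(e * fs)
    for (ch in seq_len(n_ch)) {
      out[e, ch, ] <- onset_channel_features(record$samples[ch, cols],
                                             bands = bands, levels = levels,
                                             filters = filters,
                                             extension_mode = extension_mode)
    }
  }
  out
}

#' Channel-majority seizure vote for one epoch
#'
#' @param channel_votes Binary (0/1 or logical) vector, one vote per channel.
#' @param threshold_fraction Declare a seizure when the fraction of positive
#'   channels is at least this value (default 0.6; the boundary is
#'   inclusive, so 14 of 23 channels declare and 13 of 23 do not).
#' @return Logical scalar.
#' @export
vote <- function(channel_votes, threshold_fraction = 0.6) {
  if (length(channel_votes) == 0L) stop("empty channel vote vector")
  mean(as.numeric(channel_votes)) >= threshold_fraction
}

#' Locate the detected onset of one annotated seizure
#'
#' Searches the declared-seizure epoch sequence for the first declared epoch
#' whose start time is at or after the annotated onset and before the
#' seizure end (the default search window). Latency is the detected minus
#' the annotated onset, in seconds, and is non-negative by construction.
#'
#' @param declared Logical vector over consecutive epochs; epoch k (1-based)
#'   covers `[k-1, k)` seconds.
#' @param annotated_onset_s,annotated_end_s Seizure annotation, seconds from
#'   record start.
#' @return An object of class `seizure_evaluation`: list with
#'   `annotated_onset_s`, `detected` (logical), `detected_onset_s` and
#'   `latency_s` (`NA` when undetected).
#' @export
detect_onset <- function(declared, annotated_onset_s, annotated_end_s) {
  n_epochs <- length(declared)
  if (annotated_onset_s < 0 || annotated_onset_s >= n_epochs)
    stop("annotated onset lies outside the record's epochs")
  if (annotated_end_s <= annotated_onset_s)
    stop("annotated end must exceed the onset")
  starts <- seq_len(n_epochs) - 1
  window <- which(starts >= annotated_onset_s & starts < annotated_end_s & declared)
  if (length(window) == 0L) {
    ev <- list(annotated_onset_s = annotated_onset_s, detected = FALSE,
               detected_onset_s = NA_real_, latency_s = NA_real_)
  } else {
    det <- starts[window[1L]]
    ev <- list(annotated_onset_s = annotated_onset_s, detected = TRUE,
               detected_onset_s = det, latency_s = det - annotated_onset_s)
  }
  structure(ev, class = "seizure_evaluation")
}

# Epoch index sets for one record: seizure epochs (fully inside an
# annotation) and normal epochs (outside every annotation, with a guard gap).
.epoch_index_sets <- function(record, gap_s = 0) {
  fs <- as.integer(record$sampling_rate_hz)
  n_epochs <- ncol(record$samples) %/% fs
  starts <- seq_len(n_epochs) - 1
  ann <- record$annotations
  seiz <- lapply(seq_len(nrow(ann)), function(i)
    which(starts >= ann$start_s[i] & (starts + 1) <= ann$end_s[i]))
  near <- rep(FALSE, n_epochs)
  for (i in seq_len(nrow(ann)))
    near <- near | (starts + 1 > ann$start_s[i] - gap_s & starts < ann$end_s[i] + gap_s)
  list(seizure = seiz, normal = which(!near), n_epochs = n_epochs)
}

#' Train and evaluate the onset detector for one patient
#'
#' Seizures are pooled across the patient's records in chronological order
#' (record order, then onset time); the first `ceiling(train_frac * n)`
#' train, the rest test. Training data are the per-channel feature vectors
#' of every epoch inside a training seizure (label 1) plus an equal number
#' of normal epochs per training seizure, sampled (seeded) at least
#' `normal_gap_s` away from any seizure (label 0). Test seizures are scored
#' by [detect_onset()] on the epoch votes of their record; false detections
#' are counted over all non-seizure epochs not used for training.
#'
#' @param records List of annotated `eeg_record`s for one patient (or a
#'   single record).
#' @param patient_id Identifier echoed in the report.
#' @param train_frac Minimum fraction of seizures used for training
#'   (default 0.6; the count is `ceiling(train_frac * n)`).
#' @param vote_threshold Channel-vote fraction declaring a seizure epoch.
#' @param normal_gap_s Minimum distance (s) between a normal training epoch
#'   and any seizure (default 60).
#' @param seed Integer seed for the normal-epoch sampling (required).
#' @param trainer,standardize Passed to [linear_classifier()].
#' @param bands,levels,extension_mode Passed to the feature extractor.
#' @return An object of class `patient_report`: per-seizure
#'   `seizure_evaluation`s plus `sensitivity_pct`, `mean_latency_s` (over
#'   detected test seizures), `false_detection_pct`, seizure counts and the
#'   configuration echo.
#' @export
evaluate_patient <- function(records, patient_id = "patient", train_frac = 0.6,
                             vote_threshold = 0.6, normal_gap_s = 60, seed,
                             trainer = "lda", standardize = FALSE,
                             bands = c("D3", "D4", "A4"), levels = 4L,
                             extension_mode = "symmetric") {
  if (missing(seed)) stop("seed is required")
  if (inherits(records, "eeg_record")) records <- list(records)
  n_feat <- 6L * length(bands) + 2L

  feats <- lapply(records, epoch_matrix, bands = bands, levels = levels,
                  extension_mode = extension_mode)
  idx <- lapply(records, .epoch_index_sets, gap_s = normal_gap_s)

  # chronological seizure table: record index, seizure index, onset, end
  seiz <- do.call(rbind, lapply(seq_along(records), function(r) {
    ann <- records[[r]]$annotations
    if (nrow(ann) == 0L) return(NULL)
    data.frame(record = r, seizure = seq_len(nrow(ann)),
               start_s = ann$start_s, end_s = ann$end_s)
  }))
  if (is.null(seiz) || nrow(seiz) < 2L)
    stop("need at least 2 annotated seizures (>= 1 train, >= 1 test)")
  n_seiz <- nrow(seiz)
  n_train <- ceiling(train_frac * n_seiz)
  if (n_train >= n_seiz)
    stop("no seizures left for testing under train_frac = ", train_frac)
  train_rows <- seq_len(n_train)
  test_rows <- seq.int(n_train + 1L, n_seiz)

  flat <- function(r, epochs) {
    if (length(epochs) == 0L) return(NULL)
    m <- feats[[r]][epochs, , , drop = FALSE]
    matrix(aperm(m, c(2, 1, 3)), ncol = n_feat,
           dimnames = list(NULL, dimnames(feats[[r]])[[3]]))
  }

  train_x <- list(); train_y <- character(0)
  normal_used <- lapply(records, function(r) integer(0))
  pool_left <- lapply(idx, `[[`, "normal")
  for (i in train_rows) {
    r <- seiz$record[i]
    sz_epochs <- idx[[r]]$seizure[[seiz$seizure[i]]]
    if (length(sz_epochs) == 0L)
      stop("training seizure shorter than one full epoch")
    xv <- flat(r, sz_epochs)
    train_x[[length(train_x) + 1L]] <- xv
    train_y <- c(train_y, rep("1", nrow(xv)))
    # matched normal epochs from the same patient, seeded
    take <- length(sz_epochs)
    norm_epochs <- with_seed(seed + i, {
      avail_rec <- which(vapply(pool_left, length, 1L) > 0L)
      picked <- integer(0); picked_rec <- integer(0)
      while (take > 0L && length(avail_rec)) {
        rr <- avail_rec[1L]
        k <- min(take, length(pool_left[[rr]]))
        sel <- sort(pool_left[[rr]][sample.int(length(pool_left[[rr]]), k)])
        pool_left[[rr]] <- setdiff(pool_left[[rr]], sel)
        picked <- c(picked, sel); picked_rec <- c(picked_rec, rep(rr, k))
        take <- take - k
        avail_rec <- which(vapply(pool_left, length, 1L) > 0L)
      }
      list(epochs = picked, recs = picked_rec)
    })
    if (length(norm_epochs$epochs) == 0L)
      stop("no normal epochs available >= ", normal_gap_s, " s from seizures")
    for (rr in unique(norm_epochs$recs)) {
      sel <- norm_epochs$epochs[norm_epochs$recs == rr]
      nv <- flat(rr, sel)
      train_x[[length(train_x) + 1L]] <- nv
      train_y <- c(train_y, rep("0", nrow(nv)))
      normal_used[[rr]] <- c(normal_used[[rr]], sel)
    }
  }
  model <- linear_classifier(do.call(rbind, train_x), train_y,
                             method = trainer, standardize = standardize)

  # epoch-level declarations per record
  declared <- lapply(seq_along(records), function(r) {
    n_epochs <- idx[[r]]$n_epochs
    votes <- predict(model, flat(r, seq_len(n_epochs))) == "1"
    vm <- matrix(votes, nrow = nrow(records[[r]]$samples))  # channel x epoch
    apply(vm, 2, vote, threshold_fraction = vote_threshold)
  })

  evaluations <- lapply(test_rows, function(i) {
    r <- seiz$record[i]
    ev <- detect_onset(declared[[r]], seiz$start_s[i], seiz$end_s[i])
    ev$record_id <- records[[r]]$record_id
    ev
  })
  detected <- vapply(evaluations, `[[`, logical(1), "detected")
  lat <- vapply(evaluations, `[[`, numeric(1), "latency_s")

  # false detections: non-seizure epochs (outside every annotation, no guard
  # gap) that were not consumed as normal training examples
  fd_declared <- 0L; fd_total <- 0L
  for (r in seq_along(records)) {
    sets <- .epoch_index_sets(records[[r]], gap_s = 0)
    eval_epochs <- setdiff(sets$normal, normal_used[[r]])
    fd_total <- fd_total + length(eval_epochs)
    fd_declared <- fd_declared + sum(declared[[r]][eval_epochs])
  }

  structure(list(patient_id = patient_id, n_seizures = n_seiz,
                 n_train_seizures = n_train,
                 n_test_seizures = length(test_rows),
                 evaluations = evaluations,
                 sensitivity_pct = 100 * mean(detected),
                 mean_latency_s = if (any(detected)) mean(lat[detected]) else NA_real_,
                 false_detection_pct = if (fd_total > 0) 100 * fd_declared / fd_total else NA_real_,
                 n_false_detection_epochs = fd_total,
                 model = model,
                 config = list(train_frac = train_frac,
                               vote_threshold = vote_threshold,
                               normal_gap_s = normal_gap_s, seed = seed,
                               trainer = trainer, standardize = standardize,
                               bands = bands, levels = levels,
                               extension_mode = extension_mode)),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("Onset-detection report for %s\n", x$patient_id))
  cat(sprintf("  seizures: %d total, %d train / %d test\n",
              x$n_seizures, x$n_train_seizures, x$n_test_seizures))
  cat(sprintf("  sensitivity: %.1f%%\n", x$sensitivity_pct))
  cat(sprintf("  mean latency: %s\n",
              if (is.na(x$mean_latency_s)) "n/a"
              else sprintf("%.2f s", x$mean_latency_s)))
  cat(sprintf("  false detections: %.2f%% of %d non-seizure epochs\n",
              x$false_detection_pct, x$n_false_detection_epochs))
  invisible(x)
}

#' Train/test seizure split counts under the minimum-60% rule
#'
#' @param n_seizures Total seizures for a patient.
#' @param train_frac Minimum training fraction (default 0.6).
#' @return Named integer vector `c(train, test)` with
#'   `train = ceiling(train_frac * n)`.
#' @export
seizure_split <- function(n_seizures, train_frac = 0.6) {
  n_train <- as.integer(ceiling(train_frac * n_seizures))
  c(train = n_train, test = as.integer(n_seizures) - n_train)
}
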