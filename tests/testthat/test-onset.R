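test_that("epoching produces one 20-feature vector per channel per second", {
  rec <- synth_chb(seed = 1, n_channels = 23, duration_s = 10)
  em <- epoch_matrix(rec)
  expect_equal(dim(em), c(10, 23, 20))
  expect_identical(dimnames(em)[[3]][19:20], c("IQR", "MAD"))
  # a single-channel record is accepted
  rec1 <- eeg_record(rec$samples[1, , drop = FALSE], 256)
  expect_equal(dim(epoch_matrix(rec1)), c(10, 1, 20))
})

test_that("epoching is causal: truncation leaves earlier epochs unchanged", {
  rec <- synth_chb(seed = 2, n_channels = 4, duration_s = 10)
  em10 <- epoch_matrix(rec)
  rec5 <- eeg_record(rec$samples[, 1:(5 * 256)], 256,
                     channel_labels = rec$channel_labels)
  em5 <- epoch_matrix(rec5)
  expect_identical(em5, em10[1:5, , , drop = FALSE])
})

test_that("the 60% channel vote has an inclusive boundary", {
  # enumerate k positive channels out of 23 against the threshold
  for (k in 0:23) {
    votes <- c(rep(1, k), rep(0, 23 - k))
    expect_identical(vote(votes), k / 23 >= 0.6, label = paste("k =", k))
  }
  expect_true(vote(c(rep(1, 14), rep(0, 9))))   # 14/23 ~ 0.609
  expect_false(vote(c(rep(1, 13), rep(0, 10)))) # 13/23 ~ 0.565
  expect_true(vote(rep(1, 23)))
  expect_false(vote(rep(0, 23)))
  expect_true(vote(1))                          # degenerate single channel
  expect_error(vote(numeric(0)), "empty")
})

test_that("voting is monotone in positive channel votes", {
  set.seed(3)
  for (i in 1:50) {
    v <- sample(0:1, 23, replace = TRUE)
    if (vote(v)) {
      v2 <- v
      v2[which(v == 0)[1]] <- 1
      if (anyNA(v2)) next
      expect_true(vote(v2))
    }
  }
})

test_that("onset latency counts whole epochs from the annotated onset", {
  declared <- rep(FALSE, 30)
  declared[21] <- TRUE                          # epoch covering [20, 21) s
  ev <- detect_onset(declared, annotated_onset_s = 20, annotated_end_s = 28)
  expect_true(ev$detected)
  expect_equal(ev$latency_s, 0)
  declared2 <- rep(FALSE, 30)
  declared2[24] <- TRUE                         # 3 epochs after onset
  ev2 <- detect_onset(declared2, 20, 28)
  expect_equal(ev2$latency_s, 3)
  ev3 <- detect_onset(rep(FALSE, 30), 20, 28)   # never declared
  expect_false(ev3$detected)
  expect_true(is.na(ev3$latency_s))
  # declarations before onset or after seizure end are ignored here
  declared4 <- rep(FALSE, 30)
  declared4[c(5, 29)] <- TRUE
  expect_false(detect_onset(declared4, 20, 28)$detected)
  expect_error(detect_onset(declared, 40, 50), "outside the record")
})

test_that("shifting the annotated onset earlier adds exactly that latency", {
  declared <- rep(FALSE, 40)
  declared[26] <- TRUE
  base <- detect_onset(declared, 25, 35)$latency_s
  for (k in 1:5)
    expect_equal(detect_onset(declared, 25 - k, 35)$latency_s, base + k)
})

test_that("the minimum-60% rule reproduces the published split counts", {
  expect_identical(seizure_split(16), c(train = 10L, test = 6L))
  expect_identical(seizure_split(3), c(train = 2L, test = 1L))
  expect_identical(seizure_split(40), c(train = 24L, test = 16L))
  expect_identical(seizure_split(18), c(train = 11L, test = 7L))
  expect_identical(seizure_split(10), c(train = 6L, test = 4L))
})

test_that("unmistakable synthetic seizures are detected with minimal latency", {
  rec <- short_patient()
  pr <- evaluate_patient(rec, seed = 7, normal_gap_s = 20)
  expect_identical(pr$n_train_seizures, 2)
  expect_identical(pr$n_test_seizures, 1L)
  expect_equal(pr$sensitivity_pct, 100)
  expect_lte(pr$mean_latency_s, 1)
  expect_lte(pr$false_detection_pct, 2)
})

test_that("patient evaluation is deterministic for a fixed seed and config", {
  rec <- short_patient(seed = 5)
  p1 <- evaluate_patient(rec, seed = 11, normal_gap_s = 20)
  p2 <- evaluate_patient(rec, seed = 11, normal_gap_s = 20)
  p1$model <- p2$model <- NULL
  expect_identical(p1, p2)
})

test_that("patient evaluation rejects unusable seizure configurations", {
  rec <- synth_chb(seed = 9, duration_s = 60,
                   seizure_intervals = data.frame(start_s = 10, end_s = 20))
  expect_error(evaluate_patient(rec, seed = 1), "at least 2")
})
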