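test_that("energy, entropy and moment features reproduce hand calculations", {
  expect_equal(subband_energy(c(1, 2, 3)), 14)
  expect_equal(subband_energy(rep(0, 10)), 0)
  expect_equal(subband_entropy(rep(0, 10)), 0)      # 0 * log 0 convention
  expect_equal(subband_entropy(c(1, -1)), 0)        # log 1 = 0
  expect_equal(subband_entropy(sqrt(exp(1))), exp(1))
  st <- subband_stats(c(1, 2, 3))
  expect_equal(unname(st), c(3, 1, 2, 1))
  expect_equal(unname(subband_stats(rep(5, 8))[["std"]]), 0)
  expect_equal(iqr_range(1:8), 3.5)                 # Q1 = 2.75, Q3 = 6.25
  expect_equal(iqr_range(rep(2, 10)), 0)
  expect_equal(mean_abs_dev(c(1, 2, 3)), 2 / 3)
  expect_equal(mean_abs_dev(rep(-4, 6)), 0)
})

test_that("features match independent loop oracles on seeded inputs", {
  set.seed(77)
  x <- rnorm(100, sd = 30)
  expect_equal(subband_energy(x), oracle_energy(x), tolerance = 1e-12)
  expect_equal(subband_entropy(x), oracle_entropy(x), tolerance = 1e-12)
  y <- rnorm(257, mean = 5)
  ms <- oracle_mean_sd(y)
  st <- subband_stats(y)
  expect_equal(st[["mean"]], ms[["mean"]], tolerance = 1e-12)
  expect_equal(st[["std"]], ms[["sd"]], tolerance = 1e-12)
  z <- rnorm(256)
  expect_equal(mean_abs_dev(z), oracle_mad(z), tolerance = 1e-12)
})

test_that("set features are invariant under sample reordering", {
  set.seed(88)
  x <- rnorm(50)
  xp <- sample(x)
  expect_equal(subband_energy(xp), subband_energy(x))
  expect_equal(subband_entropy(xp), subband_entropy(x))
  expect_equal(mean_abs_dev(xp), mean_abs_dev(x))
  expect_equal(iqr_range(xp), iqr_range(x))
  expect_equal(subband_stats(xp)[["std"]], subband_stats(x)[["std"]])
})

test_that("features obey scale equivariance identities", {
  set.seed(99)
  x <- rnorm(64)
  for (a in c(0.5, 3, 17)) {
    expect_equal(subband_energy(a * x), a^2 * subband_energy(x))
    expect_equal(mean_abs_dev(a * x), a * mean_abs_dev(x))
    expect_equal(iqr_range(a * x), a * iqr_range(x))
  }
  b <- 12.5
  expect_equal(iqr_range(3 * x + b), 3 * iqr_range(x))  # shift invariance too
})

test_that("energy, std and MAD grow monotonically with ictal amplitude", {
  frames <- lapply(c(1, 2, 5, 10), function(sc)
    synth_bonn("ictal", seed = 3, amplitude_scale = sc)$samples[1, 1:256])
  en <- vapply(frames, function(f) event_feature_vector(f)[["A4_energy"]],
               numeric(1))
  sd_ <- vapply(frames, function(f) event_feature_vector(f)[["A4_std"]],
                numeric(1))
  md <- vapply(frames, mean_abs_dev, numeric(1))
  expect_true(all(diff(en) > 0))
  expect_true(all(diff(sd_) > 0))
  expect_true(all(diff(md) > 0))
})

test_that("event feature vector has 18 features in the frozen band/feature order", {
  set.seed(101)
  fv <- event_feature_vector(rnorm(256))
  expect_length(fv, 18)
  expect_identical(names(fv), as.vector(outer(
    c("max", "min", "mean", "std", "entropy", "energy"),
    c("D3", "D4", "A4"), function(f, b) paste0(b, "_", f))))
  z <- event_feature_vector(rep(0, 256))
  expect_true(all(z == 0))
})

test_that("onset channel vector appends raw-epoch IQR and MAD for 20 features", {
  set.seed(102)
  fv <- onset_channel_features(rnorm(256))
  expect_length(fv, 20)
  expect_identical(tail(names(fv), 2), c("IQR", "MAD"))
  expect_true(all(onset_channel_features(rep(0, 256)) == 0))
})

test_that("a single large spike raises energy and MAD above a flat epoch", {
  flat <- rep(1, 256)
  spiked <- flat
  spiked[100] <- 500
  f1 <- onset_channel_features(flat)
  f2 <- onset_channel_features(spiked)
  expect_gt(f2[["A4_energy"]] + f2[["D3_energy"]] + f2[["D4_energy"]],
            f1[["A4_energy"]] + f1[["D3_energy"]] + f1[["D4_energy"]])
  expect_gte(f2[["IQR"]], f1[["IQR"]])
  expect_gt(f2[["MAD"]], f1[["MAD"]])
})

test_that("feature functions reject degenerate input", {
  expect_error(subband_energy(numeric(0)), "empty")
  expect_error(subband_entropy(numeric(0)), "empty")
  expect_error(mean_abs_dev(numeric(0)), "empty")
  expect_error(iqr_range(1:3), "at least 4")
  expect_warning(subband_stats(5), "length-1")
})

test_that("feature tables round-trip through CSV with provenance columns", {
  set.seed(103)
  m <- t(vapply(1:3, function(i) event_feature_vector(rnorm(256)), numeric(18)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(m, path, record_id = "r1", channel = 2L)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(names(back)[1:3], c("record_id", "channel", "frame"))
  expect_equal(as.matrix(back[, -(1:3)]), m, ignore_attr = TRUE)
})
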