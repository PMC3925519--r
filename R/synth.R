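# Seeded synthetic EEG generator.
#
# Background activity is Gaussian noise band-limited to 0.53-40 Hz (the pass
# band of the archives this package targets). The ictal surrogate is a 3 Hz
# spike-and-wave rhythm -- the classic absence-seizure morphology -- at ten
# times the background amplitude, so subband energy/std contrasts between
# normal and ictal signals span roughly an order of magnitude, as they do
# between real normal and ictal scalp recordings. Interictal signals add
# sparse isolated epileptiform spikes to the background.

.BASELINE_SD <- 40   # background standard deviation, uV
.ICTAL_GAIN <- 10    # ictal amplitude relative to background sd
.SPIKE_GAIN <- 5     # interictal spike amplitude relative to background sd

band_limited_noise <- function(n, fs, sd_target = .BASELINE_SD,
                               band = c(0.53, 40)) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]                      # drop filter edge transients
  x * sd_target / stats::sd(x)
}

# 3 Hz spike-and-wave: a sharp Gaussian spike riding on a half-sine slow
# wave, repeated every 1/3 s; unit peak amplitude.
spike_wave <- function(t, rate_hz = 3, phase = 0) {
  tp <- (t + phase) %% (1 / rate_hz)
  spike <- exp(-((tp - 0.06)^2) / (2 * 0.012^2))
  wave <- 0.45 * sin(2 * pi * rate_hz * (t + phase))
  spike + wave
}

# One isolated biphasic epileptiform spike of ~70 ms, unit amplitude, at t0.
isolated_spike <- function(t, t0) {
  u <- t - t0
  exp(-(u - 0.02)^2 / (2 * 0.008^2)) - 0.5 * exp(-(u - 0.05)^2 / (2 * 0.015^2))
}

#' Generate a Bonn-style single-channel synthetic record
#'
#' Emulates the three signal classes used for seizure event detection:
#' `"normal"` is band-limited background noise, `"interictal"` adds sparse
#' isolated spikes, `"ictal"` adds a sustained high-amplitude 3 Hz
#' spike-and-wave rhythm. Identical arguments (including `seed`) give
#' identical samples.
#'
#' @param mode `"normal"`, `"interictal"` or `"ictal"`.
#' @param seed Integer seed (required: the generator is deterministic).
#' @param n_samples Record length (default 4096 samples).
#' @param sampling_rate_hz Default 173.61 Hz.
#' @param amplitude_scale Multiplies the class-specific waveform amplitude
#'   (1 = the calibrated default contrast).
#' @param record_id Identifier; defaults to `"<mode>_<seed>"`.
#' @return A one-channel `eeg_record`.
#' @export
synth_bonn <- function(mode = c("normal", "interictal", "ictal"), seed,
                       n_samples = 4096L, sampling_rate_hz = 173.61,
                       amplitude_scale = 1,
                       record_id = paste0(mode[1L], "_", seed)) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  fs <- sampling_rate_hz
  t <- (seq_len(n_samples) - 1) / fs
  x <- with_seed(seed, {
    base <- band_limited_noise(n_samples, round(fs))
    extra <- switch(mode,
      normal = 0,
      interictal = {
        n_spikes <- max(1L, stats::rpois(1, n_samples / fs))   # ~1 spike/s
        t0 <- sort(stats::runif(n_spikes, 0.1, max(t) - 0.1))
        amp <- .SPIKE_GAIN * .BASELINE_SD * amplitude_scale *
          stats::runif(n_spikes, 0.8, 1.2) * sample(c(-1, 1), n_spikes, TRUE)
        Reduce(`+`, Map(function(tt, aa) aa * isolated_spike(t, tt), t0, amp))
      },
      ictal = {
        phase <- stats::runif(1, 0, 1 / 3)
        .ICTAL_GAIN * .BASELINE_SD * amplitude_scale * spike_wave(t, phase = phase)
      })
    base + extra
  })
  eeg_record(x, sampling_rate_hz, record_id = record_id)
}

#' Generate a CHB-style multichannel synthetic record with seizures
#'
#' Per-channel band-limited background noise; within each seizure interval a
#' fixed fraction of channels (default 80%, always at least 70% so a 60%
#' channel vote can fire) carries the high-amplitude 3 Hz spike-and-wave
#' pattern with channel-specific phase. Seizure intervals become the
#' record's annotations.
#'
#' @param seed Integer seed (required).
#' @param n_channels Default 23.
#' @param duration_s Record duration in whole seconds.
#' @param sampling_rate_hz Default 256 Hz.
#' @param seizure_intervals Data frame with columns `start_s`, `end_s`
#'   (half-open, seconds from record start), or `NULL` for a seizure-free
#'   record. Must be sorted, non-overlapping and inside the record.
#' @param seizure_channel_frac Fraction of channels carrying the ictal
#'   pattern in each seizure (minimum 0.7).
#' @param amplitude_scale Ictal amplitude multiplier.
#' @param record_id Identifier.
#' @return An `eeg_record` with annotations attached.
#' @export
synth_chb <- function(seed, n_channels = 23L, duration_s = 60,
                      sampling_rate_hz = 256L, seizure_intervals = NULL,
                      seizure_channel_frac = 0.8, amplitude_scale = 1,
                      record_id = paste0("chb_", seed)) {
  if (missing(seed)) stop("seed is required")
  if (seizure_channel_frac < 0.7)
    stop("seizure_channel_frac below 0.7 cannot guarantee a 60% channel vote")
  fs <- as.integer(sampling_rate_hz)
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  ann <- validate_annotations(seizure_intervals, duration_s)
  samples <- with_seed(seed, {
    m <- t(vapply(seq_len(n_channels),
                  function(ch) band_limited_noise(n, fs, sd_target = 0.75 * .BASELINE_SD),
                  numeric(n)))
    if (nrow(ann)) {
      n_on <- ceiling(seizure_channel_frac * n_channels)
      for (i in seq_len(nrow(ann))) {
        on_ch <- sample.int(n_channels, n_on)
        in_seiz <- t >= ann$start_s[i] & t < ann$end_s[i]
        for (ch in on_ch) {
          phase <- stats::runif(1, 0, 1 / 3)
          m[ch, in_seiz] <- m[ch, in_seiz] +
            .ICTAL_GAIN * .BASELINE_SD * amplitude_scale *
            spike_wave(t[in_seiz], phase = phase)
        }
      }
    }
    m
  })
  eeg_record(samples, fs,
             channel_labels = sprintf("EEG%02d", seq_len(n_channels)),
             record_id = record_id, annotations = ann)
}
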