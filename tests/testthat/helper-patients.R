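# Small synthetic patients used across onset tests: 3 obvious seizures in a
# 160-second, 23-channel record.
short_patient <- function(seed = 42, duration = 160,
                          ann = data.frame(start_s = c(20, 60, 100),
                                           end_s = c(28, 68, 108))) {
  synth_chb(seed = seed, duration_s = duration, seizure_intervals = ann)
}
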