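# Independent brute-force oracles: literal per-frame transcriptions of the
# detection criteria and small counting utilities. Deliberately naive and
# kept free of any package internals beyond public constructors.

oracle_detect_activation <- function(x, stim_onset, stim_offset,
                                     mag_mult = 2, deriv_mult = 1,
                                     win = 12, prestim = 100,
                                     frame_rate = 10) {
  n <- length(x)
  pre <- x[(stim_onset - prestim + 1):stim_onset]
  mu <- mean(pre); sdev <- sd(pre)
  dpre <- pre[-1] - pre[-length(pre)]
  mu_d <- mean(dpre); sd_d <- sd(dpre)
  for (t0 in stim_onset:(stim_offset - 1)) {      # 0-based frames
    if (t0 + win > n - 1) next
    i <- t0 + 1                                   # 1-based
    window_mean <- mean(x[i:(i + win)])
    deriv <- x[i + 1] - x[i]
    if (window_mean > mu + mag_mult * sdev &&
        deriv > mu_d + deriv_mult * sd_d)
      return(list(responded = TRUE, onset_frame = t0,
                  latency_s = (t0 - stim_onset) / frame_rate))
  }
  list(responded = FALSE, onset_frame = NA, latency_s = NA)
}

oracle_detect_inhibition <- function(s, stim_onset, stim_offset,
                                     mag_mult = 2, long_mult = 0.5,
                                     short_mult = 1.15, win = 10,
                                     short_win = 5, prestim = 100,
                                     frame_rate = 10) {
  n <- length(s)
  pre <- s[(stim_onset - prestim + 1):stim_onset]
  mu <- mean(pre); sdev <- sd(pre)
  dpre <- pre[-1] - pre[-length(pre)]
  mu_d <- mean(dpre); sd_d <- sd(dpre)
  for (t0 in stim_onset:(stim_offset - 1)) {
    if (t0 + win > n - 1) next
    i <- t0 + 1
    window_mean <- mean(s[i:(i + win)])
    d_long <- (s[i + win] - s[i]) / win
    d_short <- (s[i + short_win] - s[i]) / short_win
    if (window_mean < mu - mag_mult * sdev &&
        (d_long < mu_d - long_mult * sd_d ||
         d_short < mu_d - short_mult * sd_d))
      return(list(responded = TRUE, onset_frame = t0,
                  latency_s = (t0 - stim_onset) / frame_rate))
  }
  list(responded = FALSE, onset_frame = NA, latency_s = NA)
}

# Build a cumulative profile from a plain latency vector (NA = no response).
profile_from_latencies <- function(lat, duration_s = 10, frame_rate = 10) {
  calls <- lapply(lat, function(l)
    structure(list(responded = !is.na(l), latency_s = l,
                   magnitude = NA_real_),
              class = "response_call"))
  cumulative_profile(calls, duration_s, frame_rate)
}

# A minimal valid ensemble around a trace matrix.
tiny_ensemble <- function(traces, frame_rate = 10, stim_onset = 100,
                          stim_offset = 200, ...) {
  trace_ensemble(traces, frame_rate = frame_rate, stim_onset = stim_onset,
                 stim_offset = stim_offset, ...)
}
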