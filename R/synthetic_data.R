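#' Configuration for the synthetic trace generator
#'
#' Describes a responder ensemble with the statistical structure the
#' analysis assumes: a stable noisy baseline with little spontaneous
#' activity, per-trial Bernoulli responder status, a latency distribution,
#' a stereotyped rise with optional adaptation, optional linear
#' photobleaching, and either activation or inhibition polarity
#' (inhibition traces carry an elevated tonic level that falls after
#' odor onset).
#'
#' Defaults mirror the acquisition and phenomenology of the recordings the
#' analysis targets: 10 fps, a 10 s stimulus embedded after a 10 s
#' baseline in a 30 s trace, tens of pulses per condition, high responder
#' probability with ~1 s-scale latencies, unit-dF/F0 peaks with sub-second
#' rise, and small i.i.d. Gaussian baseline noise (an AR(1) option exists
#' for robustness checks).
#'
#' @param n_traces number of pulses to simulate (default 40).
#' @param responder_fraction Bernoulli probability a pulse responds.
#' @param latency_law list: `dist` one of `"lognormal"` (`meanlog`,
#'   `sdlog`), `"exponential"` (`rate`), `"uniform"` (`min`, `max`), plus a
#'   `shift` in seconds added to every draw.
#' @param polarity `"activation"` or `"inhibition"`.
#' @param rise_shape list: `shape` one of `"step"`, `"linear"` (`ramp_s`),
#'   `"exponential"` (`tau`), `"sigmoid"` (`k`).
#' @param peak_amplitude mean peak dF/F0 of a response.
#' @param peak_jitter_sd per-trial SD of the peak amplitude.
#' @param adaptation_tau decay time constant in seconds after the rise;
#'   `Inf` disables adaptation.
#' @param noise_sd baseline Gaussian noise SD in dF/F0 units.
#' @param noise_ar1 lag-1 autocorrelation of the noise (default 0,
#'   i.i.d.).
#' @param bleach_rate fractional fluorescence loss per second (linear).
#' @param frame_rate,trace_length,stim_onset,stim_offset acquisition
#'   geometry (frames; `stim_onset`/`stim_offset` 0-based half-open).
#' @param f_base mean raw baseline fluorescence (arbitrary units).
#' @param f_base_cv coefficient of variation of the per-trace baseline.
#' @param neuron,condition metadata labels stamped on the traces.
#' @param seed RNG seed making generation fully deterministic.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_traces = 40L, responder_fraction = 0.8,
                             latency_law = list(dist = "lognormal",
                                                meanlog = 0, sdlog = 0.5,
                                                shift = 0.2),
                             polarity = c("activation", "inhibition"),
                             rise_shape = list(shape = "exponential",
                                               tau = 0.5),
                             peak_amplitude = 1.0, peak_jitter_sd = 0.2,
                             adaptation_tau = Inf,
                             noise_sd = 0.05, noise_ar1 = 0,
                             bleach_rate = 0,
                             frame_rate = 10, trace_length = 300L,
                             stim_onset = 100L, stim_offset = 200L,
                             f_base = 100, f_base_cv = 0.1,
                             neuron = "SYN", condition = "synthetic",
                             seed = 1L) {
  polarity <- match.arg(polarity)
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (stim_onset < 0 || stim_offset <= stim_onset ||
      stim_offset > trace_length)
    stop("inconsistent stimulus window", call. = FALSE)
  structure(list(n_traces = as.integer(n_traces),
                 responder_fraction = responder_fraction,
                 latency_law = latency_law, polarity = polarity,
                 rise_shape = rise_shape,
                 peak_amplitude = peak_amplitude,
                 peak_jitter_sd = peak_jitter_sd,
                 adaptation_tau = adaptation_tau,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1,
                 bleach_rate = bleach_rate,
                 frame_rate = frame_rate,
                 trace_length = as.integer(trace_length),
                 stim_onset = as.integer(stim_onset),
                 stim_offset = as.integer(stim_offset),
                 f_base = f_base, f_base_cv = f_base_cv,
                 neuron = neuron, condition = condition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.draw_latencies <- function(law, n) {
  shift <- law$shift %||% 0
  raw <- switch(law$dist,
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    exponential = stats::rexp(n, law$rate),
    uniform = stats::runif(n, law$min, law$max),
    stop("unknown latency law: ", law$dist, call. = FALSE))
  raw + shift
}

# Deterministic response waveform: 0 before t0_s, rising toward 1 after,
# with optional adaptation decay. Times in seconds.
.rise_profile <- function(t_s, t0_s, shape, adaptation_tau) {
  u <- pmax(t_s - t0_s, 0)
  r <- switch(shape$shape,
    step = as.numeric(t_s >= t0_s),
    linear = pmin(u / (shape$ramp_s %||% 2), 1) * (t_s >= t0_s),
    exponential = (1 - exp(-u / (shape$tau %||% 0.5))) * (t_s >= t0_s),
    sigmoid = {
      k <- shape$k %||% 4
      raw <- 1 / (1 + exp(-k * (u - 4 / k)))
      (raw - 1 / (1 + exp(4))) / (1 - 1 / (1 + exp(4))) * (t_s >= t0_s)
    },
    stop("unknown rise shape: ", shape$shape, call. = FALSE))
  if (is.finite(adaptation_tau)) r <- r * exp(-u / adaptation_tau)
  r
}

#' Generate a synthetic trace ensemble with ground truth
#'
#' Raw fluorescence is built as
#' `F_base * (1 + signal(t)) * bleach(t) + F_base * noise(t)`:
#' responder status is Bernoulli, onsets are drawn from the latency law
#' after stimulus onset, the rise follows the configured shape scaled by a
#' jittered peak amplitude, bleaching is a linear decay, and noise is
#' (optionally AR(1)-correlated) Gaussian in dF/F0 units. Inhibition
#' traces carry the mirrored signal: an elevated tonic level that decays
#' to baseline after the onset. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `ensemble` (a [trace_ensemble()]) and
#'   `truth` (data frame: `trace`, `responder`, `latency_s`, `onset_frame`,
#'   `peak`).
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_traces
    len <- cf$trace_length
    t_s <- (seq_len(len) - 1L) / cf$frame_rate
    onset_s <- cf$stim_onset / cf$frame_rate
    responder <- stats::runif(n) < cf$responder_fraction
    latency <- ifelse(responder, .draw_latencies(cf$latency_law, n), NA_real_)
    peak <- pmax(stats::rnorm(n, cf$peak_amplitude, cf$peak_jitter_sd), 0.05)
    fb <- cf$f_base * pmax(stats::rnorm(n, 1, cf$f_base_cv), 0.2)
    bleach <- pmax(1 - cf$bleach_rate * t_s, 0.05)
    traces <- matrix(0, n, len)
    for (i in seq_len(n)) {
      sig <- numeric(len)
      if (cf$polarity == "activation") {
        if (responder[i])
          sig <- peak[i] * .rise_profile(t_s, onset_s + latency[i],
                                         cf$rise_shape, cf$adaptation_tau)
      } else {
        # tonically elevated cell; responders fall back to baseline
        sig <- rep(peak[i], len)
        if (responder[i])
          sig <- peak[i] * (1 - .rise_profile(t_s, onset_s + latency[i],
                                              cf$rise_shape,
                                              cf$adaptation_tau))
      }
      z <- stats::rnorm(len)
      if (cf$noise_ar1 != 0) {
        e <- numeric(len)
        e[1] <- z[1]
        for (k in 2:len)
          e[k] <- cf$noise_ar1 * e[k - 1] + sqrt(1 - cf$noise_ar1^2) * z[k]
        z <- e
      }
      traces[i, ] <- fb[i] * (1 + sig) * bleach + fb[i] * cf$noise_sd * z
    }
    meta <- data.frame(neuron = cf$neuron, condition = cf$condition,
                       animal = rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)],
                       pulse = rep(c(1L, 2L), length.out = n),
                       block = 1L)
    ens <- trace_ensemble(traces, frame_rate = cf$frame_rate,
                          stim_onset = cf$stim_onset,
                          stim_offset = cf$stim_offset, meta = meta)
    truth <- data.frame(trace = seq_len(n), responder = responder,
                        latency_s = latency,
                        onset_frame = ifelse(responder,
                          cf$stim_onset + ceiling(latency * cf$frame_rate),
                          NA_integer_),
                        peak = ifelse(responder, peak,
                                      if (cf$polarity == "inhibition")
                                        peak else NA_real_))
    list(ensemble = ens, truth = truth)
  })
}

#' Generate a stimulus-free buffer ensemble
#'
#' The responder fraction is forced to zero, emulating control switches to
#' plain buffer: pure baseline noise (plus any configured bleach) with no
#' evoked signal. Used to calibrate false-positive rates of the detector.
#'
#' @param config a [synthetic_config()]; its `responder_fraction` is
#'   overridden.
#' @return a [trace_ensemble()].
#' @export
generate_null_buffer <- function(config) {
  cf <- config
  cf$responder_fraction <- 0
  cf$condition <- paste0(cf$condition, "_buffer")
  generate_ensemble(cf)$ensemble
}
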