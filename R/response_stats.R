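#' Evaluate expressions under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded analyses never perturb the session stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.calls_df <- function(calls) {
  if (inherits(calls, "response_call")) calls <- list(calls)
  if (!is.data.frame(calls) && length(calls) == 0L)
    return(data.frame(responded = logical(0), latency_s = numeric(0),
                      magnitude = numeric(0)))
  if (is.data.frame(calls)) {
    df <- calls[!is.na(calls$responded), , drop = FALSE]
  } else {
    df <- do.call(rbind, lapply(calls, function(cl)
      data.frame(responded = cl$responded, latency_s = cl$latency_s,
                 magnitude = cl$magnitude %||% NA_real_)))
  }
  df
}

#' Cumulative response-time profile
#'
#' The fraction of all trials (responders and non-responders together) that
#' have responded by each time point on the frame grid. The curve's
#' asymptote over the analysis horizon is the response probability;
#' non-responding trials never contribute a latency but stay in the
#' denominator.
#'
#' @param calls a data frame from [detect_ensemble()] (excluded traces,
#'   i.e. rows with `responded` NA, are ignored) or a list of
#'   `response_call` objects.
#' @param duration_s analysis horizon in seconds (default 10, the stimulus
#'   pulse length).
#' @param frame_rate grid resolution in frames per second.
#' @return an object of class `cumulative_profile` with sorted responder
#'   `latencies_s`, `n_total`, `times` and `curve`.
#' @export
cumulative_profile <- function(calls, duration_s = 10, frame_rate = 10) {
  df <- .calls_df(calls)
  if (nrow(df) == 0L)
    stop("no analyzable calls", call. = FALSE)
  lat <- sort(df$latency_s[df$responded & !is.na(df$latency_s) &
                             df$latency_s <= duration_s])
  times <- seq(0, duration_s, by = 1 / frame_rate)
  counts <- vapply(times, function(t) sum(lat <= t + 1e-12), numeric(1))
  structure(list(latencies_s = lat, n_total = nrow(df),
                 duration_s = duration_s, frame_rate = frame_rate,
                 times = times, curve = counts / nrow(df)),
            class = "cumulative_profile")
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat("<cumulative_profile> ", length(x$latencies_s), "/", x$n_total,
      " trials responded within ", x$duration_s, " s",
      if (length(x$latencies_s))
        paste0("; median latency ", stats::median(x$latencies_s), " s"),
      "\n", sep = "")
  invisible(x)
}

#' Time at which a profile reaches 50% response
#'
#' First frame-grid time at which the cumulative curve reaches or exceeds
#' 0.5 (no interpolation); `NA` if the profile never reaches 50%.
#'
#' @param profile a `cumulative_profile`.
#' @export
time_to_half <- function(profile) {
  hit <- which(profile$curve >= 0.5)
  if (length(hit) == 0L) NA_real_ else profile$times[hit[1]]
}

# Upper tail of the Kolmogorov distribution, 2 * sum (-1)^(k-1) exp(-2 k^2
# lambda^2), truncated once terms fall below 1e-10.
.kolmogorov_tail <- function(lambda) {
  if (lambda <= 0) return(1)
  total <- 0
  for (k in 1:1000) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-10) break
  }
  min(max(total, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov comparison of cumulative profiles
#'
#' D is the maximum absolute gap between the two fraction-of-all-trials
#' curves over the frame grid, so non-responding trials enter as
#' right-censored mass at the horizon and the test captures both latency
#' and response probability. The p-value is the asymptotic Kolmogorov tail
#' at `lambda = sqrt(ne) * D` with effective size `ne = n1 n2 / (n1 + n2)`;
#' this form reproduces published worked values (e.g. D = 0.470 with
#' n = 28 and 24 gives p = 0.0066, printed as 0.007). The Stephens
#' small-sample form `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D` is
#' available via `correction = "stephens"`.
#'
#' @param a,b `cumulative_profile` objects on the same horizon and grid.
#' @param correction `"none"` (default) or `"stephens"`.
#' @return an object of class `ks_result` with `D`, `p`, `n1`, `n2`.
#' @export
ks_compare <- function(a, b, correction = c("none", "stephens")) {
  correction <- match.arg(correction)
  stopifnot(inherits(a, "cumulative_profile"),
            inherits(b, "cumulative_profile"))
  if (a$duration_s != b$duration_s || a$frame_rate != b$frame_rate)
    stop("profiles have mismatched horizons or grids", call. = FALSE)
  if (a$n_total < 1L || b$n_total < 1L)
    stop("both profiles need at least one trial", call. = FALSE)
  D <- max(abs(a$curve - b$curve))
  ne <- a$n_total * b$n_total / (a$n_total + b$n_total)
  lambda <- if (correction == "stephens")
    (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  else sqrt(ne) * D
  p <- if (D == 0) 1 else .kolmogorov_tail(lambda)
  structure(list(D = D, p = p, n1 = a$n_total, n2 = b$n_total,
                 correction = correction),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Two-sample KS on cumulative response profiles: D = ",
      signif(x$D, 3), ", p = ", signif(x$p, 3),
      " (n = ", x$n1, ", ", x$n2, ")\n", sep = "")
  invisible(x)
}

# 50% response time from latency vector (NA = non-responder), snapped to
# the frame grid; NA when fewer than half the trials respond.
.t50 <- function(lat, n, frame_rate, duration_s) {
  k <- ceiling(n / 2)
  resp <- sort(lat[!is.na(lat) & lat <= duration_s])
  if (length(resp) < k) return(NA_real_)
  ceiling(resp[k] * frame_rate - 1e-9) / frame_rate
}

#' Bootstrap estimate of the lag between two neurons' population responses
#'
#' The point estimate is the time at which 50% of downstream trials have
#' responded minus the same quantity upstream (first frame at or past 0.5
#' on the cumulative curve, no interpolation). Whole trials are resampled
#' with replacement within each group, both 50% times are recomputed, and
#' the SD of the resampled lags is reported as the standard error.
#' Resamples in which either group fails to reach 50% are excluded from the
#' SD and counted.
#'
#' @param upstream,downstream call sets as accepted by
#'   [cumulative_profile()].
#' @param n_resamples bootstrap draws (default 1000).
#' @param seed RNG seed governing all draws; `NULL` uses the current
#'   stream.
#' @param duration_s,frame_rate analysis horizon and grid.
#' @return an object of class `bootstrap_lag` with `lag_s`, `sem_s`,
#'   `undefined`, `n_resamples`, `n_failed`, `seed`.
#' @export
bootstrap_lag <- function(upstream, downstream, n_resamples = 1000,
                          seed = NULL, duration_s = 10, frame_rate = 10) {
  up <- .calls_df(upstream); dn <- .calls_df(downstream)
  if (nrow(up) == 0L || nrow(dn) == 0L)
    stop("both groups need at least one trial", call. = FALSE)
  lat_u <- ifelse(up$responded, up$latency_s, NA_real_)
  lat_d <- ifelse(dn$responded, dn$latency_s, NA_real_)
  t_u <- .t50(lat_u, length(lat_u), frame_rate, duration_s)
  t_d <- .t50(lat_d, length(lat_d), frame_rate, duration_s)
  if (is.na(t_u) || is.na(t_d)) {
    return(structure(list(lag_s = NA_real_, sem_s = NA_real_,
                          undefined = TRUE, n_resamples = 0L, n_failed = 0L,
                          seed = seed, lags = numeric(0)),
                     class = "bootstrap_lag"))
  }
  lags <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      ru <- lat_u[sample.int(length(lat_u), replace = TRUE)]
      rd <- lat_d[sample.int(length(lat_d), replace = TRUE)]
      bu <- .t50(ru, length(ru), frame_rate, duration_s)
      bd <- .t50(rd, length(rd), frame_rate, duration_s)
      bd - bu
    }, numeric(1))
  })
  kept <- lags[!is.na(lags)]
  structure(list(lag_s = t_d - t_u,
                 sem_s = if (length(kept) >= 2L) stats::sd(kept) else 0,
                 undefined = FALSE, n_resamples = as.integer(n_resamples),
                 n_failed = sum(is.na(lags)), seed = seed, lags = lags),
            class = "bootstrap_lag")
}

#' @export
print.bootstrap_lag <- function(x, ...) {
  if (x$undefined)
    cat("<bootstrap_lag> undefined: a group never reaches 50% response\n")
  else
    cat("<bootstrap_lag> lag = ", x$lag_s, " s, bootstrap SEM = ",
        signif(x$sem_s, 4), " s (", x$n_resamples, " resamples, ",
        x$n_failed, " failed)\n", sep = "")
  invisible(x)
}

#' Sensory-style response magnitude
#'
#' Mean dF/F0 over the final 10 in-pulse frames minus the mean over the 10
#' frames immediately before stimulus onset. Sign-free: inhibitory
#' responses yield negative magnitudes.
#'
#' @param trace a `normalized_trace` or numeric dF/F0 vector.
#' @param stim_onset,stim_offset 0-based half-open stimulus window.
#' @param n_frames frames per averaging window (default 10 = 1 s).
#' @export
magnitude_sensory <- function(trace, stim_onset, stim_offset, n_frames = 10L) {
  x <- if (inherits(trace, "normalized_trace")) trace$dff else as.numeric(trace)
  if (stim_onset < n_frames || stim_offset - stim_onset < n_frames ||
      stim_offset > length(x))
    stop("averaging windows unavailable", call. = FALSE)
  mean(x[(stim_offset - n_frames + 1L):stim_offset]) -
    mean(x[(stim_onset - n_frames + 1L):stim_onset])
}

#' Peak response magnitude
#'
#' Maximum dF/F0 within the stimulus pulse; used for neurons whose
#' responses adapt during the pulse, where the end-of-pulse mean would
#' understate the response.
#'
#' @inheritParams magnitude_sensory
#' @export
magnitude_peak <- function(trace, stim_onset, stim_offset) {
  x <- if (inherits(trace, "normalized_trace")) trace$dff else as.numeric(trace)
  if (stim_offset > length(x))
    stop("stimulus window outside trace", call. = FALSE)
  max(x[(stim_onset + 1L):stim_offset])
}

#' 33%-to-66% rise time of a called response
#'
#' Time between the first frames at or after the onset at which the dF/F0
#' reaches 33% and 66% of the within-pulse peak. Defined only for
#' responders with a positive peak; always non-negative.
#'
#' @param trace a `normalized_trace` or numeric dF/F0 vector.
#' @param call the `response_call` carrying the onset frame.
#' @param stim_onset,stim_offset 0-based half-open stimulus window.
#' @param frame_rate frames per second.
#' @return rise time in seconds.
#' @export
rise_time <- function(trace, call, stim_onset, stim_offset, frame_rate = 10) {
  if (!isTRUE(call$responded))
    stop("rise time is undefined for non-responders", call. = FALSE)
  x <- if (inherits(trace, "normalized_trace")) trace$dff else as.numeric(trace)
  peak <- magnitude_peak(x, stim_onset, stim_offset)
  if (peak <= 0)
    stop("rise time requires a positive peak magnitude", call. = FALSE)
  scan <- (call$onset_frame + 1L):stim_offset       # 1-based from onset
  first_cross <- function(q) {
    hit <- which(x[scan] >= q * peak - 1e-12)
    if (length(hit) == 0L) NA_integer_ else scan[hit[1]] - 1L   # 0-based
  }
  t33 <- first_cross(0.33)
  t66 <- first_cross(0.66)
  if (is.na(t33) || is.na(t66))
    stop("trace never crosses the rise-time thresholds within the pulse",
         call. = FALSE)
  (t66 - t33) / frame_rate
}

#' Pulse-pair reliability and correlation statistics
#'
#' Animals received two stimulus pulses; this tabulates the 2x2 contingency
#' of responding to pulse 1 by responding to pulse 2 across animals with
#' one analyzable trace per pulse, and, among double responders, Pearson
#' correlations of magnitudes and of latencies between the pulses.
#'
#' @param calls data frame from [detect_ensemble()] with `animal`, `pulse`,
#'   `responded`, `magnitude`, `latency_s`.
#' @return an object of class `pulse_pair_stats` with the `contingency`
#'   matrix, `n_pairs`, `cor_magnitude`, `cor_latency`.
#' @export
pulse_pair_stats <- function(calls) {
  df <- calls[!is.na(calls$responded), , drop = FALSE]
  pairs <- lapply(split(df, df$animal), function(d) {
    p1 <- d[d$pulse == 1L, , drop = FALSE]
    p2 <- d[d$pulse == 2L, , drop = FALSE]
    if (nrow(p1) != 1L || nrow(p2) != 1L) return(NULL)
    data.frame(r1 = p1$responded, r2 = p2$responded,
               m1 = p1$magnitude, m2 = p2$magnitude,
               l1 = p1$latency_s, l2 = p2$latency_s)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no animals with exactly one trace per pulse", call. = FALSE)
  tab <- matrix(c(sum(pairs$r1 & pairs$r2), sum(pairs$r1 & !pairs$r2),
                  sum(!pairs$r1 & pairs$r2), sum(!pairs$r1 & !pairs$r2)),
                2L, 2L, byrow = TRUE,
                dimnames = list(pulse1 = c("responded", "no_response"),
                                pulse2 = c("responded", "no_response")))
  dbl <- pairs[pairs$r1 & pairs$r2, , drop = FALSE]
  safe_cor <- function(u, v) {
    if (nrow(dbl) < 3L || stats::sd(u) == 0 || stats::sd(v) == 0)
      return(NA_real_)
    stats::cor(u, v)
  }
  structure(list(contingency = tab, n_pairs = nrow(pairs),
                 cor_magnitude = if (nrow(dbl) >= 3L)
                   safe_cor(dbl$m1, dbl$m2) else NA_real_,
                 cor_latency = if (nrow(dbl) >= 3L)
                   safe_cor(dbl$l1, dbl$l2) else NA_real_),
            class = "pulse_pair_stats")
}

#' @export
print.pulse_pair_stats <- function(x, ...) {
  cat("<pulse_pair_stats> ", x$n_pairs, " animal pulse pairs\n", sep = "")
  print(x$contingency)
  cat("double-responder correlations: magnitude ",
      signif(x$cor_magnitude, 3), ", latency ", signif(x$cor_latency, 3),
      "\n", sep = "")
  invisible(x)
}
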