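#' Normalize a raw fluorescence trace to dF/F0
#'
#' The baseline F0 is the median raw fluorescence over the `prestim_window`
#' frames immediately preceding stimulus onset (100 frames = 10 s at the
#' 10 fps acquisition convention), and
#' `dff[t] = (raw[t] - F0) / F0`.
#'
#' @param raw numeric vector of raw fluorescence (one trace).
#' @param stim_onset 0-based frame index of stimulus onset; the baseline
#'   window is the `prestim_window` frames before it.
#' @param prestim_window number of baseline frames (default 100).
#' @return an object of class `normalized_trace` with elements `dff`, `f0`,
#'   `smoothed` (FALSE) and `prestim_window`.
#' @export
compute_dff <- function(raw, stim_onset, prestim_window = 100) {
  raw <- as.numeric(raw)
  stim_onset <- as.integer(stim_onset)
  if (prestim_window < 1L || stim_onset < prestim_window)
    stop("need `prestim_window` (= ", prestim_window,
         ") frames before stimulus onset (frame ", stim_onset, ")",
         call. = FALSE)
  base_idx <- (stim_onset - prestim_window + 1L):stim_onset  # 1-based
  f0 <- stats::median(raw[base_idx])
  if (!is.finite(f0) || f0 == 0)
    stop("degenerate baseline: F0 is ", f0, call. = FALSE)
  structure(list(dff = (raw - f0) / f0, f0 = f0, smoothed = FALSE,
                 prestim_window = as.integer(prestim_window)),
            class = "normalized_trace")
}

#' Five-frame boxcar smoothing
#'
#' Each frame becomes the mean of frames t-2 through t+2. At the trace
#' boundaries the window is truncated to the available frames, so the
#' output always has the input's length.
#'
#' @param x numeric vector or `normalized_trace`.
#' @param half_width half window width in frames (default 2, i.e. a
#'   5-frame window).
#' @return same type as the input; a `normalized_trace` comes back with
#'   `smoothed = TRUE`.
#' @export
smooth_trace <- function(x, half_width = 2L) {
  if (inherits(x, "normalized_trace")) {
    x$dff <- smooth_trace(x$dff, half_width)
    x$smoothed <- TRUE
    return(x)
  }
  n <- length(x)
  if (n == 0L) return(x)
  h <- as.integer(half_width)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min-max scale a trace to [0, 1]
#'
#' Used before inhibition calling: the trace is affinely mapped so its
#' minimum over `scale_window` is 0 and its maximum is 1 (dF/Fmax units).
#' Because the map is affine, scaling the raw trace and scaling its dF/F0
#' give identical results.
#'
#' @param x numeric vector or `normalized_trace`.
#' @param scale_window optional 0-based half-open frame range
#'   `c(from, to)` over which the min and max are taken; default is the
#'   full trace.
#' @return an object of class `scaled_trace` with elements `scaled`,
#'   `scale_window`, `min` and `max`.
#' @export
minmax_scale <- function(x, scale_window = NULL) {
  v <- if (inherits(x, "normalized_trace")) x$dff else as.numeric(x)
  n <- length(v)
  if (is.null(scale_window)) scale_window <- c(0L, n)
  idx <- (scale_window[1] + 1L):scale_window[2]
  if (scale_window[1] < 0 || scale_window[2] > n || length(idx) < 1L)
    stop("`scale_window` outside trace", call. = FALSE)
  lo <- min(v[idx]); hi <- max(v[idx])
  if (hi <= lo)
    stop("degenerate scale: trace is constant over the scale window",
         call. = FALSE)
  structure(list(scaled = (v - lo) / (hi - lo),
                 scale_window = as.integer(scale_window),
                 min = lo, max = hi),
            class = "scaled_trace")
}

#' Linear photobleaching correction
#'
#' Fits a least-squares line to the frames outside every stimulus window,
#' then returns `(trace - line) / line`: the corrected trace is a dF/F
#' signal whose baseline drift has been removed. Used for recordings under
#' constant illumination, where bleaching is appreciable and approximately
#' linear.
#'
#' @param x numeric vector of raw fluorescence.
#' @param stim_windows list of 0-based half-open frame ranges
#'   `c(from, to)` to exclude from the fit (may be empty).
#' @return numeric vector, same length as `x`.
#' @export
bleach_correct <- function(x, stim_windows = list()) {
  x <- as.numeric(x)
  n <- length(x)
  keep <- rep(TRUE, n)
  for (w in stim_windows) {
    if (w[1] < 0 || w[2] > n || w[2] <= w[1])
      stop("invalid stimulus window [", w[1], ", ", w[2], ")", call. = FALSE)
    keep[(w[1] + 1L):w[2]] <- FALSE
  }
  if (sum(keep) < 2L)
    stop("need at least 2 non-stimulus frames to fit the bleach line",
         call. = FALSE)
  t_all <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t_all[keep]), x[keep])
  line <- cbind(1, t_all) %*% fit$coefficients
  line <- as.numeric(line)
  if (any(line <= 0))
    stop("degenerate bleach fit: fitted line is non-positive", call. = FALSE)
  (x - line) / line
}
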