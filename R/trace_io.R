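#' Construct a trace ensemble
#'
#' A trace ensemble bundles a set of per-pulse raw fluorescence traces with
#' the acquisition metadata the downstream analysis needs. One matrix row is
#' one stimulus pulse; columns are frames. Frame indices in the metadata are
#' 0-based, so `stim_onset` equals the number of pre-stimulus frames and the
#' stimulus occupies the half-open frame window `[stim_onset, stim_offset)`.
#'
#' Traces containing any non-finite value (NaN, NA, Inf) are flagged as
#' excluded and skipped by every analysis step; their rows and metadata are
#' retained so that pulse numbering is never disturbed.
#'
#' @param traces numeric matrix of raw fluorescence, one row per pulse.
#' @param frame_rate frames per second (default 10).
#' @param stim_onset 0-based frame index of stimulus onset.
#' @param stim_offset 0-based frame index one past the last stimulus frame.
#' @param meta data frame with one row per trace and columns `neuron`,
#'   `condition`, `animal`, `pulse` (1 or 2) and `block`. Missing columns
#'   are filled with defaults.
#' @param excluded optional logical vector of manual exclusions; traces with
#'   non-finite values are excluded regardless.
#' @return an object of class `trace_ensemble`.
#' @export
trace_ensemble <- function(traces, frame_rate = 10, stim_onset, stim_offset,
                           meta = NULL, excluded = NULL) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  n <- nrow(traces)
  len <- ncol(traces)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar", call. = FALSE)
  stim_onset <- as.integer(stim_onset)
  stim_offset <- as.integer(stim_offset)
  if (stim_onset < 0L)
    stop("`stim_onset` must be >= 0", call. = FALSE)
  if (stim_offset <= stim_onset)
    stop("`stim_offset` must exceed `stim_onset`", call. = FALSE)
  if (n > 0L && stim_offset > len)
    stop("stimulus window [", stim_onset, ", ", stim_offset,
         ") lies outside the ", len, "-frame traces", call. = FALSE)
  meta <- .complete_meta(meta, n)
  if (!all(meta$pulse %in% c(1L, 2L)))
    stop("`pulse` must be 1 or 2", call. = FALSE)
  nonfinite <- if (n > 0L) apply(traces, 1L, function(r) any(!is.finite(r)))
               else logical(0)
  if (is.null(excluded)) excluded <- logical(n)
  if (length(excluded) != n)
    stop("`excluded` must have one entry per trace", call. = FALSE)
  structure(
    list(traces = traces, frame_rate = frame_rate,
         stim_onset = stim_onset, stim_offset = stim_offset,
         meta = meta, excluded = as.logical(excluded) | nonfinite),
    class = "trace_ensemble")
}

.complete_meta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(max(n, 0L)))[seq_len(n), , drop = FALSE]
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows but there are ", n, " traces",
         call. = FALSE)
  defaults <- list(neuron = "unknown", condition = "unknown",
                   animal = seq_len(n), pulse = 1L, block = 1L)
  for (col in names(defaults)) {
    if (is.null(meta[[col]])) meta[[col]] <- rep_len(defaults[[col]], n)
  }
  meta$pulse <- as.integer(meta$pulse)
  rownames(meta) <- NULL
  meta[, c("neuron", "condition", "animal", "pulse", "block"), drop = FALSE]
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cat("<trace_ensemble> ", nrow(x$traces), " traces x ", ncol(x$traces),
      " frames @ ", x$frame_rate, " fps\n", sep = "")
  cat("  stimulus frames [", x$stim_onset, ", ", x$stim_offset, ") = ",
      (x$stim_offset - x$stim_onset) / x$frame_rate, " s\n", sep = "")
  cat("  excluded (non-finite or flagged): ", sum(x$excluded), "\n", sep = "")
  invisible(x)
}

#' Number of traces in an ensemble
#' @param x a `trace_ensemble`.
#' @export
n_traces <- function(x) nrow(x$traces)

#' Indices of traces usable for analysis
#' @param x a `trace_ensemble`.
#' @return integer vector of row indices with `excluded == FALSE`.
#' @export
included_traces <- function(x) which(!x$excluded)

#' Read a trace ensemble from disk
#'
#' The on-disk format is a purely numeric CSV of traces (rows = pulses,
#' columns = frames, no header) plus a YAML sidecar `<path>.meta.yaml`
#' holding `frame_rate`, `stim_onset`, `stim_offset` and a per-row `rows`
#' table with the trace metadata.
#'
#' @param path path to the trace CSV.
#' @param sidecar path to the metadata sidecar; defaults to
#'   `paste0(path, ".meta.yaml")`.
#' @return a validated [trace_ensemble()]. Rows containing non-finite values
#'   are flagged excluded, never dropped, so row order and metadata pairing
#'   are preserved.
#' @export
read_ensemble <- function(path, sidecar = paste0(path, ".meta.yaml")) {
  if (!file.exists(path))
    stop("trace file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  side <- yaml::read_yaml(sidecar)
  for (field in c("frame_rate", "stim_onset", "stim_offset"))
    if (is.null(side[[field]]))
      stop("sidecar is missing `", field, "`", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    traces <- matrix(numeric(0), nrow = 0L, ncol = side$n_frames %||% 0L)
  } else {
    vals <- lapply(strsplit(lines, ",", fixed = TRUE),
                   function(v) suppressWarnings(as.numeric(v)))
    if (length(unique(lengths(vals))) != 1L)
      stop("trace rows have unequal frame counts", call. = FALSE)
    traces <- do.call(rbind, vals)
    dimnames(traces) <- NULL
  }
  rows <- side$rows
  meta <- NULL
  excluded <- NULL
  if (!is.null(rows) && length(rows) > 0L) {
    meta <- do.call(rbind, lapply(rows, function(r)
      data.frame(neuron = r$neuron %||% "unknown",
                 condition = r$condition %||% "unknown",
                 animal = r$animal %||% NA,
                 pulse = r$pulse %||% 1L,
                 block = r$block %||% 1L,
                 stringsAsFactors = FALSE)))
    if (is.null(meta) || nrow(meta) != nrow(traces))
      stop("sidecar lists ", length(rows), " rows but trace file has ",
           nrow(traces), call. = FALSE)
    excluded <- vapply(rows, function(r) isTRUE(r$excluded), logical(1))
  }
  trace_ensemble(traces, frame_rate = side$frame_rate,
                 stim_onset = side$stim_onset, stim_offset = side$stim_offset,
                 meta = meta, excluded = excluded)
}

#' Write a trace ensemble to disk
#'
#' Inverse of [read_ensemble()]: values are serialized as decimal text with
#' 17 significant digits, so a read/write round trip reproduces every double
#' bit-exactly. Exclusion flags are persisted in the sidecar.
#'
#' @param x a `trace_ensemble`.
#' @param path destination CSV path; the sidecar is written to
#'   `paste0(path, ".meta.yaml")`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  stopifnot(inherits(x, "trace_ensemble"))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.nan(v)] <- "NaN"
    out[is.na(v) & !is.nan(v)] <- "NA"
    out[is.infinite(v) & v > 0] <- "Inf"
    out[is.infinite(v) & v < 0] <- "-Inf"
    out
  }
  lines <- apply(x$traces, 1L, function(r) paste(fmt(r), collapse = ","))
  ok <- tryCatch({ writeLines(as.character(lines), path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  rows <- lapply(seq_len(nrow(x$traces)), function(i)
    list(neuron = x$meta$neuron[i], condition = x$meta$condition[i],
         animal = x$meta$animal[i], pulse = x$meta$pulse[i],
         block = x$meta$block[i], excluded = x$excluded[i]))
  side <- list(frame_rate = x$frame_rate, stim_onset = x$stim_onset,
               stim_offset = x$stim_offset, n_frames = ncol(x$traces),
               rows = rows)
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
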