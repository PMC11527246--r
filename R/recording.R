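#' Continuous multichannel recording
#'
#' An `esg_recording` holds a continuous multichannel signal (channels x
#' samples, microvolts), its sampling rate, per-channel metadata, the label of
#' the recording reference, and stimulus/event markers. It is the common
#' currency of all preprocessing stages.
#'
#' Sample indexing is 0-based throughout the package: an event at sample 0
#' occurred at the first stored sample. This matches how marker positions are
#' stored on disk and keeps index arithmetic under resampling exact.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channels data.frame with columns `label`, `role` (one of
#'   `"esg"`, `"eeg"`, `"ecg"`, `"eng"`, `"other"`), `patch` (one of
#'   `"cervical"`, `"lumbar"`, `"none"`), and optional `x_cm`, `y_cm` grid
#'   coordinates for grid electrodes.
#' @param reference label of the recording reference electrode.
#' @param events data.frame with columns `sample` (0-based index) and `code`
#'   (character); may have zero rows.
#'
#' @return an object of class `esg_recording`.
#' @export
new_recording <- function(data, fs, channels, reference = "REF",
                          events = data.frame(sample = integer(0),
                                              code = character(0))) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (!all(c("label", "role") %in% names(channels)))
    stop("`channels` needs at least columns `label` and `role`")
  if (is.null(channels$patch)) channels$patch <- "none"
  if (nrow(channels) != nrow(data))
    stop("channel table has ", nrow(channels), " rows but data has ",
         nrow(data), " channels")
  if (anyDuplicated(channels$label))
    stop("channel labels must be unique")
  bad_role <- setdiff(unique(channels$role),
                      c("esg", "eeg", "ecg", "eng", "other"))
  if (length(bad_role))
    stop("unknown channel role(s): ", paste(bad_role, collapse = ", "))
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording data contains undefined values")
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    if (!all(c("sample", "code") %in% names(events)))
      stop("`events` needs columns `sample` and `code`")
    if (any(events$sample < 0 | events$sample >= ncol(data)))
      stop("event sample indices must lie in [0, n_samples)")
    events$sample <- as.integer(round(events$sample))
    events$code <- as.character(events$code)
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(data = data, fs = fs, channels = channels,
                 reference = reference, events = events),
            class = "esg_recording")
}

#' @export
print.esg_recording <- function(x, ...) {
  cat("<esg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      sprintf("%.1f", ncol(x$data) / x$fs), " s)\n", sep = "")
  cat("  reference: ", x$reference, "; events: ", nrow(x$events), "\n",
      sep = "")
  roles <- table(x$channels$role)
  cat("  roles: ", paste(names(roles), roles, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param rec an `esg_recording`.
#' @return integer count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Locate channels by label, role, or patch
#'
#' @param rec an `esg_recording`.
#' @param labels character vector of channel labels (exact match).
#' @param role,patch optional filters applied instead of `labels`.
#' @return integer row indices into `rec$channels`.
#' @export
channel_idx <- function(rec, labels = NULL, role = NULL, patch = NULL) {
  ch <- rec$channels
  if (!is.null(labels)) {
    idx <- match(labels, ch$label)
    if (anyNA(idx))
      stop("unknown channel label(s): ",
           paste(labels[is.na(idx)], collapse = ", "))
    return(idx)
  }
  keep <- rep(TRUE, nrow(ch))
  if (!is.null(role)) keep <- keep & ch$role %in% role
  if (!is.null(patch)) keep <- keep & ch$patch %in% patch
  which(keep)
}

#' Event sample indices of a recording
#' @param rec an `esg_recording`.
#' @param code optional event code filter.
#' @return integer vector of 0-based sample indices.
#' @export
event_samples <- function(rec, code = NULL) {
  ev <- rec$events
  if (!is.null(code)) ev <- ev[ev$code %in% code, , drop = FALSE]
  ev$sample
}

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))
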