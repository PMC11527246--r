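#' Read a BrainVision recording
#'
#' Parses a BrainVision header/marker/data triplet (`.vhdr`, `.vmrk`, `.eeg`)
#' into an [new_recording()] object. Binary payloads must be multiplexed IEEE
#' float32 (the format this package writes); the per-channel resolution line
#' and unit are respected and all data are returned in microvolts. Marker
#' positions, which are 1-based on disk, are converted to the package's
#' 0-based sample indices.
#'
#' Channel roles are not part of the BrainVision format. They are taken from
#' (in order of precedence) the `channel_map` argument, a sidecar
#' `<base>_channels.tsv` written by [write_recording()], or default to
#' `"other"`.
#'
#' @param path path to a `.vhdr` header, or a directory containing exactly
#'   one (a minimal BIDS-style layout).
#' @param channel_map optional data.frame with columns `label`, `role`, and
#'   optionally `patch`, `x_cm`, `y_cm`.
#' @return an `esg_recording`.
#' @export
read_recording <- function(path, channel_map = NULL) {
  if (dir.exists(path)) {
    hdrs <- list.files(path, pattern = "\\.vhdr$", recursive = TRUE,
                       full.names = TRUE)
    if (length(hdrs) != 1L)
      stop("expected exactly one .vhdr under ", path, ", found ",
           length(hdrs))
    path <- hdrs
  }
  if (!file.exists(path)) stop("no such header file: ", path)
  hdr <- readLines(path, warn = FALSE)
  base_dir <- dirname(path)
  get_kv <- function(lines, key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  data_file <- file.path(base_dir, get_kv(hdr, "DataFile"))
  marker_file <- file.path(base_dir, get_kv(hdr, "MarkerFile"))
  if (!file.exists(data_file))
    stop("missing sibling data file: ", data_file)
  if (!file.exists(marker_file))
    stop("missing sibling marker file: ", marker_file)
  if (toupper(get_kv(hdr, "DataFormat")) != "BINARY" ||
      toupper(get_kv(hdr, "DataOrientation")) != "MULTIPLEXED")
    stop("only BINARY MULTIPLEXED BrainVision data are supported")
  if (toupper(get_kv(hdr, "BinaryFormat")) != "IEEE_FLOAT_32")
    stop("only IEEE_FLOAT_32 payloads are supported")
  n_ch <- as.integer(get_kv(hdr, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_kv(hdr, "SamplingInterval"))

  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  if (length(ch_lines) != n_ch)
    stop("header lists ", length(ch_lines), " channels but declares ", n_ch)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(parts, `[`, "", 1L)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  unit <- vapply(parts, function(p)
    if (length(p) >= 4 && nzchar(p[4])) p[4] else "µV", "")
  scale <- vapply(unit, function(u) switch(u,
    "µV" = 1, "uV" = 1, "mV" = 1e3, "V" = 1e6,
    stop("unknown unit in header: ", u)), 0)

  raw <- readBin(data_file, "numeric", size = 4,
                 n = file.size(data_file) / 4, endian = "little")
  if (length(raw) %% n_ch != 0)
    stop("data payload size is not a multiple of the channel count")
  data <- matrix(raw, nrow = n_ch) * (res * scale)

  mk <- readLines(marker_file, warn = FALSE)
  mk_lines <- grep("^Mk[0-9]+=", mk, value = TRUE)
  events <- data.frame(sample = integer(0), code = character(0))
  if (length(mk_lines)) {
    mp <- strsplit(sub("^Mk[0-9]+=", "", mk_lines), ",", fixed = TRUE)
    type <- vapply(mp, `[`, "", 1L)
    desc <- vapply(mp, `[`, "", 2L)
    pos <- vapply(mp, function(p) as.integer(p[3]), 0L)
    keep <- type != "New Segment"
    events <- data.frame(sample = pos[keep] - 1L, code = desc[keep],
                         stringsAsFactors = FALSE)
  }

  chtab <- data.frame(label = labels, role = "other", patch = "none",
                      x_cm = NA_real_, y_cm = NA_real_,
                      stringsAsFactors = FALSE)
  sidecar <- sub("\\.vhdr$", "_channels.tsv", path)
  if (is.null(channel_map) && file.exists(sidecar))
    channel_map <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  reference <- "REF"
  if (!is.null(channel_map)) {
    i <- match(chtab$label, channel_map$label)
    for (col in intersect(c("role", "patch", "x_cm", "y_cm"),
                          names(channel_map)))
      chtab[[col]][!is.na(i)] <- channel_map[[col]][i[!is.na(i)]]
    if (!is.null(channel_map$reference))
      reference <- channel_map$reference[1]
  }
  new_recording(data, fs, chtab, reference = reference, events = events)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<base>.vhdr`, `<base>.vmrk`, and `<base>.eeg` (multiplexed IEEE
#' float32, microvolts, resolution 1) plus a `<base>_channels.tsv` sidecar
#' carrying the channel roles, patch membership, grid coordinates, and
#' reference label, so that [read_recording()] round-trips the object.
#'
#' @param rec an `esg_recording`.
#' @param base path without extension; directories are created as needed.
#' @return `base`, invisibly.
#' @export
write_recording <- function(rec, base) {
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  stem <- basename(base)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_channels(rec)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    paste0("Ch", seq_len(n_channels(rec)), "=",
           rec$channels$label, ",,1,µV"))
  writeLines(hdr, paste0(base, ".vhdr"))

  ev <- rec$events
  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0")
  if (nrow(ev))
    mk <- c(mk, paste0("Mk", seq_len(nrow(ev)) + 1L, "=Stimulus,", ev$code,
                       ",", ev$sample + 1L, ",1,0"))
  writeLines(mk, paste0(base, ".vmrk"))

  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")

  side <- rec$channels
  side$reference <- rec$reference
  utils::write.table(side, paste0(base, "_channels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(base)
}
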