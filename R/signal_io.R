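#' Read a multi-channel EEG recording from EDF or CSV
#'
#' Reads the file, checks that every montage label is present, and returns
#' the channels reordered to match the montage exactly (extra channels in
#' the file are dropped). For EDF the sampling rate comes from the file
#' header; for CSV it must be supplied, since CSV carries no metadata.
#'
#' The CSV dialect is one column per channel with a header row of channel
#' labels and one sample per line.
#'
#' @param path path to the file.
#' @param format `"edf"` or `"csv"`; default guessed from the extension.
#' @param montage ordered channel labels to extract.
#' @param fs sampling rate in Hz, required for CSV, ignored for EDF.
#' @param subject_id,label metadata attached to the returned recording;
#'   `subject_id` defaults to the file name.
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("edf", "csv"),
                           montage = DEFAULT_MONTAGE, fs = NULL,
                           subject_id = NULL, label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  if (format == "edf") {
    edf <- read_edf(path)
    missing_ch <- setdiff(montage, edf$channel_names)
    if (length(missing_ch))
      stop("montage channel(s) absent from EDF file: ",
           paste(missing_ch, collapse = ", "))
    sel <- match(montage, edf$channel_names)
    fs_ch <- edf$fs[sel]
    if (length(unique(fs_ch)) != 1)
      stop("format error: montage channels have inconsistent sampling rates (",
           paste(unique(fs_ch), collapse = ", "), " Hz)")
    recording(edf$data[sel, , drop = FALSE], fs = fs_ch[1],
              channel_names = montage, subject_id = subject_id, label = label)
  } else {
    if (is.null(fs)) stop("fs must be supplied for CSV input")
    tab <- utils::read.csv(path, check.names = FALSE)
    missing_ch <- setdiff(montage, names(tab))
    if (length(missing_ch))
      stop("montage channel(s) absent from CSV file: ",
           paste(missing_ch, collapse = ", "))
    data <- t(as.matrix(tab[, montage, drop = FALSE]))
    recording(data, fs = fs, channel_names = montage,
              subject_id = subject_id, label = label)
  }
}

# --- minimal EDF (European Data Format) codec -------------------------------
# EDF is a fixed-width ASCII header (256 bytes + 256 per signal) followed by
# data records of little-endian int16 samples, scaled per channel from
# digital to physical units. Only the subset needed for continuous
# multi-channel recordings is implemented.

edf_field <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Read an EDF file
#'
#' Parses the header and all data records, returning physical-unit signals.
#' Signals with differing per-record sample counts are returned at their
#' own rates; channel selection against a montage is done by
#' [read_recording()].
#'
#' @param path path to an EDF file.
#' @return List with `data` (channels x samples matrix, channels padded
#'   with `NA` up to the longest signal if rates differ), `fs` (per-channel
#'   sampling rate vector) and `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(edf_field(con, 80))  # patient id
  invisible(edf_field(con, 80))  # recording id
  invisible(edf_field(con, 8))   # start date
  invisible(edf_field(con, 8))   # start time
  header_bytes <- as.integer(edf_field(con, 8))
  invisible(edf_field(con, 44))  # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header corrupt: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w), "")
  labels <- fld(16)
  invisible(fld(80))            # transducer
  invisible(fld(8))             # physical dimension
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  invisible(fld(80))            # prefiltering
  spr <- as.integer(fld(8))     # samples per record
  invisible(fld(32))            # reserved
  seek(con, header_bytes)
  samples <- vector("list", ns)
  for (i in seq_len(ns)) samples[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      samples[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                                   signed = TRUE, endian = "little")
    }
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  sigs <- lapply(seq_len(ns), function(i) {
    dig <- unlist(samples[[i]])
    (dig - dmin[i]) * scale[i] + pmin[i]
  })
  len <- vapply(sigs, length, integer(1))
  data <- matrix(NA_real_, ns, max(len))
  for (i in seq_len(ns)) data[i, seq_len(len[i])] <- sigs[[i]]
  rownames(data) <- labels
  list(data = data, fs = spr / record_dur, channel_names = labels)
}

#' Write a recording to EDF
#'
#' Serialises a recording as a single-data-record EDF file, with
#' per-channel physical scaling chosen from the data range. Quantisation
#' to 16-bit limits round-trip fidelity to about
#' `diff(range(channel)) / 65535` per channel.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  L <- ncol(rec$data)
  pad <- function(x, w) {
    x <- as.character(x)
    if (nchar(x) > w) x <- substr(x, 1, w)
    formatC(x, width = -w)  # left-justified, space padded
  }
  num8 <- function(x) pad(formatC(x, digits = 6, format = "g"), 8)
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  pmin <- floor(pmin * 1000) / 1000   # keep 8-char fields exact enough
  pmax <- ceiling(pmax * 1000) / 1000
  dmin <- -32768; dmax <- 32767
  header_bytes <- 256 + 256 * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44)
  wr("1", 8)                               # one data record
  wr(formatC(L / rec$fs, format = "g", digits = 7), 8)
  wr(ns, 4)
  for (lab in rec$channel_names) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(num8(pmin[i]), 8)
  for (i in seq_len(ns)) wr(num8(pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(L, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a recording as CSV
#'
#' One column per channel, header row of channel labels, one sample per
#' line — the package's CSV dialect for metadata-free interchange.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$channel_names
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
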