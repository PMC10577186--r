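#' Write a recording as a plain-text matrix file
#'
#' The fixture format is a small self-describing text format: three header
#' lines (`# n_channels:`, `# sampling_rate:`, `# channels:`) followed by a
#' whitespace-separated body of samples x channels values printed with full
#' double precision, so a write/read round trip is bit-exact.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_channels: %d", n_channels(rec)),
    sprintf("# sampling_rate: %.17g", rec$sampling_rate),
    paste("# channels:", paste(rec$channel_labels, collapse = " "))
  ), con)
  body <- apply(t(rec$data), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a recording from the plain-text matrix format
#'
#' @param path File written by [write_eeg_matrix()].
#' @return An [eeg_recording()].
#' @export
read_eeg_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1L], "# n_channels:")) {
    stop("not a recognisable EEG matrix file: ", path, call. = FALSE)
  }
  nch <- as.integer(sub("# n_channels:", "", lines[1L]))
  fs <- as.numeric(sub("# sampling_rate:", "", lines[2L]))
  labels <- strsplit(trimws(sub("# channels:", "", lines[3L])), "\\s+")[[1L]]
  if (length(labels) != nch) stop("corrupt header: channel label count mismatch", call. = FALSE)
  body <- lines[-(1:3)]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) %% nch != 0L) stop("corrupt body: not a multiple of n_channels", call. = FALSE)
  data <- t(matrix(vals, ncol = nch, byrow = TRUE))
  eeg_recording(data, fs, labels)
}

# --- Minimal EDF (European Data Format) support -----------------------------
#
# 16-bit EDF with one data record spanning the whole recording. Physical
# scaling is symmetric around zero, so amplitudes survive a round trip up to
# the 16-bit quantization step. Written from scratch against the published
# EDF field layout (256-byte fixed header + 256 bytes per signal).

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording as an EDF file
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- n_channels(rec)
  nsamp <- n_samples(rec)
  dur <- nsamp / rec$sampling_rate
  phys_max <- max(abs(rec$data))
  if (phys_max == 0) phys_max <- 1
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("X X X X", 80L),                       # patient id (anonymous)
    edf_pad("Startdate 01-JAN-2020 X X X", 80L),   # recording id
    edf_pad("01.01.20", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L),
    edf_pad("", 44L),
    edf_pad(1L, 8L),                               # one data record
    edf_pad(format(dur, digits = 7), 8L),
    edf_pad(ns, 4L)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels, edf_pad, "", width = 16L), collapse = ""),
    strrep(edf_pad("", 80L), ns),                  # transducer
    strrep(edf_pad("uV", 8L), ns),
    strrep(edf_pad(format(-phys_max, digits = 7), 8L), ns),
    strrep(edf_pad(format(phys_max, digits = 7), 8L), ns),
    strrep(edf_pad(-dig_max, 8L), ns),
    strrep(edf_pad(dig_max, 8L), ns),
    strrep(edf_pad("", 80L), ns),                  # prefiltering
    strrep(edf_pad(nsamp, 8L), ns),
    strrep(edf_pad("", 32L), ns)
  )
  writeBin(charToRaw(paste0(hdr, sig)), con)
  scale <- dig_max / phys_max
  for (ch in seq_len(ns)) {
    dig <- as.integer(pmax(pmin(round(rec$data[ch, ] * scale), dig_max), -dig_max))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports uniformly sampled 16-bit EDF. Channels keep file order; the
#' sampling rate is derived from the record duration and samples-per-record
#' fields.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- as.integer(fld(fixed, 237L, 8L))
  rec_dur <- as.numeric(fld(fixed, 245L, 8L))
  ns <- as.integer(fld(fixed, 253L, 4L))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count", call. = FALSE)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  take <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset + (i - 1L) * width + 1L,
                    offset + i * width)), "")
  }
  labels <- take(0L, 16L)
  phys_min <- as.numeric(take(ns * (16L + 80L + 8L), 8L))
  phys_max <- as.numeric(take(ns * (16L + 80L + 8L + 8L), 8L))
  dig_min <- as.numeric(take(ns * (16L + 80L + 8L * 3L), 8L))
  dig_max <- as.numeric(take(ns * (16L + 80L + 8L * 4L), 8L))
  spr <- as.integer(take(ns * (16L + 80L + 8L * 5L + 80L), 8L))
  if (length(unique(round(spr / rec_dur, 6L))) != 1L) {
    stop("non-uniform sampling across EDF signals is not supported", call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  data <- matrix(0, nrow = ns, ncol = spr[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, endian = "little")
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <-
        phys_min[ch] + (dig - dig_min[ch]) * gain
    }
  }
  eeg_recording(data, fs, labels)
}

#' Read a recording from disk
#'
#' Dispatches on `format` (or the file extension when `"auto"`): `.edf`
#' files go through [read_edf()], anything else through [read_eeg_matrix()].
#' When all 19 labels of the 10-20 montage are present, channels are
#' reordered to the canonical montage order of [montage_1020()].
#'
#' @param path File path.
#' @param format One of `"auto"`, `"edf"`, `"matrix"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  rec <- switch(format, edf = read_edf(path), matrix = read_eeg_matrix(path))
  canon <- montage_1020()$label
  if (n_channels(rec) == 19L && all(canon %in% toupper(rec$channel_labels))) {
    idx <- match(canon, toupper(rec$channel_labels))
    rec <- eeg_recording(rec$data[idx, , drop = FALSE], rec$sampling_rate,
                         canon, rec$reference)
  }
  rec
}
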