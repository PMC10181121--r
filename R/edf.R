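# Minimal EDF/EDF+ reader and writer: 256-byte ASCII header, one 256-byte
# block per signal, data records of 16-bit little-endian integers scaled by
# the declared physical/digital ranges.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

# EDF labels come with vendor decorations ("EEG Fc5.", trailing dots);
# normalize before matching against a montage.
normalize_label <- function(labels) {
  labels <- trimws(labels)
  labels <- sub("^EEG[ .]*", "", labels, ignore.case = TRUE)
  labels <- gsub("\\.+$", "", labels)
  toupper(labels)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Parses the EDF header, decodes the 16-bit samples of every signal whose
#' label matches a montage channel, and rescales them to physical units.
#' Non-matching signals (including EDF+ annotation channels) are dropped
#' with a warning. All matched signals must share one sampling rate.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param montage A [montage], a built-in montage name, or \code{NULL} to
#'   try the built-ins (\code{"emotiv14"}, then \code{"bci2000_64"}) and
#'   keep the first whose channels are all present.
#' @return An [eeg_recording] with \code{fs} taken from the header and the
#'   subject id from the local patient identification field (first token;
#'   file name if absent).
#' @export
read_edf <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  if (nchar(hdr) < 256L || substr(hdr, 1L, 1L) != "0")
    stop("unreadable EDF header: ", path)
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  patient <- field(9L, 80L)
  n_records <- as.integer(field(237L, 8L))
  rec_dur <- as.numeric(field(245L, 8L))
  ns <- as.integer(field(253L, 4L))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L)
    stop("unreadable EDF header: ", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfield <- function(block_from, len) {
    # signal header stores each field contiguously for all ns signals
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, block_from + (i - 1L) * len,
                    block_from + i * len - 1L)), "")
  }
  off <- 1L
  labels <- sfield(off, 16L); off <- off + 16L * ns
  off <- off + 80L * ns            # transducer
  off <- off + 8L * ns             # physical dimension
  phys_min <- as.numeric(sfield(off, 8L)); off <- off + 8L * ns
  phys_max <- as.numeric(sfield(off, 8L)); off <- off + 8L * ns
  dig_min <- as.numeric(sfield(off, 8L)); off <- off + 8L * ns
  dig_max <- as.numeric(sfield(off, 8L)); off <- off + 8L * ns
  off <- off + 80L * ns            # prefiltering
  spr <- as.integer(sfield(off, 8L))

  norm <- normalize_label(labels)
  if (is.null(montage)) {
    for (name in c("emotiv14", "bci2000_64")) {
      cand <- load_montage(name)
      if (all(toupper(cand$channels) %in% norm)) { montage <- cand; break }
    }
    if (is.null(montage))
      stop("no montage channels found in ", path)
  } else if (is.character(montage)) montage <- load_montage(montage)
  sel <- match(toupper(montage$channels), norm)
  if (all(is.na(sel))) stop("no montage channels found in ", path)
  if (anyNA(sel))
    stop("montage channels missing from EDF: ",
         paste(montage$channels[is.na(sel)], collapse = ", "))
  extra <- setdiff(seq_len(ns), sel)
  if (length(extra) > 0L)
    warning("dropping ", length(extra), " non-montage signal(s): ",
            paste(labels[extra], collapse = ", "))

  fs_all <- spr / rec_dur
  fs <- fs_all[sel[1]]
  if (any(fs_all[sel] != fs))
    stop("montage channels have differing sampling rates")

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, length(sel), n_records * spr[sel[1]])
  record_len <- sum(spr)
  starts <- c(0L, cumsum(spr))
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", record_len, size = 2L,
                   signed = TRUE, endian = "little")
    if (length(rec) < record_len) stop("truncated EDF data record")
    for (k in seq_along(sel)) {
      s <- sel[k]
      chunk <- rec[(starts[s] + 1L):starts[s + 1L]]
      data[k, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (chunk - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  subject <- strsplit(patient, "[[:space:]]+")[[1]][1]
  if (is.na(subject) || !nzchar(subject))
    subject <- sub("\\.[^.]*$", "", basename(path))
  eeg_recording(subject, montage, data, fs)
}

#' Write a recording to an EDF file
#'
#' Emits a standard-conformant EDF file with one-second data records.
#' Each channel is scaled to the full 16-bit digital range over a symmetric
#' physical range just covering its extrema, so the round-trip error is
#' bounded by physical_range / 2^15. A trailing partial second is
#' truncated.
#'
#' @param recording An [eeg_recording] with an integer sampling rate.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(fs)
  x <- recording$samples
  if (!all(is.finite(x))) stop("non-finite sample values")
  n_ch <- nrow(x)
  n_records <- floor(ncol(x) / fs)
  if (n_records < 1L) stop("recording shorter than one data record")
  x <- x[, seq_len(n_records * fs), drop = FALSE]

  pmax_ch <- pmax(apply(abs(x), 1L, max), 1e-6) * 1.01
  pmax_ch <- signif(pmax_ch, 6)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field(recording$subject_id, 80L),
    pad_field(paste("Startdate 01-JAN-2026", recording$montage$name), 80L),
    pad_field("01.01.26", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + n_ch), 8L),
    pad_field("", 44L),
    pad_field(n_records, 8L),
    pad_field(1L, 8L),
    pad_field(n_ch, 4L))
  sig <- paste0(
    paste(pad_field(rownames(x), 16L), collapse = ""),
    paste(pad_field(rep("", n_ch), 80L), collapse = ""),
    paste(pad_field(rep("uV", n_ch), 8L), collapse = ""),
    paste(pad_field(format(-pmax_ch, trim = TRUE, digits = 6), 8L),
          collapse = ""),
    paste(pad_field(format(pmax_ch, trim = TRUE, digits = 6), 8L),
          collapse = ""),
    paste(pad_field(rep(dig_min, n_ch), 8L), collapse = ""),
    paste(pad_field(rep(dig_max, n_ch), 8L), collapse = ""),
    paste(pad_field(rep("", n_ch), 80L), collapse = ""),
    paste(pad_field(rep(fs, n_ch), 8L), collapse = ""),
    paste(pad_field(rep("", n_ch), 32L), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  # re-read the printed physical ranges so writer and header agree exactly
  pmin_hdr <- as.numeric(format(-pmax_ch, trim = TRUE, digits = 6))
  pmax_hdr <- as.numeric(format(pmax_ch, trim = TRUE, digits = 6))
  gain <- (dig_max - dig_min) / (pmax_hdr - pmin_hdr)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in seq_len(n_ch)) {
      d <- round((x[k, cols] - pmin_hdr[k]) * gain[k] + dig_min)
      d <- pmin(pmax(d, dig_min), dig_max)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
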