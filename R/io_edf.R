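# Minimal EDF (European Data Format) writer/reader.
#
# EDF is the standard binary container for polysomnography exports: a 256-byte
# ASCII header, 256 ASCII bytes per signal, then data records of 16-bit
# little-endian integers mapped linearly between a digital and a physical
# range. No R EDF package ships in this environment, so the subset needed
# here (continuous 1-second data records, integer sampling rates) is
# implemented directly against the published format.
#
# Conventions of this dialect:
# * digital range -32767..32767 for data; -32768 is a sentinel marking
#   masked/invalid samples (EDF has no native missing-value encoding);
# * the 44-byte reserved header field carries "VW-NSAMP=<n>" so that a final
#   partial data record (zero-padded with sentinels) round-trips to the exact
#   original sample count;
# * fixed epoch date/time fields, keeping output byte-reproducible.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a PPG record as an EDF file
#'
#' Writes the PPG samples as one EDF signal channel (plus an `Accel` channel
#' when the record carries accelerometer magnitude). The sampling rate must
#' be a whole number of samples per second (1-second data records); other
#' rates raise a format error. Masked samples are stored at the digital
#' sentinel value and recovered as gaps by [read_edf_record()].
#'
#' @param record A [ppg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  fs <- record$sample_rate
  if (abs(fs - round(fs)) > 1e-9 || fs < 1)
    stop_vw("EDF dialect requires an integer sampling rate (got %g Hz)", fs,
            class = "vasowave_format_error")
  fs <- as.integer(round(fs))
  n <- length(record$samples)
  n_rec <- ceiling(n / fs)

  chans <- list(list(label = "PPG", dim = "au", values = {
    v <- record$samples; v[record$gap_mask] <- NA_real_; v
  }))
  if (!is.null(record$accel_magnitude))
    chans <- c(chans, list(list(label = "Accel", dim = "g",
                                values = record$accel_magnitude)))
  ns <- length(chans)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  wr(edf_pad("0", 8))
  wr(edf_pad(record$participant_id, 80))
  wr(edf_pad(paste("Startdate 01-JAN-2000", record$night_id, record$device_id), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (ns + 1L), 8))
  wr(edf_pad(sprintf("VW-NSAMP=%d", n), 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))

  ranges <- lapply(chans, function(ch) {
    ok <- is.finite(ch$values)
    if (!any(ok)) return(c(0, 1))
    r <- range(ch$values[ok])
    if (r[1] == r[2]) r[2] <- r[1] + 1
    r
  })
  wfield <- function(width, f) for (ch in seq_len(ns)) wr(edf_pad(f(ch), width))
  wfield(16, function(i) chans[[i]]$label)
  wfield(80, function(i) "synthetic")
  wfield(8, function(i) chans[[i]]$dim)
  wfield(8, function(i) edf_num(ranges[[i]][1]))
  wfield(8, function(i) edf_num(ranges[[i]][2]))
  wfield(8, function(i) "-32767")
  wfield(8, function(i) "32767")
  wfield(80, function(i) "")
  wfield(8, function(i) fs)
  wfield(32, function(i) "")

  digitize <- function(v, r) {
    d <- round((v - r[1]) / (r[2] - r[1]) * 65534) - 32767
    d[!is.finite(v)] <- -32768
    as.integer(pmin(pmax(d, -32768), 32767))
  }
  dig <- lapply(seq_len(ns), function(i) {
    v <- c(chans[[i]]$values, rep(NA_real_, n_rec * fs - n))
    digitize(v, ranges[[i]])
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read one channel of an EDF file into a PPG record
#'
#' Reads the header and the requested signal channel, converting digital
#' values back to physical units. Sentinel samples (digital minimum - 1,
#' written for masked data) and any trailing zero-padding of the final data
#' record become masked gaps; truncated trailing records are masked as
#' unreadable.
#'
#' @param path EDF file path.
#' @param channel_name Label of the signal to read (default `"PPG"`).
#' @param device_id,participant_id,night_id Labels for the record
#'   (participant defaults to the EDF patient field).
#' @return A [ppg_record()] (no accelerometer channel; select it explicitly
#'   as its own record if needed).
#' @export
read_edf_record <- function(path, channel_name = "PPG", device_id = "finger",
                            participant_id = NULL, night_id = "night1") {
  if (!file.exists(path))
    stop_vw("file not found: %s", path, class = "vasowave_schema_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop_vw("%s is not a readable EDF file", path, class = "vasowave_schema_error")
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16)
  field(80)
  field(8)                                # physical dimension
  pmin_ <- as.numeric(field(8))
  pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8))
  dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)

  ci <- match(channel_name, labels)
  if (is.na(ci))
    stop_vw("EDF %s has no channel '%s' (channels: %s)", path, channel_name,
            paste(labels, collapse = ", "), class = "vasowave_schema_error")

  rec_words <- sum(spr)
  raw_all <- readBin(con, integer(), n = n_rec * rec_words, size = 2L,
                     endian = "little", signed = TRUE)
  full <- length(raw_all) %/% rec_words
  offs <- c(0L, cumsum(spr))
  out <- rep(NA_integer_, n_rec * spr[ci])
  if (full > 0L) {
    m <- matrix(raw_all[seq_len(full * rec_words)], nrow = rec_words)
    ch <- as.integer(m[(offs[ci] + 1L):offs[ci + 1L], , drop = FALSE])
    out[seq_len(full * spr[ci])] <- ch
  }
  sentinel <- dmin[ci] - 1
  mask <- is.na(out) | out <= sentinel
  phys <- pmin_[ci] + (out - dmin[ci]) * (pmax_[ci] - pmin_[ci]) / (dmax[ci] - dmin[ci])
  phys[mask] <- NA_real_

  n_true <- NA_integer_
  if (grepl("VW-NSAMP=", reserved, fixed = TRUE))
    n_true <- as.integer(sub(".*VW-NSAMP=([0-9]+).*", "\\1", reserved))
  if (!is.na(n_true)) {
    keep <- seq_len(min(n_true, length(phys)))
    phys <- phys[keep]; mask <- mask[keep]
  }
  ppg_record(phys, sample_rate = spr[ci] / rec_dur, device_id = device_id,
             participant_id = participant_id %||% patient,
             night_id = night_id, gap_mask = mask)
}
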