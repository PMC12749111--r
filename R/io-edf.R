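# Minimal EDF/EDF+ reader and writer (16-bit integer samples, standard
# 256-byte headers). Covers continuous recordings with a uniform sampling
# rate — sufficient for single-trial EMG files; annotations channels and
# discontinuous files are out of scope.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

read_edf_fields <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }, character(1))
}

#' Read an EDF/EDF+ file
#'
#' Parses the fixed 256-byte header, the per-signal headers and the 16-bit
#' data records, applying each signal's physical scaling. Signals declaring
#' physical dimension mV are converted to microvolts.
#'
#' @param path EDF file path.
#' @return A list: `signal` (matrix `[n_channels x n_samples]`, microvolts),
#'   `labels`, `fs_hz`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_edf_fields(con, 8)                     # version
  read_edf_fields(con, 80)                    # patient id
  read_edf_fields(con, 80)                    # recording id
  read_edf_fields(con, 8)                     # start date
  read_edf_fields(con, 8)                     # start time
  read_edf_fields(con, 8)                     # header bytes
  read_edf_fields(con, 44)                    # reserved
  n_rec <- as.integer(read_edf_fields(con, 8))
  rec_dur <- as.numeric(read_edf_fields(con, 8))
  ns <- as.integer(read_edf_fields(con, 4))
  if (!is.finite(ns) || ns < 1) {
    stop_mep("unparseable EDF header", "mep_unparseable")
  }
  labels <- read_edf_fields(con, 16, ns)
  read_edf_fields(con, 80, ns)                # transducer
  dims <- read_edf_fields(con, 8, ns)
  phys_min <- as.numeric(read_edf_fields(con, 8, ns))
  phys_max <- as.numeric(read_edf_fields(con, 8, ns))
  dig_min <- as.numeric(read_edf_fields(con, 8, ns))
  dig_max <- as.numeric(read_edf_fields(con, 8, ns))
  read_edf_fields(con, 80, ns)                # prefilter
  spr <- as.integer(read_edf_fields(con, 8, ns))
  read_edf_fields(con, 32, ns)                # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                   endian = "little")
      phys <- phys_min[s] + gain[s] * (d - dig_min[s])
      if (grepl("^mV$", dims[s], ignore.case = TRUE)) phys <- phys * 1000
      sig[s, (r - 1) * spr[s] + seq_len(spr[s])] <- phys
    }
  }
  list(signal = sig, labels = labels, fs_hz = spr[1] / rec_dur)
}

#' Write an EDF file
#'
#' Writes the recording's signal matrix as a single-data-record EDF file
#' (16-bit, per-channel physical scaling, physical dimension uV). Trial
#' metadata (setting, pulse onsets) is not representable in plain EDF and
#' is written by [write_recording()] to the JSON sidecar.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sig <- rec$signal
  ns <- nrow(sig)
  n <- ncol(sig)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    writeChar(edf_field(x, width), con, nchars = width, eos = NULL)
  }
  wr("0", 8)
  wr("X X X X", 80)
  wr(sprintf("Startdate X %s %s", rec$subject_id, rec$lead_id), 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(1, 8)                                    # one data record
  wr(format(n / rec$fs_hz, digits = 7), 8)
  wr(ns, 4)
  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  for (lb in rec$channels$label) wr(lb, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in signif(pmin, 7)) wr(format(v, digits = 7), 8)
  for (v in signif(pmax, 7)) wr(format(v, digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  pmin7 <- as.numeric(format(signif(pmin, 7), digits = 7))
  pmax7 <- as.numeric(format(signif(pmax, 7), digits = 7))
  for (s in seq_len(ns)) {
    d <- round((sig[s, ] - pmin7[s]) / (pmax7[s] - pmin7[s]) * 65535 - 32768)
    d <- pmin(32767, pmax(-32768, d))
    writeBin(as.integer(d), con, size = 2, endian = "little")
  }
  invisible(path)
}
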