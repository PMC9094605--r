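# Minimal EDF (European Data Format) continuous reader/writer.
#
# Supports the subset the pipeline needs: a single continuous recording,
# identical sampling rate across channels, 1-second data records, 16-bit
# samples with per-channel symmetric physical ranges. Reading validates
# the header and names the offending field on failure.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate (1-s data records)")
  }
  fs <- as.integer(round(fs))
  n <- ncol(rec$samples)
  n_rec <- n %/% fs
  if (n_rec < 1) abort("recording shorter than one 1-s EDF data record")
  if (n_rec * fs != n) {
    warn(sprintf("EDF writer truncating %d trailing sample(s) (partial record)",
                 n - n_rec * fs))
  }
  ns <- nrow(rec$samples)
  pmax_ <- apply(abs(rec$samples), 1, max)
  pmax_[pmax_ == 0] <- 1
  # header stores 8 ASCII chars; round first so writer and reader agree
  pmax_ <- signif(pmax_ * (1 + 1e-6), 6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("lfpath", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", -pmax_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(-32768, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  # same affine map the reader applies: gain = span / (dmax - dmin)
  gain <- (2 * pmax_) / 65535
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      x <- rec$samples[ch, ((r - 1) * fs + 1):(r * fs)]
      d <- round((x + pmax_[ch]) / gain[ch]) - 32768
      writeBin(as.integer(pmin(pmax(d, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

edf_num <- function(txt, field) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  if (is.na(v)) {
    abort(sprintf("malformed EDF header: field `%s` is not numeric (got %s)",
                  field, dQuote(trimws(txt))))
  }
  v
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) {
    abort(sprintf("malformed EDF header: file `%s` is too short (%s bytes)",
                  path, sz %||% 0))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8) # ids, date, time
  rd(8) # header bytes
  rd(44)
  n_rec <- edf_num(rd(8), "number of data records")
  rec_dur <- edf_num(rd(8), "record duration")
  ns <- edf_num(rd(4), "number of signals")
  if (ns < 1) abort("malformed EDF header: field `number of signals` < 1")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- trimws(rdv(16))
  rdv(80)
  rdv(8)
  pmin_ <- vapply(rdv(8), edf_num, 0, field = "physical minimum")
  pmax_ <- vapply(rdv(8), edf_num, 0, field = "physical maximum")
  dmin <- vapply(rdv(8), edf_num, 0, field = "digital minimum")
  dmax <- vapply(rdv(8), edf_num, 0, field = "digital maximum")
  rdv(80)
  spr <- vapply(rdv(8), edf_num, 0, field = "samples per record")
  rdv(32)
  rates <- spr / rec_dur
  if (length(unique(rates)) != 1) {
    abort("sampling-rate mismatch across EDF channels")
  }
  samples <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[ch]) {
        abort(sprintf("EDF data truncated in record %d", r))
      }
      gain <- (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      samples[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (raw - dmin[ch]) * gain + pmin_[ch]
    }
  }
  recording(samples, unname(rates[1]), labels)
}
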