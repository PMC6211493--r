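# Minimal EDF (European Data Format) reader/writer.
#
# Supports the continuous-recording subset this package needs: all channels
# share one sampling rate, samples are stored as little-endian 16-bit
# integers scaled per channel between the declared physical and digital
# ranges. Annotation channels and discontinuous (EDF+D) files are out of
# scope.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  x <- rec$samples
  nchan <- nrow(x); n <- ncol(x)
  rate <- rec$rate
  if (n < 1L) stop_io("cannot write an empty recording to EDF")
  if (abs(rate - round(rate)) < 1e-9 && n %% round(rate) == 0L) {
    spr <- as.integer(round(rate)); nrec <- n %/% spr; dur <- 1
  } else {
    spr <- n; nrec <- 1L; dur <- n / rate
  }
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("erdlia", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nchan), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_num(dur, 8), edf_pad(nchan, 4),
    paste(edf_pad(rec$channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), nchan), collapse = ""),
    paste(rep(edf_pad("uV", 8), nchan), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nchan), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nchan), collapse = ""),
    paste(rep(edf_pad("", 80), nchan), collapse = ""),
    paste(rep(edf_pad(spr, 8), nchan), collapse = ""),
    paste(rep(edf_pad("", 32), nchan), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nchan)) {
      dig <- round((x[ch, idx] - pmin[ch]) * scale[ch] + dmin)
      dig <- as.integer(pmin(pmax(dig, dmin), dmax))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

edf_field <- function(raw, from, width) {
  trimws(rawToChar(raw[from:(from + width - 1)]))
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256) stop_io("not an EDF file (truncated header): ", path)
  nrec <- as.integer(edf_field(raw, 237, 8))
  dur <- as.numeric(edf_field(raw, 245, 8))
  nchan <- as.integer(edf_field(raw, 253, 4))
  if (is.na(nchan) || nchan < 1)
    stop_io("not an EDF file (bad signal count): ", path)
  # per-signal field offsets (bytes from byte 256): label 0, transducer 16n,
  # physdim 96n, physmin 104n, physmax 112n, digmin 120n, digmax 128n,
  # prefilter 136n, samples-per-record 216n
  fld <- function(base, width)
    vapply(seq_len(nchan),
           function(i) edf_field(raw, 256 + base * nchan + (i - 1) * width + 1,
                                 width), "")
  labels <- fld(0, 16)
  pmin <- as.numeric(fld(104, 8)); pmax <- as.numeric(fld(112, 8))
  dmin <- as.numeric(fld(120, 8)); dmax <- as.numeric(fld(128, 8))
  spr <- as.integer(fld(216, 8))
  if (length(unique(spr)) != 1L)
    stop_io("EDF with per-channel sampling rates is not supported: ", path)
  spr <- spr[1]
  hdr_len <- 256 * (1 + nchan)
  vals <- readBin(raw[(hdr_len + 1):sz], "integer", size = 2,
                  n = (sz - hdr_len) / 2, endian = "little")
  expect <- nrec * nchan * spr
  if (length(vals) < expect)
    stop_io("EDF data shorter than header declares: ", path)
  x <- matrix(0, nchan, nrec * spr)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    block <- vals[((r - 1) * nchan * spr + 1):(r * nchan * spr)]
    for (ch in seq_len(nchan)) {
      seg <- block[((ch - 1) * spr + 1):(ch * spr)]
      x[ch, ((r - 1) * spr + 1):(r * spr)] <-
        (seg - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  eeg_recording(x, rate = spr / dur, channel_names = labels)
}
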