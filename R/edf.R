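#' Read an EDF (European Data Format) recording
#'
#' Minimal EDF/EDF+ continuous-recording parser: fixed 256-byte header,
#' per-signal header blocks, then data records of 16-bit little-endian
#' integers which are mapped to physical units via the per-signal
#' digital/physical calibration. Annotation channels (`EDF Annotations`)
#' are dropped. All retained signals must share one sampling rate.
#'
#' @param path path to an `.edf` file.
#' @return An [eeg_record]; the patient-identification field supplies
#'   `subject_id` when present.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L) stop("I/O error: '", path, "' truncated EDF header")
    trimws(s)
  }
  version <- rd(8)
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                        # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)                              # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop("I/O error: '", path, "' is not a parseable EDF file")

  labels    <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)       # transducer
  for (i in seq_len(ns)) rd(8)        # physical dimension
  phys_min  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min   <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max   <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)       # prefiltering
  spr       <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)       # reserved

  keep <- !grepl("^EDF Annotations", labels)
  if (!any(keep)) stop("I/O error: '", path, "' contains no signal channels")
  if (n_records < 0L) stop("I/O error: '", path, "' has unknown record count")

  raw_all <- readBin(con, integer(), n = n_records * sum(spr), size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_records * sum(spr))
    stop("I/O error: '", path, "' data section shorter than header declares")

  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(n_records * spr[i])
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * rec_len
    for (i in seq_len(ns)) {
      if (!keep[i]) next
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        raw_all[(base + offs[i] + 1L):(base + offs[i] + spr[i])]
    }
  }

  fs_all <- spr / record_dur
  fs <- unique(fs_all[keep])
  if (length(fs) != 1L)
    stop("EDF signals have mixed sampling rates (",
         paste(fs, collapse = ", "), " Hz); not supported")

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  idx <- which(keep)
  data <- matrix(0, nrow = length(idx), ncol = n_records * spr[idx[1]])
  for (k in seq_along(idx)) {
    i <- idx[k]
    data[k, ] <- (sig[[i]] - dig_min[i]) * gain[i] + phys_min[i]
  }
  subject <- if (nzchar(patient)) strsplit(patient, " ")[[1]][1]
             else tools::file_path_sans_ext(basename(path))
  eeg_record(data, fs = fs, channels = labels[keep], subject_id = subject)
}

# Internal EDF writer (16-bit, one data record per second when possible).
# Used by the tests for reader round trips and available for exporting
# synthetic cohorts to EDF-consuming tools.
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  n <- ncol(rec$data)
  ns <- nrow(rec$data)
  # pick a record duration giving an integer number of samples per record
  if (abs(rec$fs - round(rec$fs)) < 1e-9 && n %% round(rec$fs) == 0) {
    spr <- round(rec$fs); record_dur <- 1
  } else {
    spr <- n; record_dur <- n / rec$fs
  }
  n_records <- n %/% spr

  pmin_ <- apply(rec$data, 1L, min)
  pmax_ <- apply(rec$data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) {
    s <- sprintf("%-*s", width, substr(s, 1L, width))
    writeChar(s, con, nchars = width, eos = NULL)
  }
  num <- function(v, width) vapply(v, function(z) {
    s <- formatC(z, digits = width, width = 1, format = "g")
    substr(s, 1L, width)
  }, "")
  header_bytes <- 256L + 256L * ns
  wr("0", 8); wr(rec$subject_id, 80); wr(paste("label", rec$label), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(header_bytes), 8); wr("", 44)
  wr(as.character(n_records), 8); wr(num(record_dur, 8), 8)
  wr(as.character(ns), 4)
  for (ch in rec$channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in num(pmin_, 8)) wr(v, 8)
  for (v in num(pmax_, 8)) wr(v, 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      d <- round((rec$data[i, cols] - pmin_[i]) / gain[i] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
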