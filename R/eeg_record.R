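#' Construct an EEG record
#'
#' The canonical in-memory representation of a (possibly multi-channel)
#' EEG recording: a channels-by-samples amplitude matrix plus sampling-rate
#' and labelling metadata. Amplitudes are conventionally in microvolts;
#' units are carried as documentation, not enforced.
#'
#' @param data numeric matrix, one row per channel (n_channels x n_samples).
#' @param fs sampling rate in Hz (positive).
#' @param channels character vector of 10-20 channel names, one per row of
#'   `data`. Uppercased on construction; must be unique after uppercasing.
#' @param subject_id subject identifier string.
#' @param label class label, one of `"AD"`, `"FTD"`, `"HC"`, `"UNKNOWN"`.
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(256), 2, 128), fs = 128,
#'                   channels = c("FP1", "FP2"))
#' rec
#' @export
eeg_record <- function(data, fs, channels, subject_id = "S1",
                       label = c("UNKNOWN", "AD", "FTD", "HC")) {
  label <- match.arg(label)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  channels <- toupper(as.character(channels))
  if (nrow(data) != length(channels))
    stop("number of rows of `data` (", nrow(data),
         ") must equal number of channel names (", length(channels), ")")
  if (anyDuplicated(channels))
    stop("validation error: duplicate channel names after uppercasing: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (ncol(data) < 1L) stop("record must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  rownames(data) <- channels
  structure(
    list(subject_id = as.character(subject_id), label = label,
         fs = as.numeric(fs), channels = channels, data = data),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> subject %s, label %s\n", x$subject_id, x$label))
  cat(sprintf("  %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              length(x$channels), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of an EEG record in seconds
#' @param rec an [eeg_record].
#' @return numeric scalar, seconds.
#' @export
eeg_duration <- function(rec) ncol(rec$data) / rec$fs

#' Read an EEG recording from EDF or CSV
#'
#' CSV files carry one column per channel with a header row of channel
#' names, and require a JSON sidecar (same path with extension replaced by
#' `.json`, or given explicitly) holding at least `{"fs": <Hz>}` and
#' optionally `subject_id` and `label`. EDF files are parsed from their
#' own header (see [read_edf]).
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; defaults to the file extension.
#' @param label optional class label overriding any label in the file or
#'   sidecar.
#' @param sidecar optional explicit path to the JSON sidecar (CSV only).
#' @return An [eeg_record].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv"), label = NULL,
                     sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("I/O error: cannot read '", path, "': file does not exist")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format` explicitly"))
  }
  rec <- if (format == "edf") read_edf(path) else read_eeg_csv(path, sidecar)
  if (!is.null(label)) {
    rec$label <- match.arg(label, c("AD", "FTD", "HC", "UNKNOWN"))
  }
  rec
}

read_eeg_csv <- function(path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("configuration error: CSV input '", path, "' needs a JSON sidecar ",
         "with the sampling rate; '", sidecar, "' not found")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("configuration error: sidecar '", sidecar, "' lacks \"fs\"")
  tab <- read.csv(path, check.names = FALSE)
  channels <- toupper(names(tab))
  if (anyDuplicated(channels))
    stop("validation error: duplicate channel names in '", path, "': ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  data <- t(as.matrix(tab))
  eeg_record(data, fs = meta$fs, channels = channels,
             subject_id = if (!is.null(meta$subject_id)) meta$subject_id
                          else tools::file_path_sans_ext(basename(path)),
             label = if (!is.null(meta$label)) meta$label else "UNKNOWN")
}

#' Write an EEG record to CSV plus JSON sidecar
#'
#' Inverse of the CSV path of [read_eeg]: one column per channel with a
#' header row, and a `.json` sidecar carrying `fs`, `subject_id`, `label`.
#'
#' @param rec an [eeg_record].
#' @param path output CSV path; the sidecar is written alongside.
#' @param digits significant digits kept in the CSV (default 8).
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path, digits = 8) {
  tab <- as.data.frame(t(signif(rec$data, digits)))
  names(tab) <- rec$channels
  write.csv(tab, path, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(fs = rec$fs, subject_id = rec$subject_id, label = rec$label),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a time segment from an EEG record
#'
#' All channels are cut synchronously; metadata is unchanged.
#'
#' @param rec an [eeg_record].
#' @param start_s segment start in seconds (>= 0).
#' @param duration_s segment length in seconds.
#' @return An [eeg_record] with exactly `round(duration_s * fs)` samples
#'   starting at sample index `round(start_s * fs)`.
#' @export
eeg_segment <- function(rec, start_s, duration_s) {
  stopifnot(inherits(rec, "eeg_record"))
  if (start_s < 0) stop("`start_s` must be >= 0")
  n <- ncol(rec$data)
  avail <- n / rec$fs
  if (start_s + duration_s > avail + 1e-9)
    stop(sprintf(
      "range error: requested window [%g, %g] s exceeds the available %g s",
      start_s, start_s + duration_s, avail))
  i0 <- round(start_s * rec$fs)
  len <- round(duration_s * rec$fs)
  out <- rec
  out$data <- rec$data[, (i0 + 1L):(i0 + len), drop = FALSE]
  out
}

#' Resample an EEG record to a new rate
#'
#' Rational-factor polyphase resampling: each channel is zero-stuffed up by
#' p, filtered with a Kaiser windowed-sinc low-pass at the common Nyquist
#' frequency, and decimated by q, where p/q is the (reduced) rational
#' approximation of `target_fs / fs`. The FIR is linear-phase and its group
#' delay is compensated exactly, so the operation is zero-phase.
#'
#' @param rec an [eeg_record].
#' @param target_fs desired sampling rate in Hz (positive).
#' @return An [eeg_record] at `target_fs` with
#'   `round(n_samples * target_fs / fs)` samples per channel. If
#'   `target_fs == fs` the input is returned unchanged.
#' @export
eeg_resample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a single positive rate in Hz")
  if (target_fs == rec$fs) return(rec)
  out <- rec
  out$fs <- target_fs
  out$data <- t(apply(rec$data, 1L, resample_poly, fs = rec$fs,
                      target_fs = target_fs))
  rownames(out$data) <- rec$channels
  out
}

# Rational approximation p/q of a positive real with bounded denominator
# (continued fractions).
rational_ratio <- function(r, max_den = 1000L) {
  if (abs(r - round(r)) < 1e-12) return(c(p = round(r), q = 1L))
  a <- floor(r); x <- r - a
  h <- c(a, 1); k <- c(1, 0)  # convergents h/k
  while (k[1] <= max_den) {
    if (x < 1e-12) break
    x <- 1 / x
    a <- floor(x); x <- x - a
    h <- c(a * h[1] + h[2], h[1])
    k <- c(a * k[1] + k[2], k[1])
    if (abs(h[1] / k[1] - r) < 1e-9 * r) break
  }
  if (k[1] > max_den) { h[1] <- h[2]; k[1] <- k[2] }
  c(p = h[1], q = k[1])
}

# Kaiser window of length n with shape beta (I0 via besselI).
kaiser_window <- function(n, beta) {
  m <- n - 1
  t <- (0:m - m / 2) / (m / 2)
  besselI(beta * sqrt(pmax(0, 1 - t^2)), 0) / besselI(beta, 0)
}

# One-channel rational polyphase resampler (zero-phase windowed-sinc FIR).
resample_poly <- function(x, fs, target_fs, kaiser_beta = 5, half_width = 10) {
  pq <- rational_ratio(target_fs / fs)
  p <- pq[["p"]]; q <- pq[["q"]]
  n <- length(x)
  n_out <- round(n * target_fs / fs)
  if (p == 1 && q == 1) return(x)
  # upsample by p
  xu <- numeric(n * p)
  xu[seq(1L, by = p, length.out = n)] <- x
  # low-pass at min(fs, target_fs)/2, normalized to the upsampled rate
  mpq <- max(p, q)
  L <- 2L * half_width * mpq + 1L            # odd length, integer delay
  kk <- -(half_width * mpq):(half_width * mpq)
  fc <- 1 / (2 * mpq)                         # cycles per upsampled sample
  h <- 2 * fc * sinc(2 * fc * kk) * kaiser_window(L, kaiser_beta) * p
  delay <- half_width * mpq                   # (L-1)/2 samples
  y <- fft_convolve(xu, h)
  idx <- delay + 1L + (0:(n_out - 1L)) * q
  y[idx]
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Linear ("open") convolution via FFT; returns length(a)+length(b)-1 values.
fft_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, 2)
  Re(fft(fft(c(a, numeric(nf - length(a)))) *
         fft(c(b, numeric(nf - length(b)))), inverse = TRUE))[1:n] / nf
}
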