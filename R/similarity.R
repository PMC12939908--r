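#' Similarity measure specification
#'
#' Names one of the four measures used to compare a feature vector with a
#' class template, together with its orientation: DTW is a distance
#' (smaller = more similar); PCC, WC, and HTC are similarities (larger =
#' more similar).
#'
#' @param name `"DTW"`, `"PCC"`, `"WC"` or `"HTC"` (case-insensitive).
#' @param wc_wavelet complex Morlet parameters for WC as
#'   `c(bandwidth, center_frequency)`; default `c(1, 1.5)` (cmor1-1.5).
#' @param wc_scales CWT scale grid for WC; default `seq(1, 10, by = 0.5)`.
#' @return A `measure_spec` list with fields `name`, `orientation`,
#'   `params`.
#' @export
measure_spec <- function(name = c("PCC", "DTW", "WC", "HTC"),
                         wc_wavelet = c(1, 1.5),
                         wc_scales = seq(1, 10, by = 0.5)) {
  name <- toupper(name)
  name <- match.arg(name)
  structure(list(
    name = name,
    orientation = if (name == "DTW") "distance" else "similarity",
    params = list(wc_wavelet = wc_wavelet, wc_scales = wc_scales)),
    class = "measure_spec")
}

#' Dynamic time warping distance
#'
#' Unconstrained DTW between two scalar sequences with absolute
#' difference as the local cost: the minimum, over all monotone alignment
#' paths, of the summed local distances. Tolerates sequences of different
#' length; no warping window.
#'
#' @param a,b numeric sequences (length >= 1).
#' @return Nonnegative cumulative distance.
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("validation error: DTW requires nonempty sequences")
  dtw_distance_cpp(as.numeric(a), as.numeric(b))
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation of two equal-length vectors. Zero-variance
#' inputs are rejected rather than returned as NA.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b))
    stop("validation error: PCC requires equal lengths (", length(a),
         " vs ", length(b), ")")
  if (length(a) < 2L) stop("validation error: PCC requires length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop(errorCondition(
      "degenerate input: zero-variance sequence has undefined correlation",
      class = c("mefc_degenerate_input", "error")))
  cor(a, b)
}

# Complex Morlet (cmorB-C) continuous wavelet transform of a real
# sequence on a scale grid. psi(t) = (pi B)^(-1/2) exp(2 pi i C t)
# exp(-t^2 / B); at scale s the kernel is sampled at integer lags and
# normalized by 1/sqrt(s). Zero-padded ("same") linear convolution.
cwt_morlet <- function(x, scales, bandwidth = 1, center = 1.5) {
  n <- length(x)
  out <- matrix(0i, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    hw <- ceiling(6 * s * sqrt(bandwidth))   # exp(-36) tail: negligible
    t <- (-hw):hw
    u <- t / s
    psi <- (pi * bandwidth)^(-0.5) *
      exp(2i * pi * center * u) * exp(-u^2 / bandwidth)
    # W(n) = sum_t x[t] conj(psi((t-n)/s)) / sqrt(s); correlating with
    # conj(psi) equals convolving with psi since rev(Conj(psi)) == psi
    kern <- psi / sqrt(s)
    re <- fft_convolve(x, Re(kern))
    im <- fft_convolve(x, Im(kern))
    out[si, ] <- complex(real = re[(hw + 1L):(hw + n)],
                         imaginary = im[(hw + 1L):(hw + n)])
  }
  out
}

#' Wavelet coherence
#'
#' Magnitude-squared coherence of two sequences in the time-scale plane
#' under a complex Morlet (cmor1-1.5) CWT on scales 1 to 10 in steps of
#' 0.5, with the smoothing operator taken as the arithmetic mean over the
#' whole time axis. The 1/s scale normalization cancels under this global
#' smoothing. The per-scale coherences are averaged into one scalar in
#' `[0, 1]`.
#'
#' @param a,b numeric sequences of equal length >= 4.
#' @param spec a [measure_spec] carrying the wavelet parameters and scale
#'   grid.
#' @return Mean squared coherence over the scale grid, in `[0, 1]`.
#' @export
wavelet_coherence <- function(a, b, spec = measure_spec("WC")) {
  if (length(a) != length(b))
    stop("validation error: WC requires equal lengths")
  if (length(a) < 4L)
    stop("validation error: WC requires sequences of length >= 4 ",
         "(scale grid unsupported on shorter vectors)")
  bw <- spec$params$wc_wavelet[1]; ctr <- spec$params$wc_wavelet[2]
  scales <- spec$params$wc_scales
  Wa <- cwt_morlet(as.numeric(a), scales, bw, ctr)
  Wb <- cwt_morlet(as.numeric(b), scales, bw, ctr)
  r2 <- numeric(length(scales))
  for (si in seq_along(scales)) {
    sxy <- mean(Wa[si, ] * Conj(Wb[si, ]))
    sxx <- mean(Mod(Wa[si, ])^2)
    syy <- mean(Mod(Wb[si, ])^2)
    if (sxx == 0 || syy == 0)
      stop(errorCondition(
        "degenerate input: zero wavelet power at scale grid",
        class = c("mefc_degenerate_input", "error")))
    r2[si] <- Mod(sxy)^2 / (sxx * syy)
  }
  mean(r2)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of `x + i H{x}`: negative frequencies are zeroed,
#' positive ones doubled.
#'
#' @param x numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope correlation
#'
#' Mean-removes each sequence, forms its analytic signal, and correlates
#' the two instantaneous amplitude envelopes. Sensitive to shared
#' temporal modulation patterns rather than to signed amplitudes (the
#' envelope is sign-invariant).
#'
#' @param a,b numeric sequences of equal length >= 4.
#' @return Correlation of the envelopes, in `[-1, 1]`.
#' @export
hilbert_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop("validation error: HTC requires equal lengths")
  if (length(a) < 4L)
    stop("validation error: HTC requires sequences of length >= 4")
  env_a <- Mod(analytic_signal(a - mean(a)))
  env_b <- Mod(analytic_signal(b - mean(b)))
  if (sd(env_a) == 0 || sd(env_b) == 0)
    stop(errorCondition(
      "degenerate input: constant envelope has undefined correlation",
      class = c("mefc_degenerate_input", "error")))
  cor(env_a, env_b)
}

#' Compare a feature vector against a template
#'
#' Dispatches to the measure named in `spec` on the raw concatenated
#' value vectors. All measures except DTW require identical layouts
#' (same mode and window count); DTW tolerates length mismatches.
#'
#' @param sample,template `mefc_vector` objects (or bare numeric
#'   vectors).
#' @param spec a [measure_spec].
#' @return List with `score` (numeric) and `orientation` (`"distance"`
#'   or `"similarity"`).
#' @export
compare_mefc <- function(sample, template, spec = measure_spec("PCC")) {
  va <- if (inherits(sample, "mefc_vector")) sample$values else as.numeric(sample)
  vb <- if (inherits(template, "mefc_vector")) template$values else as.numeric(template)
  if (spec$name != "DTW" && length(va) != length(vb))
    stop("validation error: layout mismatch (", length(va), " vs ",
         length(vb), " values); only DTW tolerates differing lengths")
  if (inherits(sample, "mefc_vector") && inherits(template, "mefc_vector") &&
      spec$name != "DTW" && !identical(sample$mode, template$mode))
    stop("validation error: cannot compare ", sample$mode, "-mode and ",
         template$mode, "-mode vectors")
  score <- switch(spec$name,
    DTW = dtw_distance(va, vb),
    PCC = pcc(va, vb),
    WC  = wavelet_coherence(va, vb, spec),
    HTC = hilbert_correlation(va, vb))
  list(score = score, orientation = spec$orientation)
}
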