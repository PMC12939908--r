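#' Default class-conditional signal profiles
#'
#' Encodes the complexity mechanism the classifier exploits as
#' class-conditional contrasts around a common baseline, graded along
#' the oscillation-dominance/broadband-irregularity axis: the AD
#' profile couples strong phase-locked theta and beta oscillations
#' (elevated, pathologically reorganized oscillatory activity) with a
#' suppressed broadband noise floor — the in-band entropies collapse;
#' the FTD profile strengthens beta moderately over an unchanged noise
#' floor (frontal executive involvement, an intermediate
#' oscillation/noise mix); the HC profile raises the noise floor and
#' phase wander (the rich broadband variability of a healthy system) —
#' the in-band entropies are largest. The beta rhythm, whose dyadic
#' band is wide enough for a large entropy dynamic range, is the most
#' informative single rhythm under this design. Contrasts scale with
#' `separation` and vanish at `separation = 0`, where all three
#' profiles are identical.
#'
#' @param separation nonnegative contrast strength.
#' @return Named list (`AD`, `FTD`, `HC`) of per-band profile lists with
#'   fields `oscillation_amplitude`, `oscillation_regularity` (phase
#'   random-walk SD, rad/sample), `broadband_noise_sd`,
#'   `one_over_f_exponent`.
#' @export
default_class_profiles <- function(separation = 1) {
  stopifnot(separation >= 0)
  base_amp <- c(delta = 1.5, theta = 1.0, alpha = 1.2, beta = 0.8,
                gamma = 0.4)
  base_jit <- c(delta = 0.15, theta = 0.15, alpha = 0.15, beta = 0.15,
                gamma = 0.15)
  mk <- function(amp, jit, noise_sd, alpha_exp)
    list(oscillation_amplitude = amp, oscillation_regularity = jit,
         broadband_noise_sd = noise_sd, one_over_f_exponent = alpha_exp)
  s <- separation

  # AD: phase-locked oscillatory dominance with a suppressed broadband
  # floor — strong regular theta (elevated, pathologically reorganized
  # theta activity) and hyper-synchronous beta, giving the lowest
  # in-band entropies
  ad_amp <- base_amp
  ad_amp["theta"] <- ad_amp["theta"] * (1 + 2 * s)
  ad_amp["beta"] <- ad_amp["beta"] * (1 + 1.5 * s)
  ad_jit <- base_jit
  ad_jit["theta"] <- ad_jit["theta"] / (1 + 20 * s)
  ad_jit["beta"] <- ad_jit["beta"] / (1 + 10 * s)

  # FTD: moderately strengthened beta over an unchanged broadband floor
  # (frontal executive involvement; intermediate oscillation/noise mix)
  ftd_amp <- base_amp
  ftd_amp["beta"] <- ftd_amp["beta"] * (1 + 0.6 * s)

  # HC: broadband-irregular — higher noise floor and wandering phases,
  # the rich variability of a healthy system
  hc_jit <- base_jit * (1 + 1.4 * s)

  list(
    AD  = mk(ad_amp, ad_jit, 1.0 / (1 + s), 1.0),
    FTD = mk(ftd_amp, base_jit, 1.0 * (1 + 0.2 * s), 1.0),
    HC  = mk(base_amp, hc_jit, 1.0 * (1 + 0.75 * s), 1.0)
  )
}

#' Synthetic cohort specification
#'
#' @param n_per_class named integer vector of subject counts (each >= 2,
#'   the LOOCV precondition); default 10 each of AD, FTD, HC.
#' @param fs sampling rate in Hz (default 128).
#' @param duration_s segment length in seconds (default 30).
#' @param channels channel names (default: the 19-channel 10-20 montage).
#' @param seed integer master seed; every subject/channel derives its own
#'   substream deterministically from it.
#' @param separation class-contrast strength (>= 0); 0 means the classes
#'   are statistically identical.
#' @param class_profiles per-class signal profiles; default
#'   [default_class_profiles]`(separation)`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = c(AD = 10L, FTD = 10L, HC = 10L),
                        fs = 128, duration_s = 30,
                        channels = MEFC_CHANNELS_1020,
                        seed = 1L, separation = 1,
                        class_profiles = NULL) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    stop("`n_per_class` must be a named vector of class counts")
  if (any(n_per_class < 2L))
    stop("validation error: every class needs >= 2 subjects (LOOCV)")
  if (separation < 0) stop("`separation` must be >= 0")
  if (is.null(class_profiles))
    class_profiles <- default_class_profiles(separation)
  missing_cls <- setdiff(names(n_per_class), names(class_profiles))
  if (length(missing_cls))
    stop("no class profile for: ", paste(missing_cls, collapse = ", "))
  structure(list(n_per_class = n_per_class, fs = fs,
                 duration_s = duration_s, channels = toupper(channels),
                 seed = as.integer(seed), separation = separation,
                 class_profiles = class_profiles),
            class = "cohort_spec")
}

# Band-center oscillation frequencies (Hz) used by the generator.
SYNTH_BAND_FREQ <- c(delta = 2, theta = 6, alpha = 12, beta = 24,
                     gamma = 45)

# Smooth phase drift: a random walk sampled every `block` samples and
# linearly interpolated, so the oscillation's instantaneous frequency
# wanders on sub-band timescales without adding wideband FM roughness.
# `rate` is the diffusion scale in rad/sample (matching a plain random
# walk of the same long-run variance).
smooth_phase_drift <- function(n, rate, block = 32L) {
  if (rate <= 0) return(numeric(n))
  k <- ceiling(n / block) + 1L
  knots <- cumsum(c(0, rnorm(k - 1L, 0, rate * sqrt(block))))
  stats::approx(x = (0:(k - 1L)) * block, y = knots, xout = 0:(n - 1L))$y
}

# Deterministic 31-bit substream seed for (master seed, class, subject,
# channel).
derive_seed <- function(seed, class_idx, subject_index, channel_idx) {
  v <- (as.double(seed) * 2654435.0 + class_idx * 97911.0 +
        subject_index * 7907.0 + channel_idx * 131.0)
  as.integer(v %% 2147483647)
}

# 1/f^alpha background noise, unit variance, via spectral shaping with
# random phases and Hermitian symmetry (so the inverse transform is real).
pink_noise <- function(n, alpha) {
  half <- (n - 1L) %/% 2L
  spec <- complex(length.out = n)
  if (half >= 1L) {
    mag <- (1:half)^(-alpha / 2)
    ph <- runif(half, 0, 2 * pi)
    spec[2:(half + 1L)] <- mag * exp(1i * ph)
    spec[n:(n - half + 1L)] <- Conj(spec[2:(half + 1L)])
  }
  if (n %% 2L == 0L)
    spec[n / 2L + 1L] <- (n / 2)^(-alpha / 2) * (2 * runif(1) - 1)
  x <- Re(fft(spec, inverse = TRUE))
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Generate one synthetic EEG subject
#'
#' Each channel is the sum of five band-centered oscillations (sinusoids
#' with a phase random walk whose step SD sets their regularity), a
#' 1/f^alpha background, and white noise, with all parameters drawn from
#' the subject's class profile. Deterministic given `(seed, class,
#' subject_index, channel)`.
#'
#' @param spec a [cohort_spec].
#' @param class class label, a name of `spec$n_per_class`.
#' @param subject_index 1-based index within the class.
#' @return An [eeg_record] labelled with `class`.
#' @export
generate_subject <- function(spec, class, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!class %in% names(spec$class_profiles))
    stop("unknown class '", class, "'")
  prof <- spec$class_profiles[[class]]
  class_idx <- match(class, sort(names(spec$class_profiles)))
  n <- round(spec$duration_s * spec$fs)
  t <- (0:(n - 1)) / spec$fs
  data <- matrix(0, nrow = length(spec$channels), ncol = n)
  for (ci in seq_along(spec$channels)) {
    set.seed(derive_seed(spec$seed, class_idx, subject_index, ci))
    x <- numeric(n)
    for (b in names(SYNTH_BAND_FREQ)) {
      phi0 <- runif(1, 0, 2 * pi)
      jitter <- smooth_phase_drift(n, prof$oscillation_regularity[[b]])
      x <- x + prof$oscillation_amplitude[[b]] *
        sin(2 * pi * SYNTH_BAND_FREQ[[b]] * t + phi0 + jitter)
    }
    x <- x + prof$broadband_noise_sd * pink_noise(n, prof$one_over_f_exponent) +
      rnorm(n, 0, prof$broadband_noise_sd)
    data[ci, ] <- x
  }
  eeg_record(data, fs = spec$fs, channels = spec$channels,
             subject_id = sprintf("%s%02d", class, subject_index),
             label = class)
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec].
#' @param out_dir optional directory; when given, each record is written
#'   as CSV + JSON sidecar (the [read_eeg] fixture format) together with
#'   a `manifest.csv` (subject_id, label, seed material).
#' @return List with `records` (list of [eeg_record]) and `manifest`
#'   (data.frame).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- list(); rows <- list()
  for (cl in names(spec$n_per_class)) {
    for (k in seq_len(spec$n_per_class[[cl]])) {
      rec <- generate_subject(spec, cl, k)
      records[[rec$subject_id]] <- rec
      rows[[rec$subject_id]] <- data.frame(
        subject_id = rec$subject_id, label = cl, subject_index = k,
        master_seed = spec$seed, separation = spec$separation,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("I/O error: cannot create output directory '",
                    out_dir, "'")
    }
    for (rec in records)
      write_eeg_csv(rec, file.path(out_dir, paste0(rec$subject_id, ".csv")))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}
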