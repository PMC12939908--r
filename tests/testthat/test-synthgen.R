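test_that("generation is deterministic and respects the spec arithmetic", {
  spec <- cohort_spec(n_per_class = c(AD = 2L, FTD = 2L, HC = 2L),
                      duration_s = 8, channels = c("FP1", "FP2"),
                      seed = 7L, separation = 1)
  r1 <- generate_subject(spec, "AD", 1)
  r2 <- generate_subject(spec, "AD", 1)
  expect_identical(r1$data, r2$data)
  expect_equal(ncol(r1$data), 1024L)  # 8 s x 128 Hz
  expect_equal(r1$label, "AD")
  # different subjects and channels decorrelate
  r3 <- generate_subject(spec, "AD", 2)
  expect_false(identical(r1$data, r3$data))
  expect_false(identical(r1$data[1, ], r1$data[2, ]))

  coh <- generate_cohort(spec)
  expect_length(coh$records, 6L)
  expect_equal(nrow(coh$manifest), 6L)
  expect_equal(sort(unique(coh$manifest$label)), c("AD", "FTD", "HC"))
})

test_that("written fixtures are byte-identical across regenerations", {
  spec <- cohort_spec(n_per_class = c(AD = 2L, HC = 2L),
                      class_profiles = default_class_profiles(1)[c("AD", "HC")],
                      duration_s = 2, channels = "FP2", seed = 11L)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  generate_cohort(spec, out_dir = d1)
  generate_cohort(spec, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # round trip through the CSV fixture format
  back <- read_eeg(file.path(d1, "AD01.csv"))
  expect_equal(back$label, "AD")
  expect_equal(back$fs, 128)
})

test_that("spec validation rejects degenerate cohorts", {
  expect_error(cohort_spec(n_per_class = c(AD = 1L, HC = 5L)), ">= 2")
  expect_error(cohort_spec(separation = -1), ">= 0")
  expect_error(cohort_spec(n_per_class = c(2L, 2L)), "named")
  spec <- cohort_spec()
  expect_error(generate_subject(spec, "XX", 1), "unknown class")
})

test_that("injected oscillations land in their nominal DWT bands", {
  # single-band profiles with no background: band-energy plurality check
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    amp <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
    amp[b] <- 1
    prof <- list(oscillation_amplitude = amp,
                 oscillation_regularity = c(delta = .05, theta = .05,
                                            alpha = .05, beta = .05,
                                            gamma = .05),
                 broadband_noise_sd = 0.01, one_over_f_exponent = 1)
    spec <- cohort_spec(n_per_class = c(AD = 2L, HC = 2L),
                        class_profiles = list(AD = prof, HC = prof),
                        duration_s = 8, channels = "FP2", seed = 5L)
    rec <- generate_subject(spec, "AD", 1)
    rs <- extract_rhythms(rec, channel = "FP2")
    en <- vapply(rs$bands, function(v) sum(v^2), 0)
    expect_equal(names(which.max(en)), b)
  }
})

test_that("separation zero is statistically indistinguishable across classes", {
  spec <- cohort_spec(n_per_class = c(AD = 20L, HC = 20L),
                      duration_s = 8, channels = "FP2", seed = 13L,
                      separation = 0)
  coh <- generate_cohort(spec)
  cfg <- entropy_config(mode = "scalar")
  theta_se <- vapply(coh$records, function(rec) {
    rs <- extract_rhythms(rec, channel = "FP2")
    sample_entropy(rs$bands$theta)
  }, 0)
  lab <- vapply(coh$records, function(r) r$label, "")
  p <- t.test(theta_se[lab == "AD"], theta_se[lab == "HC"])$p.value
  expect_gt(p, 0.01)
})

test_that("the AD profile depresses theta-band sample entropy at separation >= 1", {
  spec <- cohort_spec(n_per_class = c(AD = 8L, FTD = 8L, HC = 8L),
                      duration_s = 8, channels = "FP2", seed = 17L,
                      separation = 1)
  coh <- generate_cohort(spec)
  cfg <- entropy_config()
  band_se <- function(band) {
    vapply(coh$records, function(rec) {
      rs <- extract_rhythms(rec, channel = "FP2")
      mean(suppressMessages(sliding_entropy(rs$bands[[band]], 128, cfg, "SE")))
    }, 0)
  }
  lab <- vapply(coh$records, function(r) r$label, "")
  theta_se <- band_se("theta")
  expect_lt(mean(theta_se[lab == "AD"]), mean(theta_se[lab == "HC"]))
  # the beta band carries the full three-way gradation
  beta_se <- band_se("beta")
  expect_lt(mean(beta_se[lab == "AD"]), mean(beta_se[lab == "FTD"]))
  expect_lt(mean(beta_se[lab == "FTD"]), mean(beta_se[lab == "HC"]))
})

test_that("downstream accuracy does not degrade as separation grows", {
  accs <- vapply(c(0, 2), function(s) {
    records <- small_cohort(seed = 23L, separation = s, n = 5L,
                            channels = "FP2")
    feats <- suppressMessages(extract_features(records, channels = "FP2"))
    loocv(feats$features$FP2$beta, feats$labels,
          measure_spec("PCC"))$accuracy
  }, 0)
  # Monte-Carlo tolerance: strong separation must clearly beat none
  expect_gt(accs[2], accs[1] + 10)
})
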