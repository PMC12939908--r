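test_that("permutation entropy analytic cases", {
  # strictly ascending ramp: a single ordinal pattern, entropy exactly 0
  expect_identical(permutation_entropy(1:8), 0)
  # hand-enumerated: patterns of [4,7,9,10,6,11,3] are
  # {123, 123, 231, 213, 231} -> p = (0.4, 0.4, 0.2)
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(x), -(0.8 * log(0.4) + 0.2 * log(0.2)))
  expect_equal(permutation_entropy(x), pe_oracle(x))
  # iid uniform approaches ln(3!) = ln 6
  set.seed(31)
  expect_equal(permutation_entropy(runif(1e5)), log(6), tolerance = 0.01)
  expect_error(permutation_entropy(c(1, 2), order = 3), "too short")
})

test_that("permutation entropy is bounded and rank-invariant", {
  set.seed(32)
  for (rep in 1:20) {
    x <- rnorm(sample(100:1000, 1))
    pe <- permutation_entropy(x)
    expect_gte(pe, 0)
    expect_lte(pe, log(factorial(3)) + 1e-12)
    # invariant under strictly monotone increasing transforms
    expect_equal(permutation_entropy(exp(x) + 3), pe)
  }
  # higher order bound
  set.seed(33)
  x <- rnorm(500)
  expect_lte(permutation_entropy(x, order = 4), log(factorial(4)))
})

test_that("sample entropy matches the double-loop reference and its limits", {
  expect_error(sample_entropy(rep(2, 50)), class = "mefc_degenerate_input")
  # huge tolerance: nearly all pairs match at m and m+1
  set.seed(34)
  expect_lt(sample_entropy(rnorm(100), r_factor = 10), 0.05)
  for (rep in 1:20) {
    x <- rnorm(sample(100:300, 1))
    expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-12)
  }
})

test_that("sample entropy is non-increasing in the tolerance factor", {
  set.seed(35)
  x <- rnorm(400)
  vals <- vapply(c(0.1, 0.15, 0.2, 0.3, 0.5, 1), function(rf)
    sample_entropy(x, r_factor = rf), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("singular spectrum entropy analytic cases and reference", {
  # long sinusoid: two near-equal dominant components, SSE ~ ln 2
  x <- sin(2 * pi * 0.05 * (1:1000))
  expect_equal(singular_spectrum_entropy(x, 20), log(2), tolerance = 0.05)
  # rank-1 trajectory matrix: a single component, exactly zero
  expect_identical(singular_spectrum_entropy(rep(1, 100), 20), 0)
  set.seed(36)
  for (rep in 1:20) {
    x <- rnorm(sample(100:1000, 1))
    L <- sample(5:20, 1)
    sse <- singular_spectrum_entropy(x, L)
    expect_equal(sse, sse_oracle(x, L), tolerance = 1e-10)
    expect_gte(sse, 0)
    expect_lte(sse, log(L))
    # scale invariance: energy fractions unchanged
    expect_equal(singular_spectrum_entropy(7.3 * x, L), sse,
                 tolerance = 1e-10)
  }
  # white noise: near-flat singular spectrum
  set.seed(37)
  z <- rnorm(512)
  expect_equal(singular_spectrum_entropy(z, 20), log(20), tolerance = 0.1 * log(20))
  expect_error(singular_spectrum_entropy(rnorm(100), 60), "validation error")
})

test_that("noise carries more sample entropy than same-variance oscillation", {
  set.seed(38)
  t <- (1:512) / 128
  se_noise <- mean(replicate(10, sample_entropy(rnorm(512))))
  se_tone <- mean(replicate(10,
    sample_entropy(sqrt(2) * sin(2 * pi * 6 * t + runif(1, 0, 2 * pi)))))
  expect_gt(se_noise, se_tone)
})

test_that("sliding windows follow the count arithmetic and are stable on stationary input", {
  set.seed(39)
  cfg <- entropy_config()
  x8 <- rnorm(8 * 128)
  expect_length(sliding_entropy(x8, 128, cfg, "PE"), 7L)   # 1 + (1024-256)/128
  x30 <- rnorm(30 * 128)
  expect_length(sliding_entropy(x30, 128, cfg, "SE"), 29L)
  pe_series <- sliding_entropy(x30, 128, cfg, "PE")
  expect_lt(sd(pe_series) / mean(pe_series), 0.10)
  expect_error(sliding_entropy(rnorm(100), 128, cfg, "PE"),
               "validation error")
})

test_that("degenerate sample-entropy windows are imputed and flagged", {
  # first two windows constant, rest noisy
  set.seed(40)
  x <- c(rep(1, 3 * 128), rnorm(5 * 128))
  cfg <- entropy_config()
  expect_message(vals <- sliding_entropy(x, 128, cfg, "SE"), "imputed")
  expect_true(all(is.finite(vals)))
  imput <- attr(vals, "imputed")
  expect_true(length(imput) >= 1)
  expect_equal(unname(vals[imput[1]]), max(vals))
})

test_that("MEFC vectors concatenate PE, SE, SSE in order, per mode", {
  set.seed(41)
  x <- rnorm(8 * 128)
  scal <- build_mefc(x, 128, entropy_config(mode = "scalar"),
                     channel = "FP2", band = "theta")
  expect_length(scal$values, 3L)
  expect_equal(scal$values[1], permutation_entropy(x))
  expect_equal(scal$values[2], sample_entropy(x))
  expect_equal(scal$values[3],
               singular_spectrum_entropy(x, 20))
  win <- build_mefc(x, 128, entropy_config(), channel = "FP2",
                    band = "theta")
  expect_length(win$values, 21L)          # 3 x 7 windows
  expect_equal(win$n_windows, 7L)
  expect_equal(win$values[1:7], sliding_entropy(x, 128, entropy_config(), "PE"),
               ignore_attr = TRUE)
  # purity: identical inputs give identical vectors
  expect_identical(win$values,
                   build_mefc(x, 128, entropy_config(), "FP2", "theta")$values)
  # errors carry channel/band context
  expect_error(build_mefc(rep(1, 1024), 128,
                          entropy_config(mode = "scalar"), "FP2", "delta"),
               "FP2.*delta")
})
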