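# Shared small-cohort builders so individual tests stay cheap.

small_cohort <- function(seed = 1L, separation = 1, n = 4L,
                         duration_s = 8, channels = c("FP1", "FP2")) {
  spec <- cohort_spec(n_per_class = c(AD = n, FTD = n, HC = n),
                      duration_s = duration_s, channels = channels,
                      seed = seed, separation = separation)
  generate_cohort(spec)$records
}

# Well-separated synthetic feature matrix: three tight clusters.
separable_features <- function(n_per_class = 10L, p = 21L, seed = 99L) {
  set.seed(seed)
  centers <- list(AD = rep(c(1, 5, 2), length.out = p),
                  FTD = rep(c(4, 1, 6), length.out = p),
                  HC = rep(c(7, 3, 1), length.out = p))
  X <- do.call(rbind, lapply(names(centers), function(cl)
    matrix(rep(centers[[cl]], n_per_class), nrow = n_per_class,
           byrow = TRUE) + matrix(rnorm(n_per_class * p, 0, 0.05),
                                  n_per_class)))
  list(X = X, labels = rep(names(centers), each = n_per_class))
}
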