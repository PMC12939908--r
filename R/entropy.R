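#' Entropy and feature-vector settings
#'
#' Collects every tunable of the per-rhythm entropy features. Defaults
#' follow common practice where the method itself fixes no value:
#' permutation entropy with order 3 / delay 1 (the smallest order giving
#' six ordinal patterns, robust on short windows); sample entropy with
#' embedding dimension 2 and tolerance 0.15 standard deviations
#' (the method's fixed choices); singular-spectrum window
#' `min(floor(N/2), 20)` so the `ln L` ceiling is comparable across 8 s
#' and 30 s inputs.
#'
#' @param pe_order ordinal-pattern embedding dimension (>= 2).
#' @param pe_delay ordinal-pattern lag in samples.
#' @param se_m sample-entropy embedding dimension.
#' @param se_r_factor sample-entropy tolerance as a multiple of the series
#'   standard deviation.
#' @param sse_embed_len singular-spectrum window length `L`, or `NULL` for
#'   the adaptive default `min(floor(N/2), 20)`.
#' @param window_s sliding-window length in seconds (windowed mode).
#' @param step_s sliding-window step in seconds; must not exceed
#'   `window_s`.
#' @param mode `"windowed"` (entropy trajectories, the classifier default)
#'   or `"scalar"` (one value per entropy per rhythm).
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(pe_order = 3L, pe_delay = 1L, se_m = 2L,
                           se_r_factor = 0.15, sse_embed_len = NULL,
                           window_s = 2, step_s = 1,
                           mode = c("windowed", "scalar")) {
  mode <- match.arg(mode)
  if (pe_order < 2L) stop("`pe_order` must be >= 2")
  if (pe_delay < 1L) stop("`pe_delay` must be >= 1")
  if (se_m < 1L) stop("`se_m` must be >= 1")
  if (se_r_factor <= 0) stop("`se_r_factor` must be positive")
  if (step_s <= 0 || window_s < step_s)
    stop("need `window_s` >= `step_s` > 0")
  if (!is.null(sse_embed_len) && sse_embed_len < 2L)
    stop("`sse_embed_len` must be >= 2")
  structure(list(pe_order = as.integer(pe_order),
                 pe_delay = as.integer(pe_delay),
                 se_m = as.integer(se_m), se_r_factor = se_r_factor,
                 sse_embed_len = sse_embed_len,
                 window_s = window_s, step_s = step_s, mode = mode),
            class = "entropy_config")
}

sse_default_L <- function(n) min(n %/% 2L, 20L)

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of
#' rank-order patterns over consecutive `(order, delay)` embedding
#' windows. Ties within a window are broken by stable earlier-index-first
#' ranking, making the symbolization deterministic. No normalization is
#' applied, so the result lies in `[0, ln(order!)]`.
#'
#' @param x numeric vector.
#' @param order embedding dimension (>= 2).
#' @param delay lag between embedded samples.
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  n_pat <- n - (order - 1L) * delay
  if (n_pat < 2L)
    stop("validation error: series of length ", n, " too short for order ",
         order, ", delay ", delay, " (needs >= ",
         (order - 1L) * delay + 2L, " samples)")
  # columns of E are the lagged copies; rank within each row with
  # earlier-index-first tie handling, encoded in base `order`
  E <- matrix(0, n_pat, order)
  for (k in seq_len(order))
    E[, k] <- x[(1L + (k - 1L) * delay):(n_pat + (k - 1L) * delay)]
  code <- numeric(n_pat)
  for (i in seq_len(order)) {
    r_i <- numeric(n_pat)               # rank_i - 1
    for (j in seq_len(order)) {
      if (j == i) next
      r_i <- r_i + (E[, j] < E[, i])
      if (j < i) r_i <- r_i + (E[, j] == E[, i])
    }
    code <- code + r_i * order^(i - 1L)
  }
  p <- tabulate(code + 1L, nbins = order^order)
  p <- p[p > 0] / n_pat
  -sum(p * log(p))
}

#' Sample entropy
#'
#' `-ln(B_{m+1} / B_m)`, where `B_k` counts ordered pairs (i != j) of
#' k-length embedding vectors within Chebyshev distance
#' r (`r_factor * sd(x)`), self-matches excluded. A lower value reflects
#' a loss of complex variability (more self-similar, regular dynamics).
#'
#' @param x numeric vector with strictly positive standard deviation.
#' @param m embedding dimension (the method fixes 2).
#' @param r_factor tolerance as a multiple of `sd(x)` (the method fixes
#'   0.15).
#' @return Entropy in nats. Degenerate inputs raise classed errors:
#'   constant series (`sd == 0`) a `mefc_degenerate_input` error, and
#'   `B_{m+1} == 0` a `mefc_undefined_entropy` error reporting the counts.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.15) {
  n <- length(x)
  if (n < m + 2L)
    stop("validation error: need at least m + 2 = ", m + 2L, " samples")
  sigma <- sd(x)
  if (!is.finite(sigma) || sigma <= 0)
    stop(errorCondition(
      "degenerate input: constant series (sd = 0) has undefined sample entropy",
      class = c("mefc_degenerate_input", "error")))
  counts <- sampen_counts(as.numeric(x), as.integer(m), r_factor * sigma)
  b_m <- counts[1]; b_m1 <- counts[2]
  if (b_m1 == 0 || b_m == 0)
    stop(errorCondition(
      sprintf("undefined sample entropy: B_m = %.0f, B_{m+1} = %.0f (no matching pairs)",
              b_m, b_m1),
      class = c("mefc_undefined_entropy", "error")))
  -log(b_m1 / b_m)
}

#' Singular spectrum entropy
#'
#' Builds the `L x (N - L + 1)` Hankel trajectory matrix of the series,
#' takes its singular values, normalizes the squared singular values to
#' an energy distribution, and returns its Shannon entropy (natural log).
#' Concentrated energy (few dominant temporal modes) gives low values;
#' a flat singular spectrum approaches `ln L`.
#'
#' @param x numeric vector.
#' @param L trajectory window length, `2 <= L <= floor(N/2)`; default
#'   `min(floor(N/2), 20)`.
#' @return Entropy in nats, in `[0, ln L]`. Zero singular values
#'   contribute nothing (`0 ln 0 := 0`).
#' @export
singular_spectrum_entropy <- function(x, L = NULL) {
  n <- length(x)
  if (is.null(L)) L <- sse_default_L(n)
  if (L < 2L || L > n %/% 2L)
    stop("validation error: need 2 <= L <= floor(N/2); got L = ", L,
         " with N = ", n)
  K <- n - L + 1L
  traj <- matrix(0, L, K)
  for (i in seq_len(L)) traj[i, ] <- x[i:(i + K - 1L)]
  sv <- svd(traj, nu = 0L, nv = 0L)$d
  # standard numerical-rank tolerance: singular values below it are noise
  sv[sv < max(sv) * max(dim(traj)) * .Machine$double.eps] <- 0
  e <- sv^2
  tot <- sum(e)
  if (tot == 0) return(0)
  rho <- e[e > 0] / tot
  -sum(rho * log(rho))
}

#' Sliding-window entropy trajectory
#'
#' Evaluates one entropy over consecutive windows of
#' `round(window_s * fs)` samples advancing by `round(step_s * fs)`,
#' producing the entropy time series that the trajectory-based similarity
#' measures (DTW, WC, HTC) operate on. Windows are self-contained: the
#' sample-entropy tolerance uses each window's own standard deviation.
#'
#' Windows where sample entropy is degenerate (constant window, or no
#' matching template pairs) are imputed with the maximum finite value
#' observed in the same series and flagged via the `"imputed"` attribute
#' and a message; fabricating zeros would instead claim "perfectly
#' regular" for windows the statistic cannot assess.
#'
#' @param x numeric vector (one rhythm series).
#' @param fs sampling rate in Hz.
#' @param cfg an [entropy_config].
#' @param which `"PE"`, `"SE"` or `"SSE"`.
#' @return Numeric vector of length `1 + floor((N - W) / S)`, with
#'   attribute `imputed` listing any imputed window indices.
#' @export
sliding_entropy <- function(x, fs, cfg = entropy_config(),
                            which = c("PE", "SE", "SSE")) {
  which <- match.arg(which)
  W <- round(cfg$window_s * fs)
  S <- round(cfg$step_s * fs)
  n <- length(x)
  if (W > n)
    stop("validation error: window of ", W, " samples exceeds series length ",
         n)
  n_win <- 1L + (n - W) %/% S
  vals <- numeric(n_win)
  degenerate <- integer(0)
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1L) * S + 1L):((w - 1L) * S + W)]
    vals[w] <- switch(which,
      PE  = permutation_entropy(seg, cfg$pe_order, cfg$pe_delay),
      SSE = singular_spectrum_entropy(seg, cfg$sse_embed_len %||%
                                        sse_default_L(W)),
      SE  = tryCatch(sample_entropy(seg, cfg$se_m, cfg$se_r_factor),
                     mefc_degenerate_input = function(e) NA_real_,
                     mefc_undefined_entropy = function(e) NA_real_))
    if (is.na(vals[w])) degenerate <- c(degenerate, w)
  }
  if (length(degenerate)) {
    if (all(is.na(vals)))
      stop("validation error: ", which,
           " undefined on every window of the series")
    vals[degenerate] <- max(vals, na.rm = TRUE)
    message("sliding ", which, ": imputed ", length(degenerate),
            " degenerate window(s) at index ",
            paste(degenerate, collapse = ", "))
    attr(vals, "imputed") <- degenerate
  }
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the multi-entropy feature vector for one rhythm
#'
#' Concatenates permutation, sample, and singular-spectrum entropy — in
#' that fixed order — computed on one rhythm of one channel. In scalar
#' mode the vector has length 3 (`[PE, SE, SSE]`); in windowed mode it is
#' the concatenation of the three sliding-window trajectories, each of
#' length `n_windows`.
#'
#' @param rhythm numeric vector, one reconstructed band signal.
#' @param fs sampling rate in Hz.
#' @param cfg an [entropy_config].
#' @param channel channel name recorded in the result.
#' @param band rhythm name recorded in the result.
#' @return An object of class `mefc_vector`: list with `channel`,
#'   `rhythm`, `values` (finite numeric vector), `mode`, `n_windows`.
#' @export
build_mefc <- function(rhythm, fs, cfg = entropy_config(),
                       channel = "NA", band = "NA") {
  res <- tryCatch(
    if (cfg$mode == "scalar") {
      list(values = c(
             permutation_entropy(rhythm, cfg$pe_order, cfg$pe_delay),
             sample_entropy(rhythm, cfg$se_m, cfg$se_r_factor),
             singular_spectrum_entropy(rhythm, cfg$sse_embed_len %||%
                                         sse_default_L(length(rhythm)))),
           n_windows = 1L)
    } else {
      pe  <- sliding_entropy(rhythm, fs, cfg, "PE")
      se  <- sliding_entropy(rhythm, fs, cfg, "SE")
      sse <- sliding_entropy(rhythm, fs, cfg, "SSE")
      list(values = c(pe, se, sse), n_windows = length(pe))
    },
    error = function(e) {
      e$message <- paste0("[channel ", channel, ", rhythm ", band, "] ",
                          conditionMessage(e))
      stop(e)
    })
  stopifnot(all(is.finite(res$values)))
  structure(list(channel = channel, rhythm = band, values = res$values,
                 mode = cfg$mode, n_windows = res$n_windows),
            class = "mefc_vector")
}

#' @export
print.mefc_vector <- function(x, ...) {
  cat(sprintf("<mefc_vector> channel %s, rhythm %s, %s mode: %d values",
              x$channel, x$rhythm, x$mode, length(x$values)))
  if (x$mode == "windowed") cat(sprintf(" (3 x %d windows)", x$n_windows))
  cat("\n")
  invisible(x)
}
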