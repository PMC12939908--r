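# Independent brute-force references. These deliberately share no code
# with the package implementations: pattern enumeration for permutation
# entropy, O(n^2) double-loop pair counting for sample entropy, direct
# Hankel assembly for singular-spectrum entropy, exhaustive alignment-path
# recursion for DTW, and time-domain double-loop CWT for coherence.

pe_oracle <- function(x, order = 3, delay = 1) {
  n_pat <- length(x) - (order - 1) * delay
  pats <- character(n_pat)
  for (i in seq_len(n_pat)) {
    w <- x[seq(i, by = delay, length.out = order)]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = "")
  }
  p <- as.numeric(table(pats)) / n_pat
  -sum(p * log(p))
}

sampen_oracle <- function(x, m = 2, r_factor = 0.15) {
  n <- length(x)
  r <- r_factor * sd(x)
  count_pairs <- function(k) {
    nv <- n - k + 1
    E <- sapply(seq_len(k), function(c) x[(c):(nv + c - 1)])
    cnt <- 0
    for (i in seq_len(nv - 1)) {
      idx <- (i + 1):nv
      d <- abs(E[idx, 1] - E[i, 1])
      for (c in seq_len(k)[-1]) d <- pmax(d, abs(E[idx, c] - E[i, c]))
      cnt <- cnt + 2 * sum(d <= r)   # ordered pairs: both directions
    }
    cnt
  }
  b_m <- count_pairs(m)
  b_m1 <- count_pairs(m + 1)
  if (b_m == 0 || b_m1 == 0) return(NA_real_)
  -log(b_m1 / b_m)
}

sse_oracle <- function(x, L) {
  n <- length(x)
  K <- n - L + 1
  H <- outer(seq_len(L), seq_len(K) - 1, function(i, j) x[i + j])
  sv <- svd(H)$d
  sv[sv < max(sv) * max(L, K) * .Machine$double.eps] <- 0
  e <- sv^2 / sum(sv^2)
  e <- e[e > 0]
  -sum(e * log(e))
}

# Exhaustive minimum over all monotone alignment paths (no memoization;
# exponential, for short sequences only).
dtw_oracle <- function(a, b) {
  walk <- function(i, j) {
    d <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(d)
    best <- Inf
    if (i > 1) best <- min(best, walk(i - 1, j))
    if (j > 1) best <- min(best, walk(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, walk(i - 1, j - 1))
    d + best
  }
  walk(length(a), length(b))
}

pcc_oracle <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
  num / den
}

# Direct time-domain CWT + global-smoothing coherence, scale by scale.
wc_oracle <- function(a, b, scales = seq(1, 10, by = 0.5),
                      bandwidth = 1, center = 1.5) {
  n <- length(a)
  cwt1 <- function(x, s) {
    hw <- ceiling(6 * s * sqrt(bandwidth))
    W <- complex(length.out = n)
    for (nn in seq_len(n)) {
      acc <- 0 + 0i
      for (t in max(1, nn - hw):min(n, nn + hw)) {
        u <- (t - nn) / s
        psi <- (pi * bandwidth)^(-0.5) *
          exp(2i * pi * center * u) * exp(-u^2 / bandwidth)
        acc <- acc + x[t] * Conj(psi)
      }
      W[nn] <- acc / sqrt(s)
    }
    W
  }
  r2 <- vapply(scales, function(s) {
    Wa <- cwt1(a, s); Wb <- cwt1(b, s)
    Mod(mean(Wa * Conj(Wb)))^2 / (mean(Mod(Wa)^2) * mean(Mod(Wb)^2))
  }, 0)
  mean(r2)
}
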