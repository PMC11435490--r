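# Independent brute-force oracles and small simulators used across tests.
# These deliberately avoid the package's compiled code paths.

# logistic map (r = 4), transient removed
logistic_series <- function(n, x0 = 0.4, burn = 100L) {
  x <- x0
  out <- numeric(n)
  for (i in seq_len(n + burn)) {
    x <- 4 * x * (1 - x)
    if (i > burn) out[i - burn] <- x
  }
  out
}

# Lorenz x-component, RK4, standard parameters, transient removed
lorenz_series <- function(n, dt = 0.01, burn = 3000L) {
  s <- c(1, 1, 1)
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - 8 / 3 * s[3])
  out <- numeric(n)
  for (i in seq_len(n + burn)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > burn) out[i - burn] <- s[1]
  }
  out
}

# plain-R delay embedding
embed_oracle <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  X <- matrix(0, n, m)
  for (j in seq_len(m)) X[, j] <- x[(1:n) + (j - 1) * tau]
  X
}

# brute-force Rosenstein divergence curve + slope: all-pairs neighbour
# search in nested loops, no spatial indexing, mirroring the documented
# pair rules (Theiler exclusion, distances above the numerical floor)
rosenstein_oracle <- function(x, tau, m, theiler, fit_offsets) {
  d_floor <- 1e-9 * stats::sd(x)
  X <- embed_oracle(x, m, tau)
  n <- nrow(X)
  nn <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (abs(i - j) <= theiler) next
      d2 <- sum((X[i, ] - X[j, ])^2)
      if (d2 < best) { best <- d2; bj <- j }
    }
    nn[i] <- bj
  }
  kmax <- max(fit_offsets)
  curve <- rep(NA_real_, kmax + 1)
  for (k in 0:kmax) {
    acc <- 0; cnt <- 0
    for (i in seq_len(n)) {
      j <- nn[i]
      if (is.na(j) || i + k > n || j + k > n) next
      d <- sqrt(sum((X[i + k, ] - X[j + k, ])^2))
      if (d > d_floor) { acc <- acc + log(d); cnt <- cnt + 1 }
    }
    if (cnt > 0) curve[k + 1] <- acc / cnt
  }
  y <- curve[fit_offsets + 1]
  ok <- is.finite(y)
  kk <- fit_offsets[ok]; y <- y[ok]
  sum((kk - mean(kk)) * (y - mean(y))) / sum((kk - mean(kk))^2)
}

# brute-force AMI scan with the same equiprobable-binning estimator,
# written independently
ami_oracle <- function(x, k) {
  n <- length(x) - k
  nb <- ceiling(sqrt(length(x) / 5))
  qs <- stats::quantile(x, seq(0, 1, length.out = nb + 1), names = FALSE)
  qs <- unique(qs); qs[1] <- -Inf; qs[length(qs)] <- Inf
  a <- cut(x[1:n], qs); b <- cut(x[(k + 1):(k + n)], qs)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  tot <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      tot <- tot + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  as.numeric(tot)
}

# small synthetic walk used by many tests
test_walk <- function(seed = 5, ...) {
  spec <- synthetic_spec(seed = seed, ...)
  generate_trace(spec)
}
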