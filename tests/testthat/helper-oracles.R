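# Independent naive reference implementations used as oracles.  These use
# explicit loops over points and pairs only, sharing no code with the
# package implementations.

naive_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

naive_indices <- function(x, labels) {
  n <- nrow(x); k <- max(labels) + 1
  cent <- matrix(0, k, ncol(x))
  for (c in 0:(k - 1)) cent[c + 1, ] <- colMeans(x[labels == c, , drop = FALSE])
  grand <- colMeans(x)
  ssw <- 0; ssb <- 0
  for (i in 1:n) ssw <- ssw + sum((x[i, ] - cent[labels[i] + 1, ])^2)
  for (c in 0:(k - 1)) ssb <- ssb + sum(labels == c) * sum((cent[c + 1, ] - grand)^2)
  # all pairwise distances with a same-cluster flag
  dists <- c(); same <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dists <- c(dists, sqrt(sum((x[i, ] - x[j, ])^2)))
    same <- c(same, labels[i] == labels[j])
  }
  minsep <- Inf
  for (a in 1:(k - 1)) for (b in (a + 1):k)
    minsep <- min(minsep, sum((cent[a, ] - cent[b, ])^2))
  nw <- sum(same)
  ds <- sort(dists)
  s_within <- sum(dists[same])
  list(
    xie_beni = ssw / (n * minsep),
    calinski_harabasz = (ssb / (k - 1)) / (ssw / (n - k)),
    c_index = (s_within - sum(ds[1:nw])) /
      (sum(ds[(length(ds) - nw + 1):length(ds)]) - sum(ds[1:nw])),
    hartigan = log(ssb / ssw),
    dunn = min(dists[!same]) / max(dists[same]),
    mclain_rao = mean(dists[same]) / mean(dists[!same])
  )
}

# Random clustered instance guaranteed to have >= 2 points per cluster.
random_instance <- function(n = 40, d = 3, k = 3) {
  labels <- c(rep(0:(k - 1), 2), sample(0:(k - 1), n - 2 * k, replace = TRUE))
  x <- matrix(rnorm(n * d), n, d) + 2.5 * matrix(rnorm(k * d), k, d)[labels + 1, ]
  list(x = x, labels = labels)
}
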