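# Independent brute-force oracles used across the suite.

# pseudo-positional block straight from the defining sums (double loop)
brute_pserecm <- function(profile, lambda) {
  L <- nrow(profile)
  means <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in 1:L) s <- s + profile[i, j]
    means[j] <- s / L
  }
  gs <- numeric(20 * lambda)
  for (l in seq_len(lambda)) {
    for (j in 1:20) {
      s <- 0
      for (i in seq_len(L - l)) s <- s + (profile[i, j] - profile[i + l, j])^2
      gs[(l - 1) * 20 + j] <- s / (L - l)
    }
  }
  c(means, gs)
}

# all-pairs Mann-Whitney AUC with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# direct cosine-sum DCT-II (unnormalised), evaluated term by term
brute_dct2 <- function(x, k) {
  n <- length(x)
  vapply(seq_len(k) - 1, function(kk) {
    s <- 0
    for (i in seq_len(n) - 1)
      s <- s + x[i + 1] * cos(pi * kk * (2 * i + 1) / (2 * n))
    2 * s
  }, 0.0)
}

# dataset with one informative feature (column 1 tracks the label) among noise
make_planted <- function(n = 120, d = 50, seed = 1, noise = 0.3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- y + rnorm(n, sd = noise)
  list(X = X, y = y)
}

# random validated protein sequence of a given length
random_sequence <- function(L) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               L, replace = TRUE), collapse = "")
}
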