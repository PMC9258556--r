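# Independent oracles used across the suite.

# Brute-force dynamic-programming Levenshtein distance (unit costs),
# written independently of the package's matcher.
dp_levenshtein <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in 1:na) {
    cur <- c(i, rep(0L, nb))
    for (j in 1:nb) {
      cost <- if (A[i] == B[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1]
}

# Naive double-loop VanRaden GRM oracle.
grm_oracle <- function(X, p) {
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  n <- nrow(X); m <- ncol(X)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in 1:m) s <- s + (X[i, k] - 2 * p[k]) * (X[j, k] - 2 * p[k])
    G[i, j] <- s / denom
  }
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

# Random plausible germplasm-style name.
random_name <- function(len = sample(3:12, 1)) {
  paste(sample(c(LETTERS, 0:9, " ", ".", "-", "_", "/"), len, replace = TRUE),
        collapse = "")
}
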