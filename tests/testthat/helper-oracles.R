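# Independent brute-force oracles used to check the implementation.

# Pearson correlation of two vectors from the explicit sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Sample-correlation matrix by an explicit double loop over column pairs.
oracle_corr_matrix <- function(v) {
  n <- ncol(v)
  f <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    f[i, j] <- oracle_pearson(v[, i], v[, j])
  }
  f
}

# Adjusted Rand Index by explicit enumeration of sample pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (n11 - expected) / (maxi - expected)
}

# RDC by explicit enumeration of all sample pairs.
oracle_rdc <- function(pts, labels) {
  n <- nrow(pts)
  win <- c(); btw <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (labels[i] == labels[j]) win <- c(win, dij) else btw <- c(btw, dij)
  }
  mean(win) / mean(btw)
}

# Random ExpressionMatrix with unique identifiers.
random_expr <- function(m, n, seed = 1, nonneg = FALSE) {
  set.seed(seed)
  v <- matrix(rnorm(m * n), m, n)
  if (nonneg) v <- exp(v)
  expression_matrix(v, paste0("g", seq_len(m)), paste0("s", seq_len(n)))
}

# Mean within-cluster minus mean between-cluster entry of a similarity
# matrix (upper triangle only).
similarity_contrast <- function(f, labels) {
  same <- outer(labels, labels, "==")
  up <- upper.tri(f)
  mean(f[up & same]) - mean(f[up & !same])
}
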