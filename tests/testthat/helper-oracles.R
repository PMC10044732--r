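# Independent oracles used to cross-check the package implementations.
# They deliberately share no code with the functions they verify.

# quadratic-weighted kappa by explicit double loop over the k x k table
kappa_oracle <- function(x, y, categories) {
  k <- length(categories)
  n <- length(x)
  O <- matrix(0, k, k)
  for (r in seq_len(n)) {
    i <- match(x[r], categories)
    j <- match(y[r], categories)
    O[i, j] <- O[i, j] + 1 / n
  }
  pr <- rowSums(O)
  pc <- colSums(O)
  num <- 0
  den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- (i - j)^2
      num <- num + w * O[i, j]
      den <- den + w * pr[i] * pc[j]
    }
  }
  1 - num / den
}

# mid-rank Spearman via explicit rank-then-Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# 0..8 interval assignment by looping over the 9 intervals
interval_oracle <- function(value, lo, hi) {
  width <- (hi - lo) / 9
  if (value >= hi) return(8L)
  if (value <= lo) return(0L)
  for (i in 0:8) {
    if (value >= lo + i * width && value < lo + (i + 1) * width) return(i)
  }
  8L
}

# logistic MLE by Newton-Raphson on the Bernoulli log-likelihood
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - p))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}
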