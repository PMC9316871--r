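# Independent oracles used across the suite. Each one recomputes a quantity
# from first principles along a different code path than the package.

# A small random regression problem as a tibble with known truth.
random_problem <- function(n, p, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%d", seq_len(p))))
  beta <- rnorm(p)
  y <- drop(x %*% beta) + 0.2 + rnorm(n, 0, noise_sd)
  out <- tibble::as_tibble(as.data.frame(x))
  out$teac <- y
  out
}

# Least squares through the Moore-Penrose pseudoinverse (SVD), no QR.
pinv_coefficients <- function(x, y) {
  z <- cbind(1, x)
  sv <- svd(z)
  drop(sv$v %*% ((t(sv$u) %*% y) / sv$d))
}

# Leave-one-out predictions by literally refitting n times.
brute_loo_predictions <- function(x, y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    zi <- cbind(1, x[-i, , drop = FALSE])
    beta <- qr.solve(zi, y[-i])
    drop(c(1, x[i, ]) %*% beta)
  }, numeric(1))
}

# Lin's concordance correlation, transcribed term by term from the moment
# form (biased n-denominator variances/covariance).
lin_ccc_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Eigenvalue-dispersion K index computed directly.
k_index_oracle <- function(x) {
  p <- ncol(x)
  if (p == 1) return(0)
  lam <- eigen(cor(x), symmetric = TRUE)$values
  lam <- pmax(lam, 0) / sum(pmax(lam, 0))
  sum(abs(lam - 1 / p)) / (2 * (p - 1) / p)
}

# Explicit hat matrix Z (Z'Z)^-1 Z'.
hat_matrix_oracle <- function(x) {
  z <- cbind(1, x)
  diag(z %*% solve(crossprod(z)) %*% t(z))
}
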