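# Fixtures are generated in code; nothing is stored on disk.

# the standard evaluation phantom: 128 px, 3 tissue regions, 8 px lesion
standard_phantom <- function(seed = 0) make_phantom(128, 3, 8, seed = seed)

small_phantom <- function(seed = 0) make_phantom(64, 2, 6, seed = seed)

# two well-separated Gaussian classes in D dimensions (columns = samples)
two_class_data <- function(n_per = 500, D = 8, sep = 10, seed = 42) {
  withr::with_seed(seed, {
    X <- cbind(matrix(stats::rnorm(n_per * D, 0), D),
               matrix(stats::rnorm(n_per * D, sep), D))
    list(X = X, labels = rep(1:2, each = n_per),
         mu = cbind(rep(0, D), rep(sep, D)))
  })
}

# random low-rank + noise cluster matrix for shrinkage comparisons
lowrank_plus_noise <- function(m = 6, d = 12, r = 2, sv = c(10, 5), sigma = 0.3) {
  L <- matrix(stats::rnorm(m * r), m) %*% diag(sv, r) %*%
    (matrix(stats::rnorm(r * d), r) / sqrt(d))
  list(L = L, P = L + matrix(stats::rnorm(m * d, 0, sigma), m), sigma = sigma)
}

# projected gradient descent on the spectral form of the cluster energy:
# minimise tau * sum(q) + (1/sigma^2) * sum((s - q)^2) over q >= 0.
# Independent of the closed-form soft threshold.
pgd_spectral_minimiser <- function(s, tau, sigma, iters = 2000) {
  q <- s
  step <- sigma^2 / 4  # Lipschitz constant of the data term is 2/sigma^2
  for (k in seq_len(iters)) {
    grad <- tau - (2 / sigma^2) * (s - q)
    q <- pmax(q - step * grad, 0)
  }
  q
}
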