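test_that("class log-density matches hand-computed Gaussian values", {
  # univariate: mu = 0, Sigma = 1, x = 2 -> -log(sqrt(2*pi)) - 2
  pr1 <- gmm_prior(1, matrix(0, 1, 1), array(1, c(1, 1, 1)))
  expect_equal(class_density(2, 1, pr1), -0.5 * log(2 * pi) - 2)

  # at the mean the exponent vanishes: log c = -1/2 log((2*pi)^D |Sigma|)
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  pr2 <- gmm_prior(1, matrix(c(3, -1), 2, 1), array(S, c(2, 2, 1)))
  expect_equal(class_density(c(3, -1), 1, pr2),
               -0.5 * log((2 * pi)^2 * det(S)))
})

test_that("noise inflation can only lower the density at the mean", {
  S <- diag(c(1, 2, 3))
  pr <- gmm_prior(1, matrix(0, 3, 1), array(S, c(3, 3, 1)))
  d0 <- class_density(rep(0, 3), 1, pr, sigma_noise = 0)
  d1 <- class_density(rep(0, 3), 1, pr, sigma_noise = 1)
  d2 <- class_density(rep(0, 3), 1, pr, sigma_noise = 2)
  expect_gt(d0, d1)
  expect_gt(d1, d2)
})

test_that("a single-class fit reduces to the sample mean and ML covariance", {
  withr::with_seed(1, X <- matrix(rnorm(50 * 3, 2, 1.5), 3))
  pr <- fit_gmm_prior(X, H = 1, seed = 0, remove_dc = FALSE)
  n <- ncol(X)
  expect_equal(pr$w, 1)
  expect_equal(pr$mu[, 1], rowMeans(X))
  S_ml <- stats::cov(t(X)) * (n - 1) / n
  expect_equal(pr$sigma[, , 1], S_ml + diag(pr$eps_reg, 3),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("EM recovers a well-separated two-class mixture", {
  d <- two_class_data()
  pr <- fit_gmm_prior(d$X, H = 2, seed = 1, remove_dc = FALSE)
  ord <- order(colMeans(pr$mu))
  expect_lt(max(abs(pr$mu[, ord[1]] - d$mu[, 1])), 0.2)
  expect_lt(max(abs(pr$mu[, ord[2]] - d$mu[, 2])), 0.2)
  expect_lt(max(abs(pr$w - 0.5)), 0.05)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(d$labels, pr$train_labels), 0.95)
})

test_that("EM log-likelihood is non-decreasing and the fit is deterministic", {
  ph <- small_phantom(0)
  ps <- extract_patches(ph$image, 4, 4)
  for (seed in 1:5) {
    pr <- fit_gmm_prior(ps, H = 3, seed = seed)
    expect_true(all(diff(pr$loglik_trace) >=
                      -1e-9 * abs(pr$loglik_trace[-length(pr$loglik_trace)])))
  }
  a <- fit_gmm_prior(ps, H = 3, seed = 7)
  b <- fit_gmm_prior(ps, H = 3, seed = 7)
  expect_identical(a$mu, b$mu)
  expect_identical(a$sigma, b$sigma)
  expect_identical(a$w, b$w)
})

test_that("responsibilities are a proper posterior", {
  ph <- small_phantom(1)
  ps <- extract_patches(ph$image, 4, 4)
  pr <- fit_gmm_prior(ps, H = 4, seed = 0)
  asn <- assign_clusters(ps, pr, sigma_noise = 3)
  expect_equal(rowSums(asn$responsibilities), rep(1, length(asn$labels)),
               tolerance = 1e-8)
  expect_equal(asn$labels, max.col(asn$responsibilities, ties.method = "first"))
})

test_that("assignment with zero noise reproduces the final EM responsibilities", {
  ph <- small_phantom(2)
  ps <- extract_patches(ph$image, 4, 4)
  pr <- fit_gmm_prior(ps, H = 3, seed = 0)
  asn <- assign_clusters(ps, pr, sigma_noise = 0)
  expect_equal(asn$responsibilities, pr$train_resp, tolerance = 1e-12)
  expect_equal(asn$labels, pr$train_labels)
})

test_that("single-class assignment is trivial and separation saturates", {
  pr1 <- gmm_prior(1, matrix(0, 2, 1), array(diag(2), c(2, 2, 1)))
  asn <- assign_clusters(matrix(rnorm(20), 2), pr1)
  expect_true(all(asn$labels == 1))
  expect_true(all(asn$responsibilities == 1))

  mu <- cbind(rep(0, 2), rep(50, 2))
  pr2 <- gmm_prior(c(0.5, 0.5), mu, array(diag(2), c(2, 2, 2)))
  asn2 <- assign_clusters(matrix(mu[, 1], 2, 1), pr2, sigma_noise = 1)
  expect_gt(asn2$responsibilities[1, 1], 0.99)
})

test_that("permuting the classes permutes labels identically", {
  d <- two_class_data(n_per = 50, seed = 9)
  pr <- fit_gmm_prior(d$X, H = 2, seed = 0, remove_dc = FALSE)
  perm <- c(2, 1)
  pr_perm <- gmm_prior(pr$w[perm], pr$mu[, perm], pr$sigma[, , perm],
                       remove_dc = FALSE)
  a <- assign_clusters(d$X, pr, sigma_noise = 0.5)
  b <- assign_clusters(d$X, pr_perm, sigma_noise = 0.5)
  expect_equal(b$labels, perm[a$labels])
  expect_equal(b$loglik, a$loglik)
})

test_that("fitted priors agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  d <- two_class_data(n_per = 200, D = 4, sep = 6, seed = 5)
  pr <- fit_gmm_prior(d$X, H = 2, seed = 1, remove_dc = FALSE)
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the calling frame
  mc <- mclust::Mclust(t(d$X), G = 2, modelNames = "VVV", verbose = FALSE)
  ord_own <- order(colMeans(pr$mu))
  ord_mc <- order(colMeans(mc$parameters$mean))
  expect_equal(pr$mu[, ord_own], mc$parameters$mean[, ord_mc],
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(sort(pr$w), sort(mc$parameters$pro), tolerance = 0.02)
})

test_that("prior serialisation round-trips through JSON", {
  ph <- small_phantom(3)
  pr <- fit_gmm_prior(extract_patches(ph$image, 4, 4), H = 2, seed = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_prior(pr, path)
  back <- read_prior(path)
  expect_equal(back$w, pr$w)
  expect_equal(back$mu, pr$mu)
  expect_equal(back$sigma, pr$sigma)
  expect_equal(back$remove_dc, pr$remove_dc)
  asn1 <- assign_clusters(extract_patches(ph$image, 4, 4), pr, 2)
  asn2 <- assign_clusters(extract_patches(ph$image, 4, 4), back, 2)
  expect_equal(asn1$labels, asn2$labels)
})

test_that("tidy and glance summarise a fitted prior", {
  ph <- small_phantom(4)
  pr <- fit_gmm_prior(extract_patches(ph$image, 4, 4), H = 3, seed = 0)
  td <- tidy(pr)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight), 1, tolerance = 1e-10)
  gl <- glance(pr)
  expect_equal(gl$H, 3)
  expect_true(is.finite(gl$loglik))
})
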