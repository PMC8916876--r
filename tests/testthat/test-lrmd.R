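test_that("the cluster energy matches hand evaluation", {
  P <- diag(c(3, 4))
  expect_equal(lrmd_energy(diag(c(1, 1)), P, tau = 1, sigma = 1), 15)  # 2 + 13
  expect_equal(lrmd_energy(P, P, tau = 2, sigma = 3), 2 * 7)   # zero residual
  expect_equal(lrmd_energy(P * 0, P, tau = 1, sigma = 2), 25 / 4)  # zero Q
  expect_error(lrmd_energy(diag(2), diag(3), 1, 1), "shapes")
})

test_that("svt soft-thresholds the spectrum at tau * sigma^2 / 2", {
  res <- svt_denoise(diag(c(5, 1)), tau = 4, sigma = 1)  # lambda = 2
  expect_equal(res$Q, diag(c(3, 0)), tolerance = 1e-12)
  expect_equal(res$singular_values_after, c(3, 0))

  # tau -> 0: no regularisation, identity
  P <- matrix(rnorm(24), 4)
  expect_equal(svt_denoise(P, 0, 1)$Q, P, tolerance = 1e-12)
  # threshold above the largest singular value: everything shrinks to zero
  expect_equal(svt_denoise(diag(c(2, 1)), tau = 10, sigma = 1)$Q,
               matrix(0, 2, 2))
})

test_that("svt is optimal in its spectral coordinates (projected gradient oracle)", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      P <- matrix(rnorm(48), 6, 8)
      tau <- runif(1, 0.2, 3); sigma <- runif(1, 0.3, 1.5)
      res <- svt_denoise(P, tau, sigma)
      q_star <- pgd_spectral_minimiser(res$singular_values_before, tau, sigma)
      expect_equal(res$singular_values_after, q_star, tolerance = 1e-8)
    }
  })
})

test_that("shrinkage conserves Pbar = Q + T and never grows the spectrum", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      P <- matrix(rnorm(60), 6, 10)
      for (res in list(svt_denoise(P, 1.3, 0.7), wnnm_denoise(P, 0.7))) {
        expect_lt(max(abs(res$Q + res$T - P)), 1e-10)
        expect_true(all(res$singular_values_after <=
                          res$singular_values_before + 1e-12))
        expect_lte(sum(res$singular_values_after),
                   sum(res$singular_values_before))
      }
    }
  })
})

test_that("wnnm preserves a dominant singular value and kills the rest", {
  u <- rep(1, 8) / sqrt(8)
  v <- rep(1, 12) / sqrt(12)
  P <- 100 * u %*% t(v)                      # rank 1, s1 = 100
  sigma <- 0.5                               # C sqrt(d) sigma^2 = 2.42 << 100
  res <- wnnm_denoise(P, sigma)
  s <- res$singular_values_after
  expect_lt(abs(s[1] - 100) / 100, 0.05)
  expect_true(all(s[-1] == 0))
  # weights non-decreasing along the sorted spectrum
  expect_true(all(diff(res$weights) >= 0))
})

test_that("wnnm with zero noise is the identity", {
  P <- matrix(rnorm(40), 5)
  expect_equal(wnnm_denoise(P, 0)$Q, P, tolerance = 1e-12)
})

test_that("weighted shrinkage beats plain thresholding under its own objective", {
  # On low-rank + noise matrices with strongly decaying spectra, the
  # reweighted solution attains lower weighted-nuclear-norm energy than the
  # uniform-threshold solution with tau = mean weight, and recovers the true
  # low-rank matrix with smaller error. Fixed seeded set; both hold on all 50.
  withr::with_seed(0, {
    for (rep in 1:50) {
      lp <- lowrank_plus_noise()
      wn <- wnnm_denoise(lp$P, lp$sigma)
      w <- pmin(wn$weights, 1e6)
      sv <- svt_denoise(lp$P, mean(w), lp$sigma)
      ew <- function(Q) {
        s <- svd(Q, nu = 0, nv = 0)$d
        sum(w[seq_along(s)] * s) + sum((lp$P - Q)^2) / lp$sigma^2
      }
      expect_lte(ew(wn$Q), ew(sv$Q))
      expect_lte(norm(wn$Q - lp$L, "F"), norm(sv$Q - lp$L, "F"))
    }
  })
})

test_that("noise estimation recovers sigma on noise fields and noisy phantoms", {
  expect_warning(s0 <- estimate_sigma(matrix(5, 32, 32)), "constant")
  expect_equal(s0, 0)

  withr::with_seed(1, n <- matrix(rnorm(256^2, 0, 5), 256))
  expect_true(estimate_sigma(n) > 4.75 && estimate_sigma(n) < 5.25)

  ph <- make_phantom(256, 3, 8, seed = 1)
  noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 2))
  sig <- attr(noisy, "sigma")
  expect_lt(abs(estimate_sigma(noisy) - sig) / sig, 0.15)
})

test_that("the pipeline with zero threshold is the identity", {
  ph <- small_phantom(0)
  prior <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 2, seed = 0)
  cfg <- denoise_config(tau = 0, shrinkage = "svt", sigma_noise = 1,
                        n_outer_iters = 1, H = 2)
  out <- denoise_image(ph$image, prior, cfg)
  expect_lt(max(abs(out$image - ph$image)), 1e-10)
})

test_that("denoising improves PSNR on the standard noisy phantom", {
  ph <- standard_phantom(0)
  noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 100))
  prior <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 8, seed = 0)
  den <- denoise_image(noisy, prior, denoise_config(), reference = ph$image,
                       data_range = ph$i_max)
  gain <- psnr(ph$image, den$image, 255) - psnr(ph$image, noisy, 255)
  expect_gt(gain, 3)
  # diagnostics carry the conservation check and per-iteration PSNR
  td <- tidy(den)
  expect_equal(nrow(td), 3)
  expect_true(all(td$recon_err < 1e-10))
  expect_true(all(is.finite(td$psnr)))
})

test_that("doubling the outer iterations does not catastrophically degrade", {
  ph <- standard_phantom(0)
  noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 100))
  prior <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 8, seed = 0)
  p3 <- psnr(ph$image,
             denoise_image(noisy, prior, denoise_config(n_outer_iters = 3))$image,
             255)
  p6 <- psnr(ph$image,
             denoise_image(noisy, prior, denoise_config(n_outer_iters = 6))$image,
             255)
  expect_gte(p6, p3 - 0.3)
})

test_that("residual error grows with injected noise", {
  ph <- standard_phantom(1)
  prior <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 8, seed = 0)
  err <- sapply(c(1, 3, 5, 7), function(pct) {
    noisy <- add_noise(ph, noise_spec("gaussian", pct, seed = 50 + pct))
    rmse(ph$image, denoise_image(noisy, prior, denoise_config())$image)
  })
  expect_true(all(diff(err) > 0))
})

test_that("denoising is deterministic for a fixed configuration", {
  ph <- small_phantom(5)
  noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 8))
  prior <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 4, seed = 3)
  a <- denoise_image(noisy, prior, denoise_config(H = 4))
  b <- denoise_image(noisy, prior, denoise_config(H = 4))
  expect_identical(a$image, b$image)
})

test_that("singleton clusters are handled", {
  # two patches, forced into 2 classes: each cluster matrix has one column
  X <- cbind(rep(0, 16), rep(10, 16)) + matrix(rnorm(32, 0, 0.01), 16)
  prior <- fit_gmm_prior(X, H = 2, seed = 0, remove_dc = FALSE)
  res <- wnnm_denoise(X[, 1, drop = FALSE], sigma = 0.5)
  expect_equal(dim(res$Q), c(16, 1))
  expect_lt(max(abs(res$Q + res$T - X[, 1, drop = FALSE])), 1e-10)
})
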