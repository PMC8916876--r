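# Gaussian mixture prior over image patches.
#
# The prior models a clean patch x (length D = p^2, optionally with its mean
# intensity removed) as drawn from class h with probability w_h and
# x | h ~ N(mu_h, Sigma_h). Noisy patches are assigned with the covariance
# inflated to Sigma_h + sigma^2 I, the posterior implied by the additive
# Gaussian observation model.

# log N(x; mu, Sigma) for all rows of X (n x D), full normalisation constant
.log_mvn_rows <- function(X, mu, Sigma, class_idx = NA) {
  R <- tryCatch(chol(Sigma), error = function(e) {
    stop(sprintf("covariance for class %s is not positive definite: %s",
                 class_idx, conditionMessage(e)), call. = FALSE)
  })
  D <- ncol(X)
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, t(X) - mu, transpose = TRUE)  # R^T z = (x - mu)
  quad <- colSums(Z^2)
  -0.5 * (D * log(2 * pi) + logdet + quad)
}

.logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

# k-means++ seeding (deterministic under the caller's RNG state)
.kmeanspp_centers <- function(X, H) {
  n <- nrow(X)
  centers <- matrix(0, H, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  if (H > 1) {
    for (h in 2:H) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[h, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - rep(centers[h, ], each = n))^2))
    }
  }
  centers
}

.patch_matrix <- function(patches) {
  if (inherits(patches, "lrmd_patches")) patches$patches
  else if (is.matrix(patches)) patches
  else stop("`patches` must be an lrmd_patches object or a D x n matrix",
            call. = FALSE)
}

#' Construct a Gaussian mixture patch prior by hand
#'
#' Mostly useful for tests and for evaluating densities under known
#' parameters; fitted priors come from [fit_gmm_prior()].
#'
#' @param w Mixture weights (non-negative, summing to 1).
#' @param mu `D x H` matrix of class means (columns).
#' @param sigma `D x D x H` array of class covariances.
#' @param patch_size Side length `p` with `p^2 = D`, if the prior is tied to
#'   image patches; `NA` for free vectors.
#' @param remove_dc Whether patches are mean-centred before evaluation when
#'   this prior is used by [assign_clusters()].
#' @return An object of class `lrmd_prior`.
#' @export
gmm_prior <- function(w, mu, sigma, patch_size = NA, remove_dc = FALSE) {
  if (is.vector(mu)) mu <- matrix(mu, ncol = length(w))
  if (length(dim(sigma)) == 2) sigma <- array(sigma, c(dim(sigma), 1))
  H <- length(w)
  D <- nrow(mu)
  stopifnot(ncol(mu) == H, all(dim(sigma) == c(D, D, H)))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(H = H, D = D, w = as.numeric(w), mu = mu, sigma = sigma,
                 patch_size = patch_size, remove_dc = isTRUE(remove_dc),
                 eps_reg = NA_real_, loglik_trace = numeric(0),
                 n_iter = 0L, converged = NA),
            class = "lrmd_prior")
}

#' @export
print.lrmd_prior <- function(x, ...) {
  cat(sprintf("<lrmd_prior> H = %d classes, dimension %d%s\n", x$H, x$D,
              if (is.na(x$patch_size)) "" else
                sprintf(" (%dx%d patches%s)", x$patch_size, x$patch_size,
                        if (x$remove_dc) ", DC removed" else "")))
  if (length(x$loglik_trace)) {
    cat(sprintf("  EM: %d iterations, final log-likelihood %.4g, converged: %s\n",
                x$n_iter, utils::tail(x$loglik_trace, 1), x$converged))
  }
  invisible(x)
}

#' Log-density of a patch under one Gaussian class
#'
#' Evaluates `log N(patch; mu_h, Sigma_h + sigma_noise^2 I)` with the full
#' normalisation constant (the `(2*pi)^(D/2) |Sigma|^(1/2)` factor included).
#' With `sigma_noise = 0` this is exactly the class density of the clean-patch
#' model; a positive `sigma_noise` inflates the covariance to account for
#' additive observation noise. The vector is evaluated as given — any mean
#' centring is the caller's concern ([assign_clusters()] applies the prior's
#' `remove_dc` setting itself).
#'
#' @param patch Numeric vector of length `D`.
#' @param h Class index in `1..H`.
#' @param prior An `lrmd_prior`.
#' @param sigma_noise Observation noise SD (>= 0).
#' @return The log-density (scalar).
#' @export
class_density <- function(patch, h, prior, sigma_noise = 0) {
  stopifnot(inherits(prior, "lrmd_prior"))
  if (length(patch) != prior$D) stop("patch length must equal prior dimension",
                                     call. = FALSE)
  if (h < 1 || h > prior$H) stop("invalid class index", call. = FALSE)
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  S <- prior$sigma[, , h] + diag(sigma_noise^2, prior$D)
  as.numeric(.log_mvn_rows(matrix(patch, 1), prior$mu[, h], S, h))
}

#' Fit the Gaussian mixture prior to clean patches by EM
#'
#' Maximum-likelihood fit of mixture weights, means and covariances to a set
#' of (clean) patches. Initialisation is k-means++ under the run seed; the
#' E-step uses log-sum-exp throughout; covariances are regularised by adding
#' `eps_reg` to the diagonal so every class stays positive definite. A class
#' whose responsibility mass collapses to zero is re-seeded at the patch
#' farthest from its assigned class mean. The log-likelihood is non-decreasing
#' across iterations (a property the test suite asserts), and the fit stops
#' when its relative gain drops below `tol`.
#'
#' By default each patch's mean intensity (DC component) is removed before
#' fitting, so the prior captures local structure rather than brightness;
#' the same centring is applied when the prior is later used for assignment
#' and denoising.
#'
#' @param patches An `lrmd_patches` object or a `D x n` matrix of patch
#'   columns.
#' @param H Number of Gaussian classes (`n >= H`).
#' @param seed Integer seed for the k-means++ initialisation.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood gain below which EM stops.
#' @param eps_reg Diagonal regulariser; default `1e-6` times the mean
#'   diagonal of the pooled patch covariance.
#' @param remove_dc Remove each patch's mean intensity before fitting.
#' @return An `lrmd_prior` with the EM trace (`loglik_trace`, `n_iter`,
#'   `converged`) and the final training responsibilities (`train_resp`,
#'   `train_labels`).
#' @examples
#' X <- cbind(matrix(rnorm(200), 4), matrix(rnorm(200, 6), 4))
#' fit_gmm_prior(X, H = 2, seed = 1, remove_dc = FALSE)
#' @export
fit_gmm_prior <- function(patches, H, seed = 0, max_iter = 200, tol = 1e-6,
                          eps_reg = NULL, remove_dc = TRUE) {
  P <- .patch_matrix(patches)
  patch_size <- if (inherits(patches, "lrmd_patches")) patches$patch_size else NA
  X <- t(P)                       # n x D
  n <- nrow(X); D <- ncol(X)
  if (!all(is.finite(X))) stop("patches must be finite", call. = FALSE)
  if (n < H) stop("need at least H patches", call. = FALSE)
  if (remove_dc) X <- X - rowMeans(X)

  pooled <- stats::cov(X) * (n - 1) / n
  if (is.null(eps_reg)) eps_reg <- 1e-6 * mean(diag(pooled))
  if (!is.finite(eps_reg) || eps_reg <= 0) eps_reg <- 1e-10
  regI <- diag(eps_reg, D)

  withr::with_seed(as.integer(seed), {
    centers <- .kmeanspp_centers(X, H)
    # hard initial assignment to the k-means++ centres
    d2 <- sapply(seq_len(H), function(h)
      rowSums((X - rep(centers[h, ], each = n))^2))
    if (H == 1) d2 <- matrix(d2, ncol = 1)
    lab <- max.col(-d2, ties.method = "first")

    w <- as.numeric(tabulate(lab, H))
    w[w == 0] <- 1
    w <- w / sum(w)
    mu <- matrix(0, D, H)
    sigma <- array(0, c(D, D, H))
    for (h in seq_len(H)) {
      idx <- which(lab == h)
      if (length(idx) < 2) {
        mu[, h] <- centers[h, ]
        sigma[, , h] <- pooled + regI
      } else {
        mu[, h] <- colMeans(X[idx, , drop = FALSE])
        Xc <- sweep(X[idx, , drop = FALSE], 2, mu[, h])
        sigma[, , h] <- crossprod(Xc) / length(idx) + regI
      }
    }

    loglik_trace <- numeric(0)
    converged <- FALSE
    resp <- NULL
    iter_done <- 0L
    # best-iterate bookkeeping: the diagonal ridge added after each M-step
    # means exact ascent is not guaranteed once a class covariance is nearly
    # singular; on a detected decrease we restore the previous parameters
    # (whose likelihood the trace already holds) and stop
    prev <- NULL

    estep <- function() {
      L <- matrix(0, n, H)
      for (h in seq_len(H)) {
        L[, h] <- log(w[h]) + .log_mvn_rows(X, mu[, h], sigma[, , h], h)
      }
      lse <- .logsumexp_rows(L)
      list(resp = exp(L - lse), loglik = sum(lse))
    }

    for (iter in seq_len(max_iter)) {
      es <- estep()
      if (!is.null(prev) && es$loglik < prev$loglik) {
        w <- prev$w; mu <- prev$mu; sigma <- prev$sigma
        converged <- TRUE
        break
      }
      resp <- es$resp
      loglik_trace <- c(loglik_trace, es$loglik)
      iter_done <- iter
      prev <- list(w = w, mu = mu, sigma = sigma, resp = resp,
                   loglik = es$loglik)

      Nh <- colSums(resp)
      empty <- which(Nh < 1e-8)
      if (length(empty)) {
        lab_now <- max.col(resp, ties.method = "first")
        for (h in empty) {
          # re-seed at the patch farthest from its assigned class mean
          dev <- rowSums((X - t(mu)[lab_now, , drop = FALSE])^2)
          far <- which.max(dev)
          message(sprintf("EM: class %d emptied; re-seeded at patch %d", h, far))
          mu[, h] <- X[far, ]
          sigma[, , h] <- pooled + regI
          w[h] <- 1 / n
          resp[, h] <- 0
          resp[far, ] <- 0; resp[far, h] <- 1
        }
        w <- w / sum(w)
        Nh <- colSums(resp)
      }

      w <- Nh / n
      for (h in seq_len(H)) {
        mu[, h] <- colSums(resp[, h] * X) / Nh[h]
        Xc <- sweep(X, 2, mu[, h])
        sigma[, , h] <- crossprod(Xc * sqrt(resp[, h]), Xc * sqrt(resp[, h])) /
          Nh[h] + regI
      }

      if (iter > 1) {
        gain <- (loglik_trace[iter] - loglik_trace[iter - 1]) /
          abs(loglik_trace[iter - 1])
        if (is.finite(gain) && gain < tol) { converged <- TRUE; break }
      }
    }

    # final E-step under the final parameters, so stored responsibilities
    # match what assign_clusters(sigma_noise = 0) recomputes; if the last
    # M-step lowered the likelihood, keep the previous (better) parameters
    es <- estep()
    if (!is.null(prev) && es$loglik < prev$loglik) {
      w <- prev$w; mu <- prev$mu; sigma <- prev$sigma
      es <- list(resp = prev$resp, loglik = prev$loglik)
    } else {
      loglik_trace <- c(loglik_trace, es$loglik)
    }

    prior <- gmm_prior(w, mu, sigma, patch_size = patch_size,
                       remove_dc = remove_dc)
    prior$eps_reg <- eps_reg
    prior$loglik_trace <- loglik_trace
    prior$n_iter <- iter_done
    prior$converged <- converged
    prior$train_resp <- es$resp
    prior$train_labels <- max.col(es$resp, ties.method = "first")
    prior$train_loglik <- es$loglik
    prior
  })
}

#' Assign (noisy) patches to Gaussian classes
#'
#' Posterior responsibilities under the prior with noise-inflated class
#' covariances: `r_ih` proportional to
#' `w_h N(x_i; mu_h, Sigma_h + sigma_noise^2 I)`, rows normalised with
#' log-sum-exp. Labels are the row-wise argmax; the reported log-likelihood is
#' the sum over patches of the log mixture density (the independence product
#' over patches, in log space). If the prior was fitted with `remove_dc`,
#' patch means are removed here too before evaluation.
#'
#' @param patches An `lrmd_patches` object or a `D x n` matrix.
#' @param prior An `lrmd_prior`.
#' @param sigma_noise Observation noise SD (>= 0); 0 evaluates the clean
#'   model exactly.
#' @return An object of class `lrmd_assignment`: `labels` (length n),
#'   `responsibilities` (`n x H`), `loglik`, `H`.
#' @export
assign_clusters <- function(patches, prior, sigma_noise = 0) {
  stopifnot(inherits(prior, "lrmd_prior"))
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  P <- .patch_matrix(patches)
  X <- t(P)
  if (ncol(X) != prior$D) {
    stop("patch dimension does not match the prior", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("patches must be finite", call. = FALSE)
  if (prior$remove_dc) X <- X - rowMeans(X)

  n <- nrow(X); H <- prior$H
  L <- matrix(0, n, H)
  infl <- diag(sigma_noise^2, prior$D)
  for (h in seq_len(H)) {
    L[, h] <- log(prior$w[h]) +
      .log_mvn_rows(X, prior$mu[, h], prior$sigma[, , h] + infl, h)
  }
  lse <- .logsumexp_rows(L)
  structure(list(labels = max.col(L, ties.method = "first"),
                 responsibilities = exp(L - lse),
                 loglik = sum(lse),
                 H = H),
            class = "lrmd_assignment")
}

#' @export
print.lrmd_assignment <- function(x, ...) {
  cat(sprintf("<lrmd_assignment> %d patches over %d classes, loglik %.4g\n",
              length(x$labels), x$H, x$loglik))
  print(table(factor(x$labels, levels = seq_len(x$H))))
  invisible(x)
}

#' Serialise a fitted prior to JSON / read it back
#'
#' The archive is a single JSON file holding the weights, means, covariances
#' and fitting metadata, loadable by the command-line tools via `--prior`.
#'
#' @param prior An `lrmd_prior`.
#' @param path Output/input file path.
#' @return `write_prior` returns `path` invisibly; `read_prior` returns the
#'   `lrmd_prior`.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "lrmd_prior"))
  obj <- list(H = prior$H, D = prior$D, w = prior$w,
              mu = prior$mu, sigma = prior$sigma,
              patch_size = prior$patch_size, remove_dc = prior$remove_dc,
              eps_reg = prior$eps_reg)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prior <- gmm_prior(obj$w,
                     matrix(unlist(obj$mu), obj$D, obj$H),
                     array(unlist(obj$sigma), c(obj$D, obj$D, obj$H)),
                     patch_size = if (is.null(obj$patch_size) ||
                                      is.na(obj$patch_size)) NA
                                  else obj$patch_size,
                     remove_dc = isTRUE(obj$remove_dc))
  prior$eps_reg <- obj$eps_reg
  prior
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted patch prior
#'
#' One row per Gaussian class: weight, mean-vector norm, and the trace of the
#' class covariance (total within-class variance).
#'
#' @param x An `lrmd_prior`.
#' @param ... Unused.
#' @method tidy lrmd_prior
#' @export
tidy.lrmd_prior <- function(x, ...) {
  tibble::tibble(
    class = seq_len(x$H),
    weight = x$w,
    mean_norm = sqrt(colSums(x$mu^2)),
    cov_trace = vapply(seq_len(x$H), function(h) sum(diag(x$sigma[, , h])),
                       numeric(1)))
}

#' @rdname tidy.lrmd_prior
#' @method glance lrmd_prior
#' @export
glance.lrmd_prior <- function(x, ...) {
  tibble::tibble(
    H = x$H,
    dimension = x$D,
    n_iter = x$n_iter,
    loglik = if (length(x$loglik_trace)) utils::tail(x$loglik_trace, 1)
             else NA_real_,
    converged = isTRUE(x$converged))
}
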