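#' Decompose an image into overlapping patches
#'
#' Extracts `p x p` blocks on a regular grid with the given stride, with the
#' final row/column offsets snapped to the image edge so every pixel is
#' covered. Each block is flattened row-major into one column of the patch
#' matrix. Coordinates are 0-based `(row, col)` of each block's top-left
#' pixel; this convention is fixed here and used throughout the package.
#'
#' @param img Numeric matrix (or `lrmd_phantom`).
#' @param patch_size Block side length `p` (`p <= min(dim(img))`).
#' @param stride Grid step `s`, `1 <= s <= p`.
#' @return An object of class `lrmd_patches`: list with `patches`
#'   (`p^2 x n` matrix), `coords` (`n x 2` integer matrix, 0-based),
#'   `patch_size`, `image_shape`.
#' @examples
#' ps <- extract_patches(matrix(1:64, 8, 8), patch_size = 4, stride = 2)
#' ncol(ps$patches)  # 9
#' @export
extract_patches <- function(img, patch_size = 8, stride = 4) {
  if (inherits(img, "lrmd_phantom")) img <- img$image
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  p <- as.integer(patch_size); s <- as.integer(stride)
  H <- nrow(img); W <- ncol(img)
  if (p > min(H, W)) stop("`patch_size` exceeds an image dimension", call. = FALSE)
  if (s < 1 || s > p) stop("`stride` must be in [1, patch_size]", call. = FALSE)

  grid_starts <- function(extent) {
    st <- seq.int(0L, extent - p, by = s)
    if (st[length(st)] != extent - p) st <- c(st, extent - p)  # edge snap
    st
  }
  rows <- grid_starts(H)
  cols <- grid_starts(W)
  coords <- cbind(row = rep(rows, times = length(cols)),
                  col = rep(cols, each = length(rows)))
  n <- nrow(coords)

  patches <- matrix(0, p * p, n)
  for (i in seq_len(n)) {
    block <- img[coords[i, 1] + seq_len(p), coords[i, 2] + seq_len(p)]
    patches[, i] <- as.vector(t(block))  # row-major flatten
  }

  structure(list(patches = patches,
                 coords = coords,
                 patch_size = p,
                 image_shape = c(H, W)),
            class = "lrmd_patches")
}

#' Reassemble an image from (possibly modified) patches
#'
#' Each pixel becomes the weighted average of all patch values that cover it.
#' With unmodified patches and any positive weights this is an exact inverse
#' of [extract_patches()] (a partition-of-unity identity): overlapping copies
#' of the same pixel agree, so averaging returns the original value.
#'
#' @param ps An `lrmd_patches` object (its `patches` matrix may have been
#'   modified, e.g. by per-cluster shrinkage).
#' @param weights Optional per-patch positive weights (length `n`); uniform
#'   by default.
#' @return Numeric matrix of shape `ps$image_shape`.
#' @examples
#' img <- matrix(rnorm(256), 16, 16)
#' ps <- extract_patches(img, 8, 3)
#' max(abs(aggregate_patches(ps) - img))  # ~1e-16
#' @export
aggregate_patches <- function(ps, weights = NULL) {
  stopifnot(inherits(ps, "lrmd_patches"))
  p <- ps$patch_size
  H <- ps$image_shape[1]; W <- ps$image_shape[2]
  n <- ncol(ps$patches)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("`weights` must be positive and one per patch", call. = FALSE)
  }

  acc <- matrix(0, H, W)
  wsum <- matrix(0, H, W)
  for (i in seq_len(n)) {
    ri <- ps$coords[i, 1] + seq_len(p)
    ci <- ps$coords[i, 2] + seq_len(p)
    block <- matrix(ps$patches[, i], p, p, byrow = TRUE)
    acc[ri, ci] <- acc[ri, ci] + weights[i] * block
    wsum[ri, ci] <- wsum[ri, ci] + weights[i]
  }
  if (any(wsum == 0)) {
    stop("some pixels are covered by no patch; extraction was inconsistent",
         call. = FALSE)
  }
  acc / wsum
}

#' @export
print.lrmd_patches <- function(x, ...) {
  cat(sprintf("<lrmd_patches> %d patches of %dx%d from a %dx%d image\n",
              ncol(x$patches), x$patch_size, x$patch_size,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Patch set as a tibble (one row per patch) for inspection/export
#'
#' @param x An `lrmd_patches` object.
#' @param ... Unused.
#' @return A tibble with `row`, `col` (0-based top-left corner) and `v1..vP`
#'   columns holding the row-major flattened patch values.
#' @importFrom tibble as_tibble
#' @method as_tibble lrmd_patches
#' @export
as_tibble.lrmd_patches <- function(x, ...) {
  vals <- t(x$patches)
  colnames(vals) <- paste0("v", seq_len(nrow(x$patches)))
  tibble::as_tibble(cbind(tibble::tibble(row = x$coords[, 1],
                                         col = x$coords[, 2]),
                          tibble::as_tibble(vals)))
}
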