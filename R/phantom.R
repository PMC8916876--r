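#' Generate a synthetic brain-like phantom slice
#'
#' Builds a 2-D piecewise-smooth phantom that plays the statistical role of a
#' clean MRI slice: nested elliptical "tissue" regions of distinct intensity
#' with a gentle intensity gradient across the tissue, plus (optionally) one
#' small hypointense disc lesion mimicking a cerebral microbleed (a round,
#' uniform, low-signal focus of 2-5 mm with sharp borders). Patches drawn from
#' such an image are strongly self-similar, which is the property the mixture
#' prior and low-rank recovery exploit.
#'
#' @param size Image side length in pixels (square image, `size >= 32`).
#' @param n_tissue_regions Number of nested elliptical tissue regions
#'   (0 gives a uniform background image).
#' @param lesion_diameter Diameter of the disc lesion in pixels; 0 disables
#'   the lesion. Must satisfy `lesion_diameter < size / 4`.
#' @param seed Integer seed; the phantom is bit-identical for a fixed seed.
#' @param i_max Maximum representable intensity (default 255, 8-bit scale).
#'
#' @return An object of class `lrmd_phantom`: a list with
#'   \describe{
#'     \item{image}{`size x size` numeric matrix of clean intensities in
#'       `[0, i_max]`.}
#'     \item{region_map}{integer matrix of the same shape; 0 = background,
#'       `1..n_tissue_regions` = tissue (outermost first),
#'       `n_tissue_regions + 1` = lesion (when present).}
#'     \item{params}{geometry descriptors (ellipse centres, semi-axes,
#'       region intensities, lesion centre/diameter).}
#'     \item{i_max}{the recorded intensity ceiling.}
#'   }
#' @examples
#' ph <- make_phantom(size = 64, n_tissue_regions = 2, lesion_diameter = 6, seed = 1)
#' table(ph$region_map)
#' @export
make_phantom <- function(size = 128, n_tissue_regions = 3, lesion_diameter = 8,
                         seed = 0, i_max = 255) {
  if (!is.numeric(size) || length(size) != 1 || size < 32) {
    stop("`size` must be a single number >= 32", call. = FALSE)
  }
  if (lesion_diameter < 0 || lesion_diameter >= size / 4) {
    stop("`lesion_diameter` must satisfy 0 <= lesion_diameter < size/4",
         call. = FALSE)
  }
  if (n_tissue_regions < 0) stop("`n_tissue_regions` must be >= 0", call. = FALSE)
  size <- as.integer(size)
  n_tissue_regions <- as.integer(n_tissue_regions)

  withr::with_seed(as.integer(seed), {
    bg_intensity <- 20
    img <- matrix(bg_intensity, size, size)
    region_map <- matrix(0L, size, size)

    # pixel-centre coordinate grids (1-based centres)
    rr <- matrix(seq_len(size), size, size)
    cc <- matrix(seq_len(size), size, size, byrow = TRUE)

    centre <- size / 2 + stats::runif(2, -size / 32, size / 32)
    # region intensities: distinct, spread over the mid range, seeded order
    levels <- if (n_tissue_regions > 0) {
      base <- seq(90, 220, length.out = n_tissue_regions)
      base + stats::runif(n_tissue_regions, -15, 15)
    } else numeric(0)

    ellipses <- vector("list", n_tissue_regions)
    if (n_tissue_regions > 0) {
      # nested: semi-axes shrink geometrically from ~0.85 of the half-size
      a0 <- 0.85 * size / 2
      b0 <- 0.72 * size / 2
      shrink <- 0.72^(seq_len(n_tissue_regions) - 1)
      for (r in seq_len(n_tissue_regions)) {
        a <- a0 * shrink[r] * stats::runif(1, 0.92, 1.05)
        b <- b0 * shrink[r] * stats::runif(1, 0.92, 1.05)
        inside <- ((rr - centre[1]) / b)^2 + ((cc - centre[2]) / a)^2 <= 1
        img[inside] <- levels[r]
        region_map[inside] <- r
        ellipses[[r]] <- list(centre = centre, a = a, b = b,
                              intensity = levels[r])
      }
    }

    lesion <- NULL
    if (lesion_diameter > 0) {
      if (n_tissue_regions == 0) {
        stop("a lesion requires at least one tissue region to sit in",
             call. = FALSE)
      }
      # place the lesion off-centre inside the innermost ellipse
      inner <- ellipses[[n_tissue_regions]]
      rad <- lesion_diameter / 2
      repeat {
        off <- stats::runif(2, -0.5, 0.5)
        lc <- c(centre[1] + off[1] * inner$b, centre[2] + off[2] * inner$a)
        # disc must fit inside the innermost ellipse (conservative check)
        margin <- ((lc[1] - centre[1]) / (inner$b - rad))^2 +
                  ((lc[2] - centre[2]) / (inner$a - rad))^2
        if (is.finite(margin) && margin <= 1) break
      }
      inside <- (rr - lc[1])^2 + (cc - lc[2])^2 <= rad^2
      lesion_int <- 0.25 * min(levels)  # hypointense: well below any tissue
      img[inside] <- lesion_int
      region_map[inside] <- n_tissue_regions + 1L
      lesion <- list(centre = lc, diameter = lesion_diameter,
                     intensity = lesion_int)
    }

    # gentle smooth gradient across the tissue only, so the degenerate
    # zero-region phantom stays exactly uniform
    if (n_tissue_regions > 0) {
      slope <- stats::runif(2, -1, 1)
      grad <- 6 * (slope[1] * (rr - centre[1]) + slope[2] * (cc - centre[2])) / size
      tissue <- region_map > 0L
      img[tissue] <- img[tissue] + grad[tissue]
    }

    img[img < 0] <- 0
    img[img > i_max] <- i_max

    structure(
      list(image = img,
           region_map = region_map,
           params = list(size = size, n_tissue_regions = n_tissue_regions,
                         centre = centre, ellipses = ellipses, lesion = lesion,
                         background = bg_intensity, seed = as.integer(seed)),
           i_max = i_max),
      class = "lrmd_phantom")
  })
}

#' @export
print.lrmd_phantom <- function(x, ...) {
  cat(sprintf("<lrmd_phantom> %dx%d, %d tissue region(s)%s, i_max = %g\n",
              nrow(x$image), ncol(x$image), x$params$n_tissue_regions,
              if (is.null(x$params$lesion)) "" else
                sprintf(", lesion d=%g px", x$params$lesion$diameter),
              x$i_max))
  invisible(x)
}

#' Describe a noise model for image corruption
#'
#' Noise intensity is expressed as a percentage of the clean image's maximum
#' intensity: the corruption standard deviation is
#' `sigma = intensity_percent / 100 * i_max`. This is the convention common to
#' MRI denoising benchmarks, where "5% noise" on an 8-bit image means
#' `sigma = 12.75`.
#'
#' @param model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian-corrupted signal, the noise law of magnitude MRI).
#' @param intensity_percent Noise level as a percentage of `i_max`
#'   (non-negative; 0 means no corruption).
#' @param seed Integer seed making the corruption reproducible.
#' @return An object of class `lrmd_noise_spec`.
#' @examples
#' noise_spec("gaussian", 5, seed = 1)
#' @export
noise_spec <- function(model = c("gaussian", "rician"), intensity_percent,
                       seed = 0) {
  model <- match.arg(model)
  if (!is.numeric(intensity_percent) || length(intensity_percent) != 1 ||
      intensity_percent < 0) {
    stop("`intensity_percent` must be a single non-negative number",
         call. = FALSE)
  }
  structure(list(model = model,
                 intensity_percent = intensity_percent,
                 seed = as.integer(seed)),
            class = "lrmd_noise_spec")
}

#' @export
print.lrmd_noise_spec <- function(x, ...) {
  cat(sprintf("<lrmd_noise_spec> %s, %g%% of i_max, seed %d\n",
              x$model, x$intensity_percent, x$seed))
  invisible(x)
}

#' Corrupt an image with calibrated noise
#'
#' Gaussian noise adds `N(0, sigma^2)` to every pixel. Rician noise forms
#' `sqrt((img + n1)^2 + n2^2)` with independent `n1, n2 ~ N(0, sigma^2)`,
#' which is positively biased in dark regions (mean `sigma * sqrt(pi/2)` on a
#' zero background) and close to Gaussian at high signal-to-noise. The output
#' is deliberately not clipped to `[0, i_max]`; clipping is a display concern
#' and would bias the noise statistics the denoiser relies on.
#'
#' @param img An `lrmd_phantom` or a numeric matrix of intensities.
#' @param spec An [noise_spec()] object.
#' @param i_max Intensity ceiling defining the percent scale; defaults to the
#'   phantom's recorded `i_max`, otherwise `max(img)`.
#' @return A numeric matrix of the same shape, with attributes `sigma` (the
#'   corruption SD actually used) and `i_max`.
#' @examples
#' ph <- make_phantom(64, 2, 0, seed = 1)
#' noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 2))
#' attr(noisy, "sigma")  # 5% of 255
#' @export
add_noise <- function(img, spec, i_max = NULL) {
  if (!inherits(spec, "lrmd_noise_spec")) {
    stop("`spec` must be created with noise_spec()", call. = FALSE)
  }
  if (inherits(img, "lrmd_phantom")) {
    if (is.null(i_max)) i_max <- img$i_max
    img <- img$image
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix or an lrmd_phantom", call. = FALSE)
  }
  if (is.null(i_max)) i_max <- max(img)
  sigma <- spec$intensity_percent / 100 * i_max

  out <- if (sigma == 0) {
    img
  } else {
    withr::with_seed(spec$seed, {
      n <- length(img)
      switch(spec$model,
        gaussian = img + matrix(stats::rnorm(n, 0, sigma), nrow(img)),
        rician = {
          n1 <- matrix(stats::rnorm(n, 0, sigma), nrow(img))
          n2 <- matrix(stats::rnorm(n, 0, sigma), nrow(img))
          sqrt((img + n1)^2 + n2^2)
        })
    })
  }
  attr(out, "sigma") <- sigma
  attr(out, "i_max") <- i_max
  out
}
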