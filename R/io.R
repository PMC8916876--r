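# Image file I/O. PNG (8-bit grayscale) and NIfTI (float32) cover the two
# common cases: quick-look exports and medical-imaging pipelines. TIFF input
# is supported when the tiff package is available.

.file_ext <- function(path) tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))

#' Load a 2-D grayscale image
#'
#' PNG and TIFF intensities are rescaled from the decoder's `[0, 1]` to the
#' 8-bit `[0, 255]` scale; multi-channel images are averaged to grayscale.
#' NIfTI volumes keep their native float intensities; from a 3-D volume the
#' middle axial slice (index `floor(n/2)` counting from 0) is taken unless
#' `slice` is given.
#'
#' @param path File path (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @param slice 1-based slice index into the third dimension of a NIfTI
#'   volume; default is the middle slice.
#' @return Numeric matrix with attributes `data_range` and `source`.
#' @export
load_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- .file_ext(path)
  img <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                           drop = FALSE], c(1, 2), mean)
      out <- a * 255
      attr(out, "data_range") <- 255
      out
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the tiff package is required to read ", path, call. = FALSE)
      }
      a <- tiff::readTIFF(path)
      if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                           drop = FALSE], c(1, 2), mean)
      out <- a * 255
      attr(out, "data_range") <- 255
      out
    },
    nii = {
      vol <- RNifti::readNifti(path)
      a <- as.array(vol)
      if (length(dim(a)) > 3) a <- a[, , , 1]
      if (length(dim(a)) == 3) {
        if (is.null(slice)) {
          slice <- floor(dim(a)[3] / 2) + 1
          message(sprintf("taking middle slice %d of %d", slice, dim(a)[3]))
        }
        a <- a[, , slice]
      }
      out <- matrix(as.numeric(a), nrow(a), ncol(a))
      attr(out, "data_range") <- max(out)
      out
    },
    stop("unsupported image format for ", path, call. = FALSE))
  attr(img, "source") <- path
  img
}

#' Save a 2-D grayscale image
#'
#' PNG output clips to `[0, data_range]` and quantises to 8 bits; NIfTI
#' output stores the float intensities untouched (float32 on disk).
#'
#' @param img Numeric matrix (or `lrmd_phantom`, whose clean image is saved).
#' @param path Output path ending in `.png` or `.nii`.
#' @param data_range Intensity ceiling for PNG scaling (default 255).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, data_range = 255) {
  if (inherits(img, "lrmd_phantom")) img <- img$image
  ext <- .file_ext(path)
  switch(ext,
    png = {
      a <- pmin(pmax(img / data_range, 0), 1)
      png::writePNG(a, path)
    },
    nii = {
      RNifti::writeNifti(RNifti::asNifti(img, datatype = "float"), path)
    },
    stop("unsupported output format for ", path, call. = FALSE))
  invisible(path)
}

#' Write a phantom (clean PNG + NIfTI + sidecar JSON)
#'
#' Writes `<prefix>.png`, `<prefix>.nii` and `<prefix>.json`; the sidecar
#' records `i_max`, the generator seed and geometry, and (optionally) the
#' noise specification used for a companion corrupted image.
#'
#' @param phantom An `lrmd_phantom`.
#' @param prefix Output path prefix (no extension).
#' @param noise Optional [noise_spec()] recorded in the sidecar.
#' @return The three paths written, invisibly.
#' @export
write_phantom <- function(phantom, prefix, noise = NULL) {
  stopifnot(inherits(phantom, "lrmd_phantom"))
  paths <- paste0(prefix, c(".png", ".nii", ".json"))
  save_image(phantom$image, paths[1], data_range = phantom$i_max)
  save_image(phantom$image, paths[2])
  side <- list(i_max = phantom$i_max,
               seed = phantom$params$seed,
               size = phantom$params$size,
               n_tissue_regions = phantom$params$n_tissue_regions,
               lesion = phantom$params$lesion,
               noise = if (is.null(noise)) NULL else unclass(noise))
  jsonlite::write_json(side, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
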