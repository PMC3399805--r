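## Raster and volume I/O: PNG/TIFF images, NIfTI volumes.

#' Read a grayscale raster image (PNG or TIFF)
#'
#' Multi-channel images are collapsed to grayscale by averaging the color
#' channels (alpha, if present, is dropped).
#'
#' @param path path to a .png, .tif or .tiff file.
#' @return a [GrayImage-class].
#' @export
readVesselImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: '", ext, "'"))
  if (length(dim(a)) == 3L) {
    nc <- min(dim(a)[3L], 3L)  # drop alpha
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  GrayImage(a)
}

#' Write a binary image as PNG
#'
#' Foreground is written white (1), background black (0).
#'
#' @param image a [BinaryImage-class].
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
writeBinaryImage <- function(image, path) {
  png::writePNG(pixels(image) * 1.0, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param axes axis labels to attach, in array order.
#' @return a [Volume3D-class].
#' @export
readVolume <- function(path, axes = c("axial", "coronal", "sagittal")) {
  v <- RNifti::readNifti(path)
  if (length(dim(v)) != 3L) stop("expected a 3-D volume")
  a <- array(as.numeric(v), dim = dim(v))  # strip NIfTI attributes
  a[a < 0] <- 0  # clip stray negative intensities
  Volume3D(a, axes = axes)
}
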