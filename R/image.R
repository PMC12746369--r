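#' Greyscale micrograph container
#'
#' A `grey_image` is a numeric matrix of finite intensities with an attached
#' physical pixel size in micrometres per pixel. Rows index image rows (top to
#' bottom), columns index image columns (left to right). All analysis
#' functions in the package accept either a `grey_image` or a plain numeric
#' matrix.
#'
#' @param pixels Numeric matrix of intensities; all values must be finite.
#' @param pixel_size Physical pixel size in micrometres per pixel. Defaults to
#'   0.25, a typical scanning-helium-microscope pixel pitch.
#' @return An object of class `grey_image`: the matrix with a `pixel_size`
#'   attribute.
#' @examples
#' img <- grey_image(matrix(runif(64), 8), pixel_size = 0.25)
#' dim(img)
#' @export
grey_image <- function(pixels, pixel_size = 0.25) {
  pixels <- as_pixel_matrix(pixels)
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  structure(pixels, pixel_size = pixel_size, class = c("grey_image", "matrix", "array"))
}

# Validate and strip an image down to a plain finite numeric matrix.
as_pixel_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("image must be a numeric matrix")
  if (nrow(x) < 1 || ncol(x) < 1)
    stop("image must have at least one row and one column")
  if (!all(is.finite(x)))
    stop("image contains non-finite intensities")
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  storage.mode(x) <- "double"
  x
}

pixel_size_of <- function(x, default = 0.25) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) default else ps
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("grey_image: %d x %d px, %.3g um/px, intensity range [%.4g, %.4g]\n",
              nrow(x), ncol(x), pixel_size_of(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.grey_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  r <- range(x)
  z <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(x) / nrow(x))
  graphics::rasterImage(z, 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

#' Read a greyscale micrograph from TIFF or PNG
#'
#' Reads 8- or 16-bit TIFF or PNG rasters. Multi-channel (RGB) inputs are
#' converted to greyscale by the Rec. 709 luminance combination with a
#' warning; an alpha channel, if present, is dropped.
#'
#' @param path File path; format is chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param pixel_size Micrometres per pixel to attach to the result.
#' @return A [grey_image()] with intensities in \[0, 1\].
#' @export
read_grey_image <- function(path, pixel_size = 0.25) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      warning("RGB input converted to greyscale by luminance")
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  grey_image(arr, pixel_size = pixel_size)
}

#' Write a greyscale image to TIFF or PNG
#'
#' Intensities are rescaled to \[0, 1\] unless already within it, then written
#' at the requested bit depth (TIFF) or as 8-bit PNG.
#'
#' @param image A [grey_image()] or numeric matrix.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits Bits per sample for TIFF output (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(image, path, bits = 16) {
  m <- as_pixel_matrix(image)
  r <- range(m)
  if (r[1] < 0 || r[2] > 1)
    m <- if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = bits),
    png = png::writePNG(m, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

# Gaussian blur via EBImage's convolution engine, with the brush clipped so
# it never exceeds the image (replicate boundary avoids wrap-around halos).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  maxs <- min(dim(m))
  if (size > maxs) size <- if (maxs %% 2L == 1L) maxs else maxs - 1L
  if (size < 3L) return(m)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(m, brush, boundary = "replicate")
  as_pixel_matrix(as.matrix(out))
}

# Clamp keeping the matrix's dim attribute (x must come first for pmin/pmax).
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
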