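#' Sliding-window texture map
#'
#' Computes one Haralick feature over a square window slid across the image,
#' yielding a spatially resolved texture map. Within each window the feature
#' is computed per offset (0/45/90/135 deg) and averaged over the four
#' offsets, matching the whole-image convention of [haralick()]; the value is
#' placed at the window centre. The whole image is quantized once against a
#' shared range (by default its own min-max) so that windows are compared on
#' a common grey scale; the map value at a centre therefore equals
#' `haralick(window, range = <map range>)$mean[feature]` for the window
#' extracted as a standalone image.
#'
#' @param image A [grey_image()] or numeric matrix.
#' @param feature One of `"contrast"`, `"correlation"`, `"energy"`,
#'   `"homogeneity"`, `"entropy"`.
#' @param window Odd window side in pixels, at least `d + 2`. Default 21
#'   (about 5 um at 0.25 um/px — a few cell widths).
#' @param stride Step between computed window centres (default 1). With
#'   `stride > 1`, skipped centres are filled from the nearest computed
#'   centre.
#' @param boundary `"valid"` (default) leaves a missing border of width
#'   `(window - 1) / 2`; `"reflect"` pads the image by reflection so the map
#'   covers every pixel.
#' @param L,d,symmetric,range,entropy_base As in [haralick()]; `range`
#'   defaults to the image's min-max.
#' @return An object of class `texture_map`: a numeric matrix the size of the
#'   image (NA where undefined), with the window/quantization parameters and
#'   a `valid` mask attached as attributes.
#' @export
texture_map <- function(image, feature = "energy", window = 21L, stride = 1L,
                        boundary = c("valid", "reflect"), L = 8L, d = 1L,
                        symmetric = FALSE, range = NULL,
                        entropy_base = exp(1)) {
  boundary <- match.arg(boundary)
  feature <- match.arg(feature, c("contrast", "correlation", "energy",
                                  "homogeneity", "entropy"))
  m <- as_pixel_matrix(image)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window < d + 2L) stop("window must be at least d + 2")
  if (stride < 1L) stop("stride must be >= 1")
  if (window > nrow(m) || window > ncol(m)) stop("window larger than image")
  if (is.null(range)) range <- c(min(m), max(m))

  half <- (window - 1L) %/% 2L
  work <- m
  if (boundary == "reflect") {
    work <- reflect_pad(m, half)
  }
  maps <- cpp_texture_map(work, window, stride, as.integer(L),
                          range[1], range[2], as.integer(d),
                          isTRUE(symmetric))
  vals <- maps[[feature]]
  if (!identical(entropy_base, exp(1)) && feature == "entropy")
    vals <- vals / log(entropy_base)
  if (boundary == "reflect")
    vals <- vals[(half + 1L):(half + nrow(m)), (half + 1L):(half + ncol(m)),
                 drop = FALSE]
  filled <- fill_stride_gaps(vals, nrow(m), ncol(m), half, stride,
                             boundary == "reflect")
  structure(filled$values, feature = feature, window = window,
            stride = stride, boundary = boundary, L = as.integer(L),
            d = as.integer(d), symmetric = isTRUE(symmetric), range = range,
            entropy_base = entropy_base, valid = filled$valid,
            pixel_size = pixel_size_of(image),
            class = c("texture_map", "matrix", "array"))
}

# Reflection padding by `half` pixels on every side (no edge duplication
# beyond what reflection implies for small images).
reflect_pad <- function(m, half) {
  H <- nrow(m); W <- ncol(m)
  ridx <- c(pmin(H, pmax(1, (half:1) + 1)), 1:H, pmin(H, pmax(1, H - (1:half))))
  cidx <- c(pmin(W, pmax(1, (half:1) + 1)), 1:W, pmin(W, pmax(1, W - (1:half))))
  m[ridx, cidx, drop = FALSE]
}

# With stride > 1 the kernel leaves gaps between computed centres; fill each
# in-range pixel from its nearest computed centre and record validity.
fill_stride_gaps <- function(vals, H, W, half, stride, padded) {
  lo_r <- if (padded) 1L else half + 1L
  hi_r <- if (padded) H else H - half
  lo_c <- if (padded) 1L else half + 1L
  hi_c <- if (padded) W else W - half
  valid <- matrix(FALSE, H, W)
  if (lo_r > hi_r || lo_c > hi_c)
    return(list(values = vals, valid = valid))
  if (padded) {
    # computed centres in padded coordinates start at the first padded centre;
    # after cropping they land on rows (1 + k*stride) of the output
    grid_r <- seq.int(1L, H, stride)
    grid_c <- seq.int(1L, W, stride)
  } else {
    grid_r <- seq.int(lo_r, hi_r, stride)
    grid_c <- seq.int(lo_c, hi_c, stride)
  }
  if (stride > 1L) {
    rows <- lo_r:hi_r; cols <- lo_c:hi_c
    near_r <- grid_r[pmin(length(grid_r),
                          pmax(1L, as.integer(round((rows - grid_r[1]) / stride)) + 1L))]
    near_c <- grid_c[pmin(length(grid_c),
                          pmax(1L, as.integer(round((cols - grid_c[1]) / stride)) + 1L))]
    vals[rows, cols] <- vals[near_r, near_c, drop = FALSE]
  }
  valid[lo_r:hi_r, lo_c:hi_c] <- TRUE
  list(values = vals, valid = valid)
}

#' @export
print.texture_map <- function(x, ...) {
  v <- x[attr(x, "valid")]
  v <- v[!is.na(v)]
  cat(sprintf(
    "texture_map of %s: %d x %d px, window %d, stride %d, %s boundary\n",
    attr(x, "feature"), nrow(x), ncol(x), attr(x, "window"),
    attr(x, "stride"), attr(x, "boundary")))
  if (length(v))
    cat(sprintf("  defined values: n = %d, mean %.4g, range [%.4g, %.4g]\n",
                length(v), mean(v), min(v), max(v)))
  invisible(x)
}

#' Mean of the defined values of a texture map
#'
#' @param x A `texture_map`.
#' @param ... Ignored.
#' @return Mean over the defined (computed, non-missing) map values.
#' @export
mean.texture_map <- function(x, ...) {
  v <- unclass(x)[attr(x, "valid")]
  mean(v[!is.na(v)])
}

#' @export
plot.texture_map <- function(x, n_colours = 64, ...) {
  pal <- grDevices::colorRampPalette(c("red", "orange", "green"))(n_colours)
  m <- unclass(x)
  # image() draws column-major from bottom; transpose/flip to display as raster
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = pal, axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  graphics::title(main = paste("Haralick", attr(x, "feature"), "map"))
  invisible(x)
}

#' Feature-map overlay on a grey base image
#'
#' Renders the base micrograph in grey and tints it by the texture map on a
#' red (low) to green (high) linear colour scale, the standard presentation
#' for spatially resolved energy maps. Pixels where the map is missing show
#' the grey base only.
#'
#' @param base A [grey_image()] or matrix, same size as the map.
#' @param map A [texture_map()].
#' @param bounds Length-2 numeric colour-scale bounds; default the 2nd and
#'   98th percentiles of the defined map values (recorded in the output's
#'   provenance).
#' @param alpha Blend weight of the colour layer in \[0, 1\] (default 0.5);
#'   `alpha = 0` returns the grey base unchanged.
#' @param low_colour,high_colour Colours for the scale ends (defaults red and
#'   green).
#' @return An `overlay_image`: an H x W x 3 RGB array in \[0, 1\] with a
#'   `provenance` attribute recording sources, colours and bounds.
#' @export
render_feature_overlay <- function(base, map, bounds = NULL, alpha = 0.5,
                                   low_colour = "red", high_colour = "green") {
  b <- as_pixel_matrix(base)
  if (!all(dim(b) == dim(map))) stop("base and map shapes differ")
  stopifnot(alpha >= 0, alpha <= 1)
  v <- unclass(map)
  defined <- attr(map, "valid") & !is.na(v)
  if (is.null(bounds)) {
    dv <- v[defined]
    bounds <- if (length(dv)) unname(stats::quantile(dv, c(0.02, 0.98)))
              else c(0, 1)
  }
  r <- range(b)
  grey <- if (r[2] > r[1]) (b - r[1]) / (r[2] - r[1]) else b * 0
  lo_rgb <- grDevices::col2rgb(low_colour)[, 1] / 255
  hi_rgb <- grDevices::col2rgb(high_colour)[, 1] / 255
  t_ <- (v - bounds[1]) / max(bounds[2] - bounds[1], .Machine$double.eps)
  t_ <- pmin(1, pmax(0, t_))
  out <- array(0, c(dim(b), 3))
  for (k in 1:3) {
    tint <- lo_rgb[k] * (1 - t_) + hi_rgb[k] * t_
    plane <- grey
    plane[defined] <- (1 - alpha) * grey[defined] + alpha * tint[defined]
    out[, , k] <- plane
  }
  structure(out, provenance = list(
    kind = "feature_overlay", feature = attr(map, "feature"),
    low_colour = low_colour, high_colour = high_colour,
    bounds = bounds, alpha = alpha),
    class = c("overlay_image", "array"))
}

#' @export
print.overlay_image <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("overlay_image: %d x %d px (%s)\n", dim(x)[1], dim(x)[2],
              pv$kind %||% "overlay"))
  if (!is.null(pv$bounds))
    cat(sprintf("  colour scale %s -> %s over [%.4g, %.4g], alpha %.2f\n",
                pv$low_colour, pv$high_colour, pv$bounds[1], pv$bounds[2],
                pv$alpha))
  invisible(x)
}

#' @export
plot.overlay_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(x)[2] / dim(x)[1])
  graphics::rasterImage(unclass(x), 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

#' Write a texture map as float TIFF with a JSON sidecar
#'
#' The map values are written as a 32-bit float TIFF and the analysis
#' parameters (feature, window, stride, grey levels, offsets, quantization
#' range) as `<path>.json`. Missing values are stored as the sentinel
#' recorded in the sidecar (0; the missing region is fully determined by the
#' window, stride and boundary fields).
#'
#' @param map A [texture_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_texture_map <- function(map, path) {
  v <- unclass(map)
  attributes(v) <- list(dim = dim(v))
  sentinel <- 0
  v[is.na(v)] <- sentinel
  tiff::writeTIFF(v, path, bits.per.sample = 32)
  meta <- list(feature = attr(map, "feature"), window = attr(map, "window"),
               stride = attr(map, "stride"), boundary = attr(map, "boundary"),
               L = attr(map, "L"), d = attr(map, "d"),
               symmetric = attr(map, "symmetric"),
               quantization_range = attr(map, "range"),
               offsets_deg = glcm_angles(), missing_sentinel = sentinel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an overlay as PNG
#'
#' @param overlay An `overlay_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(unclass(overlay), path)
  invisible(path)
}
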