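#' The four canonical GLCM offsets
#'
#' Displacements follow the standard convention in (row, col) coordinates
#' with rows increasing downward: 0 deg is (0, +d), 45 deg is (-d, +d),
#' 90 deg is (-d, 0) and 135 deg is (-d, -d).
#'
#' @return Integer vector of the four angles in degrees.
#' @export
glcm_angles <- function() c(0L, 45L, 90L, 135L)

offset_displacement <- function(angle, d = 1L) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("angle must be one of 0, 45, 90, 135")
  )
}

#' Quantize a greyscale image to discrete grey levels
#'
#' Bins intensities linearly: the interval \[`lo`, `hi`\] is split into `L`
#' equal bins, values at or below `lo` map to level 0 and values at or above
#' `hi` map to level `L - 1`. This matches the linear scaling convention of
#' the classical GLCM toolchain. A constant image (or degenerate range) maps
#' entirely to level 0.
#'
#' @param image A [grey_image()] or numeric matrix of finite intensities.
#' @param L Number of grey levels, at least 2. Default 8.
#' @param range Optional length-2 numeric `c(lo, hi)`. When omitted the
#'   image's own min and max are used. A fixed range is recommended when
#'   several images (or windows of one image) must share a grey scale.
#' @return Integer matrix of levels in `[0, L - 1]` with attribute `L`.
#' @examples
#' quantize(matrix(c(10, 20, 30, 40), 2, byrow = TRUE), L = 4, range = c(10, 40))
#' @export
quantize <- function(image, L = 8L, range = NULL) {
  m <- as_pixel_matrix(image)
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be an integer >= 2")
  if (is.null(range)) range <- c(min(m), max(m))
  stopifnot(length(range) == 2, all(is.finite(range)))
  q <- cpp_quantize(m, L, range[1], range[2])
  attr(q, "L") <- L
  q
}

#' Grey-level co-occurrence matrix at one directional offset
#'
#' Entry (i, j) counts ordered pixel pairs whose reference pixel has level i
#' and whose neighbour, at the offset displacement, has level j (levels are
#' 0-based; the matrix rows/columns are labelled accordingly). Pairs whose
#' neighbour falls outside the image are skipped. With
#' `symmetric = TRUE` each pair is also accumulated with the roles reversed,
#' making the matrix equal to its transpose.
#'
#' @param q A quantized image from [quantize()], or any integer matrix with
#'   values in `[0, L - 1]`.
#' @param angle Offset direction in degrees: 0, 45, 90 or 135.
#' @param d Offset distance in pixels (default 1).
#' @param symmetric Accumulate pairs in both orders? Default `FALSE`.
#' @param L Number of grey levels; taken from `attr(q, "L")` when present,
#'   otherwise `max(q) + 1`.
#' @return An object of class `glcm`: an `L x L` count matrix with attributes
#'   `kind = "counts"`, `angle`, `d`, `symmetric`.
#' @examples
#' g <- glcm(matrix(c(0L, 1L, 0L, 1L), 2), angle = 0)
#' sum(g)
#' @export
glcm <- function(q, angle = 0L, d = 1L, symmetric = FALSE, L = NULL) {
  if (!is.matrix(q)) stop("q must be a matrix of quantized levels")
  storage.mode(q) <- "integer"
  if (anyNA(q)) stop("quantized image contains NA")
  if (is.null(L)) L <- attr(q, "L")
  if (is.null(L)) L <- max(q) + 1L
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  if (min(q) < 0L || max(q) > L - 1L) stop("levels out of [0, L-1]")
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  angle <- as.integer(angle)
  m <- cpp_glcm_counts(q, L, angle, d, isTRUE(symmetric))
  if (attr(m, "total") <= 0)
    stop(sprintf("no valid pixel pairs at angle %d, d = %d (image too small)",
                 angle, d))
  structure(m, kind = "counts", angle = angle, d = d,
            symmetric = isTRUE(symmetric), class = c("glcm", "matrix", "array"))
}

#' Normalize a GLCM from counts to probabilities
#'
#' Divides every entry by the total pair count so the matrix sums to one and
#' each entry is the probability of observing that ordered level pair.
#'
#' @param g A `glcm` count matrix (or any non-negative matrix of counts).
#' @return The matrix rescaled to probabilities, `kind = "probabilities"`.
#' @export
normalize_glcm <- function(g) {
  if (identical(attr(g, "kind"), "probabilities")) return(g)
  total <- sum(g)
  if (total <= 0) stop("cannot normalize an empty GLCM (total count is 0)")
  p <- unclass(g) / total
  attrs <- attributes(g)
  attrs$kind <- "probabilities"
  attrs$total <- NULL
  attributes(p) <- attrs[names(attrs) != "class"]
  class(p) <- c("glcm", "matrix", "array")
  p
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("glcm (%s): %d levels, angle %s deg, d = %s, %s\n",
              attr(x, "kind") %||% "counts", nrow(x),
              attr(x, "angle") %||% "?", attr(x, "d") %||% "?",
              if (isTRUE(attr(x, "symmetric"))) "symmetric" else "asymmetric"))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Haralick texture features of a probability GLCM
#'
#' Computes the five texture statistics from a normalized co-occurrence
#' matrix `P` with entries `p(i, j)`:
#' contrast \eqn{\sum (i-j)^2 p(i,j)}; correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)} with marginal
#' means and standard deviations \eqn{\mu, \sigma}; energy (angular second
#' moment) \eqn{\sum p(i,j)^2}; homogeneity \eqn{\sum p(i,j)/(1+|i-j|)};
#' entropy \eqn{-\sum p(i,j) \log p(i,j)} with \eqn{0 \log 0 = 0}.
#' Correlation is `NA` when either marginal variance is zero (e.g. a constant
#' image), never silently 0.
#'
#' @param P A probability GLCM (entries summing to 1, e.g. from
#'   [normalize_glcm()]). Count matrices are rejected.
#' @param entropy_base Logarithm base for entropy; default `exp(1)` (nats).
#' @return Named numeric vector: `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `entropy`.
#' @examples
#' haralick_features(matrix(c(0.5, 0, 0, 0.5), 2))
#' @export
haralick_features <- function(P, entropy_base = exp(1)) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be a square matrix")
  Pm <- unclass(P)
  attributes(Pm) <- list(dim = dim(Pm))
  storage.mode(Pm) <- "double"
  if (any(Pm < 0)) stop("P has negative entries")
  if (abs(sum(Pm) - 1) > 1e-8)
    stop("P is not normalized (entries must sum to 1); see normalize_glcm()")
  f <- cpp_haralick(Pm)
  if (!identical(entropy_base, exp(1)))
    f["entropy"] <- f[["entropy"]] / log(entropy_base)
  f
}
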