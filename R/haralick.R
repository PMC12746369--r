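#' Directional Haralick texture summary of a micrograph
#'
#' The package's central analysis. The image is quantized to `L` grey levels,
#' a co-occurrence matrix is built at each of the four canonical offsets
#' (0, 45, 90 and 135 degrees) and normalized to probabilities, the five
#' Haralick features are computed per offset, and each feature is summarized
#' by its mean and standard deviation over the four directions — the standard
#' way directional texture statistics are reported for micrographs.
#'
#' @param image A [grey_image()] or numeric matrix of finite intensities.
#' @param L Number of grey levels (default 8).
#' @param d Offset distance in pixels (default 1).
#' @param symmetric Symmetric pair accumulation? Default `FALSE`.
#' @param range Optional fixed quantization range `c(lo, hi)`; default is the
#'   image's own min-max. Use a fixed range when comparing images or windows
#'   that must share a grey scale.
#' @param entropy_base Logarithm base for entropy (default nats).
#' @return An object of class `haralick` with components:
#'   \item{features}{4 x 5 matrix of per-offset feature values (rows are
#'     angles 0/45/90/135).}
#'   \item{mean, sd}{Named vectors of the per-feature mean and population
#'     standard deviation (division by 4) over the four offsets.}
#'   plus the parameters used (`L`, `d`, `symmetric`, `range`,
#'   `entropy_base`, `pixel_size`).
#' @examples
#' set.seed(1)
#' h <- haralick(matrix(runif(1024), 32))
#' h
#' coef(h)
#' @export
haralick <- function(image, L = 8L, d = 1L, symmetric = FALSE, range = NULL,
                     entropy_base = exp(1)) {
  m <- as_pixel_matrix(image)
  if (is.null(range)) range <- c(min(m), max(m))
  q <- quantize(m, L = L, range = range)
  angles <- glcm_angles()
  feats <- matrix(NA_real_, 4, 5,
                  dimnames = list(paste0(angles, "deg"),
                                  c("contrast", "correlation", "energy",
                                    "homogeneity", "entropy")))
  for (k in seq_along(angles)) {
    g <- tryCatch(glcm(q, angle = angles[k], d = d, symmetric = symmetric),
                  error = function(e)
                    stop(sprintf("offset %d deg yields an empty GLCM: %s",
                                 angles[k], conditionMessage(e)), call. = FALSE))
    feats[k, ] <- haralick_features(normalize_glcm(g),
                                    entropy_base = entropy_base)
  }
  mu <- apply(feats, 2, function(v) (v[1] + v[2] + v[3] + v[4]) / 4)
  sdv <- apply(feats, 2, function(v) {
    m4 <- (v[1] + v[2] + v[3] + v[4]) / 4
    sqrt(((v[1] - m4)^2 + (v[2] - m4)^2 + (v[3] - m4)^2 + (v[4] - m4)^2) / 4)
  })
  structure(list(features = feats, mean = mu, sd = sdv,
                 L = as.integer(L), d = as.integer(d),
                 symmetric = isTRUE(symmetric), range = range,
                 entropy_base = entropy_base,
                 pixel_size = pixel_size_of(image),
                 dim = dim(m), call = match.call()),
            class = "haralick")
}

# "0.037 +/- 0.007" cells, Table-style.
format_pm <- function(mean, sd, digits = 3) {
  ifelse(is.na(mean), "undef",
         sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean, sd))
}

#' @export
print.haralick <- function(x, digits = 3, ...) {
  cat(sprintf("Haralick texture summary (%d x %d px, L = %d, d = %d, %s)\n",
              x$dim[1], x$dim[2], x$L, x$d,
              if (x$symmetric) "symmetric" else "asymmetric"))
  cat("Mean ± SD over offsets 0/45/90/135 deg:\n")
  cells <- format_pm(x$mean, x$sd, digits)
  for (i in seq_along(cells))
    cat(sprintf("  %-12s %s\n", names(x$mean)[i], cells[i]))
  invisible(x)
}

#' @export
summary.haralick <- function(object, ...) {
  out <- data.frame(feature = colnames(object$features),
                    mean = unname(object$mean), sd = unname(object$sd),
                    stringsAsFactors = FALSE)
  out[paste0("offset_", rownames(object$features))] <- t(object$features)
  class(out) <- c("summary.haralick", "data.frame")
  out
}

#' @export
print.summary.haralick <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.haralick <- function(object, ...) object$mean

#' @export
as.data.frame.haralick <- function(x, ...) {
  data.frame(feature = colnames(x$features), mean = unname(x$mean),
             sd = unname(x$sd), L = x$L, d = x$d, symmetric = x$symmetric,
             stringsAsFactors = FALSE)
}

#' Feature table export
#'
#' Writes one or more `haralick` summaries as a long-format CSV with columns
#' `image`, `condition`, `modality`, `feature`, `mean`, `std`, `L`, `d`,
#' `symmetric`.
#'
#' @param summaries Named list of `haralick` objects; names become the
#'   `image` column.
#' @param path Output CSV path.
#' @param condition,modality Optional character vectors (recycled) recorded
#'   per summary.
#' @return The table, invisibly.
#' @export
write_feature_table <- function(summaries, path, condition = NA, modality = NA) {
  stopifnot(is.list(summaries), length(summaries) > 0)
  nm <- names(summaries) %||% as.character(seq_along(summaries))
  condition <- rep_len(condition, length(summaries))
  modality <- rep_len(modality, length(summaries))
  rows <- mapply(function(h, img, cond, mod) {
    data.frame(image = img, condition = cond, modality = mod,
               feature = names(h$mean), mean = unname(h$mean),
               std = unname(h$sd), L = h$L, d = h$d,
               symmetric = h$symmetric, stringsAsFactors = FALSE)
  }, summaries, nm, condition, modality, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
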