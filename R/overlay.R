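#' Two-channel cross-modality composite
#'
#' Writes two greyscale micrographs of the same field into two distinct
#' colour channels of one RGB image — the standard red/blue composite used to
#' compare a surface-sensitive modality against a bulk-sensitive one: regions
#' that appear in only one channel flag features visible in one modality but
#' masked in the other. Each image is min-max normalized independently
#' (modalities have incommensurate intensity scales) before being written
#' into its channel. Image B may be shifted by an integer (row, col)
#' translation; outside the overlap each channel is zero.
#'
#' @param a,b [grey_image()]s or numeric matrices with the same pixel size.
#' @param channels Length-2 character: the colour channel of `a` and of `b`,
#'   from `"red"`, `"green"`, `"blue"`; must be distinct. Default
#'   `c("red", "blue")`.
#' @param shift Integer `c(rows, cols)` translation applied to `b` (positive
#'   shifts move `b` down/right). Default `c(0, 0)`.
#' @return An `overlay_image` (H x W x 3, the size of `a`) whose
#'   `provenance` records the channels, normalization bounds and translation.
#' @export
channel_overlay <- function(a, b, channels = c("red", "blue"),
                            shift = c(0L, 0L)) {
  am <- as_pixel_matrix(a); bm <- as_pixel_matrix(b)
  if (abs(pixel_size_of(a) - pixel_size_of(b)) > 1e-12)
    stop("images have different pixel sizes")
  channels <- match.arg(channels, c("red", "green", "blue"),
                        several.ok = TRUE)
  if (length(channels) != 2 || channels[1] == channels[2])
    stop("channels must be two distinct colour channels")
  shift <- as.integer(shift)
  stopifnot(length(shift) == 2)

  H <- nrow(am); W <- ncol(am)
  # overlap of a's frame with b translated by `shift`
  r_lo <- max(1L, 1L + shift[1]); r_hi <- min(H, nrow(bm) + shift[1])
  c_lo <- max(1L, 1L + shift[2]); c_hi <- min(W, ncol(bm) + shift[2])
  if (r_lo > r_hi || c_lo > c_hi)
    stop("empty overlap between images after translation")

  norm01 <- function(m) {
    r <- range(m)
    list(values = if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0,
         bounds = r)
  }
  na <- norm01(am); nb <- norm01(bm)
  out <- array(0, c(H, W, 3))
  ch_index <- c(red = 1L, green = 2L, blue = 3L)
  plane_a <- matrix(0, H, W)
  plane_a[r_lo:r_hi, c_lo:c_hi] <- na$values[r_lo:r_hi, c_lo:c_hi]
  plane_b <- matrix(0, H, W)
  plane_b[r_lo:r_hi, c_lo:c_hi] <-
    nb$values[(r_lo:r_hi) - shift[1], (c_lo:c_hi) - shift[2], drop = FALSE]
  out[, , ch_index[channels[1]]] <- plane_a
  out[, , ch_index[channels[2]]] <- plane_b
  structure(out, provenance = list(
    kind = "channel_overlay", channel_a = channels[1],
    channel_b = channels[2], bounds_a = na$bounds, bounds_b = nb$bounds,
    shift = shift,
    overlap = c(rows = r_hi - r_lo + 1L, cols = c_hi - c_lo + 1L)),
    class = c("overlay_image", "array"))
}
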