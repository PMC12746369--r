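#' Parameters of a synthetic biofilm scene
#'
#' Describes a simulated field of rod-shaped bacterial cells in clusters,
#' optionally veiled by a smooth extracellular-matrix (EPS) overlayer, to be
#' rendered by [render_scene()] and imaged by [modality_transform()]. The
#' generator is phenomenological: it reproduces the texture statistics that
#' the downstream analysis measures (smooth veiled surfaces versus exposed
#' cells and debris), not the physics of any instrument.
#'
#' The `native` condition carries a nearly complete, strong EPS veil and no
#' debris; the `treated` condition (emulating enzymatic disruption of the
#' matrix) has sparse veil remnants, exposed cells and added fragments.
#'
#' @param condition `"native"` or `"treated"`; sets the veil and fragment
#'   defaults below, all of which can be overridden.
#' @param width,height Field size in pixels (default 400 x 400).
#' @param pixel_size Micrometres per pixel (default 0.25).
#' @param n_cells Number of rod-shaped cells (default 60).
#' @param cell_length,cell_width Cell dimensions in micrometres (defaults
#'   4.0 x 0.6, rod-shaped).
#' @param n_clusters Number of cell clusters (default 3).
#' @param cluster_spread Standard deviation of cell placement around its
#'   cluster centre, in micrometres (default 8).
#' @param eps_coverage Fraction of the field covered by the EPS veil
#'   (native default 1.0; treated default 0.2).
#' @param veil_strength Blend weight of the veil in \[0, 1\] (native default
#'   0.85; treated default 0.25).
#' @param fragment_density Debris fragments per 1000 square micrometres
#'   (native default 0; treated default 8).
#' @param modality Imaging profile for [modality_transform()]: `"optical"`,
#'   `"sem"`, `"shem"` or `"identity"`.
#' @param blur_sigma Rendering blur of the raw scene in pixels (default 0.6).
#' @param noise_sd Rendering noise of the raw scene (default 0.01).
#' @param seed Integer seed; fixes the entire scene.
#' @return A `scene_params` list.
#' @export
scene_params <- function(condition = c("native", "treated"),
                         width = 400L, height = 400L, pixel_size = 0.25,
                         n_cells = 60L, cell_length = 4.0, cell_width = 0.6,
                         n_clusters = 3L, cluster_spread = 8,
                         eps_coverage = NULL, veil_strength = NULL,
                         fragment_density = NULL,
                         modality = "shem", blur_sigma = 0.6,
                         noise_sd = 0.01, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(eps_coverage))
    eps_coverage <- if (condition == "native") 1.0 else 0.2
  if (is.null(veil_strength))
    veil_strength <- if (condition == "native") 0.85 else 0.25
  if (is.null(fragment_density))
    fragment_density <- if (condition == "native") 0 else 8
  stopifnot(eps_coverage >= 0, eps_coverage <= 1,
            veil_strength >= 0, veil_strength <= 1,
            fragment_density >= 0, width >= 1, height >= 1,
            pixel_size > 0, n_cells >= 0, cell_length > 0, cell_width > 0)
  p <- list(condition = condition, width = as.integer(width),
            height = as.integer(height), pixel_size = pixel_size,
            n_cells = as.integer(n_cells), cell_length = cell_length,
            cell_width = cell_width, n_clusters = as.integer(n_clusters),
            cluster_spread = cluster_spread, eps_coverage = eps_coverage,
            veil_strength = veil_strength,
            fragment_density = fragment_density, modality = modality,
            blur_sigma = blur_sigma, noise_sd = noise_sd,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  p
}

#' Render a synthetic biofilm scene
#'
#' Draws rod-shaped cells as oriented capsules with Lambertian-like
#' cross-section shading, grouped into clusters over a smoothly varying
#' background, then applies the EPS veil and (for the treated condition)
#' debris fragments as dictated by the parameters. Fully deterministic given
#' the seed.
#'
#' @param params A [scene_params()] object.
#' @return A `biofilm_scene` list: `image` (a [grey_image()] before any
#'   modality transform), and `truth` with `cell_mask`, `eps_mask` (logical
#'   matrices) and `cells` (a data frame of per-cell geometry: centre, angle,
#'   length and width in pixels, cluster id).
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  H <- p$height; W <- p$width
  len_px <- p$cell_length / p$pixel_size
  wid_px <- p$cell_width / p$pixel_size
  if (len_px >= min(H, W))
    stop("cells cannot fit the field (cell length exceeds field size)")
  spread_px <- p$cluster_spread / p$pixel_size

  scene <- with_seed(p$seed, {
    # smooth background whose large-scale relief genuinely spans several
    # grey levels (standardized by sd; scale chosen so +/-2 sd covers about
    # half the intensity range)
    f <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), 10)
    bg <- 0.45 + 0.15 * (f - mean(f)) / stats::sd(f)
    img <- bg
    cell_mask <- matrix(FALSE, H, W)

    cells <- NULL
    if (p$n_cells > 0) {
      ctr_r <- stats::runif(p$n_clusters, 0.2 * H, 0.8 * H)
      ctr_c <- stats::runif(p$n_clusters, 0.2 * W, 0.8 * W)
      base_ang <- stats::runif(p$n_clusters, 0, pi)
      cl <- sample(rep_len(seq_len(p$n_clusters), p$n_cells))
      rows <- pmin(H - 2, pmax(2, ctr_r[cl] + stats::rnorm(p$n_cells, sd = spread_px)))
      cols <- pmin(W - 2, pmax(2, ctr_c[cl] + stats::rnorm(p$n_cells, sd = spread_px)))
      angs <- base_ang[cl] + stats::rnorm(p$n_cells, sd = 25 * pi / 180)
      lens <- len_px * stats::runif(p$n_cells, 0.8, 1.2)
      for (i in seq_len(p$n_cells)) {
        res <- draw_capsule(img, cell_mask, rows[i], cols[i], angs[i],
                            lens[i], wid_px)
        img <- res$img; cell_mask <- res$mask
      }
      cells <- data.frame(row = rows, col = cols, angle = angs,
                          length_px = lens, width_px = wid_px, cluster = cl)
    }

    # debris fragments: short dim capsules scattered over the field
    area_um2 <- H * W * p$pixel_size^2
    n_frag <- round(p$fragment_density * area_um2 / 1000)
    if (n_frag > 0) {
      fr <- stats::runif(n_frag, 2, H - 2)
      fc <- stats::runif(n_frag, 2, W - 2)
      fa <- stats::runif(n_frag, 0, pi)
      fl <- stats::runif(n_frag, 0.3, 1.2) * len_px * 0.25
      for (i in seq_len(n_frag)) {
        res <- draw_capsule(img, cell_mask, fr[i], fc[i], fa[i], fl[i],
                            wid_px * 0.7, peak = 0.62, base = 0.45,
                            mask_too = FALSE)
        img <- res$img
      }
    }

    img <- gaussian_blur(img, p$blur_sigma)
    img <- img + stats::rnorm(H * W, sd = p$noise_sd)

    eps_mask <- make_eps_mask(c(H, W), p$eps_coverage,
                              seed = p$seed + 101L)
    img <- apply_eps_veil(img, eps_mask, strength = p$veil_strength)
    list(image = img, cell_mask = cell_mask, eps_mask = eps_mask,
         cells = cells)
  })
  structure(list(image = grey_image(clamp(scene$image, 0, 1),
                                    pixel_size = p$pixel_size),
                 truth = list(cell_mask = scene$cell_mask,
                              eps_mask = scene$eps_mask,
                              cells = scene$cells),
                 params = p),
            class = "biofilm_scene")
}

scale01 <- function(m) {
  r <- range(m)
  if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
}

# Composite one capsule (rounded rod) into the image with a cylindrical
# shading profile; overlapping cells take the maximum, not the sum.
draw_capsule <- function(img, mask, row, col, angle, length_px, width_px,
                         peak = 0.95, base = 0.55, mask_too = TRUE) {
  half_axis <- max(length_px / 2 - width_px / 2, 0.5)
  rad <- max(width_px / 2, 0.8)
  dr <- sin(angle) * half_axis; dc <- cos(angle) * half_axis
  dist <- cpp_segment_distance(nrow(img), ncol(img),
                               row - dr, col - dc, row + dr, col + dc, rad)
  inside <- dist <= rad
  if (any(inside)) {
    shade <- base + (peak - base) * sqrt(pmax(0, 1 - (dist[inside] / rad)^2))
    img[inside] <- pmax(img[inside], shade)
    if (mask_too) mask[inside] <- TRUE
  }
  list(img = img, mask = mask)
}

#' EPS coverage mask from a smooth random field
#'
#' Thresholds a heavily blurred white-noise field at the quantile that leaves
#' the requested fraction of pixels covered, producing contiguous blob-shaped
#' coverage regions.
#'
#' @param dim Length-2 integer `c(H, W)`.
#' @param coverage Covered fraction in \[0, 1\].
#' @param seed Integer seed.
#' @param scale Correlation length of the field in pixels (default 25).
#' @return Logical H x W matrix with `mean(mask)` within 2% of `coverage`.
#' @export
make_eps_mask <- function(dim, coverage, seed = 1L, scale = 25) {
  stopifnot(coverage >= 0, coverage <= 1)
  if (coverage == 0) return(matrix(FALSE, dim[1], dim[2]))
  if (coverage == 1) return(matrix(TRUE, dim[1], dim[2]))
  field <- with_seed(seed,
    gaussian_blur(matrix(stats::rnorm(dim[1] * dim[2]), dim[1], dim[2]),
                  scale))
  thr <- stats::quantile(field, 1 - coverage, names = FALSE)
  field >= thr
}

#' Veil an image under a smooth EPS-like overlayer
#'
#' Within the masked region, blends the image toward a heavily blurred,
#' intensity-flattened version of itself, emulating a smooth matrix layer
#' that obscures underlying cell texture. `strength = 0` returns the image
#' unchanged; `strength = 1` with full coverage yields a near-featureless
#' surface whose windowed energy approaches 1. The mask edge is feathered so
#' the veil boundary itself does not introduce sharp texture.
#'
#' @param image A [grey_image()] or numeric matrix.
#' @param mask Logical matrix (e.g. from [make_eps_mask()]), same size.
#' @param strength Blend weight in \[0, 1\].
#' @return The veiled image (same class handling as the input matrix).
#' @export
apply_eps_veil <- function(image, mask, strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  m <- as_pixel_matrix(image)
  if (!all(dim(mask) == dim(m))) stop("mask and image shapes differ")
  if (strength == 0 || !any(mask)) return(image)
  smooth <- gaussian_blur(m, 8)
  mu <- mean(smooth[mask])
  # flattened veil surface: keeps subdued large-scale relief only
  target <- mu + 0.7 * (smooth - mu)
  w <- strength * gaussian_blur(matrix(as.numeric(mask), nrow(m)), 2)
  out <- (1 - w) * m + w * target
  if (inherits(image, "grey_image"))
    grey_image(out, pixel_size = pixel_size_of(image))
  else out
}

#' Imaging-modality transform
#'
#' Re-images a rendered scene under one of three phenomenological modality
#' profiles chosen so that, on a common scene, whole-image Haralick contrast
#' orders optical < SEM < SHeM and energy the reverse — the characteristic
#' ordering of these modalities on biofilm surfaces:
#' \describe{
#'   \item{optical}{strong defocus blur, very low detector noise: smooth,
#'     low-contrast, highly homogeneous images.}
#'   \item{sem}{moderate blur, mild gamma, intermediate noise.}
#'   \item{shem}{edge emphasis (unsharp masking) and the highest
#'     pixel-to-pixel noise, reflecting the count-limited, highly
#'     surface-sensitive signal.}
#' }
#' `"identity"` returns the image unchanged.
#'
#' @param image A [grey_image()] or numeric matrix with intensities in
#'   \[0, 1\] (values outside are clipped; no rescaling is applied, so a
#'   featureless surface stays featureless).
#' @param profile `"optical"`, `"sem"`, `"shem"` or `"identity"`.
#' @param seed Integer seed for the noise realization.
#' @return The transformed image, intensities clipped to \[0, 1\].
#' @export
modality_transform <- function(image, profile, seed = 1L) {
  profile <- match.arg(profile, c("optical", "sem", "shem", "identity"))
  if (profile == "identity") return(image)
  m <- clamp(as_pixel_matrix(image), 0, 1)
  out <- with_seed(seed, switch(profile,
    optical = {
      b <- gaussian_blur(m, 2.5)
      b + stats::rnorm(length(m), sd = 0.002)
    },
    sem = {
      b <- gaussian_blur(m, 0.8)
      b + stats::rnorm(length(m), sd = 0.005)
    },
    shem = {
      sharp <- m + 1.5 * (m - gaussian_blur(m, 1.5))
      sharp + stats::rnorm(length(m), sd = 0.06)
    }))
  out <- clamp(out, 0, 1)
  if (inherits(image, "grey_image"))
    grey_image(out, pixel_size = pixel_size_of(image))
  else out
}

#' Simulate one micrograph
#'
#' Convenience wrapper: builds [scene_params()] for the condition, renders
#' the scene and applies the modality transform. The scene and the modality
#' noise use seeds derived deterministically from `seed`, so the same call
#' always returns the same image, and native/treated pairs at the same seed
#' share nothing but the seed arithmetic.
#'
#' @param condition `"native"` or `"treated"`.
#' @param modality `"optical"`, `"sem"`, `"shem"` or `"identity"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scene_params()].
#' @return A [grey_image()].
#' @export
simulate_micrograph <- function(condition = "native", modality = "shem",
                                seed = 1L, ...) {
  seed <- as.integer(seed)
  # both conditions share the scene seed: the same field imaged before and
  # after treatment, differing only in veil and debris
  scene_seed <- seed * 7L + 11L
  p <- scene_params(condition = condition, modality = modality,
                    seed = scene_seed, ...)
  sc <- render_scene(p)
  noise_seed <- scene_seed + 1000L +
    match(modality, c("optical", "sem", "shem", "identity"))
  modality_transform(sc$image, modality, seed = noise_seed)
}

#' @export
print.biofilm_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "biofilm_scene (%s): %d x %d px, %d cells / %d clusters, EPS %.0f%% x %.2f, %d fragments/1000um2, seed %d\n",
    p$condition, p$height, p$width, p$n_cells, p$n_clusters,
    100 * p$eps_coverage, p$veil_strength, p$fragment_density, p$seed))
  invisible(x)
}

#' @export
plot.biofilm_scene <- function(x, ...) plot(x$image, ...)

#' Generate a full synthetic study on disk
#'
#' Writes native and treated scenes imaged under all three modality profiles
#' (six 16-bit greyscale TIFFs), the two conditions' truth masks (PNG) and a
#' JSON manifest holding every parameter and derived seed. Regenerating with
#' the same seed (or from the manifest) is bit-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param manifest Optional path to a manifest written by a previous call;
#'   when given, its seed is reused and `seed` is ignored.
#' @return The manifest list, invisibly.
#' @export
generate_study <- function(dir, seed = 1L, manifest = NULL) {
  if (!is.null(manifest)) {
    man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    seed <- as.integer(man$seed)
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  seed <- as.integer(seed)
  modalities <- c("optical", "sem", "shem")
  files <- list()
  for (cond in c("native", "treated")) {
    scene_seed <- seed * 7L + 11L
    sc <- render_scene(scene_params(condition = cond, seed = scene_seed))
    for (mod in modalities) {
      img <- modality_transform(sc$image, mod,
                                seed = scene_seed + 1000L +
                                  match(mod, c("optical", "sem", "shem",
                                               "identity")))
      fn <- file.path(dir, sprintf("%s_%s.tif", cond, mod))
      write_grey_image(img, fn, bits = 16)
      files[[sprintf("%s_%s", cond, mod)]] <- basename(fn)
    }
    for (msk in c("cell_mask", "eps_mask")) {
      fn <- file.path(dir, sprintf("%s_%s.png", cond, msk))
      png::writePNG(matrix(as.numeric(sc$truth[[msk]]), nrow(sc$image)), fn)
      files[[sprintf("%s_%s", cond, msk)]] <- basename(fn)
    }
  }
  man <- list(seed = seed, pixel_size = 0.25, modalities = modalities,
              conditions = c("native", "treated"), files = files,
              native_params = unclass(scene_params("native",
                seed = seed * 7L + 11L)),
              treated_params = unclass(scene_params("treated",
                seed = seed * 7L + 11L)))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
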