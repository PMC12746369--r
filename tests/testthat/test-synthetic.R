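small_params <- function(condition = "native", seed = 1, n_cells = 12L, ...) {
  scene_params(condition, width = 128L, height = 128L, n_cells = n_cells,
               n_clusters = 2L, cluster_spread = 4, seed = seed, ...)
}

test_that("scene rendering is bit-identical under a fixed seed", {
  s1 <- render_scene(small_params(seed = 7))
  s2 <- render_scene(small_params(seed = 7))
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(s1$truth$cell_mask, s2$truth$cell_mask)
  s3 <- render_scene(small_params(seed = 8))
  expect_false(identical(unclass(s1$image), unclass(s3$image)))
})

test_that("an empty scene is background only", {
  sc <- render_scene(small_params(n_cells = 0L, eps_coverage = 0,
                                  fragment_density = 0))
  expect_false(any(sc$truth$cell_mask))
  expect_null(sc$truth$cells)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
})

test_that("cells that cannot fit the field are rejected", {
  expect_error(render_scene(scene_params(width = 12L, height = 12L,
                                         cell_length = 4)),
               "cannot fit")
})

test_that("cell mask area is consistent with summed capsule geometry", {
  sc <- render_scene(scene_params("native", n_cells = 50L, n_clusters = 3L,
                                  eps_coverage = 0, veil_strength = 0,
                                  seed = 7))
  cells <- sc$truth$cells
  rad <- cells$width_px / 2
  analytic <- sum((cells$length_px - cells$width_px) * cells$width_px +
                    pi * rad^2)
  measured <- sum(sc$truth$cell_mask)
  expect_gt(measured, 0.6 * analytic)  # overlap within clusters
  expect_lt(measured, 1.2 * analytic)
})

test_that("eps masks hit the requested coverage", {
  for (cov in c(0.2, 0.5, 0.9)) {
    m <- make_eps_mask(c(200, 200), cov, seed = 3)
    expect_lt(abs(mean(m) - cov), 0.02)
  }
  expect_identical(make_eps_mask(c(10, 10), 0), matrix(FALSE, 10, 10))
  expect_identical(make_eps_mask(c(10, 10), 1), matrix(TRUE, 10, 10))
})

test_that("the veil is the identity at zero strength and smooths otherwise", {
  sc <- render_scene(small_params(eps_coverage = 0, veil_strength = 0,
                                  seed = 9))
  img <- unclass(sc$image)
  mask <- matrix(TRUE, nrow(img), ncol(img))
  expect_identical(apply_eps_veil(img, mask, strength = 0), img)
  veiled <- apply_eps_veil(img, mask, strength = 1)
  e0 <- mean(texture_map(img, "energy", window = 11, range = c(0, 1)))
  e1 <- mean(texture_map(veiled, "energy", window = 11, range = c(0, 1)))
  expect_gt(e1, e0)
})

test_that("windowed energy is non-decreasing in veil strength", {
  sc <- render_scene(small_params(eps_coverage = 0, veil_strength = 0,
                                  seed = 10))
  img <- unclass(sc$image)
  mask <- matrix(TRUE, nrow(img), ncol(img))
  e <- sapply(c(0, 0.3, 0.6, 0.9), function(s)
    mean(texture_map(apply_eps_veil(img, mask, s), "energy", window = 11,
                     range = c(0, 1))))
  expect_true(all(diff(e) >= 0))
})

test_that("a half-veiled field has higher energy on the veiled half", {
  sc <- render_scene(small_params(eps_coverage = 0, veil_strength = 0,
                                  seed = 11))
  img <- unclass(sc$image)
  mask <- matrix(FALSE, 128, 128); mask[, 1:64] <- TRUE
  veiled <- apply_eps_veil(img, mask, strength = 0.9)
  tm <- texture_map(veiled, "energy", window = 11, range = c(0, 1))
  expect_gt(mean(unclass(tm)[12:116, 12:55], na.rm = TRUE),
            mean(unclass(tm)[12:116, 74:116], na.rm = TRUE))
})

test_that("modality transforms are seeded, bounded and reject unknowns", {
  sc <- render_scene(small_params(seed = 12))
  m1 <- modality_transform(sc$image, "shem", seed = 4)
  m2 <- modality_transform(sc$image, "shem", seed = 4)
  expect_identical(unclass(m1), unclass(m2))
  expect_false(identical(unclass(m1),
                         unclass(modality_transform(sc$image, "shem",
                                                    seed = 5))))
  expect_identical(modality_transform(sc$image, "identity"), sc$image)
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_error(modality_transform(sc$image, "xray"), "should be one of")
})

test_that("modality profiles order contrast and energy on a common scene", {
  sc <- render_scene(scene_params("treated", seed = 31))
  f <- sapply(c("optical", "sem", "shem"), function(mod)
    haralick(modality_transform(sc$image, mod, seed = 3),
             range = c(0, 1))$mean)
  expect_lt(f["contrast", "optical"], f["contrast", "sem"])
  expect_lt(f["contrast", "sem"], f["contrast", "shem"])
  expect_gt(f["energy", "optical"], f["energy", "sem"])
  expect_gt(f["energy", "sem"], f["energy", "shem"])
})

test_that("simulated native surfaces are more uniform than treated ones", {
  hn <- haralick(simulate_micrograph("native", "shem", seed = 1),
                 range = c(0, 1))
  ht <- haralick(simulate_micrograph("treated", "shem", seed = 1),
                 range = c(0, 1))
  expect_gt(hn$mean["energy"], ht$mean["energy"])
  expect_lt(hn$mean["contrast"], ht$mean["contrast"])
})

test_that("a generated study is complete and regenerates bit-identically", {
  d1 <- file.path(tempdir(), "study1")
  d2 <- file.path(tempdir(), "study2")
  man <- generate_study(d1, seed = 5)
  expect_length(man$files, 10)  # 6 images + 2 x 2 truth masks
  imgs <- list.files(d1, pattern = "\\.tif$")
  expect_length(imgs, 6)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  generate_study(d2, manifest = file.path(d1, "manifest.json"))
  for (f in names(man$files)) {
    expect_identical(readBin(file.path(d1, man$files[[f]]), "raw", 1e7),
                     readBin(file.path(d2, man$files[[f]]), "raw", 1e7),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
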