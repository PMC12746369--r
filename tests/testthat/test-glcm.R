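test_that("quantization follows the linear-binning convention", {
  # one value per bin
  expect_equal(
    unclass(quantize(matrix(c(10, 20, 30, 40), 2, byrow = TRUE), L = 4,
                     range = c(10, 40))),
    matrix(c(0L, 1L, 2L, 3L), 2, byrow = TRUE), ignore_attr = TRUE)
  # constant image collapses onto a single level
  expect_true(all(quantize(matrix(5, 4, 4), L = 8) == 0L))
  # 0..255 into 8 bins: edges at multiples of 32 for integer intensities
  x <- matrix(0:255, 16)
  q <- quantize(x, L = 8, range = c(0, 255))
  expect_equal(unclass(q), matrix(pmin(7L, (0:255) %/% 32L), 16),
               ignore_attr = TRUE)
  # out-of-range values clamp to the end bins
  q2 <- quantize(matrix(c(-5, 0.2, 0.9, 99), 2), L = 4, range = c(0, 1))
  expect_equal(sort(as.vector(q2)), c(0L, 0L, 3L, 3L))
})

test_that("quantization rejects bad input", {
  expect_error(quantize(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(quantize(matrix(c(1, Inf, 2, 3), 2)), "non-finite")
  expect_error(quantize(matrix(1:4, 2), L = 1), "L must be")
})

test_that("co-occurrence counts match the worked examples", {
  # two horizontal pairs, same level each
  g <- glcm(matrix(c(0L, 0L, 1L, 1L), 2, byrow = TRUE), angle = 0)
  expect_equal(unclass(g), matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  # checkerboard
  g2 <- glcm(matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE), angle = 0)
  expect_equal(unclass(g2), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # an image smaller than the displacement has no pairs
  expect_error(glcm(matrix(0L, 1, 2), angle = 0, d = 5, L = 2),
               "no valid pixel pairs")
})

test_that("counts equal exhaustive pair enumeration at every offset", {
  set.seed(11)
  for (rep in 1:10) {
    L <- sample(c(2, 4, 8), 1)
    q <- random_quantized(sample(4:16, 1), sample(4:16, 1), L)
    for (ang in glcm_angles()) {
      for (sym in c(FALSE, TRUE)) {
        got <- glcm(q, angle = ang, d = 1, symmetric = sym, L = L)
        expect_equal(unclass(got), oracle_glcm(q, L, ang, 1, sym),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("total count obeys the closed-form pair-count formula", {
  set.seed(12)
  for (rep in 1:20) {
    H <- sample(3:20, 1); W <- sample(3:20, 1); d <- sample(1:2, 1)
    q <- random_quantized(H, W, 4)
    for (ang in glcm_angles()) {
      for (sym in c(FALSE, TRUE)) {
        n_exp <- expected_pair_count(H, W, ang, d, sym)
        if (n_exp == 0) {
          expect_error(glcm(q, angle = ang, d = d, symmetric = sym, L = 4))
        } else {
          expect_equal(sum(glcm(q, angle = ang, d = d, symmetric = sym,
                                L = 4)), n_exp)
        }
      }
    }
  }
})

test_that("normalization yields probabilities summing to one", {
  expect_equal(unclass(normalize_glcm(matrix(c(1, 0, 0, 1), 2))),
               matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  expect_equal(unclass(normalize_glcm(matrix(c(0, 1, 1, 0), 2))),
               matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rpois(16, 3), 4)
    if (sum(m) == 0) m[1, 1] <- 1
    expect_equal(sum(normalize_glcm(m)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_glcm(matrix(0, 3, 3)), "empty")
})

test_that("symmetric accumulation gives a symmetric matrix", {
  set.seed(14)
  q <- random_quantized(12, 12, 8)
  for (ang in glcm_angles()) {
    g <- glcm(q, angle = ang, symmetric = TRUE)
    expect_identical(unclass(g), t(unclass(g)))
  }
})

test_that("feature closed forms hold for the two-level cases", {
  f <- haralick_features(matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(unname(f), c(0, 1, 0.5, 1, log(2)), tolerance = 1e-12)
  f2 <- haralick_features(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(unname(f2), c(1, -1, 0.5, 0.5, log(2)), tolerance = 1e-12)
  # single-entry matrix: the constant-image limit
  P <- matrix(0, 4, 4); P[2, 2] <- 1
  f3 <- haralick_features(P)
  expect_equal(unname(f3[c("contrast", "energy", "homogeneity", "entropy")]),
               c(0, 1, 1, 0))
  expect_true(is.na(f3["correlation"]))
})

test_that("features match naive double-loop evaluation on random matrices", {
  set.seed(15)
  for (rep in 1:20) {
    L <- sample(c(2, 4, 8), 1)
    P <- matrix(rexp(L * L), L); P <- P / sum(P)
    expect_equal(unname(haralick_features(P)), unname(oracle_haralick(P)),
                 tolerance = 1e-12)
  }
})

test_that("features reject unnormalized or invalid matrices", {
  expect_error(haralick_features(matrix(c(1, 0, 0, 1), 2)), "not normalized")
  expect_error(haralick_features(matrix(0.25, 2, 4)), "square")
})

test_that("entropy base is configurable", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(unname(haralick_features(P, entropy_base = 2)["entropy"]), 1)
})

test_that("grey-level reversal preserves all five features", {
  set.seed(16)
  for (rep in 1:10) {
    L <- 8
    q <- random_quantized(10, 10, L)
    for (ang in c(0L, 90L)) {
      f1 <- haralick_features(normalize_glcm(glcm(q, angle = ang, L = L)))
      f2 <- haralick_features(normalize_glcm(glcm(L - 1L - q, angle = ang,
                                                  L = L)))
      expect_equal(f1, f2, tolerance = 1e-12)
    }
  }
})

test_that("directional summary behaves on isotropic and striped images", {
  h <- haralick(matrix(7, 8, 8))
  expect_equal(unname(h$mean[c("contrast", "energy", "homogeneity",
                               "entropy")]), c(0, 1, 1, 0))
  expect_true(is.na(h$mean["correlation"]))
  expect_equal(unname(h$sd[c("contrast", "energy")]), c(0, 0))
  # vertical stripes: horizontal offset sees transitions, vertical does not
  stripes <- matrix(rep(c(0, 1), each = 8, times = 4), 8, 8)
  hs <- haralick(stripes, L = 2)
  expect_gt(hs$features["0deg", "contrast"],
            hs$features["90deg", "contrast"])
  expect_gt(hs$sd["contrast"], 0)
})

test_that("summary statistics use the population convention over offsets", {
  set.seed(17)
  img <- matrix(runif(400), 20)
  h <- haralick(img)
  v <- h$features[, "contrast"]
  expect_equal(unname(h$mean["contrast"]), mean(v))
  expect_equal(unname(h$sd["contrast"]), sqrt(mean((v - mean(v))^2)))
})

test_that("printed summaries use the mean-plus-minus-sd cell format", {
  set.seed(18)
  h <- haralick(matrix(runif(256), 16))
  out <- capture.output(print(h))
  expect_true(any(grepl("contrast\\s+\\d+\\.\\d{3} ± \\d+\\.\\d{3}", out)))
})

test_that("feature table export has the documented columns", {
  set.seed(19)
  h <- haralick(matrix(runif(256), 16))
  f <- tempfile(fileext = ".csv")
  tab <- write_feature_table(list(img1 = h), f, condition = "native",
                             modality = "shem")
  expect_true(file.exists(f))
  got <- read.csv(f)
  expect_named(got, c("image", "condition", "modality", "feature", "mean",
                      "std", "L", "d", "symmetric"))
  expect_equal(nrow(got), 5)
})
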