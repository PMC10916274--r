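# Feature chain building blocks: modality preprocessing, kNN + ratio
# matching, robust homography estimation, warping.

test_that("modality preprocessing reconciles intensity conventions", {
  const <- matrix(0.4, 30, 30)
  for (m in c("generic", "he", "nlo")) {
    out <- preprocess_modality(const, m)
    expect_true(all(out == out[1, 1]))
  }
  # H&E: dark tissue on bright background -> tissue becomes the bright part
  img <- matrix(0.9, 40, 40)   # bright background
  img[10:30, 10:30] <- 0.2     # dark tissue
  he <- preprocess_modality(img, "he")
  expect_gt(he[20, 20], he[2, 2])
  expect_equal(range(he), c(0, 1))
  # NLO: contrast stretch preserves intensity ordering
  set.seed(1)
  g <- matrix(runif(100, 0.2, 0.6), 10, 10)
  nlo <- preprocess_modality(g, "nlo")
  expect_identical(order(g), order(nlo))
})

test_that("ratio-test matching keeps unambiguous correspondences", {
  set.seed(42)
  # identical descriptor sets: every descriptor matches itself at distance 0
  d <- matrix(runif(20 * 8), 20, 8)
  ms <- match_and_filter(d, d)
  expect_equal(nrow(ms$matches), 20L)
  expect_equal(ms$matches$index_fixed, ms$matches$index_moving)
  expect_true(all(ms$matches$distance < 1e-6))
  # planted correspondences among noise survive; ambiguous ones do not
  base <- matrix(runif(30 * 16), 30, 16)
  planted_f <- base[1:10, ]
  planted_m <- planted_f + matrix(rnorm(10 * 16, sd = 0.005), 10, 16)
  ms2 <- match_and_filter(rbind(planted_f, matrix(runif(20 * 16), 20, 16)),
                          planted_m)
  expect_true(all(ms2$matches$index_fixed == ms2$matches$index_moving))
  expect_gte(nrow(ms2$matches), 9L)
  # fewer than two descriptors on either side is an insufficient-features error
  expect_error(match_and_filter(d, d[1, , drop = FALSE]), "insufficient features")
  expect_error(match_and_filter(d[1, , drop = FALSE], d), "insufficient features")
  # hamming metric counts differing bits
  a <- rbind(c(1, 0, 1, 0), c(0, 0, 0, 0), c(1, 1, 1, 1))
  msh <- match_and_filter(a, a[c(1, 3), ], metric = "hamming", ratio = 0.9)
  expect_true(all(msh$matches$distance == 0))
})

test_that("homography estimation recovers exact and contaminated transforms", {
  # 4 exact correspondences of a pure translation
  src <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  dst <- src + rep(c(12, -5), each = 4)
  est <- estimate_homography(list(src = src, dst = dst))
  expect_lt(max(abs(est$homography$m - hg_translate(12, -5)$m)), 1e-6)
  expect_true(all(est$inliers))
  # similarity transform + 30% gross outliers
  set.seed(5)
  n <- 40L
  src2 <- matrix(runif(2 * n, 0, 400), ncol = 2)
  th <- 15 * pi / 180; s <- 1.2
  rot <- s * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  dst2 <- t(rot %*% t(src2)) + rep(c(30, -12), each = n)
  out_idx <- sample(n, 12)
  dst2[out_idx, ] <- dst2[out_idx, ] + matrix(runif(24, 60, 200), ncol = 2)
  est2 <- estimate_homography(list(src = src2, dst = dst2), seed = 1)
  expect_true(all(!est2$inliers[out_idx]))
  truth <- homography(rbind(cbind(rot, c(30, -12)), c(0, 0, 1)))
  expect_lt(max(abs(est2$homography$m - truth$m)), 1e-3)
  # under-determined
  expect_error(estimate_homography(list(src = src[1:3, ], dst = dst[1:3, ])),
               ">= 4 matches")
})

test_that("RANSAC is deterministic under a fixed seed and restores RNG state", {
  set.seed(99)
  n <- 30L
  src <- matrix(runif(2 * n, 0, 200), ncol = 2)
  dst <- src + rep(c(4, 9), each = n) + matrix(rnorm(2 * n, sd = 0.5), ncol = 2)
  before <- runif(1)
  set.seed(99); invisible(runif(1))  # same RNG position as 'before'
  e1 <- estimate_homography(list(src = src, dst = dst), seed = 3)
  e2 <- estimate_homography(list(src = src, dst = dst), seed = 3)
  expect_identical(e1$homography$m, e2$homography$m)
  after <- runif(1)
  set.seed(99); invisible(runif(1)); expected_after <- runif(1)
  expect_identical(after, expected_after)  # estimator did not disturb the stream
})

test_that("warping inverts a known transform of a textured image", {
  img <- textured_image(96, 96, seed = 2)
  h <- hg_translate(7, 3)
  warped <- warp_image(img, h, dim(img))
  # interior pixels shifted exactly (integer translation, bilinear is exact)
  expect_equal(warped[21:80, 21:80], img[(21:80) - 3, (21:80) - 7],
               tolerance = 1e-12)
  # out-of-frame area filled with the background value
  expect_true(all(warped[, 1:7] == 0))
})
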