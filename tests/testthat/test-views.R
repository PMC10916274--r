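# Composite QC views: availability rule, chessboard provenance, overlays.

test_that("view availability is a pure function of present result fields", {
  fixed <- textured_image(64, 64, seed = 1)
  moving <- textured_image(64, 64, seed = 2)
  # success with all optionals absent: original + warp + chessboard only
  minimal <- validate_result(registration_result(succ = TRUE, warping = moving))
  v1 <- render_views(fixed, moving, minimal)
  expect_setequal(names(v1), c("original", "warp", "chessboard"))
  # failure: original only
  failed <- validate_result(registration_result(succ = FALSE, messages = "x"))
  expect_named(render_views(fixed, moving, failed), "original")
  # full result + annotations: all six views
  anns <- masks_to_coco(mask_stack(rect_mask(64, 64, 10, 30, 10, 30), "m"))
  full <- validate_result(registration_result(
    succ = TRUE, warping = moving, Homography = hg_identity(),
    f_fix = as_rgb_test(fixed), f_mov = as_rgb_test(moving),
    line_matching = as_rgb_test(fixed), metrics = list(ssd = 0),
    messages = "ok"), annotations_present = TRUE)
  v6 <- render_views(fixed, moving, full, annotations = anns)
  expect_setequal(names(v6), c("original", "feature_extraction", "line_matching",
                               "warp", "chessboard", "annotation"))
})

test_that("chessboard cells come verbatim from their parity source", {
  set.seed(20)
  for (n in c(2L, 4L, 7L)) {
    h <- sample(80:130, 1); w <- sample(80:130, 1)
    a <- matrix(runif(h * w), h, w); b <- matrix(runif(h * w), h, w)
    comp <- chessboard(a, b, n = n)
    ch <- h %/% n; cw <- w %/% n
    rc <- pmin((row(comp) - 1L) %/% ch, n - 1L)
    cc <- pmin((col(comp) - 1L) %/% cw, n - 1L)
    odd <- (rc + cc) %% 2L == 1L
    expect_identical(comp[!odd], a[!odd])
    expect_identical(comp[odd], b[odd])
    # every pixel traces to exactly one source
    expect_true(all(comp == a | comp == b))
  }
  # identical inputs reproduce themselves; n = 4 gives 16 cells, 8 each
  img <- textured_image(100, 100, seed = 3)
  expect_identical(chessboard(img, img, 4L), img)
  expect_error(chessboard(img, img[1:50, ]), "identical shape")
  # n = 2 on 100 x 100: top-left quadrant from fixed, top-right from warped
  a <- matrix(0, 100, 100); b <- matrix(1, 100, 100)
  q <- chessboard(a, b, 2L)
  expect_true(all(q[1:50, 1:50] == 0))
  expect_true(all(q[1:50, 51:100] == 1))
})

test_that("annotation overlays recolour outline pixels per category", {
  img <- matrix(0.5, 40, 40)
  empty <- coco_set(images = data.frame(id = 1L, file_name = "x",
                                        width = 40L, height = 40L),
                    categories = data.frame(id = 1L, name = "c"))
  expect_identical(overlay_annotations(img, empty), as_rgb_test(img))
  # axis-aligned square at integer vertices, width-1 outline
  sq <- coco_set(
    images = data.frame(id = 1L, file_name = "x", width = 40L, height = 40L),
    categories = data.frame(id = 1L, name = "c"),
    annotations = list(list(id = 1L, image_id = 1L, category_id = 1L,
                            segmentation = list(c(10, 10, 20, 10, 20, 20, 10, 20)),
                            bbox = c(10, 10, 10, 10), area = 100, iscrowd = 0L)))
  out <- overlay_annotations(img, sq, width = 1L)
  changed <- which(out[, , 1] != 0.5, arr.ind = TRUE) - 1L  # 0-based (row, col)
  on_boundary <- (changed[, 1] %in% c(10, 20) & changed[, 2] >= 10 & changed[, 2] <= 20) |
                 (changed[, 2] %in% c(10, 20) & changed[, 1] >= 10 & changed[, 1] <= 20)
  expect_true(all(on_boundary))
  expect_equal(nrow(changed), 4 * 10)  # perimeter pixels of the lattice square
  # two categories draw with two distinct palette colours
  m2 <- array(0L, dim = c(40, 40, 2))
  m2[5:10, 5:10, 1] <- 1L; m2[25:35, 25:35, 2] <- 1L
  cs2 <- masks_to_coco(mask_stack(m2, c("a", "b")))
  out2 <- overlay_annotations(img, cs2, width = 1L)
  cols <- unique(apply(which(out2[, , 1] != 0.5, arr.ind = TRUE), 1, function(rc)
    paste(out2[rc[1], rc[2], ], collapse = ",")))
  expect_length(cols, 2L)
})

test_that("side-by-side layout is deterministic with divider and padding", {
  a <- matrix(0, 100, 100); b <- matrix(1, 100, 100)
  comp <- side_by_side(a, b)
  expect_identical(dim(comp), c(100L, 203L))
  expect_true(all(comp[, 101:103] == 0.5))
  expect_true(all(comp[, 1:100] == 0) && all(comp[, 104:203] == 1))
  # identical inputs give a mirror-symmetric composite
  img <- textured_image(50, 50, seed = 6)
  sym <- side_by_side(img, img)
  expect_identical(sym[, 1:50], sym[, 54:103])
  # height mismatch pads the shorter input with background
  tall <- matrix(1, 80, 20); short <- matrix(1, 50, 20)
  padded <- side_by_side(tall, short, background = 0)
  expect_identical(dim(padded), c(80L, 43L))
  expect_true(all(padded[51:80, 24:43] == 0))
})

test_that("feature and match drawings stay within canvas bounds", {
  img <- textured_image(60, 60, seed = 7)
  kp <- data.frame(x = c(5, 30, 59), y = c(5, 30, 59), scale = c(1, 2, 1))
  fi <- draw_features(img, kp)
  expect_identical(dim(fi), c(60L, 60L, 3L))
  expect_true(any(fi[, , 2] == 1))  # green marks present
  matches <- data.frame(index_fixed = c(1, 2), index_moving = c(2, 1))
  dm <- draw_matches(img, img, kp, kp, matches)
  expect_identical(dim(dm), c(60L, 123L, 3L))
})
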