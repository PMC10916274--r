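# Annotation model: mask ingestion (images, npz arrays), marching-squares
# instance extraction to COCO, rasterization, and COCO JSON round trips.

test_that("3-channel mask images are read in BGR channel order", {
  # blue channel (spec channel 0) marks Crypts, green Mucosa, red Background
  img <- array(0, dim = c(8, 8, 3))
  img[2, 2, 3] <- 1   # blue plane (decoded RGB plane 3)
  img[3, 3, 2] <- 1   # green
  img[4, 4, 1] <- 1   # red
  f <- tempfile(fileext = ".png")
  png::writePNG(img, f)
  spec <- class_spec(c(0, 1, 2), c("Crypts", "Mucosa", "Background"))
  st <- load_mask_image(f, spec)
  expect_identical(st$class_names, c("Crypts", "Mucosa", "Background"))
  expect_equal(which(st$data[, , 1] == 1), which(img[, , 3] == 1))
  expect_equal(which(st$data[, , 2] == 1), which(img[, , 2] == 1))
  expect_equal(which(st$data[, , 3] == 1), which(img[, , 1] == 1))
  expect_error(load_mask_image(f, class_spec(c(0, 3), c("a", "b"))), "out of range")
})

test_that("16-bit and empty 1-channel masks binarize by threshold at zero", {
  m <- matrix(0, 10, 12)
  m[3:5, 4:9] <- 1  # stored as 65535 in 16-bit
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f, bits.per.sample = 16L)
  st <- load_mask_image(f)
  expect_equal(st$n_classes, 1L)
  expect_identical(st$data[, , 1], matrix(as.integer(m > 0), 10, 12))
  # all-zero image -> one all-zero plane
  f0 <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 6, 6), f0)
  st0 <- load_mask_image(f0)
  expect_true(all(st0$data == 0))
  # idempotence: re-binarizing binary data changes nothing
  expect_identical(mask_stack(st$data)$data, st$data)
})

test_that("mask arrays load with [x, y, nC] shape handling and binarization", {
  arr <- array(0, dim = c(20, 30, 5))
  arr[1, 2, 3] <- 7  # nonzero values map to 1
  f <- tempfile(fileext = ".npz")
  write_npz(f, list(m = arr))
  st <- load_mask_array(f)
  expect_equal(st$height, 20L)
  expect_equal(st$width, 30L)
  expect_equal(st$n_classes, 5L)
  expect_identical(st$class_names, paste0("class_", 0:4))
  expect_setequal(unique(as.vector(st$data)), c(0L, 1L))
  expect_equal(st$data[1, 2, 3], 1L)
  # rank violation
  f2 <- tempfile(fileext = ".npz")
  write_npz(f2, list(m = matrix(0, 4, 4)))
  expect_error(load_mask_array(f2), "rank 3")
  expect_error(load_mask_array(f, class_names = c("a", "b")), "class_names")
})

test_that("marching-squares extraction yields one annotation per instance", {
  # empty plane: zero annotations, category still present
  empty <- masks_to_coco(mask_stack(matrix(0L, 15, 15), "bg"))
  expect_length(empty$annotations, 0)
  expect_equal(nrow(empty$categories), 1L)
  # two disjoint rectangles in one plane: two annotations, same category
  m <- matrix(0L, 30, 30)
  m[3:9, 3:9] <- 1L
  m[16:26, 11:21] <- 1L
  two <- masks_to_coco(mask_stack(m, "tissue"))
  expect_length(two$annotations, 2)
  expect_equal(unique(vapply(two$annotations, `[[`, integer(1), "category_id")), 1L)
  # category count equals n_classes regardless of empty planes
  stack3 <- mask_stack(array(c(m, m * 0L, m), dim = c(30, 30, 3)))
  cs3 <- masks_to_coco(stack3)
  expect_equal(nrow(cs3$categories), 3L)
  expect_length(cs3$annotations, 4)
})

test_that("rectangle contours respect the half-pixel convention", {
  # filled rectangle over columns 2-11, rows 3-12 (0-based, inclusive)
  m <- rect_mask(20, 20, 2, 11, 3, 12)
  cs <- masks_to_coco(mask_stack(m, "rect"))
  expect_length(cs$annotations, 1)
  a <- cs$annotations[[1]]
  expect_equal(a$bbox[3], 10)  # width
  expect_equal(a$bbox[4], 10)  # height
  expect_equal(a$bbox[1:2], c(1.5, 2.5))
  # shoelace area vs pixel count, within the half-pixel contour convention
  n_px <- sum(m)
  perimeter <- 2 * (10 + 10)
  expect_lt(abs(a$area - n_px), perimeter / 2)
  # collinear runs are simplified: a rectangle needs few vertices
  expect_lte(length(a$segmentation[[1]]) / 2, 12)
  # every produced annotation passes the validator
  expect_silent(validate_coco_set(cs))
})

test_that("rasterization inverts polygon extraction", {
  # unit-square-style polygon fills the expected block
  sq <- coco_set(
    images = data.frame(id = 1L, file_name = "x", width = 20L, height = 20L),
    categories = data.frame(id = 1L, name = "c"),
    annotations = list(list(id = 1L, image_id = 1L, category_id = 1L,
                            segmentation = list(c(0, 0, 10, 0, 10, 10, 0, 10)),
                            bbox = c(0, 0, 10, 10), area = 100, iscrowd = 0L)))
  st <- rasterize_annotations(sq, 20, 20)
  expect_equal(sum(st$data), 100)
  expect_true(all(st$data[1:10, 1:10, 1] == 1L))
  # empty set -> all zero
  none <- coco_set(images = data.frame(id = 1L, file_name = "x",
                                       width = 5L, height = 5L),
                   categories = data.frame(id = 1L, name = "c"))
  expect_true(all(rasterize_annotations(none, 5, 5)$data == 0))
})

test_that("mask -> COCO -> mask round trip is near-lossless on blobs", {
  for (seed in 1:4) {
    tt <- make_tissue_image(160, 160, n_blobs = 3L, seed = seed)
    cs <- masks_to_coco(tt$masks)
    expect_length(cs$annotations, tt$masks$n_classes)
    back <- rasterize_annotations(cs, tt$masks$width, tt$masks$height)
    for (k in seq_len(tt$masks$n_classes))
      expect_gte(iou(back$data[, , k], tt$masks$data[, , k]), 0.99)
    # conversion stabilizes: same annotation count the second time around
    cs2 <- masks_to_coco(back)
    expect_length(cs2$annotations, length(cs$annotations))
  }
})

test_that("COCO JSON round trips field-for-field", {
  m <- matrix(0L, 40, 40)
  m[5:15, 5:15] <- 1L; m[20:30, 22:33] <- 1L
  cs <- masks_to_coco(mask_stack(array(c(m, m), dim = c(40, 40, 2)),
                                 c("alpha", "beta")), image_id = 7L,
                      file_name = "moving.png")
  f <- tempfile(fileext = ".json")
  write_coco(cs, f)
  back <- read_coco(f)
  expect_equal(back$images, cs$images)
  expect_equal(back$categories, cs$categories)
  expect_length(back$annotations, length(cs$annotations))
  for (i in seq_along(cs$annotations)) expect_equal(back$annotations[[i]],
                                                    cs$annotations[[i]])
})

test_that("COCO reader validates structure", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(images = list(), categories = list()), f)
  expect_error(read_coco(f), "annotations")
  # minimal hand-written file with one triangle
  writeLines('{
    "images": [{"id": 1, "file_name": "a.png", "width": 10, "height": 10}],
    "categories": [{"id": 1, "name": "cell"}],
    "annotations": [{"id": 1, "image_id": 1, "category_id": 1,
      "segmentation": [[1, 1, 8, 1, 4, 7]],
      "bbox": [1, 1, 7, 6], "area": 21.0, "iscrowd": 0}]
  }', f)
  tri <- read_coco(f)
  expect_length(tri$annotations, 1)
  expect_length(tri$annotations[[1]]$segmentation[[1]], 6)
})

test_that("the validator rejects inconsistent annotation sets", {
  img <- data.frame(id = 1L, file_name = "a", width = 10L, height = 10L)
  cat1 <- data.frame(id = 1L, name = "c")
  good <- list(id = 1L, image_id = 1L, category_id = 1L,
               segmentation = list(c(0, 0, 4, 0, 4, 4)),
               bbox = c(0, 0, 4, 4), area = 8, iscrowd = 0L)
  expect_silent(coco_set(img, cat1, list(good)))
  bad_cat <- good; bad_cat$category_id <- 9L
  expect_error(coco_set(img, cat1, list(bad_cat)), "unknown category")
  bad_poly <- good; bad_poly$segmentation <- list(c(0, 0, 1, 1))
  expect_error(coco_set(img, cat1, list(bad_poly)), "vertices")
  bad_box <- good; bad_box$bbox <- c(0, 0, 9, 9)
  expect_error(coco_set(img, cat1, list(bad_box)), "tight")
  dup <- list(good, good)
  expect_error(coco_set(img, cat1, dup), "unique")
})
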