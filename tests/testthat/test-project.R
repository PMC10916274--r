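# Project model: batch pairing, on-disk layout, run and export.

test_that("batch pairing sorts case-insensitively and pairs positionally", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "fx")); dir.create(file.path(d, "mv"))
  img <- quantized_image(16, 16)
  for (f in c("b.png", "a.png", "C.png")) png::writePNG(img, file.path(d, "fx", f))
  for (f in c("y.png", "x.png", "Z.png")) png::writePNG(img, file.path(d, "mv", f))
  pairs <- pair_batch(file.path(d, "fx"), file.path(d, "mv"))
  expect_equal(pairs$pair_id, c("a", "b", "C"))
  expect_equal(basename(pairs$moving), c("x.png", "y.png", "Z.png"))
  # five against four is refused with both counts quoted
  png::writePNG(img, file.path(d, "fx", "d.png"))
  expect_error(pair_batch(file.path(d, "fx"), file.path(d, "mv")),
               "exactly the same.*4 fixed vs 3 moving")
  # empty folders are refused
  d2 <- withr::local_tempdir()
  dir.create(file.path(d2, "e1")); dir.create(file.path(d2, "e2"))
  expect_error(pair_batch(file.path(d2, "e1"), file.path(d2, "e2")),
               "at least one")
  expect_error(pair_batch(file.path(d2, "missing"), file.path(d2, "e1")),
               "does not exist")
})

test_that("pairing is a deterministic function of the directory listings", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "fx")); dir.create(file.path(d, "mv"))
  img <- quantized_image(16, 16)
  set.seed(4)
  stems <- replicate(5, paste(sample(letters, 6), collapse = ""))
  for (s in stems) {
    png::writePNG(img, file.path(d, "fx", paste0(s, ".png")))
    png::writePNG(img, file.path(d, "mv", paste0(s, "_m.png")))
  }
  p1 <- pair_batch(file.path(d, "fx"), file.path(d, "mv"))
  p2 <- pair_batch(file.path(d, "fx"), file.path(d, "mv"))
  expect_identical(p1, p2)
  expect_identical(p1$pair_id, sort(stems, method = "radix"))
})

test_that("create_project lays out images, pyramids and annotations", {
  d <- withr::local_tempdir()
  img <- quantized_image(40, 40, seed = 1)
  png::writePNG(img, file.path(d, "f.png"))
  png::writePNG(img, file.path(d, "m.png"))
  # npz mask source attached to the moving image
  masks <- array(0L, dim = c(40, 40, 2))
  masks[10:20, 10:20, 1] <- 1L; masks[25:35, 5:15, 2] <- 1L
  write_npz(file.path(d, "m.npz"), list(masks = masks))
  ws <- file.path(d, "ws")
  p <- create_project("demo", ws, file.path(d, "f.png"), file.path(d, "m.png"),
                      plugins = "sift_flann",
                      annotations = list(path = file.path(d, "m.npz"),
                                         format = "npz"),
                      tile_size = 32L)
  expect_true(file.exists(file.path(p$dir, "project.json")))
  # one pyramid per input image
  expect_true(dir.exists(file.path(p$dir, "images", "f_fixed_files")))
  expect_true(dir.exists(file.path(p$dir, "images", "f_moving_files")))
  # annotations converted to COCO, one per pair
  aset <- read_coco(file.path(p$dir, "annotations", "f.json"))
  expect_length(aset$annotations, 2)
  # round trip through project.json preserves the project
  q <- load_project("demo", ws)
  expect_equal(q$name, p$name)
  expect_equal(q$pairs, p$pairs)
  expect_equal(q$plugins, p$plugins)
  expect_equal(q$project_type, p$project_type)
  # duplicate names conflict; empty plugin lists are invalid
  expect_error(create_project("demo", ws, file.path(d, "f.png"),
                              file.path(d, "m.png"), plugins = "x"),
               "already exists")
  expect_error(create_project("demo2", ws, file.path(d, "f.png"),
                              file.path(d, "m.png"), plugins = character()),
               "plugin list")
  expect_true("demo" %in% list_projects(ws))
  delete_project("demo", ws)
  expect_false("demo" %in% list_projects(ws))
})

test_that("run and export produce a complete, reproducible archive", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "fx")); dir.create(file.path(d, "mv"))
  for (i in 1:2) {
    img <- quantized_image(48, 48, seed = i)
    png::writePNG(img, file.path(d, "fx", sprintf("p%d.png", i)))
    png::writePNG(img, file.path(d, "mv", sprintf("p%d.png", i)))
  }
  pdir <- file.path(d, "plugins"); dir.create(pdir)
  write_translation_plugin(pdir, "shift")
  ws <- file.path(d, "ws")
  create_project("batch", ws, file.path(d, "fx"), file.path(d, "mv"),
                 plugins = "shift", project_type = "batch",
                 build_pyramids = FALSE)
  # export before running is an error
  expect_error(export_project("batch", ws, tempfile(fileext = ".zip")),
               "no results")
  run_project("batch", ws, plugin_dir = pdir, views = FALSE)
  z1 <- file.path(d, "out1.zip"); z2 <- file.path(d, "out2.zip")
  export_project("batch", ws, z1)
  inside <- utils::unzip(z1, list = TRUE)$Name
  expect_length(grep("homography\\.json$", inside), 2L)  # one per pair x plugin
  # deterministic plugin -> re-run + re-export is byte-identical
  run_project("batch", ws, plugin_dir = pdir, views = FALSE)
  export_project("batch", ws, z2)
  expect_identical(readBin(z1, "raw", file.size(z1)),
                   readBin(z2, "raw", file.size(z2)))
})
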