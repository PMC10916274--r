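# Plugin contract validation, discovery, and fault-isolated execution.

test_that("the result validator enforces the eight-key contract", {
  img <- matrix(0.5, 10, 10)
  ok <- validate_result(registration_result(succ = TRUE, warping = img))
  expect_s3_class(ok, "registration_result")
  expect_named(ok, histreg:::RESULT_KEYS)
  # all optionals may be NULL when no annotations are attached
  expect_silent(validate_result(list(succ = TRUE, warping = img,
                                     Homography = NULL, f_mov = NULL,
                                     f_fix = NULL, line_matching = NULL,
                                     metrics = NULL, messages = character())))
  # unknown keys rejected
  expect_error(validate_result(list(succ = TRUE, warping = img, extra = 1)),
               "unknown key")
  # mandatory keys
  expect_error(validate_result(list(warping = img)), "succ")
  expect_error(validate_result(list(succ = TRUE)), "warping")
  # annotated project: Homography becomes mandatory on success
  expect_error(validate_result(list(succ = TRUE, warping = img),
                               annotations_present = TRUE), "Homography")
  expect_silent(validate_result(list(succ = TRUE, warping = img,
                                     Homography = hg_identity()),
                                annotations_present = TRUE))
  # failure results must explain themselves
  expect_error(validate_result(list(succ = FALSE)), "message")
  fl <- validate_result(list(succ = FALSE, messages = "no matches"))
  expect_false(fl$succ)
  # warped image must match the fixed canvas
  expect_error(validate_result(list(succ = TRUE, warping = img),
                               fixed_dim = c(20, 20)), "does not match")
})

test_that("plugin discovery registers well-formed files and skips broken ones", {
  empty <- withr::local_tempdir()
  expect_length(discover_plugins(empty), 0)
  expect_error(discover_plugins(file.path(empty, "nope")), "does not exist")
  # the two shipped reference plugins
  reg <- discover_plugins(default_plugin_dir())
  expect_setequal(names(reg), c("sift_flann", "orb_flann"))
  # a file raising on load is skipped with a warning; others survive
  d <- withr::local_tempdir()
  write_translation_plugin(d, "good")
  writeLines("stop('corrupt plugin file')", file.path(d, "bad.R"))
  expect_warning(reg2 <- discover_plugins(d), "bad\\.R")
  expect_named(reg2, "good")
  # a file without the required symbols is also skipped
  writeLines("x <- 1", file.path(d, "empty.R"))
  # both malformed files warn; the good plugin still registers
  expect_warning(expect_warning(reg3 <- discover_plugins(d), "bad\\.R"),
                 "empty\\.R")
  expect_named(reg3, "good")
})

make_pair_files <- function(dir, h = 48L, w = 48L, seed = 1L) {
  img <- quantized_image(h, w, seed)
  fixed <- file.path(dir, "fixed.png"); moving <- file.path(dir, "moving.png")
  png::writePNG(img, fixed)
  png::writePNG(img, moving)
  list(fixed = fixed, moving = moving)
}

test_that("execute_pair persists validated results and transferred annotations", {
  d <- withr::local_tempdir()
  pf <- make_pair_files(d)
  pdir <- file.path(d, "plugins"); dir.create(pdir)
  write_translation_plugin(pdir, "shift")
  reg <- discover_plugins(pdir)
  anns <- masks_to_coco(mask_stack(rect_mask(48, 48, 10, 20, 10, 20), "m"))
  out <- file.path(d, "results")
  ex <- execute_pair(pf$fixed, pf$moving, reg$shift, out, pair_id = "p1",
                     annotations = anns, views = TRUE)
  expect_true(ex$succ)
  rd <- file.path(out, "shift", "p1")
  for (f in c("warped.png", "homography.json", "metrics.json", "messages.txt",
              "annotations_transformed.json"))
    expect_true(file.exists(file.path(rd, f)), label = f)
  # transferred polygons shifted by the plugin's translation
  tr <- read_coco(file.path(rd, "annotations_transformed.json"))
  expect_equal(tr$annotations[[1]]$bbox[1:2],
               anns$annotations[[1]]$bbox[1:2] + c(3, -2))
  # views: original always; warp + chessboard on success
  expect_true(all(file.exists(file.path(rd, "views",
                                        c("original.png", "warp.png",
                                          "chessboard.png")))))
})

test_that("a throwing plugin is contained as a failure result", {
  d <- withr::local_tempdir()
  pf <- make_pair_files(d)
  pdir <- file.path(d, "plugins"); dir.create(pdir)
  write_throwing_plugin(pdir, "boom")
  reg <- discover_plugins(pdir)
  ex <- execute_pair(pf$fixed, pf$moving, reg$boom, file.path(d, "results"),
                     pair_id = "p1", views = FALSE)
  expect_false(ex$succ)
  msgs <- readLines(file.path(d, "results", "boom", "p1", "messages.txt"))
  expect_match(paste(msgs, collapse = " "), "synthetic plugin crash")
})

test_that("missing homography on an annotated project is a contract failure", {
  d <- withr::local_tempdir()
  pf <- make_pair_files(d)
  pdir <- file.path(d, "plugins"); dir.create(pdir)
  write_translation_plugin(pdir, "nohom", with_homography = FALSE)
  reg <- discover_plugins(pdir)
  anns <- masks_to_coco(mask_stack(rect_mask(48, 48, 5, 12, 5, 12), "m"))
  ex <- execute_pair(pf$fixed, pf$moving, reg$nohom, file.path(d, "results"),
                     pair_id = "p1", annotations = anns, views = FALSE)
  expect_false(ex$succ)
  expect_true(ex$contract_failure)
  expect_match(paste(ex$result$messages, collapse = " "), "Homography")
})

test_that("execute_project runs the full pair x plugin product with fault isolation", {
  d <- withr::local_tempdir()
  # a 2-pair batch project with one good and one crashing plugin
  for (sub in c("fx", "mv")) dir.create(file.path(d, sub))
  for (i in 1:2) {
    img <- quantized_image(48, 48, seed = i)
    png::writePNG(img, file.path(d, "fx", sprintf("s%d.png", i)))
    png::writePNG(img, file.path(d, "mv", sprintf("s%d.png", i)))
  }
  pdir <- file.path(d, "plugins"); dir.create(pdir)
  write_translation_plugin(pdir, "shift")
  write_throwing_plugin(pdir, "boom")
  ws <- file.path(d, "ws")
  project <- create_project("batch1", ws, file.path(d, "fx"), file.path(d, "mv"),
                            plugins = c("shift", "boom"), project_type = "batch",
                            build_pyramids = FALSE)
  s <- execute_project(project, discover_plugins(pdir), views = FALSE)
  expect_equal(nrow(s), 4L)  # 2 pairs x 2 plugins
  expect_equal(sum(s$succ[s$plugin == "shift"]), 2L)
  expect_equal(sum(s$succ[s$plugin == "boom"]), 0L)
  # result directories exist for every combination
  for (p in c("shift", "boom")) for (pr in c("s1", "s2"))
    expect_true(dir.exists(file.path(project$dir, "results", p, pr)))
  # deterministic plugins give byte-identical homography JSON on re-run
  h1 <- readBin(file.path(project$dir, "results", "shift", "s1", "homography.json"),
                "raw", 1e4)
  execute_project(project, discover_plugins(pdir), views = FALSE)
  h2 <- readBin(file.path(project$dir, "results", "shift", "s1", "homography.json"),
                "raw", 1e4)
  expect_identical(h1, h2)
  # empty plugin list is a configuration error
  project$plugins <- character()
  expect_error(execute_project(project, discover_plugins(pdir)), "no plugins")
})
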