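# Shared fixtures: all built in code at test time.

# deterministic textured grayscale image with enough structure for
# feature detection
textured_image <- function(h = 256L, w = 256L, seed = 1L) {
  nb <- if (min(h, w) < 128L) 2L else 4L
  make_tissue_image(w, h, n_blobs = nb, seed = seed)$image
}

# image whose values are exact 8-bit levels (k / 255), so PNG round trips
# are byte-identical
quantized_image <- function(h, w, seed = 1L, channels = 1L) {
  set.seed(seed)
  v <- sample(0:255, h * w * channels, replace = TRUE) / 255
  if (channels == 1L) matrix(v, h, w) else array(v, dim = c(h, w, channels))
}

# axis-aligned filled rectangle mask (0-based pixel ranges, inclusive)
rect_mask <- function(h, w, x0, x1, y0, y1) {
  m <- matrix(0L, h, w)
  m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- 1L
  m
}

# a small deterministic "plugin" that registers by returning a fixed
# translation; used for engine tests where real feature matching is overkill
write_translation_plugin <- function(dir, name = "shift", tx = 3, ty = -2,
                                     with_homography = TRUE) {
  code <- sprintf('
plugin_name <- "%s"
plugin_entry <- function(fixed, moving, options) {
  h <- histreg::hg_translate(%f, %f)
  histreg::registration_result(
    succ = TRUE,
    warping = histreg::warp_image(moving, h, dim(fixed)[1:2]),
    Homography = %s,
    metrics = list(ssd = histreg::ssd(fixed, histreg::warp_image(moving, h, dim(fixed)[1:2]))),
    messages = "translation plugin")
}
', name, tx, ty, if (with_homography) "h" else "NULL")
  path <- file.path(dir, paste0(name, ".R"))
  writeLines(code, path)
  path
}

write_throwing_plugin <- function(dir, name = "boom") {
  path <- file.path(dir, paste0(name, ".R"))
  writeLines(sprintf('
plugin_name <- "%s"
plugin_entry <- function(fixed, moving, options) stop("synthetic plugin crash")
', name), path)
  path
}

corner_points <- function(h, w) rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))

mean_corner_error <- function(h_est, h_true, height, width) {
  p <- corner_points(height, width)
  mean(sqrt(rowSums((histreg::apply_homography(p, h_est) -
                       histreg::apply_homography(p, h_true))^2)))
}

random_homography <- function() {
  m <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  m[3, 1:2] <- rnorm(2, sd = 1e-4)
  histreg::homography(m)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

as_rgb_test <- function(img) histreg:::as_rgb(img)
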