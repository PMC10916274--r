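# Composite QC views rendered from a validated registration result:
# original, feature extraction, line matching, warp, chessboard, and
# annotation views. A view is emitted only when the result fields it needs
# are present.

#' Chessboard composite of two registered images
#'
#' Partitions the canvas into an `n x n` cell grid (integer-division cell
#' sizes; the last row/column absorbs the remainder) and copies cell
#' `(i, j)` from `fixed` when `i + j` is even and from `warped` when odd.
#' Misalignments show up as discontinuities at cell borders.
#'
#' @param fixed,warped images of identical shape.
#' @param n grid order (default 4, i.e. a 4 x 4 pattern); must be >= 2.
#' @return composite image.
#' @export
chessboard <- function(fixed, warped, n = 4L) {
  if (!all(dim(fixed) == dim(warped)))
    stop("chessboard: images must have identical shape", call. = FALSE)
  if (n < 2L) stop("chessboard: n must be >= 2", call. = FALSE)
  d <- image_dims(fixed)
  ch <- d[1] %/% n; cw <- d[2] %/% n
  if (ch < 1L || cw < 1L) stop("chessboard: grid finer than the image", call. = FALSE)
  row_cell <- pmin((seq_len(d[1]) - 1L) %/% ch, n - 1L)
  col_cell <- pmin((seq_len(d[2]) - 1L) %/% cw, n - 1L)
  odd <- outer(row_cell, col_cell, "+") %% 2L == 1L
  out <- fixed
  if (is.matrix(out)) out[odd] <- warped[odd]
  else for (c in seq_len(dim(out)[3])) {
    pf <- out[, , c]; pw <- warped[, , c]; pf[odd] <- pw[odd]; out[, , c] <- pf
  }
  out
}

# default qualitative palette indexed by category id
default_palette <- function() {
  rbind(c(0.894, 0.102, 0.110), c(0.216, 0.494, 0.722), c(0.302, 0.686, 0.290),
        c(0.596, 0.306, 0.639), c(1.000, 0.498, 0.000), c(1.000, 1.000, 0.200),
        c(0.651, 0.337, 0.157), c(0.969, 0.506, 0.749))
}

# set pixels along the closed polygon outline (dense edge sampling)
draw_polygon_outline <- function(img, xs, ys, colour, width = 1L) {
  d <- image_dims(img)
  n <- length(xs)
  px <- integer(0); py <- integer(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    len <- max(abs(xs[j] - xs[i]), abs(ys[j] - ys[i]))
    k <- max(2L, ceiling(len * 4) + 1L)
    t <- seq(0, 1, length.out = k)
    px <- c(px, round(xs[i] + t * (xs[j] - xs[i])))
    py <- c(py, round(ys[i] + t * (ys[j] - ys[i])))
  }
  if (width > 1L) {
    r <- width %/% 2L
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.5, ]
    px <- rep(px, times = nrow(off)) + rep(off$dx, each = length(px))
    py <- rep(py, times = nrow(off)) + rep(off$dy, each = length(py))
  }
  keep <- px >= 0 & px < d[2] & py >= 0 & py < d[1]
  px <- px[keep]; py <- py[keep]
  for (c in 1:3) {
    plane <- img[, , c]
    plane[cbind(py + 1L, px + 1L)] <- colour[c]
    img[, , c] <- plane
  }
  img
}

#' Overlay COCO annotations on an image
#'
#' Draws polygon outlines (and optionally a translucent fill) per category
#' with a stable category-id-indexed palette.
#'
#' @param image image to draw on (converted to RGB).
#' @param annotation_set a [coco_set].
#' @param palette `k x 3` RGB matrix in `[0, 1]`, recycled by category id.
#' @param width outline width in pixels (default 2).
#' @param fill alpha of the polygon fill, 0 (default) disables filling.
#' @return RGB image with annotations drawn.
#' @export
overlay_annotations <- function(image, annotation_set, palette = default_palette(),
                                width = 2L, fill = 0) {
  img <- as_rgb(image)
  if (!length(annotation_set$annotations)) return(img)
  d <- image_dims(img)
  for (a in annotation_set$annotations) {
    colour <- palette[(as.integer(a$category_id) - 1L) %% nrow(palette) + 1L, ]
    for (p in a$segmentation) {
      xs <- p[c(TRUE, FALSE)]; ys <- p[c(FALSE, TRUE)]
      if (fill > 0) {
        mask <- poly_fill(xs, ys, d[2], d[1]) == 1L
        for (c in 1:3) {
          plane <- img[, , c]
          plane[mask] <- (1 - fill) * plane[mask] + fill * colour[c]
          img[, , c] <- plane
        }
      }
      img <- draw_polygon_outline(img, xs, ys, colour, width)
    }
  }
  img
}

#' Side-by-side composite
#'
#' Concatenates two images horizontally with a divider; the shorter image
#' is padded at the bottom with the background value.
#'
#' @param a,b images.
#' @param divider divider width in pixels (default 3).
#' @param divider_value divider intensity (default mid-gray).
#' @param background pad value.
#' @return composite image (RGB if either input is RGB).
#' @export
side_by_side <- function(a, b, divider = 3L, divider_value = 0.5, background = 0) {
  rgb_needed <- !is.matrix(a) || !is.matrix(b)
  if (rgb_needed) { a <- as_rgb(a); b <- as_rgb(b) }
  da <- image_dims(a); db <- image_dims(b)
  h <- max(da[1], db[1]); w <- da[2] + divider + db[2]
  pad <- function(img, dims) {
    if (dims[1] == h) return(img)
    if (is.matrix(img)) rbind(img, matrix(background, h - dims[1], dims[2]))
    else {
      out <- array(background, dim = c(h, dims[2], dim(img)[3]))
      out[seq_len(dims[1]), , ] <- img
      out
    }
  }
  a <- pad(a, da); b <- pad(b, db)
  if (is.matrix(a)) {
    cbind(a, matrix(divider_value, h, divider), b)
  } else {
    out <- array(divider_value, dim = c(h, w, 3L))
    out[, seq_len(da[2]), ] <- a
    out[, da[2] + divider + seq_len(db[2]), ] <- b
    out
  }
}

#' Draw detected keypoints on an image
#'
#' Marks each keypoint with a small cross scaled by its detection scale.
#'
#' @param image image to annotate.
#' @param keypoints data.frame with `x`, `y` (and optionally `scale`).
#' @param colour RGB triplet.
#' @return RGB image.
#' @export
draw_features <- function(image, keypoints, colour = c(0, 1, 0)) {
  img <- as_rgb(image)
  if (!nrow(keypoints)) return(img)
  d <- image_dims(img)
  sc <- if ("scale" %in% names(keypoints)) keypoints$scale else rep(1, nrow(keypoints))
  arm <- pmax(2L, round(2 * sc))
  px <- integer(0); py <- integer(0)
  for (i in seq_len(nrow(keypoints))) {
    o <- -arm[i]:arm[i]
    px <- c(px, round(keypoints$x[i]) + o, rep(round(keypoints$x[i]), length(o)))
    py <- c(py, rep(round(keypoints$y[i]), length(o)), round(keypoints$y[i]) + o)
  }
  keep <- px >= 0 & px < d[2] & py >= 0 & py < d[1]
  for (c in 1:3) {
    plane <- img[, , c]
    plane[cbind(py[keep] + 1L, px[keep] + 1L)] <- colour[c]
    img[, , c] <- plane
  }
  img
}

#' Draw matched keypoints as connecting lines
#'
#' Renders the two images side by side and connects matched keypoints.
#'
#' @param fixed,moving the two images.
#' @param keypoints_fixed,keypoints_moving keypoint tables.
#' @param matches data.frame with `index_fixed`, `index_moving`.
#' @param colour line colour.
#' @return RGB composite image.
#' @export
draw_matches <- function(fixed, moving, keypoints_fixed, keypoints_moving,
                         matches, colour = c(1, 1, 0)) {
  comp <- side_by_side(as_rgb(fixed), as_rgb(moving))
  off <- ncol(to_gray(fixed)) + 3L
  for (i in seq_len(nrow(matches))) {
    kf <- keypoints_fixed[matches$index_fixed[i], ]
    km <- keypoints_moving[matches$index_moving[i], ]
    comp <- draw_polygon_outline(comp, c(kf$x, km$x + off, kf$x),
                                 c(kf$y, km$y, kf$y), colour, width = 1L)
  }
  comp
}

#' Render the available QC views for a registration result
#'
#' Emits exactly the views whose inputs exist: `original` (always),
#' `feature_extraction` (iff both `f_fix` and `f_mov` are present),
#' `line_matching` (iff present), `warp` and `chessboard` (iff the
#' registration succeeded), and `annotation` (iff an annotation set and a
#' homography are present — annotations are transferred into the fixed
#' frame and overlaid).
#'
#' @param fixed,moving the input images.
#' @param result a validated `registration_result`.
#' @param annotations optional [coco_set] on the moving image.
#' @param chessboard_n chessboard grid order.
#' @return named list of view images.
#' @export
render_views <- function(fixed, moving, result, annotations = NULL,
                         chessboard_n = 4L) {
  views <- list(original = side_by_side(fixed, moving))
  if (!is.null(result$f_fix) && !is.null(result$f_mov))
    views$feature_extraction <- side_by_side(result$f_fix, result$f_mov)
  if (!is.null(result$line_matching))
    views$line_matching <- result$line_matching
  if (isTRUE(result$succ)) {
    views$warp <- result$warping
    views$chessboard <- chessboard(as_rgb(fixed), as_rgb(result$warping),
                                   n = chessboard_n)
  }
  if (!is.null(annotations) && !is.null(result$Homography) && isTRUE(result$succ)) {
    d <- image_dims(fixed)
    transferred <- transform_annotation_set(
      annotations, result$Homography,
      list(id = 1L, file_name = "fixed", width = d[2], height = d[1]))
    views$annotation <- overlay_annotations(fixed, transferred)
  }
  views
}
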