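# Planar homographies and annotation transfer between image frames.
#
# Direction convention: a plugin's homography maps moving-image coordinates
# into fixed-image coordinates (it is the matrix that produces the warped
# moving image), so moving-frame annotation vertices are transformed by H
# directly, never by its inverse.

#' Construct a planar homography
#'
#' A 3x3 invertible projective transform. The matrix is stored normalized so
#' that the bottom-right element equals 1 whenever it is nonzero.
#'
#' @param m 3x3 numeric matrix.
#' @return object of class `homography`.
#' @export
homography <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !all(dim(m) == c(3L, 3L)))
    stop("a homography must be a 3x3 numeric matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop("homography contains non-finite entries", call. = FALSE)
  if (abs(det(m)) <= 1e-12)
    stop("homography matrix is singular (|det| <= 1e-12)", call. = FALSE)
  if (abs(m[3, 3]) > .Machine$double.eps) m <- m / m[3, 3]
  structure(list(m = unname(m)), class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("Planar homography (moving -> fixed):\n")
  print(round(x$m, 6))
  invisible(x)
}

is_homography <- function(x) inherits(x, "homography")

#' @rdname homography
#' @export
hg_identity <- function() homography(diag(3))

#' Elementary homographies
#'
#' `hg_translate`, `hg_scale` and `hg_rotate` build common transforms;
#' `hg_rotate` rotates by `degrees` counter-clockwise in pixel coordinates
#' about `(cx, cy)`.
#'
#' @param tx,ty translation in pixels.
#' @param sx,sy scale factors.
#' @param degrees rotation angle.
#' @param cx,cy rotation centre.
#' @return `homography` objects.
#' @export
hg_translate <- function(tx, ty) homography(matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3))

#' @rdname hg_translate
#' @export
hg_scale <- function(sx, sy = sx) homography(diag(c(sx, sy, 1)))

#' @rdname hg_translate
#' @export
hg_rotate <- function(degrees, cx = 0, cy = 0) {
  th <- degrees * pi / 180
  r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  compose_homography(hg_translate(cx, cy),
                     compose_homography(homography(r), hg_translate(-cx, -cy)))
}

#' Apply a homography to 2D points
#'
#' @param points n x 2 numeric matrix (or length-2 vector) of `(x, y)` points.
#' @param h a [homography].
#' @return n x 2 matrix of transformed points.
#' @export
apply_homography <- function(points, h) {
  stopifnot(is_homography(h))
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  if (ncol(p) != 2) stop("points must be n x 2", call. = FALSE)
  hp <- h$m %*% rbind(t(p), 1)
  w <- hp[3, ]
  bad <- abs(w) < 1e-12
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("degenerate projective point (w ~ 0) at (%g, %g)", p[i, 1], p[i, 2]),
         call. = FALSE)
  }
  cbind(hp[1, ] / w, hp[2, ] / w)
}

#' Compose two homographies
#'
#' `compose_homography(h2, h1)` applies `h1` first: the result maps `p` to
#' `h2(h1(p))`.
#'
#' @param h2,h1 [homography] objects.
#' @return a [homography].
#' @export
compose_homography <- function(h2, h1) {
  stopifnot(is_homography(h2), is_homography(h1))
  homography(h2$m %*% h1$m)
}

#' Invert a homography
#'
#' @param h a [homography].
#' @return the inverse [homography].
#' @export
invert_homography <- function(h) {
  stopifnot(is_homography(h))
  inv <- tryCatch(solve(h$m), error = function(e)
    stop("homography is not invertible", call. = FALSE))
  homography(inv)
}

#' Read / write a homography as JSON
#'
#' The on-disk format is a JSON object with a single key `"matrix"` holding
#' the 3x3 row-major nested list.
#'
#' @param path JSON file path.
#' @param h a [homography].
#' @return `read_homography` returns a [homography]; `write_homography`
#'   returns `path` invisibly.
#' @export
read_homography <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$matrix)) stop("homography JSON lacks key 'matrix'", call. = FALSE)
  homography(matrix(as.numeric(t(obj$matrix)), 3, 3, byrow = TRUE))
}

#' @rdname read_homography
#' @export
write_homography <- function(h, path) {
  stopifnot(is_homography(h))
  rows <- lapply(seq_len(3), function(i) h$m[i, ])
  jsonlite::write_json(list(matrix = rows), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# insert vertices so no edge of the closed polygon is longer than d px
densify_polygon <- function(xy, d) {
  n <- nrow(xy)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- xy[i, ]; b <- xy[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / d))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Transform a COCO annotation set into another image frame
#'
#' Every polygon vertex is mapped by `h` (moving frame to fixed frame); the
#' bounding box and shoelace area are recomputed from the transformed polygon
#' and the `images` entry is replaced by `target_image`. Vertex-only mapping
#' is exact for affine transforms and approximate for strongly projective
#' ones; `densify` inserts intermediate vertices every `densify` pixels
#' before mapping to tighten that approximation.
#'
#' @param annotation_set a [coco_set].
#' @param h a [homography].
#' @param target_image list or data.frame row with `id`, `file_name`,
#'   `width`, `height` describing the fixed image.
#' @param densify optional edge-subdivision step in pixels (default off).
#' @param clip clip transformed vertices to the target bounds (default FALSE,
#'   lossless transfer).
#' @return a [coco_set] in the target frame.
#' @export
transform_annotation_set <- function(annotation_set, h, target_image,
                                     densify = NULL, clip = FALSE) {
  stopifnot(inherits(annotation_set, "coco_set"), is_homography(h))
  target_image <- as.list(target_image)
  stopifnot(all(c("id", "file_name", "width", "height") %in% names(target_image)))
  anns <- lapply(annotation_set$annotations, function(a) {
    polys <- lapply(a$segmentation, function(flat) {
      xy <- matrix(flat, ncol = 2, byrow = TRUE)
      if (!is.null(densify)) xy <- densify_polygon(xy, densify)
      txy <- tryCatch(apply_homography(xy, h), error = function(e)
        stop(sprintf("annotation %d: %s", a$id, conditionMessage(e)), call. = FALSE))
      if (clip) {
        txy[, 1] <- pmin(pmax(txy[, 1], 0), target_image$width - 1)
        txy[, 2] <- pmin(pmax(txy[, 2], 0), target_image$height - 1)
      }
      as.vector(t(txy))
    })
    xs <- unlist(lapply(polys, function(p) p[c(TRUE, FALSE)]))
    ys <- unlist(lapply(polys, function(p) p[c(FALSE, TRUE)]))
    a$segmentation <- polys
    a$bbox <- c(min(xs), min(ys), max(xs) - min(xs), max(ys) - min(ys))
    a$area <- sum(vapply(polys, function(p)
      shoelace_area(p[c(TRUE, FALSE)], p[c(FALSE, TRUE)]), numeric(1)))
    a$image_id <- as.integer(target_image$id)
    a
  })
  coco_set(
    images = data.frame(id = as.integer(target_image$id),
                        file_name = target_image$file_name,
                        width = as.integer(target_image$width),
                        height = as.integer(target_image$height),
                        stringsAsFactors = FALSE),
    categories = annotation_set$categories,
    annotations = anns
  )
}
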