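# Segmented-annotation model: mask ingestion from images / multichannel
# arrays, instance extraction via marching squares, and COCO JSON I/O.
#
# All segmented annotations are converted to COCO instance polygons: each
# connected foreground region of each class plane becomes one annotation.

# ---- ClassSpec ----

#' Class specification for 3-channel mask images
#'
#' Maps mask-image channels to class names. For 3-channel images channels are
#' indexed in BGR order (0 = blue, 1 = green, 2 = red), matching the fill-in
#' order used by OpenCV-based annotation tooling.
#'
#' @param channels integer vector of channel indices (>= 0, unique).
#' @param names character vector of class names (unique, non-empty).
#' @return object of class `class_spec`.
#' @export
class_spec <- function(channels, names) {
  channels <- as.integer(channels)
  names <- as.character(names)
  if (length(channels) != length(names) || !length(channels))
    stop("channels and names must be non-empty and of equal length", call. = FALSE)
  if (anyDuplicated(channels) || any(channels < 0))
    stop("channel indices must be unique and >= 0", call. = FALSE)
  if (anyDuplicated(names) || any(!nzchar(names)))
    stop("class names must be unique and non-empty", call. = FALSE)
  structure(list(entries = data.frame(channel = channels, name = names,
                                      stringsAsFactors = FALSE),
                 channel_order = "BGR"),
            class = "class_spec")
}

# ---- MaskStack ----

#' Construct a stack of per-class binary masks
#'
#' The canonical in-memory annotation format: a `[row, col, class]` array
#' where any nonzero source value is mapped to 1.
#'
#' @param data 3-axis numeric/logical array `[row, col, class]` (a matrix is
#'   promoted to a single-class stack).
#' @param class_names character vector, one name per class plane.
#' @return object of class `mask_stack` with fields `data`, `width`,
#'   `height`, `n_classes`, `class_names`.
#' @export
mask_stack <- function(data, class_names = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("mask data must be a [row, col, class] array", call. = FALSE)
  d <- dim(data)
  if (is.null(class_names))
    class_names <- paste0("class_", seq_len(d[3]) - 1L)
  class_names <- as.character(class_names)
  if (length(class_names) != d[3])
    stop(sprintf("class_names length %d does not match %d class planes",
                 length(class_names), d[3]), call. = FALSE)
  bin <- array(as.integer(data != 0), dim = d)
  structure(list(data = bin, width = d[2], height = d[1],
                 n_classes = d[3], class_names = class_names),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("mask_stack: %d x %d px, %d class(es)\n", x$width, x$height, x$n_classes))
  px <- apply(x$data, 3, sum)
  for (i in seq_len(x$n_classes))
    cat(sprintf("  [%d] %-20s %d foreground px\n", i - 1L, x$class_names[i], px[i]))
  invisible(x)
}

#' Load segmented annotations from a mask image
#'
#' Accepts 8- and 16-bit PNG/TIFF/JPEG with 1 or 3 channels. Each selected
#' channel must hold a binary mask for one class; any nonzero pixel becomes
#' foreground. A 1-channel image yields a single class. For 3-channel images
#' the `class_spec` channel indices follow BGR order.
#'
#' @param path image file path.
#' @param spec a [class_spec] mapping channels to class names; optional for
#'   1-channel images (defaults to a single class `"class_0"`).
#' @return a [mask_stack].
#' @export
load_mask_image <- function(path, spec = NULL) {
  img <- read_image(path)
  if (is.matrix(img)) {
    nm <- if (is.null(spec)) "class_0" else {
      if (nrow(spec$entries) != 1L || spec$entries$channel[1] != 0L)
        stop("1-channel mask image admits a single class at channel 0", call. = FALSE)
      spec$entries$name[1]
    }
    return(mask_stack(array(img, dim = c(dim(img), 1L)), nm))
  }
  if (is.null(spec))
    stop("a class_spec is required for 3-channel mask images", call. = FALSE)
  nch <- dim(img)[3]
  if (any(spec$entries$channel >= nch))
    stop(sprintf("class_spec channel index out of range (image has %d channels)", nch),
         call. = FALSE)
  # decoded planes are RGB; spec indices are BGR: 0 -> plane 3 (B), 2 -> plane 1 (R)
  plane_for <- function(ch) nch - ch
  planes <- lapply(spec$entries$channel, function(ch) img[, , plane_for(ch)])
  mask_stack(array(unlist(planes), dim = c(dim(img)[1:2], nrow(spec$entries))),
             spec$entries$name)
}

#' Load segmented annotations from a multichannel array archive
#'
#' The archive must contain exactly one array of shape `[x, y, nC]` (one
#' binary plane per class). Values are binarized (nonzero -> 1).
#'
#' @param path `.npz` archive path.
#' @param class_names optional class names; defaults to
#'   `class_0 ... class_{nC-1}`.
#' @return a [mask_stack].
#' @export
load_mask_array <- function(path, class_names = NULL) {
  arrays <- read_npz(path)
  if (length(arrays) != 1L)
    stop(sprintf("mask archive must contain exactly one array (found %d)",
                 length(arrays)), call. = FALSE)
  arr <- arrays[[1]]
  if (length(dim(arr)) != 3L)
    stop(sprintf("mask array must have rank 3 [x, y, nC]; got rank %d",
                 max(1L, length(dim(arr)))), call. = FALSE)
  mask_stack(arr, class_names)
}

# ---- COCO containers ----

#' Construct a COCO-format annotation set
#'
#' @param images data.frame with columns `id`, `file_name`, `width`, `height`.
#' @param categories data.frame with columns `id`, `name`.
#' @param annotations list of annotation records (`id`, `image_id`,
#'   `category_id`, `segmentation` (list of flat `[x1,y1,x2,y2,...]`
#'   polygons), `bbox`, `area`, `iscrowd`).
#' @return object of class `coco_set`.
#' @export
coco_set <- function(images, categories, annotations = list()) {
  images <- as.data.frame(images)
  categories <- as.data.frame(categories)
  obj <- structure(list(images = images, categories = categories,
                        annotations = annotations), class = "coco_set")
  validate_coco_set(obj)
  obj
}

#' Validate a COCO annotation set
#'
#' Checks the structural invariants: resolvable image/category references,
#' unique annotation ids, closed polygons with at least 3 vertices, tight
#' bounding boxes and positive shoelace area.
#'
#' @param x a [coco_set].
#' @param tol tolerance for the bbox-tightness check.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_coco_set <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "coco_set"))
  req <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop(sprintf("%s must have columns %s", what, paste(cols, collapse = ", ")),
           call. = FALSE)
  req(x$images, c("id", "file_name", "width", "height"), "images")
  req(x$categories, c("id", "name"), "categories")
  ids <- vapply(x$annotations, function(a) as.integer(a$id), integer(1))
  if (anyDuplicated(ids)) stop("annotation ids are not unique", call. = FALSE)
  for (a in x$annotations) {
    if (!a$image_id %in% x$images$id)
      stop(sprintf("annotation %d references unknown image %d", a$id, a$image_id),
           call. = FALSE)
    if (!a$category_id %in% x$categories$id)
      stop(sprintf("annotation %d references unknown category %d", a$id, a$category_id),
           call. = FALSE)
    for (p in a$segmentation) {
      if (length(p) < 6L || length(p) %% 2L != 0L)
        stop(sprintf("annotation %d: polygon needs >= 3 (x, y) vertices", a$id),
             call. = FALSE)
    }
    xs <- unlist(lapply(a$segmentation, function(p) p[c(TRUE, FALSE)]))
    ys <- unlist(lapply(a$segmentation, function(p) p[c(FALSE, TRUE)]))
    want <- c(min(xs), min(ys), max(xs) - min(xs), max(ys) - min(ys))
    if (max(abs(a$bbox - want)) > tol)
      stop(sprintf("annotation %d: bbox is not the tight hull of its vertices", a$id),
           call. = FALSE)
    if (!(a$area > 0))
      stop(sprintf("annotation %d: non-positive area", a$id), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.coco_set <- function(x, ...) {
  cat(sprintf("coco_set: %d image(s), %d categorie(s), %d annotation(s)\n",
              nrow(x$images), nrow(x$categories), length(x$annotations)))
  invisible(x)
}

# signed shoelace area of a closed polygon (absolute value returned)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# drop vertices lying on the straight line through their neighbours
simplify_collinear <- function(xy, tol = 1e-9) {
  repeat {
    n <- nrow(xy)
    if (n <= 3L) return(xy)
    ip <- c(n, seq_len(n - 1L)); im <- c(seq_len(n)[-1L], 1L)
    cross <- (xy[, 1] - xy[ip, 1]) * (xy[im, 2] - xy[ip, 2]) -
             (xy[, 2] - xy[ip, 2]) * (xy[im, 1] - xy[ip, 1])
    drop <- abs(cross) < tol
    if (!any(drop)) return(xy)
    # never drop below a triangle; remove in one sweep but keep 3 vertices
    keep <- !drop
    if (sum(keep) < 3L) keep[which(drop)[seq_len(3L - sum(keep))]] <- TRUE
    xy2 <- xy[keep, , drop = FALSE]
    if (nrow(xy2) == n) return(xy)
    xy <- xy2
  }
}

# Marching-squares outer contours of one binary plane.
# The plane is zero-padded by one pixel before tracing at iso-level 0.5 so
# regions touching the border still yield closed loops; with 0-based pixel
# centres at integers, contour vertices land on pixel-edge midpoints.
trace_plane_polygons <- function(plane) {
  h <- nrow(plane); w <- ncol(plane)
  lab <- EBImage::bwlabel(plane)
  n_inst <- max(lab)
  if (n_inst == 0L) return(list())
  out <- vector("list", n_inst)
  for (k in seq_len(n_inst)) {
    comp <- lab == k
    rows <- range(which(rowSums(comp) > 0)); cols <- range(which(colSums(comp) > 0))
    # crop with a 1-px zero pad around the component
    sub <- comp[max(1, rows[1] - 1):min(h, rows[2] + 1),
                max(1, cols[1] - 1):min(w, cols[2] + 1), drop = FALSE]
    pad <- matrix(0, nrow(sub) + 2L, ncol(sub) + 2L)
    pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
    y0 <- max(1, rows[1] - 1) - 1L  # 0-based row coord of sub[1, ]
    x0 <- max(1, cols[1] - 1) - 1L
    cl <- grDevices::contourLines(x = seq_len(nrow(pad)) - 2 + y0,
                                  y = seq_len(ncol(pad)) - 2 + x0,
                                  z = pad, levels = 0.5)
    if (!length(cl)) { out[[k]] <- NULL; next }
    polys <- lapply(cl, function(g) {
      xy <- cbind(g$y, g$x)  # contourLines x follows rows (our y)
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
      xy
    })
    areas <- vapply(polys, function(p) shoelace_area(p[, 1], p[, 2]), numeric(1))
    out[[k]] <- polys[[which.max(areas)]]  # outer contour; holes ignored
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Convert a mask stack to COCO instance annotations
#'
#' Each connected foreground region (4-connectivity) of each class plane is
#' traced with marching squares at iso-level 0.5 on a zero-padded copy of the
#' plane (closing border-touching contours), the pad offset is subtracted,
#' collinear vertex runs are dropped, and the polygon is stored as one COCO
#' annotation. Regions whose contour has fewer than 3 vertices or shoelace
#' area below `min_area` are dropped (a count is reported via `message`).
#'
#' @param stack a [mask_stack].
#' @param image_id integer id for the (moving) image the masks annotate.
#' @param file_name file name recorded in the COCO `images` entry.
#' @param min_area minimum polygon area in px^2 (default 1).
#' @return a [coco_set] with one category per class (ids `1..n_classes`).
#' @export
masks_to_coco <- function(stack, image_id = 1L, file_name = "image", min_area = 1.0) {
  stopifnot(inherits(stack, "mask_stack"))
  anns <- list(); next_id <- 1L; dropped <- 0L
  for (ci in seq_len(stack$n_classes)) {
    polys <- trace_plane_polygons(stack$data[, , ci])
    for (xy in polys) {
      xy <- simplify_collinear(xy)
      if (nrow(xy) < 3L) { dropped <- dropped + 1L; next }
      area <- shoelace_area(xy[, 1], xy[, 2])
      if (area < min_area) { dropped <- dropped + 1L; next }
      anns[[length(anns) + 1L]] <- list(
        id = next_id, image_id = as.integer(image_id), category_id = ci,
        segmentation = list(as.vector(t(xy))),
        bbox = c(min(xy[, 1]), min(xy[, 2]),
                 max(xy[, 1]) - min(xy[, 1]), max(xy[, 2]) - min(xy[, 2])),
        area = area, iscrowd = 0L)
      next_id <- next_id + 1L
    }
  }
  if (dropped > 0L)
    message(sprintf("masks_to_coco: dropped %d degenerate region(s)", dropped))
  coco_set(
    images = data.frame(id = as.integer(image_id), file_name = file_name,
                        width = stack$width, height = stack$height,
                        stringsAsFactors = FALSE),
    categories = data.frame(id = seq_len(stack$n_classes),
                            name = stack$class_names, stringsAsFactors = FALSE),
    annotations = anns)
}

# even-odd polygon fill over integer pixel centres, 0-based coords
poly_fill <- function(xs, ys, width, height) {
  out <- matrix(0L, height, width)
  cx0 <- max(0L, floor(min(xs))); cx1 <- min(width - 1L, ceiling(max(xs)))
  cy0 <- max(0L, floor(min(ys))); cy1 <- min(height - 1L, ceiling(max(ys)))
  if (cx1 < cx0 || cy1 < cy0) return(out)
  px <- cx0:cx1; py <- cy0:cy1
  grid_x <- rep(px, times = length(py))
  grid_y <- rep(py, each = length(px))
  inside <- rep(FALSE, length(grid_x))
  n <- length(xs)
  j <- n
  for (i in seq_len(n)) {
    yi <- ys[i]; yj <- ys[j]; xi <- xs[i]; xj <- xs[j]
    if (yi != yj) {
      crosses <- ((yi > grid_y) != (yj > grid_y)) &
        (grid_x < (xj - xi) * (grid_y - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  out[cbind(grid_y + 1L, grid_x + 1L)] <- as.integer(inside)
  out
}

#' Rasterize COCO annotations back to a mask stack
#'
#' Fills every polygon (even-odd rule, pixel-centre sampling) and unions the
#' fills per category into binary planes. Vertices outside the raster are
#' handled by clipping the fill to the raster bounds.
#'
#' @param annotation_set a [coco_set].
#' @param width,height raster dimensions in pixels.
#' @return a [mask_stack] with one plane per category (in category order).
#' @export
rasterize_annotations <- function(annotation_set, width, height) {
  stopifnot(inherits(annotation_set, "coco_set"))
  validate_coco_set(annotation_set)
  ncat <- nrow(annotation_set$categories)
  planes <- array(0L, dim = c(height, width, ncat))
  cat_index <- match(
    vapply(annotation_set$annotations, function(a) as.integer(a$category_id), integer(1)),
    annotation_set$categories$id)
  for (i in seq_along(annotation_set$annotations)) {
    a <- annotation_set$annotations[[i]]
    for (p in a$segmentation) {
      f <- poly_fill(p[c(TRUE, FALSE)], p[c(FALSE, TRUE)], width, height)
      planes[, , cat_index[i]] <- pmax(planes[, , cat_index[i]], f)
    }
  }
  mask_stack(planes, annotation_set$categories$name)
}

#' Read / write COCO JSON
#'
#' The writer emits the standard top-level keys `images`, `categories`,
#' `annotations`; the round trip `read_coco(write_coco(A))` reproduces `A`
#' field-for-field.
#'
#' @param path JSON file path.
#' @param annotation_set a [coco_set].
#' @return `read_coco` returns a [coco_set].
#' @export
read_coco <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed COCO JSON: ",
                                           conditionMessage(e), call. = FALSE))
  miss <- setdiff(c("images", "categories", "annotations"), names(obj))
  if (length(miss))
    stop(sprintf("COCO file lacks required key(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  images <- do.call(rbind, lapply(obj$images, function(im)
    data.frame(id = as.integer(im$id), file_name = as.character(im$file_name),
               width = as.integer(im$width), height = as.integer(im$height),
               stringsAsFactors = FALSE)))
  categories <- do.call(rbind, lapply(obj$categories, function(ct)
    data.frame(id = as.integer(ct$id), name = as.character(ct$name),
               stringsAsFactors = FALSE)))
  anns <- lapply(obj$annotations, function(a) list(
    id = as.integer(a$id), image_id = as.integer(a$image_id),
    category_id = as.integer(a$category_id),
    segmentation = lapply(a$segmentation, function(p) as.numeric(unlist(p))),
    bbox = as.numeric(unlist(a$bbox)), area = as.numeric(a$area),
    iscrowd = as.integer(a$iscrowd %||% 0L)))
  coco_set(images, categories, anns)
}

#' @rdname read_coco
#' @export
write_coco <- function(annotation_set, path) {
  stopifnot(inherits(annotation_set, "coco_set"))
  obj <- list(
    images = lapply(seq_len(nrow(annotation_set$images)), function(i) {
      r <- annotation_set$images[i, ]
      list(id = r$id, file_name = r$file_name, width = r$width, height = r$height)
    }),
    categories = lapply(seq_len(nrow(annotation_set$categories)), function(i) {
      r <- annotation_set$categories[i, ]
      list(id = r$id, name = r$name)
    }),
    annotations = lapply(annotation_set$annotations, function(a) list(
      id = a$id, image_id = a$image_id, category_id = a$category_id,
      segmentation = lapply(a$segmentation, as.numeric),
      bbox = as.numeric(a$bbox), area = a$area, iscrowd = a$iscrowd))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
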