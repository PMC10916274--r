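# Tiled multiresolution pyramids: every input and result image can be
# converted into a tile tree where each level halves the previous
# resolution (ceiling division) down to a 1-pixel edge, and any region of
# any level can be reassembled from exactly the intersecting tiles.

#' Number of pyramid levels for an image size
#'
#' `ceil(log2(max(width, height))) + 1` for images larger than one pixel;
#' a 1 x 1 image has a single level.
#'
#' @param width,height base-image dimensions in pixels.
#' @return integer level count.
#' @export
n_levels <- function(width, height) {
  m <- max(width, height)
  if (m <= 1L) return(1L)
  as.integer(ceiling(log2(m)) + 1L)
}

level_dimensions <- function(width, height) {
  dims <- list(c(width, height))
  w <- width; h <- height
  while (max(w, h) > 1L) {
    w <- as.integer(ceiling(w / 2)); h <- as.integer(ceiling(h / 2))
    dims <- c(dims, list(c(w, h)))
  }
  rev(dims)  # coarsest first
}

#' Halve an image by 2x2 area averaging
#'
#' Output dimensions are the ceiling of half the input; edge rows/columns of
#' odd-sized inputs average the available samples.
#'
#' @param image matrix or `[row, col, c]` array.
#' @return halved image.
#' @export
downsample_half <- function(image) {
  half_mat <- function(m) {
    h <- nrow(m); w <- ncol(m)
    oh <- ceiling(h / 2); ow <- ceiling(w / 2)
    # pad odd edges by replicating the last row/col, then average 2x2 blocks
    if (h %% 2L) m <- rbind(m, m[h, , drop = FALSE])
    if (w %% 2L) m <- cbind(m, m[, w, drop = FALSE])
    e <- seq_len(oh) * 2L
    rows <- (m[e - 1L, , drop = FALSE] + m[e, , drop = FALSE]) / 2
    ec <- seq_len(ow) * 2L
    (rows[, ec - 1L, drop = FALSE] + rows[, ec, drop = FALSE]) / 2
  }
  if (is.matrix(image)) return(half_mat(image))
  d <- dim(image)
  out <- array(0, dim = c(ceiling(d[1] / 2), ceiling(d[2] / 2), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- half_mat(image[, , c])
  out
}

pyramid_spec <- function(width, height, tile_size) {
  dims <- level_dimensions(as.integer(width), as.integer(height))
  structure(list(width = as.integer(width), height = as.integer(height),
                 tile_size = as.integer(tile_size), n_levels = length(dims),
                 level_dims = dims),
            class = "pyramid_spec")
}

#' @export
print.pyramid_spec <- function(x, ...) {
  cat(sprintf("pyramid_spec: %d x %d px, tile %d, %d levels\n",
              x$width, x$height, x$tile_size, x$n_levels))
  invisible(x)
}

#' Build a tiled image pyramid on disk
#'
#' Level `n_levels - 1` (finest) is the unmodified source; each coarser
#' level is produced by ceiling-halving with 2x2 area averaging until the
#' larger edge reaches 1 pixel. Every level is cut into `tile_size` square
#' tiles (right/bottom edge tiles smaller), written losslessly as PNG under
#' `<out_dir>/<level>/<col>_<row>.png` with level 0 the coarsest, plus a
#' JSON descriptor `pyramid.json`. With `dzi = TRUE` a Deep Zoom XML
#' descriptor is written alongside for viewer compatibility.
#'
#' @param image image array, or a path readable by [read_image()].
#' @param out_dir output directory for the tile tree.
#' @param tile_size tile edge in pixels (default 1024).
#' @param dzi also emit a Deep Zoom `.dzi` descriptor.
#' @return the [pyramid_spec], with the directory attached as attribute
#'   `"dir"`.
#' @export
build_pyramid <- function(image, out_dir, tile_size = 1024L, dzi = FALSE) {
  if (is.character(image)) image <- read_image(image)
  d <- image_dims(image)
  spec <- pyramid_spec(width = d[2], height = d[1], tile_size = tile_size)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create pyramid directory: %s", out_dir), call. = FALSE)
  lev_img <- image
  for (lev in rev(seq_len(spec$n_levels) - 1L)) {
    ldir <- file.path(out_dir, lev)
    dir.create(ldir, showWarnings = FALSE)
    ld <- image_dims(lev_img)
    ncol_t <- ceiling(ld[2] / tile_size); nrow_t <- ceiling(ld[1] / tile_size)
    for (tc in seq_len(ncol_t) - 1L) {
      for (tr in seq_len(nrow_t) - 1L) {
        x0 <- tc * tile_size + 1L; x1 <- min((tc + 1L) * tile_size, ld[2])
        y0 <- tr * tile_size + 1L; y1 <- min((tr + 1L) * tile_size, ld[1])
        tile <- if (is.matrix(lev_img)) lev_img[y0:y1, x0:x1, drop = FALSE]
                else lev_img[y0:y1, x0:x1, , drop = FALSE]
        png::writePNG(tile, file.path(ldir, sprintf("%d_%d.png", tc, tr)))
      }
    }
    if (lev > 0L) lev_img <- downsample_half(lev_img)
  }
  jsonlite::write_json(
    list(width = spec$width, height = spec$height,
         tile_size = spec$tile_size, n_levels = spec$n_levels),
    file.path(out_dir, "pyramid.json"), auto_unbox = TRUE)
  if (dzi) write_dzi(spec, out_dir)
  attr(spec, "dir") <- out_dir
  spec
}

write_dzi <- function(spec, out_dir) {
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(paste0('<Image TileSize="%d" Overlap="0" Format="png" ',
                   'xmlns="http://schemas.microsoft.com/deepzoom/2008">\n'),
            spec$tile_size),
    sprintf('  <Size Width="%d" Height="%d"/>\n', spec$width, spec$height),
    "</Image>\n")
  writeLines(xml, file.path(out_dir, "image.dzi"))
  invisible(NULL)
}

#' Load a pyramid descriptor from disk
#'
#' @param dir directory previously populated by [build_pyramid()].
#' @return the [pyramid_spec] with attribute `"dir"`.
#' @export
load_pyramid <- function(dir) {
  meta_path <- file.path(dir, "pyramid.json")
  if (!file.exists(meta_path))
    stop(sprintf("no pyramid descriptor at %s", meta_path), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spec <- pyramid_spec(meta$width, meta$height, meta$tile_size)
  attr(spec, "dir") <- dir
  spec
}

#' Read a region of a pyramid level
#'
#' Assembles the requested rectangle from exactly the tiles it intersects.
#' Coordinates are 0-based pixels in the chosen level's frame.
#'
#' @param pyramid a [pyramid_spec] with attribute `"dir"` (as returned by
#'   [build_pyramid()] or [load_pyramid()]).
#' @param level level index, 0 = coarsest.
#' @param x,y top-left corner of the region.
#' @param w,h region width and height.
#' @return image array of size `h x w`.
#' @export
read_region <- function(pyramid, level, x, y, w, h) {
  dir <- attr(pyramid, "dir")
  stopifnot(!is.null(dir))
  if (level < 0L || level >= pyramid$n_levels)
    stop(sprintf("level %d out of range [0, %d]", level, pyramid$n_levels - 1L),
         call. = FALSE)
  ld <- pyramid$level_dims[[level + 1L]]  # (width, height)
  if (x < 0 || y < 0 || x + w > ld[1] || y + h > ld[2])
    stop("requested region exceeds the level's dimensions", call. = FALSE)
  ts <- pyramid$tile_size
  out <- NULL
  for (tc in (x %/% ts):((x + w - 1L) %/% ts)) {
    for (tr in (y %/% ts):((y + h - 1L) %/% ts)) {
      tile <- read_image(file.path(dir, level, sprintf("%d_%d.png", tc, tr)))
      if (is.null(out)) {
        nch <- if (is.matrix(tile)) 1L else dim(tile)[3]
        out <- if (nch == 1L) matrix(0, h, w) else array(0, dim = c(h, w, nch))
      }
      tx0 <- tc * ts; ty0 <- tr * ts
      sx0 <- max(x, tx0); sx1 <- min(x + w, tx0 + ncol(tile))
      sy0 <- max(y, ty0); sy1 <- min(y + h, ty0 + nrow(tile))
      if (sx1 <= sx0 || sy1 <= sy0) next
      src_r <- (sy0 - ty0 + 1L):(sy1 - ty0); src_c <- (sx0 - tx0 + 1L):(sx1 - tx0)
      dst_r <- (sy0 - y + 1L):(sy1 - y); dst_c <- (sx0 - x + 1L):(sx1 - x)
      if (is.matrix(out)) {
        tm <- if (is.matrix(tile)) tile else tile[, , 1L]
        out[dst_r, dst_c] <- tm[src_r, src_c]
      } else {
        ta <- if (is.matrix(tile)) array(tile, dim = c(dim(tile), 1L)) else tile
        for (c in seq_len(dim(out)[3]))
          out[dst_r, dst_c, c] <- ta[src_r, src_c, min(c, dim(ta)[3])]
      }
    }
  }
  out
}
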