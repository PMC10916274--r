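# Synthetic multimodal fixtures: textured "tissue" images with per-blob
# masks and image pairs related by a known ground-truth homography, so the
# whole registration chain is testable without any external dataset.

#' Generate a synthetic tissue image with known per-blob masks
#'
#' Produces a deterministic (seeded) texture: a dark, faintly textured
#' background carrying `n_blobs` smooth elliptical "tissue" regions filled
#' with band-limited speckle so that feature detectors find stable
#' keypoints. Blob placement uses rejection sampling to keep regions
#' disjoint.
#'
#' @param width,height image size in pixels (default 512 x 512).
#' @param n_blobs number of tissue regions (default 5).
#' @param seed RNG seed; all randomness flows from it.
#' @return list with `image` (grayscale matrix in `[0, 1]`) and `masks`
#'   (a [mask_stack] with one binary plane per blob).
#' @export
make_tissue_image <- function(width = 512L, height = 512L, n_blobs = 5L, seed = 0L) {
  with_local_seed(seed, {
    gx <- matrix(rep(seq_len(width) - 1L, each = height), height, width)
    gy <- matrix(rep(seq_len(height) - 1L, times = width), height, width)
    smooth_noise <- function(sigma) {
      n <- matrix(stats::rnorm(height * width), height, width)
      stretch01(gaussian_blur(n, sigma))
    }
    img <- 0.06 + 0.06 * smooth_noise(6)
    masks <- array(0L, dim = c(height, width, max(n_blobs, 1L)))
    placed <- 0L; attempts <- 0L
    params <- list()
    while (placed < n_blobs && attempts < 200L * max(n_blobs, 1L)) {
      attempts <- attempts + 1L
      a <- stats::runif(1, 0.09, 0.16) * min(width, height)
      b <- stats::runif(1, 0.6, 1) * a
      cx <- stats::runif(1, a + 8, width - a - 9)
      cy <- stats::runif(1, a + 8, height - a - 9)
      th <- stats::runif(1, 0, pi)
      ok <- TRUE
      for (p in params)
        if (sqrt((p$cx - cx)^2 + (p$cy - cy)^2) < (p$a + a + 6)) { ok <- FALSE; break }
      if (!ok) next
      placed <- placed + 1L
      params[[placed]] <- list(cx = cx, cy = cy, a = a, b = b, th = th)
      u <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
      v <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      masks[, , placed][inside] <- 1L
      tex <- 0.45 + 0.45 * smooth_noise(1.2) + 0.10 * smooth_noise(4)
      img[inside] <- tex[inside]
    }
    if (placed < n_blobs)
      warning(sprintf("placed only %d of %d blobs", placed, n_blobs), call. = FALSE)
    masks <- masks[, , seq_len(max(placed, 1L)), drop = FALSE]
    if (placed == 0L) masks <- array(0L, dim = c(height, width, 1L))
    list(image = clamp01(img),
         masks = mask_stack(masks, paste0("blob_", seq_len(dim(masks)[3]))))
  })
}

# ground-truth homography: scale then rotate about the image centre, then
# translate, with optional projective bottom-row terms
synth_homography <- function(width, height, rotation = 10, translation = c(15, -7),
                             scale = 1, projective = 0) {
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  h <- compose_homography(
    hg_translate(translation[1], translation[2]),
    compose_homography(hg_rotate(rotation, cx, cy),
                       compose_homography(hg_translate(cx, cy),
                                          compose_homography(hg_scale(scale),
                                                             hg_translate(-cx, -cy)))))
  if (projective != 0) {
    m <- h$m
    m[3, 1] <- projective; m[3, 2] <- projective
    h <- homography(m)
  }
  h
}

#' Generate a registered multimodal image pair with known ground truth
#'
#' The fixed image is the input; the moving image is the input resampled
#' through the inverse of the ground-truth homography onto the same canvas
#' (out-of-frame content clipped), then modality-transformed and corrupted
#' with Gaussian noise. The returned `true_homography` maps moving-image
#' coordinates to fixed-image coordinates. `modality_effect = "invert"`
#' emulates the opposite intensity conventions of NLO (bright tissue) and
#' H&E (bright background) imagery; `"recolor"` produces an RGB
#' eosin-toned rendition; `"none"` leaves intensities untouched.
#'
#' @param image grayscale input image (the fixed frame).
#' @param rotation rotation in degrees about the image centre.
#' @param translation `c(tx, ty)` in pixels.
#' @param scale uniform scale factor.
#' @param projective projective bottom-row perturbation (0 = affine).
#' @param modality_effect `"invert"`, `"recolor"` or `"none"`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed for the noise.
#' @return list with `fixed`, `moving`, `true_homography`.
#' @export
make_pair <- function(image, rotation = 10, translation = c(15, -7), scale = 1,
                      projective = 0, modality_effect = c("invert", "recolor", "none"),
                      noise_sd = 5 / 255, seed = 0L) {
  modality_effect <- match.arg(modality_effect)
  d <- image_dims(image)
  h_true <- synth_homography(d[2], d[1], rotation, translation, scale, projective)
  moving <- warp_image(image, invert_homography(h_true), d)
  moving <- switch(modality_effect,
                   invert = 1 - moving,
                   recolor = {
                     rgb <- array(0, dim = c(d, 3L))
                     rgb[, , 1] <- clamp01(0.95 - 0.55 * moving)
                     rgb[, , 2] <- clamp01(0.90 - 0.75 * moving)
                     rgb[, , 3] <- clamp01(0.95 - 0.35 * moving)
                     rgb
                   },
                   none = moving)
  if (noise_sd > 0) {
    moving <- with_local_seed(seed, clamp01(moving + stats::rnorm(length(moving),
                                                                  sd = noise_sd)))
    if (!is.matrix(moving) && length(dim(moving)) == 3L)
      moving <- array(moving, dim = c(d, 3L))
  }
  list(fixed = image, moving = moving, true_homography = h_true)
}

#' Warp a mask stack with a homography
#'
#' Each plane is resampled bilinearly and re-thresholded at 0.5.
#'
#' @param stack a [mask_stack].
#' @param h a [homography] mapping source to target coordinates.
#' @param out_dim target `c(height, width)`.
#' @return a [mask_stack] in the target frame.
#' @export
warp_mask_stack <- function(stack, h, out_dim) {
  planes <- array(0L, dim = c(out_dim[1], out_dim[2], stack$n_classes))
  for (k in seq_len(stack$n_classes))
    planes[, , k] <- (warp_image(stack$data[, , k], h, out_dim) >= 0.5) + 0L
  mask_stack(planes, stack$class_names)
}

#' Write ready-to-register synthetic project inputs
#'
#' Creates `fixed/`, `moving/` and `masks/` directories holding `n_pairs`
#' synthetic multimodal pairs (PNG) with per-moving-image mask archives
#' (`.npz`, moving frame) and the ground-truth homographies as JSON under
#' `ground_truth/`.
#'
#' @param dir output directory.
#' @param n_pairs number of pairs.
#' @param width,height,n_blobs passed to [make_tissue_image()].
#' @param seed base seed; pair `i` uses `seed + i - 1`.
#' @param ... further arguments passed to [make_pair()].
#' @return `dir`, invisibly.
#' @export
make_synth_inputs <- function(dir, n_pairs = 1L, width = 512L, height = 512L,
                              n_blobs = 5L, seed = 0L, ...) {
  for (sub in c("fixed", "moving", "masks", "ground_truth"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_pairs)) {
    s <- seed + i - 1L
    tissue <- make_tissue_image(width, height, n_blobs, seed = s)
    pair <- make_pair(tissue$image, seed = s, ...)
    stem <- sprintf("pair_%02d", i)
    write_image(pair$fixed, file.path(dir, "fixed", paste0(stem, ".png")))
    write_image(pair$moving, file.path(dir, "moving", paste0(stem, ".png")))
    moving_masks <- warp_mask_stack(tissue$masks,
                                    invert_homography(pair$true_homography),
                                    image_dims(pair$fixed))
    write_npz(file.path(dir, "masks", paste0(stem, ".npz")),
              list(masks = moving_masks$data))
    write_homography(pair$true_homography,
                     file.path(dir, "ground_truth", paste0(stem, "_homography.json")))
  }
  invisible(dir)
}
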