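# Feature-based registration chain: modality-aware preprocessing,
# multi-scale corner detection with orientation assignment, SIFT-like
# gradient-histogram descriptors and ORB-like rotated binary descriptors,
# brute-force kNN matching with the ratio test, and robust (RANSAC + DLT)
# homography estimation.

#' Modality-aware grayscale preprocessing
#'
#' Registration across brightfield H&E and non-linear optical (NLO)
#' microscopy must reconcile opposite intensity conventions: in NLO images
#' the tissue is the bright structure, in H&E it is the background that is
#' bright. `modality = "he"` therefore inverts intensities (tissue becomes
#' bright) and contrast-stretches to full range; `"nlo"` contrast-stretches
#' only; `"generic"` performs plain grayscale conversion.
#'
#' @param image input image.
#' @param modality one of `"generic"`, `"he"`, `"nlo"`.
#' @return grayscale matrix in `[0, 1]`.
#' @export
preprocess_modality <- function(image, modality = c("generic", "he", "nlo")) {
  modality <- match.arg(modality)
  g <- to_gray(image)
  switch(modality,
         generic = g,
         he = stretch01(1 - g),
         nlo = stretch01(g))
}

# central-difference gradients; x = column direction, y = row direction
gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

gaussian_blur <- function(m, sigma) {
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  EBImage::filter2(m, EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma),
                   boundary = "replicate")
}

# grayscale max filter over a (2r+1)^2 window by shifting
max_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (dy in -r:r) {
    ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
    for (dx in -r:r) {
      if (dx == 0L && dy == 0L) next
      ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
      out <- pmax(out, m[ri, ci])
    }
  }
  out
}

# dominant gradient orientation per keypoint (36-bin weighted histogram)
assign_orientation <- function(gx, gy, kx, ky, radius = 8L, sigma = 4.5) {
  off <- expand.grid(ox = -radius:radius, oy = -radius:radius)
  wgt0 <- exp(-(off$ox^2 + off$oy^2) / (2 * sigma^2))
  n <- length(kx); m <- nrow(off)
  X <- outer(kx, off$ox, "+"); Y <- outer(ky, off$oy, "+")
  X <- pmin(pmax(X, 0L), ncol(gx) - 1L); Y <- pmin(pmax(Y, 0L), nrow(gx) - 1L)
  lin <- Y + 1L + X * nrow(gx)
  gxv <- gx[lin]; gyv <- gy[lin]
  mag <- sqrt(gxv^2 + gyv^2)
  ang <- atan2(gyv, gxv)
  bin <- floor((ang + pi) / (2 * pi) * 36) %% 36
  w <- as.vector(mag * rep(wgt0, each = n))
  idx <- as.vector(row(X) + n * bin)  # 1..n for bin 0, etc.
  hist <- matrix(0, n, 36)
  acc <- rowsum(w, idx)
  hist[as.integer(rownames(acc))] <- acc
  # circular smoothing, twice
  for (i in 1:2) {
    hist <- (hist[, c(36, 1:35), drop = FALSE] + hist +
               hist[, c(2:36, 1), drop = FALSE]) / 3
  }
  peak <- max.col(hist, ties.method = "first")
  (peak - 0.5) / 36 * 2 * pi - pi
}

#' Detect oriented corner keypoints
#'
#' Multi-scale Harris corner detection (derivative scale 1, integration
#' scale 2, k = 0.04) with non-maximum suppression and a dominant gradient
#' orientation assigned per keypoint. Coarser scales are obtained by
#' area-averaged halving of the image.
#'
#' @param gray grayscale matrix in `[0, 1]`.
#' @param max_keypoints keep at most this many keypoints (by response).
#' @param n_scales number of octaves examined (default 2).
#' @param nms_radius non-maximum-suppression radius in pixels.
#' @param margin border margin excluded from detection, in pixels.
#' @return data.frame with columns `x`, `y`, `scale`, `orientation`,
#'   `response` (full-resolution 0-based coordinates) plus internal
#'   level-frame columns `lx`, `ly`, `level`.
#' @export
detect_keypoints <- function(gray, max_keypoints = 500L, n_scales = 2L,
                             nms_radius = 4L, margin = 20L) {
  stopifnot(is.matrix(gray))
  levels <- list(gray)
  if (n_scales > 1L) for (l in 2:n_scales) {
    prev <- levels[[l - 1L]]
    if (min(dim(prev)) < 2L * margin + 8L) break
    levels[[l]] <- downsample_half(prev)
  }
  kps <- list()
  for (l in seq_along(levels)) {
    img <- levels[[l]]
    g <- gaussian_blur(img, 1.0)
    gr <- gradients(g)
    A <- gaussian_blur(gr$gx^2, 2.0)
    B <- gaussian_blur(gr$gy^2, 2.0)
    C <- gaussian_blur(gr$gx * gr$gy, 2.0)
    R <- A * B - C^2 - 0.04 * (A + B)^2
    mx <- max_filter(R, nms_radius)
    cand <- which(R >= mx & R > 1e-9)
    if (!length(cand)) next
    ri <- (cand - 1L) %% nrow(R) + 1L
    ci <- (cand - 1L) %/% nrow(R) + 1L
    keep <- ri > margin & ri <= nrow(R) - margin & ci > margin & ci <= ncol(R) - margin
    if (!any(keep)) next
    ri <- ri[keep]; ci <- ci[keep]; resp <- R[cbind(ri, ci)]
    ori <- assign_orientation(gr$gx, gr$gy, ci - 1L, ri - 1L)
    # sub-pixel localization: 1D parabolic fit of the response in x and y
    parab <- function(m1, p1) {
      den <- m1 - 2 * resp + p1
      off <- ifelse(abs(den) > 1e-12, 0.5 * (m1 - p1) / den, 0)
      pmin(pmax(off, -0.5), 0.5)
    }
    sx <- parab(R[cbind(ri, ci - 1L)], R[cbind(ri, ci + 1L)])
    sy <- parab(R[cbind(ri - 1L, ci)], R[cbind(ri + 1L, ci)])
    lx <- ci - 1L + sx; ly <- ri - 1L + sy
    sc <- 2^(l - 1L)
    kps[[l]] <- data.frame(
      x = lx * sc + (sc - 1) / 2, y = ly * sc + (sc - 1) / 2,
      scale = sc, orientation = ori, response = resp * sc^2,
      lx = lx, ly = ly, level = l)
  }
  if (!length(kps))
    return(data.frame(x = numeric(), y = numeric(), scale = numeric(),
                      orientation = numeric(), response = numeric(),
                      lx = numeric(), ly = numeric(), level = integer()))
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp$response), , drop = FALSE]
  kp <- utils::head(kp, max_keypoints)
  rownames(kp) <- NULL
  kp
}

# SIFT-like descriptor: 16x16 rotated sample grid, 4x4 spatial cells x 8
# orientation bins, Gaussian-weighted, L2-normalized with 0.2 clipping.
describe_gradient_hist <- function(levels, kp) {
  n <- nrow(kp)
  grid <- expand.grid(u = seq(-7.5, 7.5, by = 1), v = seq(-7.5, 7.5, by = 1))
  m <- nrow(grid)  # 256
  cell <- floor((grid$u + 8) / 4) * 4 + floor((grid$v + 8) / 4)  # 0..15
  wspat <- exp(-(grid$u^2 + grid$v^2) / (2 * 8^2))
  desc <- matrix(0, n, 128)
  grads <- lapply(levels, function(im) gradients(gaussian_blur(im, 1.0)))
  for (l in sort(unique(kp$level))) {
    sel <- which(kp$level == l)
    g <- grads[[l]]
    cosb <- cos(kp$orientation[sel]); sinb <- sin(kp$orientation[sel])
    # n_l x m sample coordinates in the level frame
    dx <- outer(cosb, grid$u) - outer(sinb, grid$v)
    dy <- outer(sinb, grid$u) + outer(cosb, grid$v)
    X <- kp$lx[sel] + dx; Y <- kp$ly[sel] + dy
    gxv <- matrix(bilinear_sample(g$gx, as.vector(X), as.vector(Y)), nrow = length(sel))
    gyv <- matrix(bilinear_sample(g$gy, as.vector(X), as.vector(Y)), nrow = length(sel))
    # rotate gradients into the keypoint frame
    rgx <- gxv * cosb + gyv * sinb
    rgy <- -gxv * sinb + gyv * cosb
    mag <- sqrt(rgx^2 + rgy^2)
    ang <- atan2(rgy, rgx)
    bin <- floor((ang + pi) / (2 * pi) * 8) %% 8
    w <- mag * rep(wspat, each = length(sel))
    feat <- rep(cell, each = length(sel)) * 8 + bin  # 0..127
    idx <- as.vector(row(X) + length(sel) * feat)
    acc <- rowsum(as.vector(w), idx)
    block <- matrix(0, length(sel), 128)
    block[as.integer(rownames(acc))] <- acc
    desc[sel, ] <- block
  }
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc <- pmin(desc / nrm, 0.2)
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc / nrm
}

# fixed random sampling pattern for the binary descriptor, generated once
brief_pattern <- local({
  pat <- NULL
  function(n_bits = 256L, radius = 14) {
    if (is.null(pat)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      set.seed(20240305L)
      p <- matrix(stats::rnorm(n_bits * 4L, sd = radius / 2.2), ncol = 4L)
      p <- pmin(pmax(p, -radius), radius)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      pat <<- p
    }
    pat
  }
})

# ORB-like rotated binary descriptor on a smoothed image
describe_binary <- function(levels, kp, n_bits = 256L) {
  n <- nrow(kp)
  pat <- brief_pattern(n_bits)
  desc <- matrix(0, n, n_bits)
  smoothed <- lapply(levels, gaussian_blur, sigma = 2.0)
  for (l in sort(unique(kp$level))) {
    sel <- which(kp$level == l)
    im <- smoothed[[l]]
    cosb <- cos(kp$orientation[sel]); sinb <- sin(kp$orientation[sel])
    x1 <- kp$lx[sel] + outer(cosb, pat[, 1]) - outer(sinb, pat[, 2])
    y1 <- kp$ly[sel] + outer(sinb, pat[, 1]) + outer(cosb, pat[, 2])
    x2 <- kp$lx[sel] + outer(cosb, pat[, 3]) - outer(sinb, pat[, 4])
    y2 <- kp$ly[sel] + outer(sinb, pat[, 3]) + outer(cosb, pat[, 4])
    s1 <- matrix(bilinear_sample(im, as.vector(x1), as.vector(y1)), nrow = length(sel))
    s2 <- matrix(bilinear_sample(im, as.vector(x2), as.vector(y2)), nrow = length(sel))
    desc[sel, ] <- (s1 < s2) + 0
  }
  desc
}

# rebuild the octave images a keypoint table refers to
octave_images <- function(gray, n_levels) {
  levels <- list(gray)
  if (n_levels > 1L) for (l in 2:n_levels) levels[[l]] <- downsample_half(levels[[l - 1L]])
  levels
}

#' Compute descriptors for detected keypoints
#'
#' @param gray grayscale matrix the keypoints were detected on.
#' @param keypoints data.frame from [detect_keypoints()].
#' @param method `"sift"` (128-d gradient-histogram descriptor, Euclidean
#'   metric) or `"orb"` (256-bit rotated binary descriptor, Hamming metric).
#' @return numeric matrix, one descriptor per row.
#' @export
compute_descriptors <- function(gray, keypoints, method = c("sift", "orb")) {
  method <- match.arg(method)
  if (!nrow(keypoints)) return(matrix(0, 0, if (method == "sift") 128 else 256))
  levels <- octave_images(gray, max(keypoints$level))
  if (method == "sift") describe_gradient_hist(levels, keypoints)
  else describe_binary(levels, keypoints)
}

#' Match descriptors with kNN and the ratio test
#'
#' Brute-force k = 2 nearest-neighbour search (Euclidean for real-valued
#' descriptors, Hamming for binary) from each moving descriptor into the
#' fixed set, keeping a match when `best < ratio * second_best`.
#'
#' @param desc_fixed,desc_moving descriptor matrices (rows = keypoints).
#' @param ratio ratio-test threshold (default 0.75).
#' @param metric `"euclidean"` or `"hamming"`.
#' @param keypoints_fixed,keypoints_moving optional keypoint tables carried
#'   into the result for downstream homography estimation.
#' @return object of class `match_set`: list with `keypoints_fixed`,
#'   `keypoints_moving` and a `matches` data.frame
#'   (`index_fixed`, `index_moving`, `distance`).
#' @export
match_and_filter <- function(desc_fixed, desc_moving, ratio = 0.75,
                             metric = c("euclidean", "hamming"),
                             keypoints_fixed = NULL, keypoints_moving = NULL) {
  metric <- match.arg(metric)
  nf <- nrow(desc_fixed); nm <- nrow(desc_moving)
  if (is.null(nf) || is.null(nm) || nf < 2L || nm < 2L)
    stop("insufficient features: kNN matching needs >= 2 descriptors on each side",
         call. = FALSE)
  D <- if (metric == "euclidean") {
    d2 <- outer(rowSums(desc_fixed^2), rep(1, nm)) +
      outer(rep(1, nf), rowSums(desc_moving^2)) -
      2 * desc_fixed %*% t(desc_moving)
    sqrt(pmax(d2, 0))
  } else {
    desc_fixed %*% (1 - t(desc_moving)) + (1 - desc_fixed) %*% t(desc_moving)
  }
  best <- integer(nm); d1 <- numeric(nm); d2nd <- numeric(nm)
  for (j in seq_len(nm)) {
    o <- order(D[, j])[1:2]
    best[j] <- o[1]; d1[j] <- D[o[1], j]; d2nd[j] <- D[o[2], j]
  }
  keep <- d1 < ratio * d2nd
  matches <- data.frame(index_fixed = best[keep],
                        index_moving = which(keep),
                        distance = d1[keep])
  structure(list(keypoints_fixed = keypoints_fixed,
                 keypoints_moving = keypoints_moving,
                 matches = matches),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set: %d match(es)\n", nrow(x$matches)))
  invisible(x)
}

# normalized DLT: exact least-squares homography from >= 4 correspondences
dlt_homography <- function(src, dst) {
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    d <- sqrt(rowSums((p - rep(c0, each = nrow(p)))^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    t <- matrix(c(s, 0, 0, 0, s, 0, -s * c0[1], -s * c0[2], 1), 3, 3)
    list(p = cbind(s * (p[, 1] - c0[1]), s * (p[, 2] - c0[2])), t = t)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  n <- length(x)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  A[seq(2, 2 * n, 2), ] <- cbind(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
  sv <- svd(A, nu = 0, nv = 9)
  hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(nd$t) %*% hn %*% ns$t
  if (abs(det(h)) <= 1e-12) stop("degenerate homography", call. = FALSE)
  homography(h)
}

any_collinear <- function(p, tol = 1e-8) {
  cmb <- utils::combn(nrow(p), 3)
  for (i in seq_len(ncol(cmb))) {
    a <- p[cmb[1, i], ]; b <- p[cmb[2, i], ]; c <- p[cmb[3, i], ]
    if (abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) < tol)
      return(TRUE)
  }
  FALSE
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Robust homography estimation from matched keypoints
#'
#' RANSAC over 4-point minimal samples with a normalized-DLT solver and a
#' reprojection-distance inlier test, followed by a least-squares DLT refit
#' on the consensus set. The estimated matrix maps moving-image coordinates
#' to fixed-image coordinates.
#'
#' @param match_set a [match_set()] carrying keypoint tables, or a list with
#'   `src` and `dst` n x 2 coordinate matrices (`src` = moving, `dst` = fixed).
#' @param reproj_thresh RANSAC inlier threshold in pixels (default 5).
#' @param max_iter number of RANSAC iterations (default 2000).
#' @param seed RNG seed for the sampler (restores the caller's RNG state).
#' @return list with `homography` and logical `inliers`.
#' @export
estimate_homography <- function(match_set, reproj_thresh = 5, max_iter = 2000L,
                                seed = 0L) {
  if (inherits(match_set, "match_set")) {
    m <- match_set$matches
    src <- as.matrix(match_set$keypoints_moving[m$index_moving, c("x", "y")])
    dst <- as.matrix(match_set$keypoints_fixed[m$index_fixed, c("x", "y")])
  } else {
    src <- as.matrix(match_set$src); dst <- as.matrix(match_set$dst)
  }
  n <- nrow(src)
  if (n < 4L)
    stop(sprintf("homography estimation needs >= 4 matches (have %d)", n),
         call. = FALSE)
  best_inl <- NULL; best_count <- -1L
  with_local_seed(seed, {
    for (it in seq_len(max_iter)) {
      s <- sample.int(n, 4L)
      if (any_collinear(src[s, , drop = FALSE]) ||
          any_collinear(dst[s, , drop = FALSE])) next
      h <- tryCatch(dlt_homography(src[s, , drop = FALSE], dst[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(h)) next
      proj <- tryCatch(apply_homography(src, h), error = function(e) NULL)
      if (is.null(proj)) next
      err <- sqrt(rowSums((proj - dst)^2))
      inl <- err < reproj_thresh
      if (sum(inl) > best_count) { best_count <- sum(inl); best_inl <- inl }
    }
  })
  if (is.null(best_inl) || best_count < 4L)
    stop("RANSAC consensus failure: no homography explains >= 4 matches",
         call. = FALSE)
  # iterative least-squares refit on the consensus set until it stabilizes
  inl <- best_inl
  h <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  for (round in 1:5) {
    err <- sqrt(rowSums((apply_homography(src, h) - dst)^2))
    new_inl <- err < reproj_thresh
    if (sum(new_inl) < 4L || identical(new_inl, inl)) break
    inl <- new_inl
    h <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  }
  list(homography = h, inliers = inl)
}

#' Warp an image with a homography
#'
#' Inverse-maps every output pixel of the fixed-frame canvas through
#' `h^{-1}` and samples the input bilinearly; samples outside the input
#' return `fill`.
#'
#' @param image input (moving) image.
#' @param h [homography] mapping moving to fixed coordinates.
#' @param out_dim output `c(height, width)` (the fixed image's canvas).
#' @param fill background fill value.
#' @return warped image of size `out_dim`.
#' @export
warp_image <- function(image, h, out_dim, fill = 0) {
  hh <- out_dim[1]; ww <- out_dim[2]
  hi <- invert_homography(h)
  gx <- rep(seq_len(ww) - 1, each = hh)
  gy <- rep(seq_len(hh) - 1, times = ww)
  src <- apply_homography(cbind(gx, gy), hi)
  sample_plane <- function(m)
    matrix(bilinear_sample(m, src[, 1], src[, 2], fill = fill), hh, ww)
  if (is.matrix(image)) return(sample_plane(image))
  out <- array(0, dim = c(hh, ww, dim(image)[3]))
  for (c in seq_len(dim(image)[3])) out[, , c] <- sample_plane(image[, , c])
  out
}
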