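# Registration quality metrics reported under the plugin result's `metrics`
# key: SSD, normalized cross-correlation, mutual information, and landmark
# target registration error.

# intensities to a common [0,1] grayscale
norm_gray <- function(img) {
  g <- to_gray(img)
  if (max(g) > 1) g <- g / 255
  g
}

#' Sum of squared differences
#'
#' Intensities are normalized to `[0, 1]` internally; the sum runs over all
#' pixels. Lower is better; 0 iff the images are identical.
#'
#' @param a,b images of equal dimensions.
#' @return non-negative scalar.
#' @export
ssd <- function(a, b) {
  ga <- norm_gray(a); gb <- norm_gray(b)
  if (!all(dim(ga) == dim(gb))) stop("ssd: images must have equal shape", call. = FALSE)
  sum((ga - gb)^2)
}

#' Normalized cross-correlation
#'
#' Pearson correlation of the flattened intensities; 1 for identical images,
#' -1 for perfectly anti-correlated ones.
#'
#' @param a,b images of equal dimensions.
#' @return scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  ga <- norm_gray(a); gb <- norm_gray(b)
  if (!all(dim(ga) == dim(gb))) stop("ncc: images must have equal shape", call. = FALSE)
  if (stats::sd(ga) == 0 || stats::sd(gb) == 0)
    stop("ncc undefined for zero-variance input", call. = FALSE)
  stats::cor(as.vector(ga), as.vector(gb))
}

#' Mutual information (bits)
#'
#' Estimated from the joint intensity histogram on a `bins x bins` grid over
#' `[0, 1]`: `sum p(i,j) log2(p(i,j) / (p(i) p(j)))`, skipping empty cells.
#' `mutual_information(a, a)` equals the marginal (histogram) entropy of `a`.
#'
#' @param a,b images of equal dimensions.
#' @param bins number of histogram bins per axis (default 64).
#' @return non-negative scalar in bits.
#' @export
mutual_information <- function(a, b, bins = 64L) {
  ga <- norm_gray(a); gb <- norm_gray(b)
  if (!all(dim(ga) == dim(gb))) stop("mutual_information: equal shapes required",
                                     call. = FALSE)
  bi <- function(g) pmin(pmax(floor(as.vector(g) * bins), 0L), bins - 1L)
  ia <- bi(ga); ib <- bi(gb)
  joint <- tabulate(ia + bins * ib + 1L, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

# histogram entropy in bits, same binning as mutual_information
marginal_entropy <- function(a, bins = 64L) {
  g <- norm_gray(a)
  idx <- pmin(pmax(floor(as.vector(g) * bins), 0L), bins - 1L)
  p <- tabulate(idx + 1L, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Target registration error
#'
#' Euclidean distance between each fixed-image landmark and its moving-image
#' counterpart mapped through `h`. Besides the raw per-landmark distances,
#' distances normalized by the fixed-image diagonal are reported when
#' `fixed_dim` is supplied (the "relative" flavour).
#'
#' @param landmarks_fixed,landmarks_moving n x 2 `(x, y)` matrices, n >= 1.
#' @param h a [homography] mapping moving to fixed coordinates.
#' @param fixed_dim optional `c(height, width)` of the fixed image, enabling
#'   diagonal-normalized output.
#' @return list with `mean`, `per_landmark`, and (when `fixed_dim` is given)
#'   `mean_relative`, `per_landmark_relative`.
#' @export
tre <- function(landmarks_fixed, landmarks_moving, h, fixed_dim = NULL) {
  lf <- as.matrix(landmarks_fixed); lm <- as.matrix(landmarks_moving)
  if (nrow(lf) != nrow(lm) || nrow(lf) < 1L)
    stop("tre: landmark lists must be non-empty and of equal length", call. = FALSE)
  mapped <- apply_homography(lm, h)
  d <- sqrt(rowSums((mapped - lf)^2))
  out <- list(mean = mean(d), per_landmark = d)
  if (!is.null(fixed_dim)) {
    diag_len <- sqrt(sum(as.numeric(fixed_dim)^2))
    out$mean_relative <- out$mean / diag_len
    out$per_landmark_relative <- d / diag_len
  }
  out
}

# metrics block for a plugin result: fixed vs warped moving image
registration_metrics <- function(fixed, warped, bins = 64L) {
  list(ssd = ssd(fixed, warped),
       ncc = tryCatch(ncc(fixed, warped), error = function(e) NA_real_),
       mutual_information = mutual_information(fixed, warped, bins))
}
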