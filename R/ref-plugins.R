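# Reference registration plugins: the full feature-based chain
# (preprocess -> detect/describe -> kNN + ratio matching -> RANSAC
# homography -> warp), populating all eight result-contract keys.

plugin_option <- function(options, name, default) {
  if (!is.null(options[[name]])) options[[name]] else default
}

register_feature_based <- function(fixed, moving, options = list(),
                                   method = c("sift", "orb")) {
  method <- match.arg(method)
  opts <- list(
    modality_fixed = plugin_option(options, "modality_fixed", "generic"),
    modality_moving = plugin_option(options, "modality_moving", "generic"),
    ratio = plugin_option(options, "ratio", 0.75),
    reproj_thresh = plugin_option(options, "reproj_thresh", 5),
    seed = plugin_option(options, "seed", 0L),
    max_keypoints = plugin_option(options, "max_keypoints", 500L),
    min_matches = plugin_option(options, "min_matches", 4L),
    n_scales = plugin_option(options, "n_scales", 2L),
    max_iter = plugin_option(options, "max_iter", 2000L)
  )
  fail <- function(msg) validate_result(
    registration_result(succ = FALSE, messages = sprintf("%s: %s", method, msg)))
  gf <- preprocess_modality(fixed, opts$modality_fixed)
  gm <- preprocess_modality(moving, opts$modality_moving)
  kpf <- detect_keypoints(gf, max_keypoints = opts$max_keypoints,
                          n_scales = opts$n_scales)
  kpm <- detect_keypoints(gm, max_keypoints = opts$max_keypoints,
                          n_scales = opts$n_scales)
  if (nrow(kpf) < 2L || nrow(kpm) < 2L)
    return(fail(sprintf("insufficient features (%d fixed, %d moving keypoints)",
                        nrow(kpf), nrow(kpm))))
  df <- compute_descriptors(gf, kpf, method)
  dm <- compute_descriptors(gm, kpm, method)
  metric <- if (method == "sift") "euclidean" else "hamming"
  ms <- tryCatch(
    match_and_filter(df, dm, ratio = opts$ratio, metric = metric,
                     keypoints_fixed = kpf, keypoints_moving = kpm),
    error = function(e) NULL)
  if (is.null(ms)) return(fail("insufficient features for kNN matching"))
  if (nrow(ms$matches) < opts$min_matches)
    return(fail(sprintf("too few matches after ratio test (%d < %d)",
                        nrow(ms$matches), opts$min_matches)))
  est <- tryCatch(
    estimate_homography(ms, reproj_thresh = opts$reproj_thresh,
                        max_iter = opts$max_iter, seed = opts$seed),
    error = function(e) conditionMessage(e))
  if (is.character(est)) return(fail(est))
  h <- est$homography
  warped <- warp_image(moving, h, image_dims(fixed))
  gw <- warp_image(gm, h, image_dims(gf))
  inl <- ms$matches[est$inliers, , drop = FALSE]
  result <- registration_result(
    succ = TRUE,
    warping = warped,
    Homography = h,
    f_fix = draw_features(fixed, kpf),
    f_mov = draw_features(moving, kpm),
    line_matching = draw_matches(fixed, moving, kpf, kpm, inl),
    metrics = registration_metrics(gf, gw),
    messages = sprintf(
      "%s: %d/%d keypoints, %d ratio-test matches, %d RANSAC inliers",
      method, nrow(kpf), nrow(kpm), nrow(ms$matches), sum(est$inliers)))
  validate_result(result, annotations_present = FALSE, fixed_dim = image_dims(fixed))
}

#' Reference feature-based registration plugins
#'
#' `register_sift` uses the 128-d gradient-histogram descriptor with
#' Euclidean matching; `register_orb` uses the 256-bit rotated binary
#' descriptor with Hamming matching. Both run the full chain — modality
#' preprocessing, multi-scale oriented corner detection, brute-force kNN
#' matching with the ratio test, RANSAC + DLT homography estimation, and
#' bilinear warping onto the fixed canvas — and return a result populating
#' all eight contract keys. Any stage failure yields `succ = FALSE` with a
#' stage-specific message.
#'
#' @param fixed,moving images (matrices or `[row, col, 3]` arrays, `[0,1]`).
#' @param options named list of tunables: `modality_fixed` /
#'   `modality_moving` (`"generic"`, `"he"`, `"nlo"`), `ratio` (0.75),
#'   `reproj_thresh` (5 px), `seed` (0), `max_keypoints` (500),
#'   `min_matches` (4), `n_scales` (2), `max_iter` (2000).
#' @return a validated `registration_result`.
#' @export
register_sift <- function(fixed, moving, options = list())
  register_feature_based(fixed, moving, options, "sift")

#' @rdname register_sift
#' @export
register_orb <- function(fixed, moving, options = list())
  register_feature_based(fixed, moving, options, "orb")

# ---- user-facing modelling interface ----

#' Register a moving image onto a fixed image
#'
#' High-level front end over the reference plugins, returning a classed
#' object with the usual estimator methods: `coef()` gives the 3x3
#' homography matrix, `predict()` maps moving-frame points (or annotation
#' sets) into the fixed frame, `plot()` draws the chessboard QC composite,
#' `summary()` reports match statistics and registration metrics.
#'
#' @param fixed,moving images in `[0, 1]`.
#' @param method `"sift"` or `"orb"`.
#' @param ... options passed to the plugin (see [register_sift()]).
#' @return object of class `histreg_registration`.
#' @export
register_pair <- function(fixed, moving, method = c("sift", "orb"), ...) {
  method <- match.arg(method)
  opts <- list(...)
  res <- register_feature_based(fixed, moving, opts, method)
  structure(list(result = res, method = method, fixed = fixed, moving = moving,
                 call = match.call()),
            class = "histreg_registration")
}

#' @export
print.histreg_registration <- function(x, ...) {
  cat(sprintf("Feature-based registration (%s)\n", x$method))
  cat(sprintf("  success: %s\n", x$result$succ))
  if (!is.null(x$result$Homography)) {
    cat("  homography (moving -> fixed):\n")
    print(round(x$result$Homography$m, 5))
  }
  if (length(x$result$messages))
    cat("  ", paste(x$result$messages, collapse = "\n   "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.histreg_registration <- function(object, ...) {
  print(object)
  if (!is.null(object$result$metrics)) {
    cat("  metrics (preprocessed fixed vs warped moving):\n")
    m <- object$result$metrics
    for (k in names(m)) cat(sprintf("    %-20s %.6g\n", k, m[[k]]))
  }
  invisible(object)
}

#' @export
coef.histreg_registration <- function(object, ...) {
  if (is.null(object$result$Homography)) return(NULL)
  object$result$Homography$m
}

#' Map moving-frame points or annotations into the fixed frame
#'
#' @param object a fitted `histreg_registration`.
#' @param newdata n x 2 point matrix or a [coco_set].
#' @param ... unused.
#' @return transformed points or annotation set.
#' @export
predict.histreg_registration <- function(object, newdata, ...) {
  h <- object$result$Homography
  if (is.null(h)) stop("registration failed; no homography available", call. = FALSE)
  if (inherits(newdata, "coco_set")) {
    d <- image_dims(object$fixed)
    transform_annotation_set(newdata, h,
                             list(id = 1L, file_name = "fixed",
                                  width = d[2], height = d[1]))
  } else {
    apply_homography(newdata, h)
  }
}

#' @export
plot.histreg_registration <- function(x, n = 4L, ...) {
  if (!isTRUE(x$result$succ)) stop("nothing to plot: registration failed", call. = FALSE)
  comp <- chessboard(as_rgb(x$fixed), as_rgb(x$result$warping), n = n)
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(clamp01(comp)), 0, 0, 1, 1)
  invisible(x)
}
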