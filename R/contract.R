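# The plugin result contract: every registration plugin returns a result
# with exactly eight possible keys — succ, warping, Homography, f_mov,
# f_fix, line_matching, metrics, messages — of which succ and warping are
# mandatory; Homography becomes mandatory when the project carries
# annotations (it is what transfers them between frames).

RESULT_KEYS <- c("succ", "warping", "Homography", "f_mov", "f_fix",
                 "line_matching", "metrics", "messages")

#' Construct a plugin registration result
#'
#' Convenience constructor filling unused optional keys with `NULL`.
#'
#' @param succ logical success flag.
#' @param warping warped moving image in the fixed frame (required when
#'   `succ` is `TRUE`).
#' @param Homography optional [homography] (moving to fixed).
#' @param f_mov,f_fix optional keypoint-overlay diagnostic images.
#' @param line_matching optional match-visualization image.
#' @param metrics optional named list of metric values.
#' @param messages character vector of log/error messages.
#' @return list with the eight contract keys (unvalidated; see
#'   [validate_result()]).
#' @export
registration_result <- function(succ, warping = NULL, Homography = NULL,
                                f_mov = NULL, f_fix = NULL, line_matching = NULL,
                                metrics = NULL, messages = character()) {
  list(succ = succ, warping = warping, Homography = Homography,
       f_mov = f_mov, f_fix = f_fix, line_matching = line_matching,
       metrics = metrics, messages = messages)
}

is_image_like <- function(x) is.numeric(x) && length(dim(x)) %in% c(2L, 3L)

#' Validate a candidate plugin result against the contract
#'
#' Enforces the eight-key contract: unknown keys are rejected; `succ` and
#' `warping` are mandatory (`warping` must be present, image-like, and —
#' when `fixed_dim` is supplied — of the fixed image's height and width
#' whenever `succ` is `TRUE`); a failed result must carry at least one
#' message; and when the project includes annotations a successful result
#' must provide an invertible 3x3 `Homography`.
#'
#' @param result named list produced by a plugin.
#' @param annotations_present does the project carry annotations?
#' @param fixed_dim optional `c(height, width)` of the fixed image for the
#'   shape check.
#' @return the validated result, classed `registration_result`.
#' @export
validate_result <- function(result, annotations_present = FALSE, fixed_dim = NULL) {
  if (!is.list(result) || is.null(names(result)))
    stop("plugin result must be a named list", call. = FALSE)
  unknown <- setdiff(names(result), RESULT_KEYS)
  if (length(unknown))
    stop(sprintf("plugin result contains unknown key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!"succ" %in% names(result) || !is.logical(result$succ) ||
      length(result$succ) != 1L || is.na(result$succ))
    stop("plugin result must contain a scalar logical 'succ'", call. = FALSE)
  if (isTRUE(result$succ)) {
    if (!"warping" %in% names(result) || !is_image_like(result$warping))
      stop("mandatory key 'warping' must carry the warped image on success",
           call. = FALSE)
    if (!is.null(fixed_dim) && !all(dim(result$warping)[1:2] == fixed_dim[1:2]))
      stop(sprintf(
        "warped image shape %s does not match the fixed image %s",
        paste(dim(result$warping)[1:2], collapse = "x"),
        paste(fixed_dim[1:2], collapse = "x")), call. = FALSE)
    if (annotations_present) {
      hm <- result$Homography
      ok <- is_homography(hm) ||
        (is.numeric(hm) && !is.null(dim(hm)) && all(dim(hm) == c(3L, 3L)) &&
           abs(det(hm)) > 1e-12)
      if (!ok)
        stop("project includes annotations: a valid invertible 3x3 'Homography' is mandatory",
             call. = FALSE)
      if (!is_homography(hm)) result$Homography <- homography(hm)
    }
  } else {
    msgs <- result$messages
    if (is.null(msgs) || !length(msgs) || !any(nzchar(msgs)))
      stop("failed result (succ = FALSE) must carry at least one message",
           call. = FALSE)
  }
  for (k in setdiff(RESULT_KEYS, names(result))) result[[k]] <- NULL
  out <- result[RESULT_KEYS]
  names(out) <- RESULT_KEYS
  class(out) <- "registration_result"
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: succ = %s\n", x$succ))
  if (!is.null(x$Homography)) {
    cat("  homography:\n")
    print(round(x$Homography$m, 5))
  }
  if (!is.null(x$metrics)) {
    cat("  metrics:", paste(sprintf("%s = %.5g", names(x$metrics),
                                    unlist(x$metrics)), collapse = ", "), "\n")
  }
  if (length(x$messages)) cat("  messages:", paste(x$messages, collapse = " | "), "\n")
  invisible(x)
}
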