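# Orchestration: run plugins over image pairs, validate results against the
# contract, and persist everything under results/<plugin>/<pair>/.

write_optional_image <- function(img, path) {
  if (!is.null(img)) write_image(clamp01(img), path)
}

persist_result <- function(result, out_dir, fixed, moving, annotations = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(result$succ)) write_image(clamp01(result$warping),
                                       file.path(out_dir, "warped.png"))
  if (!is.null(result$Homography))
    write_homography(result$Homography, file.path(out_dir, "homography.json"))
  write_optional_image(result$f_fix, file.path(out_dir, "f_fix.png"))
  write_optional_image(result$f_mov, file.path(out_dir, "f_mov.png"))
  write_optional_image(result$line_matching, file.path(out_dir, "line_matching.png"))
  if (!is.null(result$metrics))
    jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  writeLines(as.character(result$messages), file.path(out_dir, "messages.txt"))
  if (!is.null(annotations) && !is.null(result$Homography) && isTRUE(result$succ)) {
    d <- image_dims(fixed)
    transferred <- transform_annotation_set(
      annotations, result$Homography,
      list(id = 1L, file_name = "fixed", width = d[2], height = d[1]))
    write_coco(transferred, file.path(out_dir, "annotations_transformed.json"))
  }
  invisible(out_dir)
}

#' Execute one plugin on one image pair and persist the result
#'
#' The plugin is called with the decoded full-resolution images (source
#' paths are passed through in `options`); exceptions are captured and
#' converted into a `succ = FALSE` result carrying the exception text, and
#' contract violations are recorded as failures — a misbehaving plugin
#' never aborts the surrounding run. Validated results are written under
#' `<results_dir>/<plugin>/<pair_id>/` (warped image, homography JSON,
#' diagnostic images, metrics JSON, messages, transferred annotations) and
#' the QC views under `views/`, each optionally pyramid-tiled.
#'
#' @param fixed_path,moving_path image file paths.
#' @param plugin a plugin descriptor from [discover_plugins()].
#' @param results_dir root results directory.
#' @param pair_id identifier used for the result folder.
#' @param annotations optional [coco_set] attached to the moving image.
#' @param options named list forwarded to the plugin.
#' @param views render and save the QC views (default TRUE).
#' @param pyramids additionally pyramid-tile every view (default FALSE).
#' @param tile_size tile size for view pyramids.
#' @return invisibly, a list with `result`, `dir`, `succ`, `contract_failure`.
#' @export
execute_pair <- function(fixed_path, moving_path, plugin, results_dir,
                         pair_id = NULL, annotations = NULL, options = list(),
                         views = TRUE, pyramids = FALSE, tile_size = 1024L) {
  if (is.null(pair_id))
    pair_id <- tools::file_path_sans_ext(basename(fixed_path))
  fixed <- read_image(fixed_path)
  moving <- read_image(moving_path)
  options$fixed_path <- fixed_path
  options$moving_path <- moving_path
  raw <- tryCatch(plugin$entry(fixed, moving, options), error = function(e)
    registration_result(succ = FALSE,
                        messages = sprintf("plugin '%s' raised: %s", plugin$name,
                                           conditionMessage(e))))
  contract_failure <- FALSE
  result <- tryCatch(
    validate_result(raw, annotations_present = !is.null(annotations),
                    fixed_dim = image_dims(fixed)),
    error = function(e) {
      contract_failure <<- TRUE
      validate_result(registration_result(
        succ = FALSE,
        messages = sprintf("contract violation in plugin '%s': %s", plugin$name,
                           conditionMessage(e))))
    })
  out_dir <- file.path(results_dir, plugin$name, pair_id)
  persist_result(result, out_dir, fixed, moving, annotations)
  if (views) {
    v <- render_views(fixed, moving, result, annotations)
    vdir <- file.path(out_dir, "views")
    dir.create(vdir, showWarnings = FALSE)
    for (nm in names(v)) {
      write_image(clamp01(v[[nm]]), file.path(vdir, paste0(nm, ".png")))
      if (pyramids)
        build_pyramid(v[[nm]], file.path(vdir, paste0(nm, "_files")),
                      tile_size = tile_size)
    }
  }
  invisible(list(result = result, dir = out_dir, succ = isTRUE(result$succ),
                 contract_failure = contract_failure))
}

#' Execute every (pair x plugin) combination of a project
#'
#' @param project a `histreg_project` (see [create_project()]).
#' @param registry a `plugin_registry`; defaults to the shipped plugins.
#' @param options named list forwarded to every plugin call.
#' @param views,pyramids,tile_size see [execute_pair()].
#' @return summary data.frame with one row per (plugin, pair): columns
#'   `plugin`, `pair_id`, `succ`, `seconds`.
#' @export
execute_project <- function(project, registry = discover_plugins(),
                            options = list(), views = TRUE, pyramids = FALSE,
                            tile_size = 1024L) {
  stopifnot(inherits(project, "histreg_project"))
  if (!length(project$plugins))
    stop("project has no plugins configured", call. = FALSE)
  missing <- setdiff(project$plugins, names(registry))
  if (length(missing))
    stop(sprintf("plugin(s) not found in registry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  results_dir <- file.path(project$dir, "results")
  log_path <- file.path(results_dir, "run.log")
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  cat("", file = log_path)  # one log per run
  rows <- list()
  for (pname in project$plugins) {
    plugin <- registry[[pname]]
    for (i in seq_len(nrow(project$pairs))) {
      pr <- project$pairs[i, ]
      anns <- project_pair_annotations(project, pr$pair_id)
      t0 <- proc.time()[["elapsed"]]
      ex <- execute_pair(pr$fixed, pr$moving, plugin, results_dir,
                         pair_id = pr$pair_id, annotations = anns,
                         options = options, views = views, pyramids = pyramids,
                         tile_size = tile_size)
      el <- proc.time()[["elapsed"]] - t0
      cat(sprintf("[%s] %s / %s: succ=%s (%.2fs) %s\n",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), pname, pr$pair_id,
                  ex$succ, el, paste(ex$result$messages, collapse = " | ")),
          file = log_path, append = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        plugin = pname, pair_id = pr$pair_id, succ = ex$succ, seconds = el,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  attr(summary, "per_plugin") <- stats::aggregate(succ ~ plugin, summary,
                                                  function(s) sum(s))
  summary
}
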