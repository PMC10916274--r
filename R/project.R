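# Project model: plain directory-tree persistence (project.json + copied
# images + pyramids + COCO annotations + results), batch pairing by sorted
# file names, and export of the results tree.

IMAGE_EXT <- c("png", "tif", "tiff", "jpg", "jpeg")

list_image_files <- function(dir) {
  f <- list.files(dir, full.names = TRUE)
  f[tolower(tools::file_ext(f)) %in% IMAGE_EXT]
}

#' Pair fixed and moving image folders for a batch project
#'
#' Files in each directory are sorted by file name (case-insensitive
#' lexicographic, or numeric-aware with `numeric_sort`) and paired
#' positionally; the pair id is the fixed file's stem. Both folders must
#' contain exactly the same number of images.
#'
#' @param fixed_dir,moving_dir directories of images.
#' @param numeric_sort sort by the first integer embedded in each name,
#'   falling back to lexicographic order.
#' @return data.frame with columns `pair_id`, `fixed`, `moving`.
#' @export
pair_batch <- function(fixed_dir, moving_dir, numeric_sort = FALSE) {
  for (d in c(fixed_dir, moving_dir))
    if (!dir.exists(d)) stop(sprintf("directory does not exist: %s", d), call. = FALSE)
  sort_files <- function(files) {
    key <- tolower(basename(files))
    if (numeric_sort) {
      num <- suppressWarnings(as.numeric(gsub("\\D", "", key)))
      files[order(is.na(num), num, key)]
    } else files[order(key, method = "radix")]
  }
  ff <- list_image_files(fixed_dir)
  mf <- list_image_files(moving_dir)
  if (!length(ff) || !length(mf))
    stop("both folders must contain at least one image", call. = FALSE)
  if (length(ff) != length(mf))
    stop(sprintf(
      "the size of both folders must be exactly the same (%d fixed vs %d moving)",
      length(ff), length(mf)), call. = FALSE)
  ff <- sort_files(ff); mf <- sort_files(mf)
  data.frame(pair_id = tools::file_path_sans_ext(basename(ff)),
             fixed = ff, moving = mf, stringsAsFactors = FALSE)
}

project_path <- function(workspace, name) file.path(workspace, name)

write_project_json <- function(project) {
  obj <- list(
    name = project$name,
    project_type = project$project_type,
    pairs = lapply(seq_len(nrow(project$pairs)), function(i) {
      r <- project$pairs[i, ]
      list(pair_id = r$pair_id, fixed = r$fixed, moving = r$moving)
    }),
    plugins = project$plugins,
    annotations = project$annotations,
    created = project$created)
  jsonlite::write_json(obj, file.path(project$dir, "project.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(project)
}

#' Load a project from its workspace
#'
#' @param name project name.
#' @param workspace workspace directory.
#' @return a `histreg_project`.
#' @export
load_project <- function(name, workspace) {
  dir <- project_path(workspace, name)
  jp <- file.path(dir, "project.json")
  if (!file.exists(jp))
    stop(sprintf("no project '%s' in workspace %s", name, workspace), call. = FALSE)
  obj <- jsonlite::read_json(jp, simplifyVector = FALSE)
  pairs <- do.call(rbind, lapply(obj$pairs, function(p)
    data.frame(pair_id = p$pair_id, fixed = p$fixed, moving = p$moving,
               stringsAsFactors = FALSE)))
  structure(list(name = obj$name, project_type = obj$project_type, pairs = pairs,
                 plugins = unlist(obj$plugins), annotations = obj$annotations,
                 created = obj$created, dir = dir),
            class = "histreg_project")
}

#' @export
print.histreg_project <- function(x, ...) {
  cat(sprintf("histreg_project '%s' (%s): %d pair(s), plugins: %s\n",
              x$name, x$project_type, nrow(x$pairs),
              paste(x$plugins, collapse = ", ")))
  invisible(x)
}

# read the stored COCO annotations for one pair (NULL when absent)
project_pair_annotations <- function(project, pair_id) {
  p <- file.path(project$dir, "annotations", paste0(pair_id, ".json"))
  if (file.exists(p)) read_coco(p) else NULL
}

convert_annotation_source <- function(path, format, moving_path, spec = NULL) {
  img <- read_image(moving_path)
  d <- image_dims(img)
  stack <- switch(format,
    coco = return(read_coco(path)),
    mask_image = load_mask_image(path, spec),
    npz = load_mask_array(path),
    stop(sprintf("unknown annotation format '%s' (coco/mask_image/npz)", format),
         call. = FALSE))
  masks_to_coco(stack, image_id = 1L, file_name = basename(moving_path))
}

#' Create a project on disk
#'
#' Writes `project.json`, copies the input images into the project tree,
#' builds a multiresolution pyramid for every input image, and converts any
#' annotation source to COCO (stored per pair under `annotations/`).
#' Annotations attach to the moving image: for a single-pair project the
#' source is one file; for a batch project it is a directory whose files
#' are matched to moving images by stem.
#'
#' @param name unique project name within the workspace.
#' @param workspace workspace directory (created if needed).
#' @param fixed,moving single-pair mode: one image path each; batch mode:
#'   two directories.
#' @param plugins non-empty character vector of plugin names to run.
#' @param project_type `"single"` or `"batch"`.
#' @param annotations optional `list(path =, format =)` with format one of
#'   `"coco"`, `"mask_image"`, `"npz"`.
#' @param spec optional [class_spec] for `mask_image` sources.
#' @param build_pyramids build input pyramids now (default TRUE).
#' @param tile_size pyramid tile size.
#' @param numeric_sort numeric-aware batch pairing (see [pair_batch()]).
#' @return the created `histreg_project`.
#' @export
create_project <- function(name, workspace, fixed, moving, plugins,
                           project_type = c("single", "batch"),
                           annotations = NULL, spec = NULL,
                           build_pyramids = TRUE, tile_size = 1024L,
                           numeric_sort = FALSE) {
  project_type <- match.arg(project_type)
  if (missing(plugins) || !length(plugins) || !all(nzchar(plugins)))
    stop("a non-empty plugin list is required", call. = FALSE)
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  dir <- project_path(workspace, name)
  if (dir.exists(dir))
    stop(sprintf("project '%s' already exists in %s", name, workspace), call. = FALSE)
  pairs <- if (project_type == "batch") {
    pair_batch(fixed, moving, numeric_sort = numeric_sort)
  } else {
    for (f in c(fixed, moving)) if (!file.exists(f))
      stop(sprintf("image does not exist: %s", f), call. = FALSE)
    if (identical(normalizePath(fixed), normalizePath(moving)))
      stop("fixed and moving paths must be distinct", call. = FALSE)
    data.frame(pair_id = tools::file_path_sans_ext(basename(fixed)),
               fixed = fixed, moving = moving, stringsAsFactors = FALSE)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE)
  stored <- pairs
  for (i in seq_len(nrow(pairs))) {
    for (side in c("fixed", "moving")) {
      src <- pairs[[side]][i]
      dst <- file.path(dir, "images",
                       paste0(pairs$pair_id[i], "_", side, ".",
                              tolower(tools::file_ext(src))))
      if (!file.copy(src, dst))
        stop(sprintf("cannot copy image: %s", src), call. = FALSE)
      stored[[side]][i] <- dst
      if (build_pyramids)
        build_pyramid(read_image(dst),
                      file.path(dir, "images",
                                paste0(tools::file_path_sans_ext(basename(dst)),
                                       "_files")),
                      tile_size = tile_size)
    }
  }
  ann_meta <- NULL
  if (!is.null(annotations)) {
    stopifnot(is.list(annotations), !is.null(annotations$path),
              !is.null(annotations$format))
    dir.create(file.path(dir, "annotations"))
    if (project_type == "single") {
      aset <- convert_annotation_source(annotations$path, annotations$format,
                                        stored$moving[1], spec)
      write_coco(aset, file.path(dir, "annotations",
                                 paste0(stored$pair_id[1], ".json")))
    } else {
      # batch: one annotation file per moving image, matched by stem
      afiles <- list.files(annotations$path, full.names = TRUE)
      astems <- tools::file_path_sans_ext(basename(afiles))
      mstems <- tools::file_path_sans_ext(basename(pairs$moving))
      for (i in seq_len(nrow(pairs))) {
        hit <- which(astems == mstems[i])
        if (!length(hit)) next
        aset <- convert_annotation_source(afiles[hit[1]], annotations$format,
                                          stored$moving[i], spec)
        write_coco(aset, file.path(dir, "annotations",
                                   paste0(stored$pair_id[i], ".json")))
      }
    }
    ann_meta <- list(path = annotations$path, format = annotations$format)
  }
  project <- structure(
    list(name = name, project_type = project_type, pairs = stored,
         plugins = as.character(plugins), annotations = ann_meta,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), dir = dir),
    class = "histreg_project")
  write_project_json(project)
  project
}

#' Run all algorithms of a project
#'
#' Discovers plugins and delegates to [execute_project()].
#'
#' @param name project name.
#' @param workspace workspace directory.
#' @param plugin_dir plugin directory (defaults to the shipped plugins).
#' @param options,views,pyramids,tile_size see [execute_project()].
#' @return the run summary data.frame.
#' @export
run_project <- function(name, workspace, plugin_dir = default_plugin_dir(),
                        options = list(), views = TRUE, pyramids = FALSE,
                        tile_size = 1024L) {
  project <- load_project(name, workspace)
  registry <- discover_plugins(plugin_dir)
  execute_project(project, registry, options = options, views = views,
                  pyramids = pyramids, tile_size = tile_size)
}

#' Export a project's results as a zip archive
#'
#' Packs the results tree (deterministically ordered, fixed timestamps, so
#' re-exporting unchanged results is byte-identical) into `out_archive`.
#'
#' @param name project name.
#' @param workspace workspace directory.
#' @param out_archive output `.zip` path.
#' @return `out_archive`, invisibly.
#' @export
export_project <- function(name, workspace, out_archive) {
  project <- load_project(name, workspace)
  rdir <- file.path(project$dir, "results")
  files <- sort(list.files(rdir, recursive = TRUE, full.names = FALSE))
  files <- files[files != "run.log"]  # timing log is not a result artifact
  if (!length(files))
    stop(sprintf("no results for project '%s'; run it first", name), call. = FALSE)
  entries <- lapply(files, function(f) {
    p <- file.path(rdir, f)
    readBin(p, "raw", n = file.size(p))
  })
  names(entries) <- file.path("results", files)
  zip_write(out_archive, entries)
  invisible(out_archive)
}

#' List / delete projects in a workspace
#'
#' @param workspace workspace directory.
#' @return `list_projects` returns a character vector of project names.
#' @export
list_projects <- function(workspace) {
  if (!dir.exists(workspace)) return(character())
  dirs <- list.dirs(workspace, recursive = FALSE)
  basename(dirs)[file.exists(file.path(dirs, "project.json"))]
}

#' @rdname list_projects
#' @param name project name to delete.
#' @export
delete_project <- function(name, workspace) {
  dir <- project_path(workspace, name)
  if (!file.exists(file.path(dir, "project.json")))
    stop(sprintf("no project '%s' in workspace %s", name, workspace), call. = FALSE)
  unlink(dir, recursive = TRUE)
  invisible(name)
}
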