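# Plugin discovery and registry.
#
# A plugin is a single R source file in the plugin directory that defines
# two objects when evaluated: `plugin_name` (unique character scalar) and
# `plugin_entry` (a function(fixed, moving, options) returning a result
# honouring the eight-key contract). Discovery scans the directory once at
# engine start; malformed files are skipped with a warning, never aborting
# the scan.

plugin_descriptor <- function(name, entry, source_path) {
  structure(list(name = name, entry = entry, source_path = source_path),
            class = "plugin_descriptor")
}

#' Discover registration plugins in a directory
#'
#' Each `.R` file is evaluated in its own environment (with access to the
#' package namespace) and must define `plugin_name` and `plugin_entry`.
#' Files that fail to evaluate or violate the plugin shape are skipped with
#' a warning. Duplicate plugin names keep the first occurrence.
#'
#' @param plugin_dir directory to scan; defaults to the plugins shipped with
#'   the package (`sift_flann`, `orb_flann`).
#' @return a named list of plugin descriptors, classed `plugin_registry`.
#' @export
discover_plugins <- function(plugin_dir = default_plugin_dir()) {
  if (!dir.exists(plugin_dir))
    stop(sprintf("plugin directory does not exist: %s", plugin_dir), call. = FALSE)
  files <- sort(list.files(plugin_dir, pattern = "\\.[rR]$", full.names = TRUE))
  registry <- list()
  for (f in files) {
    desc <- tryCatch({
      env <- new.env(parent = asNamespace("histreg"))
      sys.source(f, envir = env)
      name <- get0("plugin_name", envir = env, inherits = FALSE)
      entry <- get0("plugin_entry", envir = env, inherits = FALSE)
      if (!is.character(name) || length(name) != 1L || !nzchar(name))
        stop("plugin_name must be a non-empty character scalar")
      if (!is.function(entry) || length(formals(entry)) < 3L)
        stop("plugin_entry must be a function(fixed, moving, options)")
      plugin_descriptor(name, entry, f)
    }, error = function(e) {
      warning(sprintf("skipping malformed plugin file '%s': %s",
                      basename(f), conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(desc)) next
    if (desc$name %in% names(registry)) {
      warning(sprintf("duplicate plugin name '%s' in '%s'; keeping first",
                      desc$name, basename(f)), call. = FALSE)
      next
    }
    registry[[desc$name]] <- desc
  }
  structure(registry, class = "plugin_registry")
}

#' @export
print.plugin_registry <- function(x, ...) {
  cat(sprintf("plugin_registry: %d plugin(s)\n", length(x)))
  for (p in x) cat(sprintf("  %-12s %s\n", p$name, p$source_path))
  invisible(x)
}

#' Directory of the plugins shipped with the package
#' @return path to the installed plugin directory.
#' @export
default_plugin_dir <- function() system.file("plugins", package = "histreg")
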