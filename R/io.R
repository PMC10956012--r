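#' Read and write the Mueller image RDS dialect
#'
#' The on-disk dialect for Mueller images is a single RDS file holding a
#' `mueller_image` object (element array, validity mask, metadata). Reading
#' validates the class and invariants; write-then-read is the identity.
#'
#' @param path file path.
#' @return a `mueller_image`.
#' @export
read_mueller <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- readRDS(path)
  if (!inherits(obj, "mueller_image"))
    stopf("%s does not hold a mueller_image", path)
  d <- dim(obj$elements)
  if (length(d) != 4L || d[3] != 4L || d[4] != 4L)
    stopf("%s: element array has wrong shape", path)
  obj
}

#' @rdname read_mueller
#' @param image a `mueller_image` to write.
#' @export
write_mueller <- function(image, path) {
  stopifnot(inherits(image, "mueller_image"))
  saveRDS(image, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' CSV with required columns `roi_id`, `patient_id`, `group`, `path`
#' (paths resolved relative to the manifest's directory when not absolute).
#'
#' @param path manifest CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("no such manifest: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "patient_id", "group", "path")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stopf("manifest %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(m) == 0) stopf("no ROIs in manifest %s", path)
  if (anyDuplicated(m$roi_id)) stopf("duplicate roi_id in manifest")
  for (col in grep("path$", names(m), value = TRUE)) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(dirname(path), m[[col]][rel])
  }
  m
}

.config_defaults <- function() {
  list(
    preprocessing = list(sigma_px = 1.0, cloude = TRUE, eig_floor = 0),
    pbp = list(selection = NULL),  # NULL = full default registry
    superpixel = list(k = 1024, seed = 0, batch_size = 4096, n_init = 10,
                      max_iter = 300, tol = 1e-3, reassignment_ratio = 0.01),
    atlas = list(n_neighbors = 30, metric = "canberra", nx = 200, ny = 200,
                 cutoff = 11, n_clusters = NULL, spread_k = 7,
                 min_frac = 0.05, min_dist = 0.1, n_epochs = 1000, seed = 0,
                 features = NULL),
    markers = list(contrasts = list())
  )
}

#' Build a pipeline configuration
#'
#' Returns the default configuration -- whose numeric defaults are the
#' study-standard parameters (1024 super-pixels, 30 neighbours, Canberra
#' metric, 200 x 200 density grid, cut-off 11) -- with the supplied
#' overrides merged in. Unknown sections or keys are rejected.
#'
#' @param ... named overrides, e.g. `superpixel = list(k = 256)`.
#' @return nested configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stopf("unknown config section '%s'", sec)
    unknown <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
    if (length(unknown))
      stopf("unknown key(s) in config section '%s': %s", sec,
            paste(unknown, collapse = ", "))
    for (key in names(over[[sec]])) cfg[[sec]][key] <- over[[sec]][key]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read and write pipeline configurations as JSON
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # normalize contrasts back to a list of length-2 character vectors
  ct <- raw$markers$contrasts
  if (!is.null(ct)) {
    raw$markers$contrasts <-
      if (is.matrix(ct)) lapply(seq_len(nrow(ct)), function(i) as.character(ct[i, ]))
      else if (is.character(ct)) list(ct)
      else lapply(ct, as.character)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config` to serialize.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}
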