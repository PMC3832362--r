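# Readers and writers: multi-page TIFF events with a CSV manifest, feature
# tables, and JSON configs/summaries.

#' Write events as multi-page TIFFs with a CSV manifest
#'
#' One 32-bit float TIFF per event (one page per channel) plus a manifest
#' recording file, class label, channel names, pixel size and seed.
#'
#' @param events list of `image_event` objects.
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth table supplying class labels.
#' @return path of the manifest CSV, invisibly.
#' @export
write_events <- function(events, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(events)
  files <- sprintf("event_%05d.tif", seq_len(n))
  for (i in seq_len(n)) {
    ev <- events[[i]]
    tiff::writeTIFF(ev$channels, file.path(dir, files[i]),
                    bits.per.sample = 32)
  }
  manifest <- data.frame(
    event_id = seq_len(n), file = files,
    class = if (!is.null(truth)) truth$class else NA_character_,
    channels = vapply(events, function(e)
      paste(names(e$channels), collapse = ";"), character(1)),
    pixel_size_um = vapply(events, function(e) e$pixel_size_um, numeric(1)),
    seed = vapply(events, function(e) e$seed, integer(1)))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read events from a manifest CSV
#'
#' Loads each referenced multi-page TIFF, mapping pages to the channel
#' names recorded in the manifest. A missing or unreadable file is recorded
#' per row and loading continues.
#'
#' @param manifest_path path to a manifest CSV written by [write_events()].
#' @return list with `events` (successfully loaded `image_event` objects)
#'   and `errors` (`data.frame` of `event_id`, `file`, `message`; zero rows
#'   when all loads succeed).
#' @export
read_events <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- tryCatch(
    utils::read.csv(manifest_path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed manifest CSV: ", conditionMessage(e)))
  need <- c("event_id", "file", "channels", "pixel_size_um", "seed")
  miss <- setdiff(need, colnames(manifest))
  if (length(miss))
    stop("malformed manifest (line 1): missing column ",
         paste(miss, collapse = ", "))
  dir <- dirname(manifest_path)
  events <- list()
  errs <- list()
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    chs <- strsplit(manifest$channels[i], ";", fixed = TRUE)[[1]]
    res <- tryCatch({
      pages <- tiff::readTIFF(path, all = TRUE)
      if (length(pages) != length(chs))
        stop("expected ", length(chs), " pages, found ", length(pages))
      names(pages) <- chs
      structure(list(channels = pages,
                     pixel_size_um = manifest$pixel_size_um[i],
                     crop_px = nrow(pages[[1]]),
                     seed = as.integer(manifest$seed[i]),
                     params = NULL),
                class = "image_event")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1]] <- data.frame(
        event_id = manifest$event_id[i], file = manifest$file[i],
        message = conditionMessage(res))
    } else {
      events[[length(events) + 1]] <- res
    }
  }
  list(events = events,
       errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(event_id = integer(), file = character(),
                    message = character()))
}

#' Write a feature table with its metric-parameter sidecar
#'
#' @param features feature table from [featurize_events()].
#' @param path CSV output path; a JSON sidecar `<path>.params.json` records
#'   the fixed metric parameters (gray levels, co-occurrence offset,
#'   boundary angles, skeleton pruning fractions).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  params <- list(texture_levels = 16, cooccurrence_offset_px = 1,
                 boundary_angles = 256, branch_prune_frac = 0.10,
                 terminal_exclude_frac = 0.10, min_mask_area_px = MIN_MASK_AREA_PX)
  jsonlite::write_json(params, paste0(path, ".params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write / read a gating configuration as JSON
#' @param config a `gating_config`.
#' @param path JSON file path.
#' @return `path` (write) or a `gating_config` (read).
#' @export
write_gating_config <- function(config, path) {
  stopifnot(inherits(config, "gating_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gating_config
#' @export
read_gating_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gate_order <- as.character(x$gate_order)
  structure(x, class = "gating_config")
}
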