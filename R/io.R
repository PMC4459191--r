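## File bindings: 16-bit grayscale TIFF (12-bit counts in the low bits),
## 8-bit PNG, targets as CSV/JSON, run logs as JSON-lines, configuration
## and thresholds as YAML.

#' Read and write grayscale images
#'
#' Images are plain numeric matrices of raw counts. TIFFs are written as
#' 16-bit single-channel with the counts in the low bits (so 12-bit data
#' round-trips exactly); PNGs as 8-bit. `readGrayImage` dispatches on the
#' file extension and returns counts.
#'
#' @param image Numeric matrix of counts.
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @return `readGrayImage`: numeric matrix; writers return `path`
#'   invisibly.
#' @export
writeGrayImage <- function(image, path) {
  assertImage(image)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    if (max(image) > 255)
      stopIO("PNG output is 8-bit; counts exceed 255 in %s", path)
    png::writePNG(image / 255, path)
  } else stopIO("unsupported image extension '%s'", ext)
  invisible(path)
}

#' @rdname writeGrayImage
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stopIO("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "double"
    m
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * 255)
  } else stopIO("unsupported image extension '%s'", ext)
}

#' Write / read a target table
#'
#' CSV columns: `id, row_px, col_px, x_um, y_um, rake_line_index, status`
#' (0-based pixel coordinates). The JSON form carries the same records.
#'
#' @param targets Target `data.frame`.
#' @param path Output path (`.csv` or `.json`).
#' @return Readers return the `data.frame`; writers return `path`
#'   invisibly.
#' @export
writeTargets <- function(targets, path) {
  ext <- tolower(tools::file_ext(path))
  cols <- c("id", "row_px", "col_px", "x_um", "y_um", "rake_line_index",
            "status")
  out <- targets[, cols]
  if (ext == "csv") write.csv(out, path, row.names = FALSE)
  else if (ext == "json")
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  else stopIO("unsupported targets extension '%s'", ext)
  invisible(path)
}

#' @rdname writeTargets
#' @export
readTargets <- function(path) {
  if (!file.exists(path)) stopIO("targets file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") read.csv(path, stringsAsFactors = FALSE)
  else if (ext == "json") {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) emptyTargets() else as.data.frame(df)
  }
  else stopIO("unsupported targets extension '%s'", ext)
}

#' Write / read ground truth
#'
#' The per-cell table goes to JSON, the label image to a 16-bit TIFF.
#'
#' @param truth A [GroundTruth-class].
#' @param json_path,label_path Output paths.
#' @return `readGroundTruth` returns the [GroundTruth-class]; the writer
#'   returns the paths invisibly.
#' @export
writeGroundTruth <- function(truth, json_path, label_path) {
  jsonlite::write_json(truthCells(truth), json_path, dataframe = "rows",
                       digits = NA)
  writeGrayImage(labelImage(truth), label_path)
  invisible(c(json_path, label_path))
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(json_path, label_path) {
  cells <- jsonlite::fromJSON(json_path)
  if (length(cells) == 0L)
    cells <- data.frame(label = integer(0), row_px = numeric(0),
                        col_px = numeric(0), radius_um = numeric(0),
                        class = character(0), dapi = numeric(0),
                        etbr = numeric(0), calcein = numeric(0))
  lab <- readGrayImage(label_path)
  storage.mode(lab) <- "integer"
  new("GroundTruth", cells = as.data.frame(cells), label_image = lab)
}

#' Serialize a scene specification to / from YAML
#'
#' @param spec A [SceneSpec-class].
#' @param path YAML file path.
#' @return `readSceneSpec` returns the [SceneSpec-class]; the writer
#'   returns `path` invisibly.
#' @export
writeSceneSpec <- function(spec, path) {
  lst <- list(
    image_height_px = spec@image_height_px,
    image_width_px = spec@image_width_px,
    pixel_size_um = spec@pixel_size_um,
    n_cells = spec@n_cells,
    cell_radius_um = spec@cell_radius_um,
    edge_contrast = spec@edge_contrast,
    background_level = spec@background_level,
    fluor_background_level = spec@fluor_background_level,
    noise_sd = spec@noise_sd,
    bit_depth = spec@bit_depth,
    class_fractions = as.list(spec@class_fractions),
    channel_models = lapply(spec@channel_models,
                            function(m) lapply(m, as.numeric)),
    non_overlapping = spec@non_overlapping,
    seed = spec@seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSceneSpec
#' @export
readSceneSpec <- function(path) {
  if (!file.exists(path)) stopIO("scene spec not found: %s", path)
  lst <- yaml::read_yaml(path)
  lst$class_fractions <- unlist(lst$class_fractions)
  do.call(SceneSpec, lst)
}

#' Write / read a run log
#'
#' Events go to JSON-lines (one event object per line); the totals to a
#' companion summary JSON.
#'
#' @param log A [RunLog-class].
#' @param events_path `.jsonl` path for the events.
#' @param summary_path `.json` path for the totals.
#' @return `readRunLog` returns the [RunLog-class]; the writer returns
#'   the paths invisibly.
#' @export
writeRunLog <- function(log, events_path, summary_path) {
  ev <- runEvents(log)
  lines <- vapply(seq_len(nrow(ev)), function(k) {
    jsonlite::toJSON(as.list(ev[k, ]), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, events_path)
  jsonlite::write_json(runTotals(log), summary_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(events_path, summary_path))
}

#' @rdname writeRunLog
#' @export
readRunLog <- function(events_path, summary_path) {
  lines <- readLines(events_path)
  ev <- if (length(lines)) {
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else data.frame(t_ms = numeric(0), kind = character(0),
                    duration_ms = numeric(0), tile = character(0),
                    detail = character(0))
  tot <- jsonlite::fromJSON(summary_path)
  new("RunLog", events = ev,
      positions_illuminated = as.integer(tot$positions_illuminated),
      elapsed_ms = as.numeric(tot$elapsed_ms),
      throughput_per_s = as.numeric(tot$throughput_per_s))
}

#' Write / read a threshold set as YAML
#'
#' @param thresholds A [ThresholdSet-class].
#' @param path YAML path.
#' @return `readThresholds` returns the [ThresholdSet-class]; the writer
#'   returns `path` invisibly.
#' @export
writeThresholds <- function(thresholds, path) {
  yaml::write_yaml(list(dapi_threshold = thresholds@dapi_threshold,
                        etbr_threshold = thresholds@etbr_threshold,
                        calcein_threshold = thresholds@calcein_threshold,
                        mode = thresholds@mode), path)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  if (!file.exists(path)) stopIO("thresholds file not found: %s", path)
  do.call(ThresholdSet, yaml::read_yaml(path))
}

#' Read calibration points for focus-plane fitting
#'
#' @param path CSV with columns `x_um, y_um, z_um`.
#' @return `data.frame`.
#' @export
readCalibrationPoints <- function(path) {
  if (!file.exists(path)) stopIO("calibration file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# Build typed components out of a parsed config list, applying
# constructor defaults for unset fields.
buildFromConfig <- function(constructor, fields) {
  if (is.null(fields)) constructor()
  else do.call(constructor, fields)
}

#' Read a full run configuration from YAML
#'
#' Sections (`scene`, `detection`, `segmentation`, `grid`, `timing`,
#' `thresholds`) each hold the arguments of the matching constructor;
#' missing sections fall back to constructor defaults. A top-level `seed`
#' overrides the scene seed.
#'
#' @param path YAML configuration path.
#' @return Named list with typed components plus `seed`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopIO("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  scene_args <- cfg$scene
  if (!is.null(scene_args$class_fractions))
    scene_args$class_fractions <- unlist(scene_args$class_fractions)
  if (!is.null(cfg$seed) && !is.null(scene_args))
    scene_args$seed <- cfg$seed
  if (!is.null(cfg$seed) && is.null(scene_args))
    scene_args <- list(seed = cfg$seed)
  list(
    scene = buildFromConfig(SceneSpec, scene_args),
    detection = buildFromConfig(DetectionParams, cfg$detection),
    segmentation = buildFromConfig(SegmentationParams, cfg$segmentation),
    grid = buildFromConfig(FOVGrid, cfg$grid),
    timing = buildFromConfig(TimingModel, cfg$timing),
    thresholds = if (is.null(cfg$thresholds)) NULL
                 else do.call(ThresholdSet, cfg$thresholds),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
}
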