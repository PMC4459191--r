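#' @import methods
#' @importFrom stats rnorm runif sd quantile optim lm.fit setNames
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv
NULL

## Central S4 containers. Images themselves are plain numeric matrices
## (mat[row, col], origin top-left); pixel coordinates in tables are 0-based.

#' Parametric description of a synthetic dish scene
#'
#' A `SceneSpec` fixes everything needed to render one synthetic field of
#' view (or dish region): geometry, bright-field contrast model, noise,
#' bit depth, the class mixture and the class-conditional fluorescence
#' intensity models. Together with its `seed` it determines the rendered
#' images byte-for-byte.
#'
#' @slot image_height_px,image_width_px Image size in pixels.
#' @slot pixel_size_um Pixel pitch in micrometres per pixel.
#' @slot n_cells Number of cells to place.
#' @slot cell_radius_um Length-2 numeric, min and max cell radius (um).
#' @slot edge_contrast Amplitude (grayscale counts) of the bright-field
#'   contour ring rendered at each cell boundary.
#' @slot background_level Bright-field background level (counts).
#' @slot fluor_background_level Fluorescence-channel background (counts).
#' @slot noise_sd Additive Gaussian noise standard deviation (counts).
#' @slot bit_depth Integer, 8 or 12; pixel values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @slot class_fractions Named numeric `(intact, optoporated_alive, dead)`
#'   summing to 1.
#' @slot channel_models Per-class list of per-channel `c(mean, sd)`
#'   intensity models; see [defaultChannelModels()].
#' @slot non_overlapping Logical; if `TRUE` cells are placed with
#'   centre-to-centre distance at least the sum of their radii.
#' @slot seed Integer root seed; placement, class, per-cell intensity and
#'   pixel-noise streams are derived from it by fixed offsets.
#' @seealso [SceneSpec()], [generateBrightField()], [generateFluorescence()]
#' @export
setClass("SceneSpec", representation(
  image_height_px = "integer",
  image_width_px = "integer",
  pixel_size_um = "numeric",
  n_cells = "integer",
  cell_radius_um = "numeric",
  edge_contrast = "numeric",
  background_level = "numeric",
  fluor_background_level = "numeric",
  noise_sd = "numeric",
  bit_depth = "integer",
  class_fractions = "numeric",
  channel_models = "list",
  non_overlapping = "logical",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@image_height_px < 1L || object@image_width_px < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@pixel_size_um <= 0)
    msg <- c(msg, "pixel_size_um must be positive")
  if (object@n_cells < 0L)
    msg <- c(msg, "n_cells must be >= 0")
  if (length(object@cell_radius_um) != 2L || any(object@cell_radius_um <= 0) ||
      object@cell_radius_um[1] > object@cell_radius_um[2])
    msg <- c(msg, "cell_radius_um must be positive c(min, max)")
  if (!object@bit_depth %in% c(8L, 12L))
    msg <- c(msg, "bit_depth must be 8 or 12")
  if (object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be >= 0")
  cf <- object@class_fractions
  if (length(cf) != 3L || any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
    msg <- c(msg, "class_fractions must be 3 nonnegative values summing to 1")
  if (!all(cellClasses() %in% names(object@channel_models)))
    msg <- c(msg, "channel_models must have entries for all three classes")
  for (cl in intersect(cellClasses(), names(object@channel_models))) {
    m <- object@channel_models[[cl]]
    if (!all(c("dapi", "etbr", "calcein") %in% names(m)))
      msg <- c(msg, sprintf("channel_models$%s must model dapi, etbr, calcein", cl))
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell ground truth of a synthetic scene
#'
#' @slot cells `data.frame` with one row per cell: `label`, centroid
#'   `row_px`/`col_px` (0-based), `radius_um`, `class`, and the true
#'   per-channel mean intensities `dapi`, `etbr`, `calcein`.
#' @slot label_image Integer matrix, 0 = background, cell pixels carry
#'   the cell's label.
#' @export
setClass("GroundTruth", representation(
  cells = "data.frame",
  label_image = "matrix"
))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  need <- c("label", "row_px", "col_px", "radius_um", "class",
            "dapi", "etbr", "calcein")
  if (!all(need %in% names(object@cells)))
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  else {
    n <- nrow(object@cells)
    if (n > 0 && !identical(sort(object@cells$label), seq_len(n)))
      msg <- c(msg, "cell labels must be 1..n_cells")
    if (n > 0 && !all(object@cells$class %in% cellClasses()))
      msg <- c(msg, "unknown cell class in ground truth")
    lab <- unique(as.vector(object@label_image))
    if (!all(lab %in% c(0L, object@cells$label)))
      msg <- c(msg, "label image contains labels absent from the cell table")
  }
  if (length(msg)) msg else TRUE
})

#' Tunables of the rake edge detector
#'
#' @slot search_area_size_um Side length (um) of the square ROI grid;
#'   sets both the rake-line spacing and the segment length. Typical
#'   values bracket the targeted cell size (10-20 um for CHO cells).
#' @slot min_edge_strength Minimum grayscale change (raw counts of the
#'   input bit depth) for a transition to qualify as an edge.
#' @slot hysteresis Extra counts demanded of rising edges and forgiven
#'   of falling edges; 0 makes the two symmetric.
#' @slot kernel_half_width_px Half-width of the moving-average kernel
#'   used to smooth the profile before edge strength is evaluated;
#'   0 = no smoothing.
#' @slot min_separation_um Radius of the near-duplicate removal pass.
#' @slot pixel_size_um Pixel pitch, um per pixel.
#' @slot scan_vertical Logical; also scan vertical rake lines
#'   (off by default, matching the horizontal-only published layout).
#' @export
setClass("DetectionParams", representation(
  search_area_size_um = "numeric",
  min_edge_strength = "numeric",
  hysteresis = "numeric",
  kernel_half_width_px = "integer",
  min_separation_um = "numeric",
  pixel_size_um = "numeric",
  scan_vertical = "logical"
))

setValidity("DetectionParams", function(object) {
  msg <- character(0)
  if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be positive")
  if (object@search_area_size_um <= 0 ||
      object@search_area_size_um / object@pixel_size_um < 2)
    msg <- c(msg, "search_area_size_um must span at least 2 px")
  if (object@min_edge_strength <= 0)
    msg <- c(msg, "min_edge_strength must be > 0")
  if (object@hysteresis < 0) msg <- c(msg, "hysteresis must be >= 0")
  if (object@hysteresis >= object@min_edge_strength)
    msg <- c(msg, "hysteresis must be smaller than min_edge_strength")
  if (object@kernel_half_width_px < 0L)
    msg <- c(msg, "kernel_half_width_px must be >= 0")
  if (object@min_separation_um <= 0)
    msg <- c(msg, "min_separation_um must be positive")
  if (length(msg)) msg else TRUE
})

#' Regular grid of microscope fields of view
#'
#' Tile `(i, j)` (0-based) has stage centre
#' `origin + (j * fov_width_um, i * fov_height_um)`.
#'
#' @slot n_rows,n_cols Grid size.
#' @slot fov_width_um,fov_height_um Field-of-view extent (um).
#' @slot origin_stage_um Stage coordinates `(x, y)` of tile (0,0) centre.
#' @export
setClass("FOVGrid", representation(
  n_rows = "integer",
  n_cols = "integer",
  fov_width_um = "numeric",
  fov_height_um = "numeric",
  origin_stage_um = "numeric"
))

setValidity("FOVGrid", function(object) {
  msg <- character(0)
  if (object@n_rows < 1L || object@n_cols < 1L)
    msg <- c(msg, "grid must have at least one row and column")
  if (object@fov_width_um <= 0 || object@fov_height_um <= 0)
    msg <- c(msg, "FOV dimensions must be positive")
  if (length(object@origin_stage_um) != 2L)
    msg <- c(msg, "origin_stage_um must be length 2")
  if (length(msg)) msg else TRUE
})

#' Serpentine visiting order over a FOV grid
#'
#' @slot tiles `data.frame` with columns `i`, `j` (0-based tile indices)
#'   and `x_um`, `y_um` (stage centre of each tile), one row per tile in
#'   visiting order.
#' @slot grid The [FOVGrid-class] the plan covers.
#' @export
setClass("MeanderPlan", representation(
  tiles = "data.frame",
  grid = "FOVGrid"
))

setValidity("MeanderPlan", function(object) {
  t <- object@tiles
  msg <- character(0)
  if (!all(c("i", "j", "x_um", "y_um") %in% names(t)))
    return("tiles must have columns i, j, x_um, y_um")
  key <- paste(t$i, t$j)
  if (anyDuplicated(key)) msg <- c(msg, "a tile appears more than once")
  if (nrow(t) != object@grid@n_rows * object@grid@n_cols)
    msg <- c(msg, "plan does not cover the grid")
  if (nrow(t) > 1) {
    dd <- abs(diff(t$i)) + abs(diff(t$j))
    if (any(dd != 1)) msg <- c(msg, "consecutive tiles must be grid-adjacent")
  }
  if (length(msg)) msg else TRUE
})

#' Instrument time constants of the virtual microscope
#'
#' Defaults reproduce the published operating point: a stage that needs
#' about 15 ms per 10 um move (acceleration included), within-FOV
#' centring moves of 30-40 ms, ~150 ms to advance one FOV, camera
#' exposures of 20-50 ms, and negligible (<1 ms) per-position detection
#' time.
#'
#' @slot stage_ms_per_10um Stage travel time per 10 um (ms).
#' @slot stage_overhead_ms Fixed overhead per centring move (ms).
#' @slot illumination_ms Laser illumination (shutter-open) time (ms).
#' @slot fov_reposition_ms Stage move to the next FOV (ms).
#' @slot camera_exposure_ms Bright-field exposure per FOV (ms).
#' @slot detection_ms_per_position Image-processing time per detected
#'   position (ms).
#' @slot shutter_latency_ms Mechanical shutter actuation latency (ms),
#'   0 by default (absorbed in `stage_overhead_ms`).
#' @export
setClass("TimingModel", representation(
  stage_ms_per_10um = "numeric",
  stage_overhead_ms = "numeric",
  illumination_ms = "numeric",
  fov_reposition_ms = "numeric",
  camera_exposure_ms = "numeric",
  detection_ms_per_position = "numeric",
  shutter_latency_ms = "numeric"
))

setValidity("TimingModel", function(object) {
  vals <- c(object@stage_ms_per_10um, object@stage_overhead_ms,
            object@illumination_ms, object@fov_reposition_ms,
            object@camera_exposure_ms, object@detection_ms_per_position,
            object@shutter_latency_ms)
  if (any(!is.finite(vals)) || any(vals < 0))
    "all timing constants must be finite and nonnegative" else TRUE
})

#' Least-squares focus plane z = a x + b y + c
#'
#' @slot a,b,c Plane coefficients; x, y, z in micrometres.
#' @slot rms_residual_um Root-mean-square residual of the fit.
#' @slot n_points Number of calibration points used.
#' @export
setClass("FocusPlane", representation(
  a = "numeric", b = "numeric", c = "numeric",
  rms_residual_um = "numeric", n_points = "integer"
))

setValidity("FocusPlane", function(object) {
  if (!all(is.finite(c(object@a, object@b, object@c))))
    return("plane coefficients must be finite")
  if (object@rms_residual_um < 0) return("rms residual must be >= 0")
  TRUE
})

#' Event trace of a (virtual) optoporation run
#'
#' @slot events `data.frame`, one row per event in time order:
#'   `t_ms` (start time), `kind` (one of `fov_advance`, `expose`,
#'   `detect`, `move`, `open_shutter`, `close_shutter`),
#'   `duration_ms`, `tile` ("i,j"), `detail`.
#' @slot positions_illuminated Total illuminated positions.
#' @slot elapsed_ms Total elapsed time; equals the sum of all event
#'   durations exactly.
#' @slot throughput_per_s Illuminated positions per second.
#' @export
setClass("RunLog", representation(
  events = "data.frame",
  positions_illuminated = "integer",
  elapsed_ms = "numeric",
  throughput_per_s = "numeric"
))

setValidity("RunLog", function(object) {
  ev <- object@events
  msg <- character(0)
  if (!all(c("t_ms", "kind", "duration_ms", "tile", "detail") %in% names(ev)))
    return("events must have columns t_ms, kind, duration_ms, tile, detail")
  if (nrow(ev)) {
    if (is.unsorted(ev$t_ms)) msg <- c(msg, "timestamps must be non-decreasing")
    if (any(ev$duration_ms < 0)) msg <- c(msg, "durations must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the DAPI nucleus segmentation
#'
#' @slot opening_radius_px Radius of the disk used for the grayscale
#'   opening that suppresses small intensity peaks; 0 disables it.
#' @slot h_value Depth of the extended h-maxima transform (counts);
#'   maxima shallower than `h_value` are merged into their surround.
#' @slot min_cell_area_px Components smaller than this are discarded.
#' @export
setClass("SegmentationParams", representation(
  opening_radius_px = "integer",
  h_value = "numeric",
  min_cell_area_px = "integer"
))

setValidity("SegmentationParams", function(object) {
  msg <- character(0)
  if (object@opening_radius_px < 0L) msg <- c(msg, "opening_radius_px must be >= 0")
  if (object@h_value <= 0) msg <- c(msg, "h_value must be > 0")
  if (object@min_cell_area_px < 1L) msg <- c(msg, "min_cell_area_px must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Intensity gates of the outcome classifier
#'
#' The DAPI gate is the control mean plus two standard deviations; the
#' EtBr and calcein gates are built the same way from the control-channel
#' background.
#'
#' @slot dapi_threshold,etbr_threshold,calcein_threshold Gates in raw counts.
#' @slot mode `"sample"` (sample mean/SD) or `"gaussian_fit"`
#'   (Gaussian fitted to the intensity histogram).
#' @export
setClass("ThresholdSet", representation(
  dapi_threshold = "numeric",
  etbr_threshold = "numeric",
  calcein_threshold = "numeric",
  mode = "character"
))

setValidity("ThresholdSet", function(object) {
  msg <- character(0)
  if (any(c(object@dapi_threshold, object@etbr_threshold,
            object@calcein_threshold) <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (!object@mode %in% c("sample", "gaussian_fit"))
    msg <- c(msg, "mode must be 'sample' or 'gaussian_fit'")
  if (length(msg)) msg else TRUE
})

#' Outcome counts and the dead / optoporated ratios
#'
#' @slot N_total,N_intact,N_dead,N_optoporated,N_ambiguous Class counts;
#'   they partition `N_total`.
#' @slot r_d Dead ratio, `N_dead / N_total`.
#' @slot r_o Optoporated-and-alive ratio, `N_optoporated / N_total`.
#' @export
setClass("OutcomeSummary", representation(
  N_total = "integer", N_intact = "integer", N_dead = "integer",
  N_optoporated = "integer", N_ambiguous = "integer",
  r_d = "numeric", r_o = "numeric"
))

setValidity("OutcomeSummary", function(object) {
  msg <- character(0)
  if (object@N_intact + object@N_dead + object@N_optoporated +
      object@N_ambiguous != object@N_total)
    msg <- c(msg, "class counts must partition N_total")
  if (object@r_d < 0 || object@r_o < 0 || object@r_d + object@r_o > 1 + 1e-12)
    msg <- c(msg, "ratios must be within [0, 1] and sum to at most 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px (%.3g um/px), %d cells, %d-bit\n",
              object@image_height_px, object@image_width_px,
              object@pixel_size_um, object@n_cells, object@bit_depth))
  cat(sprintf("  class fractions: intact %.2f / optoporated %.2f / dead %.2f\n",
              object@class_fractions[1], object@class_fractions[2],
              object@class_fractions[3]))
  cat(sprintf("  edge contrast %g, noise sd %g, seed %d\n",
              object@edge_contrast, object@noise_sd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells over a %d x %d label image\n",
              nrow(object@cells), nrow(object@label_image),
              ncol(object@label_image)))
  if (nrow(object@cells))
    print(table(object@cells$class))
})

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(paste0("DetectionParams: search area %g um, min edge strength %g,",
                     " hysteresis %g,\n  kernel half-width %d px,",
                     " min separation %g um, pixel size %g um\n"),
              object@search_area_size_um, object@min_edge_strength,
              object@hysteresis, object@kernel_half_width_px,
              object@min_separation_um, object@pixel_size_um))
})

setMethod("show", "MeanderPlan", function(object) {
  cat(sprintf("MeanderPlan: %d x %d grid, %d tiles in serpentine order\n",
              object@grid@n_rows, object@grid@n_cols, nrow(object@tiles)))
})

setMethod("show", "TimingModel", function(object) {
  cat(sprintf(paste0("TimingModel: stage %g ms/10um + %g ms overhead,",
                     " illumination %g ms,\n  FOV move %g ms, exposure %g ms,",
                     " detection %g ms/position\n"),
              object@stage_ms_per_10um, object@stage_overhead_ms,
              object@illumination_ms, object@fov_reposition_ms,
              object@camera_exposure_ms, object@detection_ms_per_position))
})

setMethod("show", "FocusPlane", function(object) {
  cat(sprintf("FocusPlane: z = %.6g x + %.6g y + %.6g (rms %.3g um, n = %d)\n",
              object@a, object@b, object@c, object@rms_residual_um,
              object@n_points))
})

setMethod("show", "RunLog", function(object) {
  cat(sprintf("RunLog: %d events, %d positions illuminated, %.1f ms elapsed (%.2f positions/s)\n",
              nrow(object@events), object@positions_illuminated,
              object@elapsed_ms, object@throughput_per_s))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet (%s): DAPI %.1f, EtBr %.1f, calcein %.1f\n",
              object@mode, object@dapi_threshold, object@etbr_threshold,
              object@calcein_threshold))
})

setMethod("show", "OutcomeSummary", function(object) {
  cat(sprintf(paste0("OutcomeSummary: N = %d (intact %d, dead %d,",
                     " optoporated %d, ambiguous %d)\n  r_d = %.3f, r_o = %.3f\n"),
              object@N_total, object@N_intact, object@N_dead,
              object@N_optoporated, object@N_ambiguous,
              object@r_d, object@r_o))
})

## ---- accessors ----------------------------------------------------------

#' The three biological outcome classes (plus the ambiguous flag)
#'
#' `cellClasses()` returns the three generated classes; classification can
#' additionally emit `"ambiguous"` where the gates are inconclusive (the
#' cases the original workflow resolved by manual inspection).
#' @return Character vector of class names.
#' @export
cellClasses <- function() c("intact", "optoporated_alive", "dead")

#' @rdname GroundTruth-class
#' @param truth A [GroundTruth-class] object.
#' @return `truthCells()`: the per-cell `data.frame`; `labelImage()`: the
#'   integer label matrix.
#' @export
truthCells <- function(truth) truth@cells

#' @rdname GroundTruth-class
#' @export
labelImage <- function(truth) truth@label_image

#' @rdname MeanderPlan-class
#' @param plan A [MeanderPlan-class].
#' @return `planTiles()`: the tile `data.frame` in visiting order.
#' @export
planTiles <- function(plan) plan@tiles

#' @rdname RunLog-class
#' @param log A [RunLog-class].
#' @return `runEvents()`: the event `data.frame`; `runTotals()`: a named
#'   list with `positions_illuminated`, `elapsed_ms`, `throughput_per_s`.
#' @export
runEvents <- function(log) log@events

#' @rdname RunLog-class
#' @export
runTotals <- function(log) {
  list(positions_illuminated = log@positions_illuminated,
       elapsed_ms = log@elapsed_ms,
       throughput_per_s = log@throughput_per_s)
}
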