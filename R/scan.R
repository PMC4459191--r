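#' Construct a FOV grid
#'
#' @param n_rows,n_cols Number of tile rows and columns.
#' @param fov_width_um,fov_height_um Field-of-view extent in um.
#' @param origin_stage_um Stage coordinates `c(x, y)` of the centre of
#'   tile (0, 0).
#' @return A validated [FOVGrid-class].
#' @export
FOVGrid <- function(n_rows = 6L, n_cols = 6L,
                    fov_width_um = 280, fov_height_um = 220,
                    origin_stage_um = c(0, 0)) {
  obj <- new("FOVGrid", n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
             fov_width_um = as.numeric(fov_width_um),
             fov_height_um = as.numeric(fov_height_um),
             origin_stage_um = as.numeric(origin_stage_um))
  validObject(obj)
  obj
}

#' Construct an instrument timing model
#'
#' @param stage_ms_per_10um Stage travel time per 10 um including
#'   acceleration and stop (default 15 ms).
#' @param stage_overhead_ms Fixed per-move overhead (default 20 ms, so a
#'   typical 10 um centring move costs 35 ms, inside the 30-40 ms band).
#' @param illumination_ms Shutter-open laser time per position
#'   (default 100 ms).
#' @param fov_reposition_ms Move to the next FOV (default 150 ms).
#' @param camera_exposure_ms Bright-field exposure (default 35 ms, middle
#'   of the 20-50 ms operating range).
#' @param detection_ms_per_position Image-processing cost per position
#'   (default 1 ms).
#' @param shutter_latency_ms Shutter actuation latency (default 0).
#' @return A validated [TimingModel-class].
#' @export
TimingModel <- function(stage_ms_per_10um = 15, stage_overhead_ms = 20,
                        illumination_ms = 100, fov_reposition_ms = 150,
                        camera_exposure_ms = 35,
                        detection_ms_per_position = 1,
                        shutter_latency_ms = 0) {
  obj <- new("TimingModel",
             stage_ms_per_10um = as.numeric(stage_ms_per_10um),
             stage_overhead_ms = as.numeric(stage_overhead_ms),
             illumination_ms = as.numeric(illumination_ms),
             fov_reposition_ms = as.numeric(fov_reposition_ms),
             camera_exposure_ms = as.numeric(camera_exposure_ms),
             detection_ms_per_position = as.numeric(detection_ms_per_position),
             shutter_latency_ms = as.numeric(shutter_latency_ms))
  validObject(obj)
  obj
}

#' Plan a serpentine (meander) scan over a FOV grid
#'
#' Row 0 is visited left to right, row 1 right to left, and so on, so
#' every stage advance between consecutive tiles is exactly one FOV.
#'
#' @param grid A [FOVGrid-class].
#' @return A validated [MeanderPlan-class].
#' @examples
#' planTiles(planMeander(FOVGrid(2, 2)))
#' @export
planMeander <- function(grid) {
  stopifnot(is(grid, "FOVGrid"))
  validObject(grid)
  i <- rep(seq_len(grid@n_rows) - 1L, each = grid@n_cols)
  j <- unlist(lapply(seq_len(grid@n_rows) - 1L, function(r) {
    cols <- seq_len(grid@n_cols) - 1L
    if (r %% 2L == 0L) cols else rev(cols)
  }))
  tiles <- data.frame(
    i = i, j = j,
    x_um = grid@origin_stage_um[1] + j * grid@fov_width_um,
    y_um = grid@origin_stage_um[2] + i * grid@fov_height_um
  )
  obj <- new("MeanderPlan", tiles = tiles, grid = grid)
  validObject(obj)
  obj
}

#' Least-squares focus plane through stage calibration points
#'
#' Fits `z = a x + b y + c` by ordinary least squares to manually focused
#' calibration points, capturing a horizontal tilt of the culture dish so
#' the focus height at any stage position can be interpolated.
#'
#' @param points `data.frame` or matrix with columns `x_um`, `y_um`,
#'   `z_um` (or three unnamed columns in that order).
#' @return A [FocusPlane-class] with coefficients and RMS residual.
#' @export
fitFocusPlane <- function(points) {
  pts <- as.data.frame(points)
  if (ncol(pts) < 3L)
    stopValidation("calibration points need x, y and z columns")
  if (!all(c("x_um", "y_um", "z_um") %in% names(pts)))
    names(pts)[1:3] <- c("x_um", "y_um", "z_um")
  if (nrow(pts) < 3L)
    stopValidation("plane fitting needs at least 3 calibration points")
  A <- cbind(pts$x_um, pts$y_um, 1)
  if (qr(A)$rank < 3L)
    stopValidation("calibration points are collinear in (x, y); cannot fit a plane")
  fit <- lm.fit(A, pts$z_um)
  cf <- fit$coefficients
  new("FocusPlane", a = cf[[1]], b = cf[[2]], c = cf[[3]],
      rms_residual_um = sqrt(mean(fit$residuals^2)),
      n_points = nrow(pts))
}

#' Evaluate the focus plane at stage coordinates
#'
#' @param plane A [FocusPlane-class].
#' @param x_um,y_um Stage coordinates (vectorised).
#' @return Focus height(s) `z_um`.
#' @export
predictFocusZ <- function(plane, x_um, y_um) {
  stopifnot(is(plane, "FocusPlane"))
  plane@a * x_um + plane@b * y_um + plane@c
}

#' Stage travel time for a centring move
#'
#' Linear in distance at `stage_ms_per_10um`, with a 10 um floor (the
#' accelerate/stop cost dominates short hops) plus the fixed per-move
#' overhead.
#'
#' @param distance_um Move length in um (>= 0).
#' @param timing A [TimingModel-class].
#' @return Time in ms.
#' @examples
#' stageMoveTime(10, TimingModel())  # 35 ms
#' @export
stageMoveTime <- function(distance_um, timing) {
  if (any(distance_um < 0))
    stopValidation("distance_um must be >= 0")
  timing@stage_overhead_ms +
    timing@stage_ms_per_10um * pmax(distance_um, 10) / 10
}

tileKey <- function(i, j) sprintf("%d,%d", i, j)

# Shared event emitter: both simulateRun and executeRun produce their logs
# through this accumulator so the two traces are identical by construction
# on the same target sets.
newEventLog <- function() {
  env <- new.env(parent = emptyenv())
  env$kind <- character(0); env$duration <- numeric(0)
  env$tile <- character(0); env$detail <- character(0)
  env
}

logEvent <- function(log, kind, duration, tile, detail = "") {
  log$kind <- c(log$kind, kind)
  log$duration <- c(log$duration, duration)
  log$tile <- c(log$tile, tile)
  log$detail <- c(log$detail, detail)
}

finishRunLog <- function(log, n_illuminated) {
  dur <- log$duration
  t0 <- if (length(dur)) c(0, cumsum(dur)[-length(dur)]) else numeric(0)
  elapsed <- sum(dur)
  events <- data.frame(t_ms = t0, kind = log$kind, duration_ms = dur,
                       tile = log$tile, detail = log$detail,
                       stringsAsFactors = FALSE)
  obj <- new("RunLog", events = events,
             positions_illuminated = as.integer(n_illuminated),
             elapsed_ms = elapsed,
             throughput_per_s = if (elapsed > 0) n_illuminated / (elapsed / 1000) else 0)
  validObject(obj)
  obj
}

# Emit the event sequence of one FOV visit. Positions are FOV-local
# (x_um, y_um); the cursor starts at the FOV centre after repositioning.
visitFOV <- function(log, key, targets, grid, timing) {
  logEvent(log, "fov_advance", timing@fov_reposition_ms, key)
  logEvent(log, "expose", timing@camera_exposure_ms, key)
  n <- if (is.null(targets)) 0L else nrow(targets)
  logEvent(log, "detect", timing@detection_ms_per_position * n, key,
           sprintf("n=%d", n))
  cx <- grid@fov_width_um / 2
  cy <- grid@fov_height_um / 2
  for (p in seq_len(n)) {
    d <- sqrt((targets$x_um[p] - cx)^2 + (targets$y_um[p] - cy)^2)
    logEvent(log, "move", stageMoveTime(d, timing), key,
             sprintf("position=%d", targets$id[p]))
    logEvent(log, "open_shutter", timing@illumination_ms, key,
             sprintf("position=%d", targets$id[p]))
    logEvent(log, "close_shutter", timing@shutter_latency_ms, key,
             sprintf("position=%d", targets$id[p]))
    cx <- targets$x_um[p]; cy <- targets$y_um[p]
  }
  n
}

#' Simulate an optoporation run over planned targets
#'
#' Walks the meander plan with the timing model: each FOV visit costs one
#' reposition, one exposure and the detection time, then each target
#' costs a centring move (distance from the previous position, starting
#' at the FOV centre) and one shutter open/close bracketing exactly
#' `illumination_ms`.
#'
#' @param targets_by_fov Named list of target `data.frame`s (FOV-local
#'   `x_um`, `y_um`), keyed `"i,j"`; tiles absent from the list are
#'   visited with zero targets.
#' @param plan A [MeanderPlan-class].
#' @param timing A [TimingModel-class].
#' @return A [RunLog-class]; `elapsed_ms` equals the sum of all event
#'   durations exactly.
#' @export
simulateRun <- function(targets_by_fov, plan, timing) {
  stopifnot(is(plan, "MeanderPlan"), is(timing, "TimingModel"))
  keys <- tileKey(plan@tiles$i, plan@tiles$j)
  unknown <- setdiff(names(targets_by_fov), keys)
  if (length(unknown))
    stopValidation("targets reference tiles not in the plan: %s",
                   paste(unknown, collapse = ", "))
  log <- newEventLog()
  n_ill <- 0L
  for (k in keys)
    n_ill <- n_ill + visitFOV(log, k, targets_by_fov[[k]], plan@grid, timing)
  finishRunLog(log, n_ill)
}

#' Virtual motorized stage
#'
#' A software stand-in honoring the stage contract of the control loop:
#' absolute moves, position read-back. `position_error_um` injects a
#' systematic read-back error to exercise the loop's contract check.
#'
#' @param position_error_um Error added to the reported x position.
#' @return List of closures `moveTo(x, y, z)` and `position()`.
#' @export
virtualStage <- function(position_error_um = 0) {
  pos <- c(x = 0, y = 0, z = 0)
  list(
    moveTo = function(x, y, z = NA_real_) {
      pos <<- c(x = x + position_error_um, y = y,
                z = if (is.na(z)) pos[["z"]] else z)
      invisible(pos)
    },
    position = function() pos
  )
}

#' Virtual mechanical shutter
#'
#' Tracks open/closed state and counts actuations; opening an open
#' shutter (or closing a closed one) violates the hardware contract.
#'
#' @return List of closures `open()`, `close()`, `isOpen()`, `cycles()`.
#' @export
virtualShutter <- function() {
  state <- FALSE
  n <- 0L
  list(
    open = function() {
      if (state) stopValidation("shutter contract violation: already open")
      state <<- TRUE; n <<- n + 1L; invisible(TRUE)
    },
    close = function() {
      if (!state) stopValidation("shutter contract violation: already closed")
      state <<- FALSE; invisible(TRUE)
    },
    isOpen = function() state,
    cycles = function() n
  )
}

#' Image source that crops FOV tiles out of one dish image
#'
#' @param image Full-dish bright-field matrix.
#' @param grid A [FOVGrid-class] whose tiles partition the image.
#' @param pixel_size_um Pixel pitch (um/px).
#' @return `function(i, j)` returning the tile submatrix.
#' @export
dishImageSource <- function(image, grid, pixel_size_um) {
  h <- as.integer(round(grid@fov_height_um / pixel_size_um))
  w <- as.integer(round(grid@fov_width_um / pixel_size_um))
  if (nrow(image) < grid@n_rows * h || ncol(image) < grid@n_cols * w)
    stopValidation("dish image (%d x %d px) is smaller than the %d x %d grid of %d x %d px tiles",
                   nrow(image), ncol(image), grid@n_rows, grid@n_cols, h, w)
  function(i, j) image[(i * h + 1L):((i + 1L) * h),
                       (j * w + 1L):((j + 1L) * w), drop = FALSE]
}

#' Execute the closed control loop against virtual hardware
#'
#' Per FOV of the meander plan: move the stage to the tile centre,
#' acquire the bright-field still, detect targets ([rakeDetect()] +
#' [deduplicateTargets()]), then centre and illuminate each kept position
#' (status `pending` to `illuminated`), applying the focus-plane height
#' correction when a plane is supplied. The stage position is read back
#' after every commanded move; a mismatch aborts with a diagnostic.
#'
#' @param imageSource `function(i, j)` returning the FOV bright-field
#'   matrix (see [dishImageSource()]).
#' @param params A [DetectionParams-class].
#' @param plan A [MeanderPlan-class].
#' @param timing A [TimingModel-class].
#' @param stage,shutter Virtual hardware (defaults [virtualStage()],
#'   [virtualShutter()]).
#' @param focus_plane Optional [FocusPlane-class] for z correction.
#' @return `list(log, targets_by_fov)`: the [RunLog-class] (identical to
#'   [simulateRun()] on the detected targets) and the per-tile target
#'   tables with final statuses.
#' @export
executeRun <- function(imageSource, params, plan, timing,
                       stage = virtualStage(), shutter = virtualShutter(),
                       focus_plane = NULL) {
  stopifnot(is(plan, "MeanderPlan"), is(timing, "TimingModel"),
            is(params, "DetectionParams"))
  grid <- plan@grid
  log <- newEventLog()
  n_ill <- 0L
  out_targets <- list()
  commandMove <- function(x, y) {
    z <- if (is.null(focus_plane)) NA_real_ else predictFocusZ(focus_plane, x, y)
    stage$moveTo(x, y, z)
    p <- stage$position()
    if (max(abs(p[c("x", "y")] - c(x, y))) > 1e-9)
      stopValidation(paste0("stage contract violation: commanded (%.3f, %.3f) um",
                            " but stage reports (%.3f, %.3f) um"),
                     x, y, p[["x"]], p[["y"]])
  }
  for (t in seq_len(nrow(plan@tiles))) {
    i <- plan@tiles$i[t]; j <- plan@tiles$j[t]
    key <- tileKey(i, j)
    tile_x <- plan@tiles$x_um[t]; tile_y <- plan@tiles$y_um[t]
    commandMove(tile_x, tile_y)
    img <- imageSource(i, j)
    all_targets <- deduplicateTargets(rakeDetect(img, params),
                                      params@min_separation_um,
                                      keep_removed = TRUE)
    kept <- all_targets[all_targets$status == "pending", , drop = FALSE]
    logEvent(log, "fov_advance", timing@fov_reposition_ms, key)
    logEvent(log, "expose", timing@camera_exposure_ms, key)
    logEvent(log, "detect", timing@detection_ms_per_position * nrow(kept), key,
             sprintf("n=%d", nrow(kept)))
    cx <- grid@fov_width_um / 2; cy <- grid@fov_height_um / 2
    for (p in seq_len(nrow(kept))) {
      d <- sqrt((kept$x_um[p] - cx)^2 + (kept$y_um[p] - cy)^2)
      # stage frame: FOV origin at the tile centre
      commandMove(tile_x - grid@fov_width_um / 2 + kept$x_um[p],
                  tile_y - grid@fov_height_um / 2 + kept$y_um[p])
      logEvent(log, "move", stageMoveTime(d, timing), key,
               sprintf("position=%d", kept$id[p]))
      shutter$open()
      logEvent(log, "open_shutter", timing@illumination_ms, key,
               sprintf("position=%d", kept$id[p]))
      shutter$close()
      logEvent(log, "close_shutter", timing@shutter_latency_ms, key,
               sprintf("position=%d", kept$id[p]))
      all_targets$status[all_targets$id == kept$id[p]] <- "illuminated"
      cx <- kept$x_um[p]; cy <- kept$y_um[p]
    }
    n_ill <- n_ill + nrow(kept)
    out_targets[[key]] <- all_targets
  }
  list(log = finishRunLog(log, n_ill), targets_by_fov = out_targets)
}
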