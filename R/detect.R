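#' Construct rake-detector parameters
#'
#' @param search_area_size_um Side of the square ROI grid (um); sets the
#'   rake-line spacing. Choose near the targeted cell size (10-20 um for
#'   CHO-like cells).
#' @param min_edge_strength Minimum grayscale change (raw counts) to
#'   qualify as an edge.
#' @param hysteresis Hysteresis (counts): rising edges must clear
#'   `min_edge_strength + hysteresis`, falling edges only
#'   `min_edge_strength - hysteresis`.
#' @param kernel_half_width_px Moving-average half-width for smoothing
#'   the profile before thresholding (0 = raw pixels).
#' @param min_separation_um Near-duplicate removal radius; defaults to
#'   half the search area size.
#' @param pixel_size_um Pixel pitch (um/px).
#' @param scan_vertical Also scan vertical rake lines (default `FALSE`).
#' @return A validated [DetectionParams-class].
#' @export
DetectionParams <- function(search_area_size_um = 12,
                            min_edge_strength = 15,
                            hysteresis = 0,
                            kernel_half_width_px = 0L,
                            min_separation_um = search_area_size_um / 2,
                            pixel_size_um = 0.5,
                            scan_vertical = FALSE) {
  obj <- new("DetectionParams",
             search_area_size_um = as.numeric(search_area_size_um),
             min_edge_strength = as.numeric(min_edge_strength),
             hysteresis = as.numeric(hysteresis),
             kernel_half_width_px = as.integer(kernel_half_width_px),
             min_separation_um = as.numeric(min_separation_um),
             pixel_size_um = as.numeric(pixel_size_um),
             scan_vertical = isTRUE(scan_vertical))
  validObject(obj)
  obj
}

# Moving-average smoothing with half-width k (window 2k + 1, truncated at
# the profile ends so the output has the input length).
smoothProfile <- function(profile, k) {
  if (k <= 0L) return(as.numeric(profile))
  n <- length(profile)
  cs <- cumsum(c(0, profile))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect rising and falling edges along an intensity profile
#'
#' The profile is scanned pixelwise from start to end against a running
#' baseline. A rising edge fires at the first index whose (smoothed)
#' value exceeds the running minimum since the last event by at least
#' `min_edge_strength + hysteresis`; a falling edge fires when the value
#' drops below the running maximum since the last event by at least
#' `min_edge_strength - hysteresis`. After an event both baselines reset
#' to the current value, so edges alternate naturally across a contour
#' crossing (one rising and one falling per crossing).
#'
#' @param profile Numeric vector of length at least 2 (raw counts).
#' @param params A [DetectionParams-class]; `min_edge_strength`,
#'   `hysteresis` and `kernel_half_width_px` are used.
#' @return `data.frame(index_px, polarity, strength)` in scan order;
#'   `index_px` is 0-based, `polarity` is `"rising"` or `"falling"`,
#'   `strength` is the excursion from the baseline at the firing pixel.
#' @examples
#' findEdges(c(10, 10, 10, 100, 100),
#'           DetectionParams(min_edge_strength = 50, hysteresis = 10))
#' @export
findEdges <- function(profile, params) {
  if (length(profile) < 2L)
    stopValidation("profile must have at least 2 samples")
  thr <- params@min_edge_strength
  hyst <- params@hysteresis
  v <- smoothProfile(profile, params@kernel_half_width_px)
  n <- length(v)
  rmin <- v[1L]; rmax <- v[1L]
  idx <- integer(0); pol <- character(0); str <- numeric(0)
  for (i in seq_len(n)) {
    x <- v[i]
    if (x < rmin) rmin <- x
    if (x > rmax) rmax <- x
    if (x >= rmin + thr + hyst) {
      idx <- c(idx, i - 1L); pol <- c(pol, "rising"); str <- c(str, x - rmin)
      rmin <- x; rmax <- x
    } else if (x <= rmax - (thr - hyst)) {
      idx <- c(idx, i - 1L); pol <- c(pol, "falling"); str <- c(str, rmax - x)
      rmin <- x; rmax <- x
    }
  }
  data.frame(index_px = idx, polarity = pol, strength = str,
             stringsAsFactors = FALSE)
}

# Scan one rake line (a full image row or column) segment by segment.
scanLine <- function(values, spacing_px, params) {
  n <- length(values)
  starts <- seq(0L, n - 1L, by = spacing_px)
  out_idx <- integer(0)
  for (s0 in starts) {
    s1 <- min(s0 + spacing_px, n)      # segment [s0, s1) in 0-based cols
    if (s1 - s0 < 2L) next
    ed <- findEdges(values[(s0 + 1L):s1], params)
    if (nrow(ed)) out_idx <- c(out_idx, s0 + ed$index_px)
  }
  out_idx
}

#' Detect laser-target positions along horizontal rake lines
#'
#' The image is subdivided into a square ROI grid of side
#' `search_area_size_um` anchored at row/column 0. Horizontal rake lines
#' run along rows `0, s, 2s, ...` (`s` = grid spacing in px); each line is
#' scanned with [findEdges()] independently per segment between
#' consecutive vertical grid lines, and every edge (rising or falling)
#' becomes a candidate target position. With `scan_vertical = TRUE`,
#' columns `0, s, 2s, ...` are scanned the same way afterwards.
#'
#' @param image Numeric matrix (grayscale counts, `image[row, col]`).
#' @param params A [DetectionParams-class].
#' @return Target `data.frame` in raster order with columns `id`,
#'   `row_px`, `col_px` (0-based), `x_um`, `y_um`, `rake_line_index`,
#'   `status` (all `"pending"`).
#' @export
rakeDetect <- function(image, params) {
  assertImage(image)
  s <- max(2L, as.integer(round(params@search_area_size_um / params@pixel_size_um)))
  if (nrow(image) < s || ncol(image) < s)
    stopValidation("image (%d x %d px) is smaller than one %d px ROI",
                   nrow(image), ncol(image), s)
  rows <- integer(0); cols <- integer(0); line <- integer(0)
  for (r0 in seq(0L, nrow(image) - 1L, by = s)) {
    hit <- scanLine(image[r0 + 1L, ], s, params)
    rows <- c(rows, rep.int(r0, length(hit)))
    cols <- c(cols, hit)
    line <- c(line, rep.int(r0 %/% s, length(hit)))
  }
  if (params@scan_vertical) {
    for (c0 in seq(0L, ncol(image) - 1L, by = s)) {
      hit <- scanLine(image[, c0 + 1L], s, params)
      rows <- c(rows, hit)
      cols <- c(cols, rep.int(c0, length(hit)))
      line <- c(line, rep.int(c0 %/% s, length(hit)))
    }
  }
  ord <- order(rows, cols)
  n <- length(ord)
  data.frame(id = seq_len(n),
             row_px = rows[ord], col_px = cols[ord],
             x_um = cols[ord] * params@pixel_size_um,
             y_um = rows[ord] * params@pixel_size_um,
             rake_line_index = line[ord],
             status = rep("pending", n),
             stringsAsFactors = FALSE)
}

#' Remove near-duplicate target positions
#'
#' Greedy single pass in raster order: a position is kept if and only if
#' its Euclidean distance (um) to every already-kept position is at least
#' `min_separation_um`; otherwise its status becomes `"removed"`. Keeping
#' the earlier position makes the pass deterministic and idempotent.
#'
#' @param targets Target `data.frame` as returned by [rakeDetect()], in
#'   raster order.
#' @param min_separation_um Minimum pairwise separation (um).
#' @param pixel_size_um Unused when `x_um`/`y_um` are present; kept so
#'   pixel-only tables can be thinned.
#' @param keep_removed If `TRUE`, return all rows with updated status;
#'   default returns only the kept rows.
#' @return Target `data.frame`.
#' @export
deduplicateTargets <- function(targets, min_separation_um,
                               pixel_size_um = NULL, keep_removed = FALSE) {
  if (nrow(targets) == 0L) return(targets)
  x <- if ("x_um" %in% names(targets)) targets$x_um
       else targets$col_px * pixel_size_um
  y <- if ("y_um" %in% names(targets)) targets$y_um
       else targets$row_px * pixel_size_um
  n <- nrow(targets)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0L ||
        all((kx - x[i])^2 + (ky - y[i])^2 >= min_separation_um^2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  out <- targets
  out$status[!keep & out$status == "pending"] <- "removed"
  if (keep_removed) out else out[keep, , drop = FALSE]
}

#' Count detected positions per ground-truth cell
#'
#' Each position is assigned to the cell whose mask contains it;
#' positions on background are tallied separately. Cells holding no
#' position count as zeros, so the mean is total assigned positions over
#' all cells.
#'
#' @param targets Target `data.frame` with `row_px`, `col_px` (0-based).
#' @param truth A [GroundTruth-class] sharing the image frame.
#' @return `list(counts, histogram, mean, n_unassigned)`: per-cell counts
#'   named by label, their table, the mean count, and the number of
#'   positions outside every mask.
#' @export
positionsPerCell <- function(targets, truth) {
  lab <- labelImage(truth)
  n_cells <- nrow(truthCells(truth))
  counts <- integer(n_cells)
  names(counts) <- as.character(seq_len(n_cells))
  unassigned <- 0L
  if (nrow(targets)) {
    hit <- lab[cbind(targets$row_px + 1L, targets$col_px + 1L)]
    unassigned <- sum(hit == 0L)
    tab <- table(hit[hit > 0L])
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts,
       histogram = table(counts),
       mean = if (n_cells) mean(counts) else 0,
       n_unassigned = unassigned)
}
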