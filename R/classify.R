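#' Construct segmentation parameters
#'
#' @param opening_radius_px Disk radius of the peak-suppressing grayscale
#'   opening (default 2 px).
#' @param h_value Depth of the extended h-maxima transform in grayscale
#'   counts (default 200 on a 12-bit scale: deeper than noise, much
#'   shallower than the nuclear DAPI signal).
#' @param min_cell_area_px Minimum component area kept (default 20 px).
#' @return A validated [SegmentationParams-class].
#' @export
SegmentationParams <- function(opening_radius_px = 2L, h_value = 200,
                               min_cell_area_px = 20L) {
  obj <- new("SegmentationParams",
             opening_radius_px = as.integer(opening_radius_px),
             h_value = as.numeric(h_value),
             min_cell_area_px = as.integer(min_cell_area_px))
  validObject(obj)
  obj
}

#' Construct an explicit threshold set
#'
#' @param dapi_threshold,etbr_threshold,calcein_threshold Gates in raw
#'   counts.
#' @param mode `"sample"` or `"gaussian_fit"` (how the DAPI gate was
#'   derived).
#' @return A validated [ThresholdSet-class].
#' @export
ThresholdSet <- function(dapi_threshold, etbr_threshold, calcein_threshold,
                         mode = "sample") {
  obj <- new("ThresholdSet", dapi_threshold = as.numeric(dapi_threshold),
             etbr_threshold = as.numeric(etbr_threshold),
             calcein_threshold = as.numeric(calcein_threshold),
             mode = mode)
  validObject(obj)
  obj
}

#' Percentile histogram normalization
#'
#' Linearly rescales intensities so the 0.5th and 99.5th percentiles map
#' to 0 and `2^bit_depth - 1`, clipping beyond; a constant image is
#' returned unchanged. Used to put DAPI images on a common footing before
#' morphological segmentation; classification statistics are always taken
#' from the raw images.
#'
#' @param image Numeric matrix.
#' @param bit_depth Target range exponent (default 12).
#' @return Rescaled matrix.
#' @export
normalizeHistogram <- function(image, bit_depth = 12L) {
  assertImage(image)
  q <- quantile(image, c(0.005, 0.995), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(image)
  top <- 2^bit_depth - 1
  clipToBitDepth((image - q[1]) / (q[2] - q[1]) * top, bit_depth)
}

# Disk structuring element: all offsets with dx^2 + dy^2 <= r^2.
diskBrush <- function(radius_px) {
  d <- 2L * radius_px + 1L
  o <- seq_len(d) - radius_px - 1L
  m <- outer(o, o, function(a, b) as.numeric(a^2 + b^2 <= radius_px^2))
  m
}

#' Suppress small intensity peaks by grayscale opening
#'
#' Opening (erosion then dilation) with a disk removes bright structures
#' narrower than the disk while leaving larger plateaus intact; the
#' output never exceeds the input. Radius 0 is the identity.
#'
#' @param image Numeric matrix.
#' @param opening_radius_px Disk radius in px.
#' @return Opened matrix.
#' @export
suppressPeaks <- function(image, opening_radius_px) {
  assertImage(image)
  r <- as.integer(opening_radius_px)
  if (r < 0L) stopValidation("opening_radius_px must be >= 0")
  if (r == 0L) return(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  # EBImage morphology operates on [0, 1]; opening commutes with the
  # positive affine rescale, so map there and back
  out <- EBImage::opening((image - lo) / (hi - lo), diskBrush(r))
  pmin(unclass(out) * (hi - lo) + lo, image)
}

# Grayscale morphological reconstruction by dilation (8-connected):
# iterated geodesic dilation of `marker` under `mask` to stability.
reconstructByDilation <- function(marker, mask) {
  if (any(marker > mask)) marker <- pmin(marker, mask)
  # work in [0, 1]: EBImage clamps grayscale morphology to that range;
  # dilation, pmin and the fixed point all commute with the affine map
  lo <- min(marker); hi <- max(mask)
  if (hi == lo) return(marker)
  m01 <- (marker - lo) / (hi - lo)
  k01 <- (mask - lo) / (hi - lo)
  box <- matrix(1, 3, 3)
  repeat {
    nxt <- pmin(unclass(EBImage::dilate(m01, box)), k01)
    if (identical(nxt, m01)) break
    m01 <- nxt
  }
  m01 * (hi - lo) + lo
}

# h-maxima transform: peaks shallower than h are levelled.
hMaxima <- function(image, h) reconstructByDilation(image - h, image)

# Extended h-maxima: regional maxima of the h-maxima transform, as a
# logical mask. Regional maxima are recovered with a second
# reconstruction at depth `delta` (1 count for integer-valued images).
extendedMaxima <- function(image, h, delta = 1) {
  hm <- hMaxima(image, h)
  (hm - reconstructByDilation(hm - delta, hm)) > delta / 2
}

#' Segment nuclei in a DAPI image by the extended h-maxima transform
#'
#' The raw DAPI image is histogram-normalized, opened with a disk
#' (suppressing small peaks), and its extended h-maxima of depth
#' `h_value` are taken as nuclear regions. Connected components smaller
#' than `min_cell_area_px` are discarded and the rest relabelled
#' 1..K in raster order of their first pixel. Per-cell mean intensities
#' are measured on the *raw* registered channels.
#'
#' @param dapi Raw DAPI matrix (counts).
#' @param params A [SegmentationParams-class].
#' @param etbr,calcein Optional registered raw channel matrices (same
#'   size as `dapi`).
#' @param bit_depth Bit depth of the raw data (default 12).
#' @return `list(labels, cells)`: the integer label matrix and a
#'   `data.frame` with one row per cell (`label`, `area_px`, centroid
#'   `row_px`/`col_px` 0-based, `mean_dapi`, `mean_etbr`, `mean_calcein`,
#'   `saturated_dapi`).
#' @export
segmentDapi <- function(dapi, params, etbr = NULL, calcein = NULL,
                        bit_depth = 12L) {
  assertImage(dapi, "dapi")
  for (ch in list(etbr = etbr, calcein = calcein)) {
    if (!is.null(ch) && !identical(dim(ch), dim(dapi)))
      stopValidation("channel images must share the DAPI image dimensions")
  }
  norm <- normalizeHistogram(dapi, bit_depth)
  opened <- suppressPeaks(norm, params@opening_radius_px)
  # no maximum can have depth > h when the whole dynamic range is <= h
  if (diff(range(opened)) <= params@h_value)
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                cells = emptyCellTable()))
  mask <- extendedMaxima(opened, params@h_value)
  lab0 <- unclass(EBImage::bwlabel(mask))
  cells <- measureCells(lab0, dapi, etbr, calcein, params@min_cell_area_px,
                        bit_depth)
  cells
}

# Filter small components, relabel in raster (row-major) order of first
# pixel, and measure per-cell statistics on the raw channels.
measureCells <- function(lab0, dapi, etbr, calcein, min_area, bit_depth) {
  H <- nrow(lab0); W <- ncol(lab0)
  labs <- sort(unique(lab0[lab0 > 0]))
  if (length(labs) == 0L) {
    return(list(labels = matrix(0L, H, W), cells = emptyCellTable()))
  }
  idx <- which(lab0 > 0)
  by_lab <- split(idx, lab0[idx])
  areas <- lengths(by_lab)
  keep <- names(by_lab)[areas >= min_area]
  if (length(keep) == 0L)
    return(list(labels = matrix(0L, H, W), cells = emptyCellTable()))
  # raster order of the first pixel: row-major, i.e. order by (row, col)
  firstpix <- vapply(by_lab[keep], function(ii) {
    r <- (ii - 1L) %% H; cl <- (ii - 1L) %/% H
    min(r * W + cl)
  }, 0)
  keep <- keep[order(firstpix)]
  out_lab <- matrix(0L, H, W)
  top <- 2^bit_depth - 1
  n <- length(keep)
  cells <- data.frame(label = seq_len(n), area_px = 0L,
                      row_px = 0, col_px = 0,
                      mean_dapi = 0, mean_etbr = NA_real_,
                      mean_calcein = NA_real_, saturated_dapi = FALSE)
  for (k in seq_len(n)) {
    ii <- by_lab[[keep[k]]]
    out_lab[ii] <- k
    r <- (ii - 1L) %% H; cl <- (ii - 1L) %/% H
    cells$area_px[k] <- length(ii)
    cells$row_px[k] <- mean(r)
    cells$col_px[k] <- mean(cl)
    cells$mean_dapi[k] <- mean(dapi[ii])
    cells$saturated_dapi[k] <- any(dapi[ii] >= top)
    if (!is.null(etbr)) cells$mean_etbr[k] <- mean(etbr[ii])
    if (!is.null(calcein)) cells$mean_calcein[k] <- mean(calcein[ii])
  }
  list(labels = out_lab, cells = cells)
}

emptyCellTable <- function() {
  data.frame(label = integer(0), area_px = integer(0), row_px = numeric(0),
             col_px = numeric(0), mean_dapi = numeric(0),
             mean_etbr = numeric(0), mean_calcein = numeric(0),
             saturated_dapi = logical(0))
}

#' DAPI gate from control-cell intensities
#'
#' The gate is the control mean plus two standard deviations. In
#' `"sample"` mode these are the sample statistics (n-1 denominator); in
#' `"gaussian_fit"` mode a Gaussian is fitted to the intensity histogram
#' by least squares and the gate is `mu + 2 sigma` of the fit, which is
#' robust to a contaminated upper tail.
#'
#' @param control_mean_intensities Per-cell mean DAPI intensities of
#'   living control cells (>= 2 values; >= 10 for `gaussian_fit`).
#' @param mode `"sample"` or `"gaussian_fit"`.
#' @return The threshold (counts).
#' @examples
#' computeDapiThreshold(c(1, 2, 3))  # 2 + 2*1 = 4
#' @export
computeDapiThreshold <- function(control_mean_intensities, mode = "sample") {
  x <- as.numeric(control_mean_intensities)
  if (mode == "sample") {
    if (length(x) < 2L)
      stopValidation("sample mode needs at least 2 control intensities")
    mean(x) + 2 * sd(x)
  } else if (mode == "gaussian_fit") {
    if (length(x) < 10L)
      stopValidation("gaussian_fit mode needs at least 10 control intensities")
    fit <- fitGaussianToHistogram(x)
    fit[["mu"]] + 2 * fit[["sigma"]]
  } else stopValidation("unknown threshold mode '%s'", mode)
}

# Least-squares Gaussian fit to a histogram of intensities.
fitGaussianToHistogram <- function(x, nbins = 64L) {
  h <- hist(x, breaks = nbins, plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  start <- c(A = max(cnt), mu = mean(x), sigma = max(sd(x), diff(mids[1:2])))
  obj <- function(p) {
    if (p[3] <= 0) return(Inf)
    sum((cnt - p[1] * exp(-(mids - p[2])^2 / (2 * p[3]^2)))^2)
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  c(mu = fit$par[[2]], sigma = abs(fit$par[[3]]))
}

#' Derive all three gates from a segmented control region
#'
#' The DAPI gate comes from the control cells' mean DAPI intensities
#' ([computeDapiThreshold()]); the EtBr and calcein gates use the same
#' mean + 2 SD construction applied to the background pixels
#' (label 0) of the respective control channel, i.e. they ask for signal
#' clearly above the channel's background.
#'
#' @param control_seg Result of [segmentDapi()] on the control images
#'   (with `etbr` and `calcein` supplied).
#' @param etbr,calcein The raw control channel matrices.
#' @param mode Passed to [computeDapiThreshold()].
#' @return A [ThresholdSet-class].
#' @export
thresholdsFromControls <- function(control_seg, etbr, calcein,
                                   mode = "sample") {
  bg <- control_seg$labels == 0L
  if (!any(bg))
    stopValidation("control region has no background pixels")
  bgGate <- function(ch) max(mean(ch[bg]) + 2 * sd(ch[bg]), 1)
  ThresholdSet(
    dapi_threshold = computeDapiThreshold(control_seg$cells$mean_dapi, mode),
    etbr_threshold = bgGate(etbr),
    calcein_threshold = bgGate(calcein),
    mode = mode
  )
}

#' Classify segmented cells from their channel intensities
#'
#' Two-step rule: a cell whose mean DAPI is at or below the gate is
#' `intact` (membrane unaffected); above the gate, high EtBr means
#' `dead`; otherwise clear calcein means `optoporated_alive`; a
#' DAPI-positive cell with neither EtBr nor calcein signal is flagged
#' `ambiguous` (the cases the bench workflow sent to manual inspection).
#'
#' @param cells Cell `data.frame` from [segmentDapi()] (or any table with
#'   `mean_dapi`, `mean_etbr`, `mean_calcein`).
#' @param thresholds A [ThresholdSet-class].
#' @return The table with a `class` column appended.
#' @export
classifyCells <- function(cells, thresholds) {
  stopifnot(is(thresholds, "ThresholdSet"))
  cls <- character(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    if (cells$mean_dapi[k] <= thresholds@dapi_threshold) cls[k] <- "intact"
    else if (!is.na(cells$mean_etbr[k]) &&
             cells$mean_etbr[k] >= thresholds@etbr_threshold) cls[k] <- "dead"
    else if (!is.na(cells$mean_calcein[k]) &&
             cells$mean_calcein[k] >= thresholds@calcein_threshold)
      cls[k] <- "optoporated_alive"
    else cls[k] <- "ambiguous"
  }
  cells$class <- cls
  cells
}

#' Summarize classified cells into the dead / optoporated ratios
#'
#' `r_d = N_dead / N_total` and `r_o = N_optoporated / N_total`;
#' ambiguous cells count in `N_total` only.
#'
#' @param classes Character vector of per-cell classes.
#' @return An [OutcomeSummary-class].
#' @export
summarizeOutcomes <- function(classes) {
  if (length(classes) == 0L)
    stopValidation("cannot summarize an empty cell list")
  bad <- setdiff(unique(classes), c(cellClasses(), "ambiguous"))
  if (length(bad))
    stopValidation("unknown cell class: %s", paste(bad, collapse = ", "))
  n <- length(classes)
  nd <- sum(classes == "dead")
  no <- sum(classes == "optoporated_alive")
  new("OutcomeSummary",
      N_total = as.integer(n),
      N_intact = as.integer(sum(classes == "intact")),
      N_dead = as.integer(nd),
      N_optoporated = as.integer(no),
      N_ambiguous = as.integer(sum(classes == "ambiguous")),
      r_d = nd / n, r_o = no / n)
}

#' Tidy table of outcome summaries across conditions
#'
#' @param groups Named list of [OutcomeSummary-class] objects, e.g. one
#'   per laser power.
#' @return `data.frame` with one row per condition: `condition`,
#'   `N_total`, `N_intact`, `N_dead`, `N_optoporated`, `N_ambiguous`,
#'   `r_d`, `r_o`.
#' @export
tabulateByCondition <- function(groups) {
  if (length(groups) == 0L)
    stopValidation("no conditions to tabulate")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stopValidation("conditions must be named")
  rows <- lapply(names(groups), function(nm) {
    s <- groups[[nm]]
    stopifnot(is(s, "OutcomeSummary"))
    data.frame(condition = nm, N_total = s@N_total, N_intact = s@N_intact,
               N_dead = s@N_dead, N_optoporated = s@N_optoporated,
               N_ambiguous = s@N_ambiguous, r_d = s@r_d, r_o = s@r_o,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
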