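## Independent oracles and fixture builders. Each oracle restates the
## rule it checks from scratch (plain R, no package internals) so that
## implementation and reference can only agree by computing the same
## mathematics.

# Literal restatement of the threshold + hysteresis edge rule as an
# explicit two-state machine over the raw profile (kernel width 0).
oracleFindEdges <- function(profile, thr, hyst) {
  events <- list()
  run_min <- profile[1]
  run_max <- profile[1]
  for (i in seq_along(profile)) {
    v <- profile[i]
    run_min <- min(run_min, v)
    run_max <- max(run_max, v)
    rising <- v >= run_min + thr + hyst
    falling <- v <= run_max - (thr - hyst)
    if (rising) {
      events[[length(events) + 1L]] <- list(index = i - 1L, pol = "rising")
      run_min <- v; run_max <- v
    } else if (falling) {
      events[[length(events) + 1L]] <- list(index = i - 1L, pol = "falling")
      run_min <- v; run_max <- v
    }
  }
  if (length(events) == 0L)
    return(data.frame(index_px = integer(0), polarity = character(0)))
  data.frame(index_px = vapply(events, function(e) e$index, 0L),
             polarity = vapply(events, function(e) e$pol, ""))
}

# O(n^2) greedy thinning: explicit pairwise-distance double loop.
oracleDedup <- function(x_um, y_um, min_sep) {
  kept <- integer(0)
  for (i in seq_along(x_um)) {
    ok <- TRUE
    for (j in kept) {
      if (sqrt((x_um[i] - x_um[j])^2 + (y_um[i] - y_um[j])^2) < min_sep) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Brute-force grayscale erosion / dilation with an explicitly
# re-derived disk element; the neighborhood is restricted to in-image
# pixels at the border (the convention of the implementation).
oracleDiskOffsets <- function(r) {
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= r^2, ]
}

oracleErode <- function(img, r) {
  off <- oracleDiskOffsets(r)
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dr[k]; jj <- j + off$dc[k]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- min(vals)
  }
  out
}

oracleDilate <- function(img, r) {
  off <- oracleDiskOffsets(r)
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(0)
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dr[k]; jj <- j + off$dc[k]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- max(vals)
  }
  out
}

oracleOpening <- function(img, r) {
  opened <- oracleDilate(oracleErode(img, r), r)
  pmin(opened, img)
}

# Shift-based grayscale reconstruction by dilation (8-connected),
# independent of EBImage: per iteration the marker becomes the pointwise
# min of the mask and the max over the 3 x 3 neighborhood, assembled
# from shifted copies.
oracleReconstruct <- function(marker, mask) {
  marker <- pmin(marker, mask)
  H <- nrow(marker); W <- ncol(marker)
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    mx <- marker
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      mx <- pmax(mx, shift(marker, dr, dc))
    }
    nxt <- pmin(mx, mask)
    if (identical(nxt, marker)) return(marker)
    marker <- nxt
  }
}

oracleExtendedMaxima <- function(img, h, delta = 1) {
  hm <- oracleReconstruct(img - h, img)
  (hm - oracleReconstruct(hm - delta, hm)) > delta / 2
}

# Normal-equations plane fit: solve (A'A) beta = A'z directly.
oraclePlaneFit <- function(x, y, z) {
  A <- cbind(x, y, 1)
  solve(t(A) %*% A, t(A) %*% z)[, 1]
}

# Re-sum a run log event by event, recomputing each duration from the
# timing constants and the target geometry.
oracleRunElapsed <- function(targets_by_fov, plan, timing) {
  total <- 0
  tiles <- planTiles(plan)
  fw <- plan@grid@fov_width_um; fh <- plan@grid@fov_height_um
  for (t in seq_len(nrow(tiles))) {
    key <- sprintf("%d,%d", tiles$i[t], tiles$j[t])
    tg <- targets_by_fov[[key]]
    n <- if (is.null(tg)) 0L else nrow(tg)
    total <- total + timing@fov_reposition_ms + timing@camera_exposure_ms +
      timing@detection_ms_per_position * n
    cx <- fw / 2; cy <- fh / 2
    for (p in seq_len(n)) {
      d <- sqrt((tg$x_um[p] - cx)^2 + (tg$y_um[p] - cy)^2)
      total <- total + timing@stage_overhead_ms +
        timing@stage_ms_per_10um * max(d, 10) / 10 +
        timing@illumination_ms + timing@shutter_latency_ms
      cx <- tg$x_um[p]; cy <- tg$y_um[p]
    }
  }
  total
}

## ---- fixture builders ---------------------------------------------------

# Ground truth whose cells are disjoint 2 x 2 blocks laid on a grid, with
# a target table realising the requested per-cell position counts.
buildCountsFixture <- function(counts_per_cell) {
  n <- length(counts_per_cell)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  H <- nrow_grid * 6L; W <- ncol_grid * 6L
  lab <- matrix(0L, H, W)
  rows <- integer(0); cols <- integer(0)
  cells <- data.frame(label = seq_len(n), row_px = 0, col_px = 0,
                      radius_um = 1, class = "intact",
                      dapi = 0, etbr = 0, calcein = 0)
  for (k in seq_len(n)) {
    gi <- (k - 1L) %/% ncol_grid
    gj <- (k - 1L) %% ncol_grid
    r0 <- gi * 6L + 2L; c0 <- gj * 6L + 2L          # 1-based block corner
    lab[r0:(r0 + 1L), c0:(c0 + 1L)] <- k
    cells$row_px[k] <- r0 - 1L + 0.5
    cells$col_px[k] <- c0 - 1L + 0.5
    cnt <- counts_per_cell[k]
    if (cnt > 0) {
      pix <- list(c(r0, c0), c(r0, c0 + 1L), c(r0 + 1L, c0), c(r0 + 1L, c0 + 1L))
      for (m in seq_len(cnt)) {
        rows <- c(rows, pix[[m]][1] - 1L)
        cols <- c(cols, pix[[m]][2] - 1L)
      }
    }
  }
  truth <- new("GroundTruth", cells = cells, label_image = lab)
  targets <- data.frame(id = seq_along(rows), row_px = rows, col_px = cols,
                        x_um = cols * 1.0, y_um = rows * 1.0,
                        rake_line_index = 0L, status = "pending",
                        stringsAsFactors = FALSE)
  list(truth = truth, targets = targets)
}

# Distance of a point to the nearest ground-truth cell contour.
distanceToContours <- function(row_px, col_px, truth, pixel_size_um) {
  cells <- truthCells(truth)
  min(abs(sqrt((cells$row_px - row_px)^2 + (cells$col_px - col_px)^2) -
            cells$radius_um / pixel_size_um))
}

# A clean (noise-free) bright-field test scene shared by the detector
# monotonicity checks.
cleanScene <- function(n_cells = 25, seed = 42, noise_sd = 0) {
  generateBrightField(SceneSpec(
    image_height_px = 360, image_width_px = 360, pixel_size_um = 0.5,
    n_cells = n_cells, cell_radius_um = c(5, 9), edge_contrast = 50,
    noise_sd = noise_sd, seed = seed))
}

# Fluorescence dish with the published-style class mixture.
mixedDish <- function(n_cells, seed,
                      fractions = c(intact = 0.2, optoporated_alive = 0.67,
                                    dead = 0.13),
                      side_px = 640) {
  generateFluorescence(SceneSpec(
    image_height_px = side_px, image_width_px = side_px, pixel_size_um = 1,
    n_cells = n_cells, cell_radius_um = c(4, 7), noise_sd = 10,
    class_fractions = fractions, seed = seed))
}

controlThresholds <- function(seed = 991, n_cells = 80, side_px = 512) {
  ctl <- mixedDish(n_cells, seed, fractions = c(1, 0, 0), side_px = side_px)
  cseg <- segmentDapi(ctl$dapi, SegmentationParams(),
                      etbr = ctl$etbr, calcein = ctl$calcein)
  thresholdsFromControls(cseg, ctl$etbr, ctl$calcein)
}
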