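test_that("meander plans are serpentine, complete and grid-adjacent", {
  expect_equal(planTiles(planMeander(FOVGrid(1, 1)))[, c("i", "j")],
               data.frame(i = 0L, j = 0L))
  t22 <- planTiles(planMeander(FOVGrid(2, 2)))
  expect_equal(t22$i, c(0L, 0L, 1L, 1L))
  expect_equal(t22$j, c(0L, 1L, 1L, 0L))

  for (nr in 1:5) for (nc in 1:5) {
    t <- planTiles(planMeander(FOVGrid(nr, nc, 100, 80)))
    expect_equal(nrow(t), nr * nc)
    expect_equal(anyDuplicated(paste(t$i, t$j)), 0L)
    if (nrow(t) > 1)
      expect_true(all(abs(diff(t$i)) + abs(diff(t$j)) == 1))
  }

  # stage coordinates follow the grid geometry
  g <- FOVGrid(3, 2, fov_width_um = 280, fov_height_um = 220,
               origin_stage_um = c(100, 50))
  t <- planTiles(planMeander(g))
  expect_equal(t$x_um, 100 + t$j * 280)
  expect_equal(t$y_um, 50 + t$i * 220)
})

test_that("focus-plane fitting recovers exact planes and matches the normal-equations oracle", {
  xy <- expand.grid(x_um = seq(0, 1000, by = 250), y_um = seq(0, 800, by = 200))
  z <- 0.01 * xy$x_um - 0.02 * xy$y_um + 50
  pl <- fitFocusPlane(data.frame(xy, z_um = z))
  expect_equal(pl@a, 0.01, tolerance = 1e-9)
  expect_equal(pl@b, -0.02, tolerance = 1e-9)
  expect_equal(pl@c, 50, tolerance = 1e-9)
  expect_lt(pl@rms_residual_um, 1e-9)

  tri <- data.frame(x_um = c(0, 90, 10), y_um = c(0, 5, 80),
                    z_um = c(1, 4, -2))
  expect_lt(fitFocusPlane(tri)@rms_residual_um, 1e-9)

  set.seed(12)
  pts <- data.frame(x_um = runif(50, 0, 2000), y_um = runif(50, 0, 2000))
  pts$z_um <- 0.004 * pts$x_um + 0.013 * pts$y_um + 30 + rnorm(50, 0, 0.5)
  pl2 <- fitFocusPlane(pts)
  beta <- oraclePlaneFit(pts$x_um, pts$y_um, pts$z_um)
  expect_equal(c(pl2@a, pl2@b, pl2@c), unname(beta), tolerance = 1e-9)

  expect_error(fitFocusPlane(pts[1:2, ]), "at least 3")
  coll <- data.frame(x_um = 1:5, y_um = 2 * (1:5) + 1, z_um = rnorm(5))
  expect_error(fitFocusPlane(coll), "collinear")
})

test_that("predictFocusZ evaluates the plane linearly", {
  flat <- fitFocusPlane(data.frame(x_um = c(0, 10, 0), y_um = c(0, 0, 10),
                                   z_um = c(7, 7, 7)))
  expect_equal(predictFocusZ(flat, 123, -45), 7)
  tilt <- fitFocusPlane(data.frame(x_um = c(0, 100, 0), y_um = c(0, 0, 100),
                                   z_um = c(50, 52, 50)))
  expect_equal(predictFocusZ(tilt, 1000, 0) - predictFocusZ(tilt, 0, 0),
               tilt@a * 1000)
})

test_that("stage move time is linear with a 10 um floor", {
  tm <- TimingModel()
  expect_equal(stageMoveTime(10, tm), 35)
  expect_equal(stageMoveTime(0, tm), 35)   # accelerate/stop floor
  expect_equal(stageMoveTime(100, tm), 20 + 150)
  expect_error(stageMoveTime(-1, tm), "distance")
})

test_that("simulateRun accounts time exactly and brackets the shutter", {
  tm <- TimingModel()
  plan <- planMeander(FOVGrid(6, 6))
  empty <- simulateRun(list(), plan, tm)
  expect_equal(runTotals(empty)$elapsed_ms, 36 * (150 + 35))
  expect_equal(runTotals(empty)$throughput_per_s, 0)
  expect_setequal(unique(runEvents(empty)$kind),
                  c("fov_advance", "expose", "detect"))

  set.seed(7)
  for (rep in 1:20) {
    g <- FOVGrid(sample(1:3, 1), sample(1:3, 1), 280, 220)
    pl <- planMeander(g)
    keys <- sprintf("%d,%d", planTiles(pl)$i, planTiles(pl)$j)
    tby <- lapply(keys, function(k) {
      n <- sample(0:6, 1)
      data.frame(id = seq_len(n), x_um = runif(n, 0, 280),
                 y_um = runif(n, 0, 220))
    })
    names(tby) <- keys
    log <- simulateRun(tby, pl, tm)
    ev <- runEvents(log)
    # time conservation: elapsed equals the sum of event durations exactly
    expect_identical(runTotals(log)$elapsed_ms, sum(ev$duration_ms))
    # independent event-by-event re-summation
    expect_equal(runTotals(log)$elapsed_ms, oracleRunElapsed(tby, pl, tm))
    # shutter events alternate and bracket exactly illumination_ms
    sh <- ev[ev$kind %in% c("open_shutter", "close_shutter"), ]
    if (nrow(sh)) {
      expect_true(all(sh$kind == rep(c("open_shutter", "close_shutter"),
                                     nrow(sh) / 2)))
      expect_true(all(abs(sh$t_ms[sh$kind == "close_shutter"] -
                            sh$t_ms[sh$kind == "open_shutter"] -
                            tm@illumination_ms) < 1e-9))
    }
    expect_false(is.unsorted(ev$t_ms))
  }

  expect_error(simulateRun(list("9,9" = data.frame(id = 1, x_um = 0, y_um = 0)),
                           planMeander(FOVGrid(2, 2)), tm),
               "not in the plan")
})

test_that("the steady-state throughput sits in the published 7-8 positions/s band", {
  # 100 ms illumination; 10 um hops keep centring at 35 ms, inside 30-40
  tg <- data.frame(id = 1:200, x_um = rep(c(130, 140), 100), y_um = 110)
  log <- simulateRun(list("0,0" = tg), planMeander(FOVGrid(1, 1)), TimingModel())
  thr <- runTotals(log)$throughput_per_s
  expect_gte(thr, 7)
  expect_lte(thr, 8)
})

test_that("executeRun closes the loop over a synthetic dish", {
  grid <- FOVGrid(2, 2, fov_width_um = 80, fov_height_um = 80)
  spec <- SceneSpec(image_height_px = 320, image_width_px = 320,
                    pixel_size_um = 0.5, n_cells = 12,
                    cell_radius_um = c(5, 8), noise_sd = 0, seed = 5)
  bf <- generateBrightField(spec)
  plan <- planMeander(grid)
  params <- DetectionParams(pixel_size_um = 0.5)
  run <- executeRun(dishImageSource(bf$image, grid, 0.5), params, plan,
                    TimingModel())

  # log equals simulateRun fed with the detected (kept) targets
  kept <- lapply(run$targets_by_fov,
                 function(df) df[df$status == "illuminated", , drop = FALSE])
  sim <- simulateRun(kept, plan, TimingModel())
  expect_identical(runEvents(sim), runEvents(run$log))
  expect_identical(runTotals(sim), runTotals(run$log))

  # every cell crossed by a rake line receives at least one illumination
  s <- round(params@search_area_size_um / params@pixel_size_um)
  cells <- truthCells(bf$truth)
  crossed <- vapply(seq_len(nrow(cells)), function(k) {
    rows <- seq(0, 319, by = s) %% 160       # rake rows inside each tile
    r_tile <- cells$row_px[k] %% 160
    any(abs(rows - r_tile) <= cells$radius_um[k] / 0.5 - 1.5)
  }, TRUE)
  hit <- rep(FALSE, nrow(cells))
  h_px <- 160L
  for (key in names(run$targets_by_fov)) {
    ij <- as.integer(strsplit(key, ",")[[1]])
    df <- run$targets_by_fov[[key]]
    df <- df[df$status == "illuminated", , drop = FALSE]
    if (!nrow(df)) next
    glob_r <- df$row_px + ij[1] * h_px
    glob_c <- df$col_px + ij[2] * h_px
    lab <- labelImage(bf$truth)[cbind(glob_r + 1L, glob_c + 1L)]
    hit[lab[lab > 0]] <- TRUE
  }
  expect_true(all(hit[crossed]))

  # empty dish: only housekeeping events
  blank <- matrix(1000, 320, 320)
  run0 <- executeRun(dishImageSource(blank, grid, 0.5), params, plan,
                     TimingModel())
  expect_setequal(unique(runEvents(run0$log)$kind),
                  c("fov_advance", "expose", "detect"))
  expect_equal(runTotals(run0$log)$positions_illuminated, 0L)
})

test_that("hardware contract violations abort with a diagnostic", {
  grid <- FOVGrid(1, 1, 80, 80)
  img <- matrix(1000, 160, 160)
  plan <- planMeander(grid)
  params <- DetectionParams(pixel_size_um = 0.5)
  expect_error(
    executeRun(dishImageSource(img, grid, 0.5), params, plan, TimingModel(),
               stage = virtualStage(position_error_um = 0.5)),
    "stage contract violation")
  sh <- virtualShutter()
  sh$open()
  expect_error(sh$open(), "already open")
  sh$close()
  expect_error(sh$close(), "already closed")
})

test_that("focus-plane correction drives the commanded z during a run", {
  grid <- FOVGrid(1, 2, fov_width_um = 80, fov_height_um = 80)
  spec <- SceneSpec(image_height_px = 160, image_width_px = 320,
                    pixel_size_um = 0.5, n_cells = 6,
                    cell_radius_um = c(5, 8), noise_sd = 0, seed = 9)
  bf <- generateBrightField(spec)
  plane <- fitFocusPlane(data.frame(x_um = c(0, 100, 0), y_um = c(0, 0, 100),
                                    z_um = c(50, 51, 50)))
  stage <- virtualStage()
  run <- executeRun(dishImageSource(bf$image, grid, 0.5),
                    DetectionParams(pixel_size_um = 0.5), planMeander(grid),
                    TimingModel(), stage = stage, focus_plane = plane)
  p <- stage$position()
  expect_equal(p[["z"]], predictFocusZ(plane, p[["x"]], p[["y"]]))
})
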