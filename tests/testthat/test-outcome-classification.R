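test_that("histogram normalization anchors the stated percentiles", {
  const <- matrix(700, 30, 30)
  expect_identical(normalizeHistogram(const), const)

  set.seed(5)
  img <- matrix(runif(10000, 0, 4095), 100)
  out <- normalizeHistogram(img, 12)
  expect_true(all(out >= 0 & out <= 4095))
  # values at the anchor percentiles map to the extremes
  q <- quantile(img, c(0.005, 0.995), names = FALSE)
  expect_lt(max(out[img <= q[1]]), 1e-9)
  expect_equal(min(out[img >= q[2]]), 4095)
  # an image already spanning the range keeps its extremes
  expect_equal(range(normalizeHistogram(img, 12)), c(0, 4095))
})

test_that("grayscale opening suppresses small peaks and matches the oracle", {
  img <- matrix(100, 20, 20)
  expect_identical(suppressPeaks(img, 0), img)

  spike <- matrix(100, 21, 21)
  spike[11, 11] <- 4000
  cleaned <- suppressPeaks(spike, 1)
  expect_equal(cleaned[11, 11], 100)
  expect_true(all(cleaned == 100))

  set.seed(8)
  rnd <- matrix(round(runif(500, 0, 120)), 20)
  for (r in c(1L, 2L)) {
    got <- suppressPeaks(rnd, r)
    expect_equal(got, oracleOpening(rnd, r), tolerance = 1e-9)
    expect_true(all(got <= rnd))                       # anti-extensive
    expect_equal(suppressPeaks(got, r), got, tolerance = 1e-9)  # idempotent
  }
})

test_that("extended h-maxima separates close blobs and matches an independent reconstruction", {
  gauss <- function(H, W, r0, c0, A, s)
    outer(seq_len(H), seq_len(W),
          function(r, c) A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2)))
  blobs <- round(gauss(40, 60, 20, 20, 100, 3) + gauss(40, 60, 20, 40, 100, 3))
  em <- optopore:::extendedMaxima(blobs, 20)
  expect_identical(em, oracleExtendedMaxima(blobs, 20))
  expect_equal(max(EBImage::bwlabel(em)), 2)

  set.seed(30)
  rnd <- matrix(round(runif(400, 0, 60)), 20)
  expect_identical(optopore:::extendedMaxima(rnd, 15),
                   oracleExtendedMaxima(rnd, 15))
})

test_that("segmentDapi finds no cells in flat images and recovers synthetic nuclei", {
  params <- SegmentationParams()
  flat <- segmentDapi(matrix(1000, 64, 64), params)
  expect_equal(nrow(flat$cells), 0L)
  expect_true(all(flat$labels == 0L))

  fl <- mixedDish(40, seed = 61, side_px = 448)
  seg <- segmentDapi(fl$dapi, params, etbr = fl$etbr, calcein = fl$calcein)
  tr <- truthCells(fl$truth)
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((seg$cells$row_px - tr$row_px[i])^2 +
               (seg$cells$col_px - tr$col_px[i])^2)), 0)
  expect_gte(sum(d <= 3), ceiling(0.95 * nrow(tr)))
  # labels are 1..K in raster order of first pixel
  expect_equal(seg$cells$label, seq_len(nrow(seg$cells)))
  expect_error(segmentDapi(fl$dapi, params, etbr = matrix(0, 2, 2)),
               "dimensions")
})

test_that("per-cell means are measured on the raw channels and saturation is flagged", {
  models <- defaultChannelModels()
  models$dead$dapi <- c(6000, 0)
  spec <- SceneSpec(image_height_px = 128, image_width_px = 128,
                    pixel_size_um = 1, n_cells = 4, cell_radius_um = c(5, 7),
                    noise_sd = 0, class_fractions = c(0, 0, 1),
                    channel_models = models, seed = 2)
  fl <- generateFluorescence(spec)
  seg <- segmentDapi(fl$dapi, SegmentationParams(), etbr = fl$etbr,
                     calcein = fl$calcein)
  expect_true(all(seg$cells$saturated_dapi))
  expect_true(all(seg$cells$mean_dapi == 4095))
})

test_that("the DAPI gate is the control mean plus two sample SDs", {
  expect_equal(computeDapiThreshold(rep(850, 5)), 850)
  expect_equal(computeDapiThreshold(c(1, 2, 3)), 4)   # sd({1,2,3}) = 1
  expect_error(computeDapiThreshold(1000), "at least 2")
  expect_error(computeDapiThreshold(rnorm(5), mode = "gaussian_fit"),
               "at least 10")
  expect_error(computeDapiThreshold(1:5, mode = "median"), "unknown")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(314)
  draws <- rnorm(10000, 1000, 100)
  thr <- computeDapiThreshold(draws)
  expect_equal(thr, 1200, tolerance = 0.01)
  # the gate's false-positive rate on control cells is the one-sided
  # 2-sigma tail, ~2.28%
  expect_equal(mean(draws > thr), pnorm(2, lower.tail = FALSE),
               tolerance = 3 * sqrt(0.0228 * 0.9772 / 10000) / 0.0228)
  thr_fit <- computeDapiThreshold(draws, mode = "gaussian_fit")
  expect_equal(thr_fit, 1200, tolerance = 0.02)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
})

test_that("the two-step classification rule gates DAPI, then EtBr, then calcein", {
  th <- ThresholdSet(1200, 150, 150)
  cells <- data.frame(
    mean_dapi = c(900, 3000, 3000, 3000, 1200),
    mean_etbr = c(2000, 2000, 40, 40, 40),
    mean_calcein = c(2000, 40, 2000, 40, 2000))
  got <- classifyCells(cells, th)$class
  expect_equal(got, c("intact",          # below the DAPI gate, whatever else
                      "dead",            # high EtBr
                      "optoporated_alive",
                      "ambiguous",       # DAPI+ but no EtBr and no calcein
                      "intact"))         # boundary: at the gate counts intact
})

test_that("outcome summaries follow the ratio definitions and partition the cells", {
  s0 <- summarizeOutcomes(rep("intact", 10))
  expect_equal(s0@r_d, 0)
  expect_equal(s0@r_o, 0)

  s <- summarizeOutcomes(c(rep("dead", 2), rep("optoporated_alive", 3),
                           rep("intact", 5)))
  expect_equal(s@r_d, 0.2)
  expect_equal(s@r_o, 0.3)
  expect_equal(s@N_total, 10L)

  expect_error(summarizeOutcomes(character(0)), "empty")
  expect_error(summarizeOutcomes(c("intact", "zombie")), "unknown")

  set.seed(44)
  for (rep in 1:10) {
    cls <- sample(c(cellClasses(), "ambiguous"), 50, replace = TRUE)
    s <- summarizeOutcomes(cls)
    expect_equal(s@N_intact + s@N_dead + s@N_optoporated + s@N_ambiguous,
                 s@N_total)
    expect_lte(s@r_d + s@r_o, 1)
  }
})

test_that("tabulateByCondition assembles per-group summaries into one table", {
  one <- summarizeOutcomes(c("dead", "intact", "intact", "intact"))
  two <- summarizeOutcomes(c(rep("optoporated_alive", 3), "intact"))
  tab <- tabulateByCondition(list(`6mW` = one, `12mW` = two))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$r_d, c(0.25, 0))
  expect_equal(tab$r_o, c(0, 0.75))
  expect_equal(tab$condition, c("6mW", "12mW"))
  expect_error(tabulateByCondition(list()), "no conditions")
  expect_error(tabulateByCondition(list(one)), "named")
})

test_that("control-derived thresholds gate the mixed dish close to its truth", {
  th <- controlThresholds(seed = 991, n_cells = 60, side_px = 448)
  expect_equal(th@dapi_threshold, 1200, tolerance = 0.05)
  expect_lt(th@etbr_threshold, 200)
  expect_lt(th@calcein_threshold, 300)

  fl <- mixedDish(80, seed = 71, side_px = 576)
  seg <- segmentDapi(fl$dapi, SegmentationParams(), etbr = fl$etbr,
                     calcein = fl$calcein)
  s <- summarizeOutcomes(classifyCells(seg$cells, th)$class)
  truth_tab <- table(factor(truthCells(fl$truth)$class,
                            levels = c(cellClasses())))
  expect_equal(s@N_dead, unname(truth_tab["dead"]), tolerance = 3)
  expect_equal(s@N_optoporated, unname(truth_tab["optoporated_alive"]),
               tolerance = 3)
})
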