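#' Default class-conditional fluorescence intensity models
#'
#' Per class, per channel `c(mean, sd)` of the true cell-mean intensity in
#' raw 12-bit counts. The control (intact) DAPI model is centred at 1000
#' counts with sd 100, the location of the control peak on a 12-bit
#' camera; perforated classes (optoporated-alive, dead) sit well above the
#' control-mean-plus-2-SD gate, with tails that saturate the 12-bit range.
#' EtBr is near background except in dead cells; calcein is bright in
#' living cells (intact and optoporated) and near zero in dead ones.
#'
#' @return Named list with entries `intact`, `optoporated_alive`, `dead`,
#'   each a list of `dapi`, `etbr`, `calcein` models.
#' @export
defaultChannelModels <- function() {
  list(
    intact = list(dapi = c(1000, 100), etbr = c(60, 15), calcein = c(2000, 200)),
    optoporated_alive = list(dapi = c(2600, 600), etbr = c(60, 15),
                             calcein = c(2000, 200)),
    dead = list(dapi = c(3000, 800), etbr = c(2000, 300), calcein = c(40, 15))
  )
}

#' Construct a synthetic scene specification
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param pixel_size_um Pixel pitch (um/px).
#' @param n_cells Number of cells.
#' @param cell_radius_um `c(min, max)` cell radius in um.
#' @param edge_contrast Amplitude of the bright-field contour ring (counts).
#' @param background_level Bright-field background (counts).
#' @param fluor_background_level Fluorescence background (counts).
#' @param noise_sd Additive Gaussian pixel noise sd (counts).
#' @param bit_depth 8 or 12.
#' @param class_fractions `(intact, optoporated_alive, dead)`, summing to 1.
#' @param channel_models See [defaultChannelModels()].
#' @param non_overlapping Place cells at least the sum of radii apart.
#' @param seed Integer root seed.
#' @return A validated [SceneSpec-class].
#' @examples
#' spec <- SceneSpec(n_cells = 5, seed = 7)
#' bf <- generateBrightField(spec)
#' dim(bf$image)
#' @export
SceneSpec <- function(image_height_px = 440L, image_width_px = 560L,
                      pixel_size_um = 0.5, n_cells = 60L,
                      cell_radius_um = c(5, 9), edge_contrast = 50,
                      background_level = 1000, fluor_background_level = 100,
                      noise_sd = 2, bit_depth = 12L,
                      class_fractions = c(intact = 1, optoporated_alive = 0,
                                          dead = 0),
                      channel_models = defaultChannelModels(),
                      non_overlapping = TRUE, seed = 1L) {
  cf <- as.numeric(class_fractions)
  names(cf) <- cellClasses()
  obj <- new("SceneSpec",
             image_height_px = as.integer(image_height_px),
             image_width_px = as.integer(image_width_px),
             pixel_size_um = as.numeric(pixel_size_um),
             n_cells = as.integer(n_cells),
             cell_radius_um = as.numeric(cell_radius_um),
             edge_contrast = as.numeric(edge_contrast),
             background_level = as.numeric(background_level),
             fluor_background_level = as.numeric(fluor_background_level),
             noise_sd = as.numeric(noise_sd),
             bit_depth = as.integer(bit_depth),
             class_fractions = cf,
             channel_models = channel_models,
             non_overlapping = isTRUE(non_overlapping),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

# Draw the latent scene: cell placement, classes and true channel means.
# Streams (root seed + fixed offset) keep the draw identical between the
# bright-field and fluorescence renderers:
#   placement (+0): radii, centres, interior offsets
#   classes (+2): class labels, sampled in one vectorised call
#   cell_intensity (+3): per-cell channel means, channels in the fixed
#     order dapi, etbr, calcein
sampleScene <- function(spec) {
  n <- spec@n_cells
  H <- spec@image_height_px; W <- spec@image_width_px
  px <- spec@pixel_size_um

  placement <- withSeed(streamSeed(spec@seed, "placement"), {
    radii_um <- runif(n, spec@cell_radius_um[1], spec@cell_radius_um[2])
    radii_px <- radii_um / px
    rows <- numeric(n); cols <- numeric(n)
    for (k in seq_len(n)) {
      r <- radii_px[k]
      if (2 * r + 2 > min(H, W))
        stopValidation("cell radius %.1f px does not fit the %d x %d image",
                       r, H, W)
      placed <- FALSE
      for (attempt in seq_len(5000L)) {
        cand_row <- runif(1, r + 1, H - r - 2)
        cand_col <- runif(1, r + 1, W - r - 2)
        if (!spec@non_overlapping || k == 1L) ok <- TRUE
        else {
          prev <- seq_len(k - 1L)
          d <- sqrt((rows[prev] - cand_row)^2 + (cols[prev] - cand_col)^2)
          # 2 px margin beyond the sum-of-radii floor keeps rings separable
          ok <- all(d >= radii_px[prev] + r + 2)
        }
        if (ok) { rows[k] <- cand_row; cols[k] <- cand_col; placed <- TRUE; break }
      }
      if (!placed)
        stopValidation("could not place %d non-overlapping cells in a %d x %d image",
                       n, H, W)
    }
    interior_offset <- runif(n, -1, 1) * spec@edge_contrast / 10
    list(rows = rows, cols = cols, radii_um = radii_um, radii_px = radii_px,
         interior_offset = interior_offset)
  })

  classes <- withSeed(streamSeed(spec@seed, "classes"), {
    if (n == 0L) character(0)
    else sample(cellClasses(), n, replace = TRUE, prob = spec@class_fractions)
  })

  means <- withSeed(streamSeed(spec@seed, "cell_intensity"), {
    out <- matrix(0, nrow = n, ncol = 3,
                  dimnames = list(NULL, c("dapi", "etbr", "calcein")))
    for (ch in c("dapi", "etbr", "calcein")) {
      mu <- vapply(classes, function(cl) spec@channel_models[[cl]][[ch]][1], 0)
      sdv <- vapply(classes, function(cl) spec@channel_models[[cl]][[ch]][2], 0)
      out[, ch] <- pmax(0, rnorm(n, mu, sdv))
    }
    out
  })

  c(placement, list(classes = classes, means = means))
}

# Paint the integer label image; cells drawn in label order, later labels
# overwrite earlier ones where masks overlap (only possible when
# non_overlapping = FALSE).
renderLabelImage <- function(scene, H, W) {
  lab <- matrix(0L, nrow = H, ncol = W)
  for (k in seq_along(scene$rows)) {
    r <- scene$radii_px[k]
    r0 <- max(1L, floor(scene$rows[k] - r)); r1 <- min(H, ceiling(scene$rows[k] + r) + 1L)
    c0 <- max(1L, floor(scene$cols[k] - r)); c1 <- min(W, ceiling(scene$cols[k] + r) + 1L)
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - 1) - scene$rows[k], (cc - 1) - scene$cols[k],
                function(a, b) a^2 + b^2)
    sub <- lab[rr, cc, drop = FALSE]
    sub[d2 <= r^2] <- k
    lab[rr, cc] <- sub
  }
  lab
}

sceneTruth <- function(scene, lab, spec) {
  n <- length(scene$rows)
  cells <- data.frame(
    label = seq_len(n),
    row_px = scene$rows,
    col_px = scene$cols,
    radius_um = scene$radii_um,
    class = if (n) scene$classes else character(0),
    dapi = if (n) scene$means[, "dapi"] else numeric(0),
    etbr = if (n) scene$means[, "etbr"] else numeric(0),
    calcein = if (n) scene$means[, "calcein"] else numeric(0),
    stringsAsFactors = FALSE
  )
  new("GroundTruth", cells = cells, label_image = lab)
}

#' Render a synthetic bright-field image
#'
#' Cells are rendered the way an adherent monolayer appears in bright
#' field at low contrast: a flat interior at the background level (plus a
#' small per-cell offset) bounded by a contour ring of amplitude
#' `edge_contrast` — the feature the rake edge detector responds to.
#' Additive Gaussian noise is applied, then values are clipped to the bit
#' depth and rounded to integer counts.
#'
#' @param spec A [SceneSpec-class].
#' @return `list(image, truth)`: the numeric matrix (counts) and the
#'   [GroundTruth-class].
#' @export
generateBrightField <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  H <- spec@image_height_px; W <- spec@image_width_px
  scene <- sampleScene(spec)
  img <- matrix(spec@background_level, nrow = H, ncol = W)
  ring_w <- 1.0  # px; contrast transition across the membrane
  for (k in seq_along(scene$rows)) {
    r <- scene$radii_px[k]
    r0 <- max(1L, floor(scene$rows[k] - r)); r1 <- min(H, ceiling(scene$rows[k] + r) + 1L)
    c0 <- max(1L, floor(scene$cols[k] - r)); c1 <- min(W, ceiling(scene$cols[k] + r) + 1L)
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - 1) - scene$rows[k], (cc - 1) - scene$cols[k],
                function(a, b) a^2 + b^2)
    sub <- img[rr, cc, drop = FALSE]
    sub[d2 <= r^2] <- spec@background_level + scene$interior_offset[k]
    ring <- d2 <= r^2 & d2 > (r - ring_w)^2
    sub[ring] <- spec@background_level + spec@edge_contrast
    img[rr, cc] <- sub
  }
  if (spec@noise_sd > 0)
    img <- img + withSeed(streamSeed(spec@seed, "bf_noise"),
                          matrix(rnorm(H * W, 0, spec@noise_sd), nrow = H))
  img <- round(clipToBitDepth(img, spec@bit_depth))
  lab <- renderLabelImage(scene, H, W)
  list(image = img, truth = sceneTruth(scene, lab, spec))
}

#' Render registered synthetic DAPI / EtBr / calcein images
#'
#' The three channels share one cell placement and label image. Each
#' cell's channel intensity is drawn from the class-conditional model in
#' `channel_models`; pixels inside the cell take that value plus Gaussian
#' noise, pixels outside sit at `fluor_background_level`. Values are
#' clipped to the bit depth (high DAPI means therefore pile up at the
#' 12-bit ceiling, as saturated cells do on a real camera) and rounded.
#'
#' @param spec A [SceneSpec-class].
#' @return `list(dapi, etbr, calcein, truth)`.
#' @export
generateFluorescence <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  H <- spec@image_height_px; W <- spec@image_width_px
  scene <- sampleScene(spec)
  lab <- renderLabelImage(scene, H, W)
  channels <- withSeed(streamSeed(spec@seed, "fl_noise"), {
    out <- list()
    for (ch in c("dapi", "etbr", "calcein")) {
      img <- matrix(spec@fluor_background_level, nrow = H, ncol = W)
      inside <- lab > 0L
      if (any(inside)) img[inside] <- scene$means[lab[inside], ch]
      if (spec@noise_sd > 0)
        img <- img + matrix(rnorm(H * W, 0, spec@noise_sd), nrow = H)
      out[[ch]] <- round(clipToBitDepth(img, spec@bit_depth))
    }
    out
  })
  list(dapi = channels$dapi, etbr = channels$etbr,
       calcein = channels$calcein, truth = sceneTruth(scene, lab, spec))
}
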