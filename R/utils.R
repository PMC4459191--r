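## Internal helpers shared across modules.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
# All package randomness flows through this so that a SceneSpec seed
# fully determines the rendered scene regardless of ambient RNG use.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Fixed offsets of the derived random streams (root seed + offset).
.streams <- c(placement = 0L, bf_noise = 1L, classes = 2L,
              cell_intensity = 3L, fl_noise = 4L)

streamSeed <- function(seed, stream) {
  as.integer(seed) + .streams[[stream]]
}

clipToBitDepth <- function(x, bit_depth) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

stopValidation <- function(...) {
  msg <- sprintf(...)
  cond <- structure(class = c("optopore_validation_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

stopIO <- function(...) {
  msg <- sprintf(...)
  cond <- structure(class = c("optopore_io_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

assertImage <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stopValidation("%s must be a nonempty numeric matrix", what)
  invisible(image)
}

emptyTargets <- function() {
  data.frame(id = integer(0), row_px = integer(0), col_px = integer(0),
              x_um = numeric(0), y_um = numeric(0),
              rake_line_index = integer(0), status = character(0),
              stringsAsFactors = FALSE)
}
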