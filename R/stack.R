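#' Acquisition calibration metadata
#'
#' Physical calibration attached to an image stack: pixel size, frame
#' interval, the frame at which agonist was added, and (optionally) the
#' frame range of a terminal Fsk/IBMX saturation epoch and the z step.
#'
#' Frame indices are 1-based, consistent with R indexing. The agonist frame
#' is the first frame acquired at or after agonist addition; time for frame
#' `i` is `(i - agonist_frame) * frame_interval` seconds, so the agonist
#' frame itself sits at t = 0.
#'
#' @param pixel_size Pixel size in micrometres per pixel. Must be positive.
#' @param frame_interval Frame interval in seconds (default 20, the
#'   acquisition rate used for the live-cell movies).
#' @param agonist_frame 1-based index of the first frame at/after agonist
#'   addition. Default 4 corresponds to a 1-minute baseline at 20 s frames
#'   (frames 1-3 are baseline).
#' @param fsk_frames Optional integer vector of frame indices belonging to
#'   the Fsk/IBMX saturation epoch.
#' @param z_step Optional z spacing in micrometres.
#' @return An object of class `calibration`.
#' @export
calibration <- function(pixel_size, frame_interval = 20, agonist_frame = 4L,
                        fsk_frames = NULL, z_step = NULL) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a positive finite number (um/px)")
  if (!is.null(frame_interval) && (!is.finite(frame_interval) || frame_interval <= 0))
    stop("'frame_interval' must be positive (seconds)")
  structure(list(pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 agonist_frame = as.integer(agonist_frame),
                 fsk_frames = if (!is.null(fsk_frames)) as.integer(fsk_frames),
                 z_step = z_step),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Calibration:", x$pixel_size, "um/px;",
      x$frame_interval, "s/frame; agonist at frame", x$agonist_frame, "\n")
  if (!is.null(x$fsk_frames))
    cat("  Fsk/IBMX frames:", min(x$fsk_frames), "-", max(x$fsk_frames), "\n")
  invisible(x)
}

#' Multi-dimensional image stack
#'
#' Wraps a numeric array in the fixed axis order (t, z, c, y, x) together
#' with its [calibration()]. Singleton axes are retained, so a single-plane
#' image has dimension `c(1, 1, 1, H, W)`.
#'
#' @param pixels Numeric array with 2 to 5 dimensions. Arrays with fewer
#'   than 5 dimensions are promoted by prepending singleton t/z/c axes
#'   (a matrix is interpreted as (y, x)).
#' @param calibration A [calibration()] object.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, calibration) {
  stopifnot(is.numeric(pixels), inherits(calibration, "calibration"))
  d <- dim(pixels)
  if (is.null(d)) stop("'pixels' must be an array, not a vector")
  if (length(d) > 5L) stop("at most 5 axes (t, z, c, y, x) are supported")
  if (length(d) < 5L) dim(pixels) <- c(rep(1L, 5L - length(d)), d)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  structure(list(pixels = pixels, calibration = calibration),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d t x %d z x %d c x %d y x %d x px, %.4g um/px\n",
              d[1], d[2], d[3], d[4], d[5], x$calibration$pixel_size))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Extract one 2-D frame from a stack
#'
#' @param stack An [image_stack()].
#' @param t,z,channel 1-based indices on the t, z and channel axes.
#' @return A numeric (y, x) matrix.
#' @export
get_frame <- function(stack, channel = 1L, t = 1L, z = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (t < 1L || t > d[1]) stop("'t' out of range")
  if (z < 1L || z > d[2]) stop("'z' out of range")
  if (channel < 1L || channel > d[3]) stop("'channel' out of range")
  matrix(stack$pixels[t, z, channel, , ], d[4], d[5])
}

#' Time axis of a stack or trace, minutes relative to agonist addition
#'
#' @param n_frames Number of frames.
#' @param calibration A [calibration()] object.
#' @return Numeric vector of length `n_frames`, in minutes; 0 at the
#'   agonist frame.
#' @export
frame_times_min <- function(n_frames, calibration) {
  (seq_len(n_frames) - calibration$agonist_frame) * calibration$frame_interval / 60
}

#' Binary region mask
#'
#' A logical (y, x) matrix with a provenance trail recording the chain of
#' operations that produced it.
#'
#' @param pixels Logical matrix.
#' @param provenance Character vector of operation descriptions.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(pixels, provenance = character()) {
  stopifnot(is.matrix(pixels))
  if (!is.logical(pixels)) {
    pixels <- pixels != 0
  }
  structure(list(pixels = pixels, provenance = provenance),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, area %d px\n",
              nrow(x$pixels), ncol(x$pixels), mask_area(x)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Foreground area of a mask in pixels
#' @param mask A [region_mask()] or logical matrix.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) {
  sum(as_mask_matrix(mask))
}

# Accept either a region_mask or a bare logical matrix.
as_mask_matrix <- function(mask) {
  if (inherits(mask, "region_mask")) mask$pixels
  else if (is.matrix(mask)) mask != 0
  else stop("expected a region_mask or a matrix")
}

with_provenance <- function(mask, ...) {
  region_mask(as_mask_matrix(mask),
              c(if (inherits(mask, "region_mask")) mask$provenance, ...))
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so simulators do not clobber user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
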