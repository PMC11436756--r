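#' Detect fluorescent spots as pruned local maxima
#'
#' Finds pixels that are strict-or-equal local maxima of their 3x3
#' neighbourhood, above an intensity threshold and inside the cell mask,
#' then greedily enforces a minimum separation: candidates are visited
#' brightest first and kept only if at least `min_separation_px` from
#' every spot already kept.
#'
#' @param image Numeric (y, x) matrix.
#' @param cell_mask Optional mask restricting the search.
#' @param intensity_threshold Minimum peak intensity (strict), or `NULL`
#'   for Otsu over the cell.
#' @param min_separation_px Minimum centre-to-centre distance, px.
#' @return A `spot_set`: data.frame (id, y, x, intensity) plus detection
#'   parameters in attributes.
#' @export
detect_spots <- function(image, cell_mask = NULL, intensity_threshold = NULL,
                         min_separation_px = 3) {
  stopifnot(is.matrix(image))
  cm <- if (is.null(cell_mask)) matrix(TRUE, nrow(image), ncol(image))
        else as_mask_matrix(cell_mask)
  if (is.null(intensity_threshold))
    intensity_threshold <- auto_threshold(image, restrict_to = cm)
  nr <- nrow(image); nc <- ncol(image)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- image
  is_max <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
    is_max <- is_max & (image >= nb)
  }
  cand <- which(is_max & cm & image > intensity_threshold, arr.ind = TRUE)
  out <- data.frame(id = integer(), y = numeric(), x = numeric(),
                    intensity = numeric())
  if (nrow(cand) > 0L) {
    inten <- image[cand]
    ord <- order(-inten, cand[, 1], cand[, 2])  # brightest first, stable
    keep_y <- numeric(0); keep_x <- numeric(0); keep_i <- numeric(0)
    for (k in ord) {
      y <- cand[k, 1]; x <- cand[k, 2]
      if (length(keep_y) == 0L ||
          all((keep_y - y)^2 + (keep_x - x)^2 >= min_separation_px^2)) {
        keep_y <- c(keep_y, y); keep_x <- c(keep_x, x)
        keep_i <- c(keep_i, inten[k])
      }
    }
    out <- data.frame(id = seq_along(keep_y), y = keep_y, x = keep_x,
                      intensity = keep_i)
  }
  attr(out, "intensity_threshold") <- intensity_threshold
  attr(out, "min_separation_px") <- min_separation_px
  class(out) <- c("spot_set", "data.frame")
  out
}

#' Classify spots as colocalized with a reference compartment
#'
#' A spot colocalizes when its centre lies within `max_distance_um` of the
#' nearest reference-mask pixel centre, the boundary inclusive ("1 um or
#' less"); spots inside the mask have distance 0. Distances are read from
#' the Euclidean [distance_map()] at the spot position (rounded to the
#' nearest pixel, or bilinearly interpolated with `interpolate = TRUE`).
#'
#' @param spots A `spot_set` (or data.frame with y, x columns, px).
#' @param reference_mask [region_mask()] or logical matrix of the
#'   reference compartment.
#' @param pixel_size um/px.
#' @param max_distance_um Colocalization radius, default 1.0 um.
#' @param interpolate Bilinear interpolation of the distance map at
#'   sub-pixel spot positions?
#' @return A `coloc_result` list: `per_spot` data.frame (id, y, x,
#'   distance_um, colocalized), `n_spots_total`, `n_colocalized`,
#'   `max_distance_um`.
#' @export
classify_colocalized <- function(spots, reference_mask, pixel_size,
                                 max_distance_um = 1.0,
                                 interpolate = FALSE) {
  stopifnot(pixel_size > 0)
  m <- as_mask_matrix(reference_mask)
  empty <- !any(m)
  dm <- if (empty) {
    warning("empty reference mask: no spot can colocalize")
    matrix(Inf, nrow(m), ncol(m))
  } else distance_map(m, pixel_size)
  n <- nrow(spots)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    y <- spots$y[i]; x <- spots$x[i]
    if (interpolate) {
      dist[i] <- bilinear_at(dm, y, x)
    } else {
      dist[i] <- dm[max(1L, min(nrow(dm), round(y))),
                    max(1L, min(ncol(dm), round(x)))]
    }
  }
  per_spot <- data.frame(id = if (n) spots$id else integer(),
                         y = spots$y, x = spots$x,
                         distance_um = dist,
                         colocalized = dist <= max_distance_um)
  structure(list(per_spot = per_spot, n_spots_total = n,
                 n_colocalized = sum(per_spot$colocalized),
                 max_distance_um = max_distance_um),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d / %d spots within %.3g um\n",
              x$n_colocalized, x$n_spots_total, x$max_distance_um))
  invisible(x)
}

bilinear_at <- function(img, y, x) {
  y <- max(1, min(nrow(img), y)); x <- max(1, min(ncol(img), x))
  y0 <- floor(y); x0 <- floor(x)
  y1 <- min(nrow(img), y0 + 1L); x1 <- min(ncol(img), x0 + 1L)
  fy <- y - y0; fx <- x - x0
  img[y0, x0] * (1 - fy) * (1 - fx) + img[y1, x0] * fy * (1 - fx) +
    img[y0, x1] * (1 - fy) * fx + img[y1, x1] * fy * fx
}
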