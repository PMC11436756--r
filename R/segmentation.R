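#' Maximum-intensity z-projection
#'
#' Per-pixel maximum over the z axis for one channel and timepoint, the
#' projection the fixed-cell quantifications are performed on.
#'
#' @param stack An [image_stack()].
#' @param channel,t 1-based channel and frame indices.
#' @return Numeric (y, x) matrix.
#' @export
max_project_z <- function(stack, channel = 1L, t = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (d[2] < 1L) stop("empty z axis")
  if (t < 1L || t > d[1]) stop("'t' out of range")
  if (channel < 1L || channel > d[3]) stop("'channel' out of range")
  sub <- stack$pixels[t, , channel, , , drop = FALSE]
  matrix(apply(sub, c(4, 5), max), d[4], d[5])
}

#' Maximum-intensity temporal projection
#'
#' Per-pixel maximum over time (after z-projection when the stack is
#' multi-z), used to refine the cell ROI in the live-cell pipeline.
#'
#' @inheritParams max_project_z
#' @return Numeric (y, x) matrix.
#' @export
max_project_t <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (d[1] < 1L) stop("empty t axis")
  planes <- vapply(seq_len(d[1]), function(t) max_project_z(stack, channel, t),
                   matrix(0, d[4], d[5]))
  matrix(apply(planes, c(1, 2), max), d[4], d[5])
}

#' Threshold an image into a binary mask
#'
#' Pixels strictly above the threshold are foreground (upper thresholding,
#' as in ImageJ). When `restrict_to` is given the result is intersected
#' with it.
#'
#' @param image Numeric (y, x) matrix.
#' @param threshold Finite intensity threshold.
#' @param restrict_to Optional [region_mask()] (or logical matrix) to
#'   intersect with.
#' @return A [region_mask()]; provenance records the threshold.
#' @export
threshold_mask <- function(image, threshold, restrict_to = NULL) {
  stopifnot(is.matrix(image), is.finite(threshold))
  m <- image > threshold
  prov <- sprintf("threshold>%g", threshold)
  if (!is.null(restrict_to)) {
    m <- m & as_mask_matrix(restrict_to)
    prov <- paste0(prov, " (restricted)")
  }
  region_mask(m, prov)
}

#' Automatic threshold selection
#'
#' Reproducible stand-in for a manually set threshold. The default method
#' is Otsu's criterion on a 256-bin histogram of the pixels under
#' `restrict_to` (or the whole frame).
#'
#' @param image Numeric (y, x) matrix.
#' @param method Currently only `"otsu"`.
#' @param restrict_to Optional mask restricting the histogram.
#' @return A single intensity threshold, on the scale of `image`.
#' @export
auto_threshold <- function(image, method = "otsu", restrict_to = NULL) {
  stopifnot(is.matrix(image))
  method <- match.arg(method, "otsu")
  vals <- if (is.null(restrict_to)) as.vector(image)
          else image[as_mask_matrix(restrict_to)]
  if (length(vals) < 2L || diff(range(vals)) == 0)
    stop("cannot auto-threshold: fewer than 2 distinct intensities in region")
  EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1L)),
                range = range(vals), levels = 256L)
}

#' Remove small connected components
#'
#' Drops components smaller than `min_area_px` pixels and re-compacts the
#' label ids; the default live-cell pipeline removes regions smaller than
#' 3 pixels.
#'
#' @param puncta A [puncta_set] from [connected_components()].
#' @param min_area_px Minimum area (pixels) to keep; components with
#'   `area_px < min_area_px` are removed.
#' @return A filtered `puncta_set` with contiguous ids from 1.
#' @export
size_filter <- function(puncta, min_area_px = 3L) {
  stopifnot(inherits(puncta, "puncta_set"), min_area_px >= 1L)
  keep <- puncta$components$area_px >= min_area_px
  comp <- puncta$components[keep, , drop = FALSE]
  remap <- integer(max(puncta$components$id, 0L))
  remap[comp$id] <- seq_len(nrow(comp))
  labels <- puncta$labels
  fg <- labels > 0L
  labels[fg] <- ifelse(keep[puncta$labels[fg]], remap[puncta$labels[fg]], 0L)
  comp$id <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  structure(list(labels = labels, components = comp), class = "puncta_set")
}

#' Morphological smoothing of a mask (1-px closing)
#'
#' Dilation by one pixel followed by erosion by one pixel — the smoothing
#' step of the live-cell endosome pipeline. Closing is extensive: the
#' output always contains the input. Computed on a frame padded by the
#' element radius so border pixels behave as in an unbounded background.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @param element `"cross"` (3x3 cross, radius-1 disk; default) or
#'   `"square"` (3x3 box).
#' @return A smoothed [region_mask()].
#' @export
smooth_mask <- function(mask, element = c("cross", "square")) {
  element <- match.arg(element)
  m <- as_mask_matrix(mask)
  kern <- EBImage::makeBrush(3L, if (element == "cross") "diamond" else "box")
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  closed <- EBImage::erode(EBImage::dilate(pad, kern), kern)
  out <- matrix(as.logical(closed[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]),
                nrow(m), ncol(m))
  region_mask(out, c(if (inherits(mask, "region_mask")) mask$provenance,
                     sprintf("close(1px,%s)", element)))
}

#' Label connected components ("Analyze Particles")
#'
#' Labels foreground components under 4- or 8-neighbour adjacency and
#' tabulates per-component area and centroid (mean of member pixel
#' centres). Default connectivity is 8, the ImageJ Analyze Particles
#' convention.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @param connectivity 4 or 8.
#' @return A `puncta_set`: `labels` (integer matrix, 0 = background) and
#'   `components` (data.frame: id, area_px, centroid_y, centroid_x).
#' @export
connected_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- as_mask_matrix(mask)
  labels <- matrix(as.integer(EBImage::bwlabel(m * 1)), nrow(m), ncol(m))
  if (connectivity == 8L && max(labels) > 1L) {
    labels <- merge_diagonal_labels(labels)
  }
  n <- max(labels)
  if (n == 0L) {
    comp <- data.frame(id = integer(), area_px = integer(),
                       centroid_y = numeric(), centroid_x = numeric())
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    area <- tabulate(lab, n)
    comp <- data.frame(
      id = seq_len(n),
      area_px = area,
      centroid_y = as.vector(rowsum(as.numeric(idx[, 1]), lab)) / area,
      centroid_x = as.vector(rowsum(as.numeric(idx[, 2]), lab)) / area)
  }
  structure(list(labels = labels, components = comp), class = "puncta_set")
}

# bwlabel is 4-connected; merge labels that touch diagonally to obtain
# 8-connectivity, using graph components over the label adjacency graph.
merge_diagonal_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nr, -nc]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-nr, -1]), as.vector(labels[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2],
                 , drop = FALSE]
  if (nrow(pairs) == 0L) return(labels)
  n <- max(labels)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  memb <- igraph::components(g)$membership  # group per original label
  # compact group ids in order of first appearance for determinism
  compact <- integer(max(memb))
  nxt <- 0L
  for (lb in seq_len(n)) {
    if (compact[memb[lb]] == 0L) { nxt <- nxt + 1L; compact[memb[lb]] <- nxt }
  }
  out <- labels
  fg <- labels > 0L
  out[fg] <- compact[memb[labels[fg]]]
  out
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d components, total area %d px\n",
              nrow(x$components), sum(x$components$area_px)))
  invisible(x)
}

#' Euclidean distance map to a reference mask
#'
#' Per-pixel Euclidean distance, in micrometres, to the nearest foreground
#' pixel centre of `mask`; 0 inside the mask. Supports the
#' spot-to-compartment colocalization rule.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return Numeric matrix of distances (um); all `Inf` (with a warning)
#'   when the mask is empty.
#' @export
distance_map <- function(mask, pixel_size) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  m <- as_mask_matrix(mask)
  if (!any(m)) {
    warning("empty reference mask: distance map is infinite everywhere")
    return(matrix(Inf, nrow(m), ncol(m)))
  }
  # distmap(x) gives distance to the nearest zero pixel of x; invert so
  # that zeros sit at the mask foreground.
  d <- EBImage::distmap(1 - m)
  matrix(as.numeric(d), nrow(m), ncol(m)) * pixel_size
}
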