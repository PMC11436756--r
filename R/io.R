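#' Write an image stack as multi-page TIFF with a metadata sidecar
#'
#' Pages are written in t-major, then z, then channel order as 16-bit
#' TIFF. Baseline TIFF tags do not carry physical pixel size or
#' frame timing reliably, so axis lengths and calibration are written to a
#' JSON sidecar `<path>.meta.json`; [read_stack()] reads it back.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- matrix(stack$pixels[t, z, ch, , ], d[4], d[5])
  }
  # stacks are stored as 16-bit TIFF, the native depth of microscopy
  # cameras. Intensities are quantized to s = round(v * 2^m) (exact for
  # values with <= m fractional bits, in particular integer camera
  # counts) and written as samples centred inside their quantization bin,
  # so the stored integer is s regardless of the TIFF layer's internal
  # rounding; read_stack recovers v = s / 2^m from the raw integers.
  mx <- max(1, max(stack$pixels))
  m <- floor(log2((2^16 - 2) / mx))
  pages <- lapply(pages, function(p) (round(p * 2^m) + 0.49) / (2^16 - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  cal <- stack$calibration
  meta <- list(axes = "tzcyx", shape = d, intensity_scale = 2^-m,
               pixel_size_um = cal$pixel_size,
               frame_interval_s = cal$frame_interval,
               agonist_frame = cal$agonist_frame,
               fsk_frames = cal$fsk_frames,
               z_step_um = cal$z_step)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()] (or any TIFF)
#'
#' Axes are normalized to (t, z, c, y, x). With a `<path>.meta.json`
#' sidecar the stored shape and calibration are used; fields of
#' `calibration_override` win over the sidecar. Without a sidecar, a
#' single-page TIFF is promoted to shape (1, 1, 1, H, W); a multi-page
#' TIFF is ambiguous and requires `shape` in the override. A missing pixel
#' size with no override is an error — never a silent default.
#'
#' @param path TIFF path.
#' @param calibration_override Optional list with any of `pixel_size`,
#'   `frame_interval`, `agonist_frame`, `fsk_frames`, `z_step`, `shape`
#'   (t, z, c lengths as a 3-vector).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, calibration_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # 32-bit samples from foreign files come back as signed ints; unwrap
  pages <- lapply(pages, function(p) {
    p <- p * 1.0
    p[p < 0] <- p[p < 0] + 2^32
    p
  })
  ov <- calibration_override
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  shape_tzc <- NULL
  if (!is.null(meta)) shape_tzc <- meta$shape[1:3]
  if (!is.null(ov$shape)) shape_tzc <- ov$shape
  if (is.null(shape_tzc)) {
    if (length(pages) == 1L) shape_tzc <- c(1L, 1L, 1L)
    else stop("multi-page TIFF with no metadata sidecar: axis layout is ",
              "ambiguous; supply calibration_override$shape = c(t, z, c)")
  }
  if (prod(shape_tzc) != length(pages))
    stop("declared (t, z, c) shape does not match page count")
  pixel_size <- ov$pixel_size %||% meta$pixel_size_um
  if (is.null(pixel_size))
    stop("calibration error: pixel size missing from metadata and no ",
         "override supplied")
  cal <- calibration(
    pixel_size = pixel_size,
    frame_interval = ov$frame_interval %||% meta$frame_interval_s %||% 20,
    agonist_frame = ov$agonist_frame %||% meta$agonist_frame %||% 1L,
    fsk_frames = ov$fsk_frames %||% meta$fsk_frames,
    z_step = ov$z_step %||% meta$z_step_um)
  hw <- dim(pages[[1]])[1:2]
  scale <- ov$intensity_scale %||% meta$intensity_scale %||% 1
  px <- array(0, c(shape_tzc, hw))
  i <- 0L
  for (t in seq_len(shape_tzc[1])) for (z in seq_len(shape_tzc[2]))
    for (ch in seq_len(shape_tzc[3])) {
      i <- i + 1L
      pg <- pages[[i]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # drop extra samples
      px[t, z, ch, , ] <- pg * scale
    }
  image_stack(px, cal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon / label region-of-interest specification
#'
#' @param roi_id Identifier string.
#' @param kind `"polygon"` (vertices in pixel coordinates) or `"label"`
#'   (a value in a label image).
#' @param vertices For polygons: numeric matrix with columns (y, x); at
#'   least 3 rows. Coordinates are continuous, with pixel (r, c) occupying
#'   the half-open box [r-1, r) x [c-1, c) and centred at (r-0.5, c-0.5).
#' @param label For label ROIs: the label value.
#' @param channel Channel the ROI was drawn on (metadata only).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(roi_id, kind = c("polygon", "label"), vertices = NULL,
                     label = NULL, channel = NA_integer_) {
  kind <- match.arg(kind)
  if (kind == "polygon") {
    vertices <- as.matrix(vertices)
    if (nrow(vertices) < 3L) stop("polygon ROI needs at least 3 vertices")
  } else if (is.null(label)) stop("label ROI needs a 'label' value")
  structure(list(roi_id = roi_id, kind = kind, vertices = vertices,
                 label = label, channel = channel), class = "roi_spec")
}

#' Rasterize a polygon ROI to a binary mask
#'
#' A pixel belongs to the mask when its centre falls inside the polygon
#' under the even-odd rule. The crossing-number test yields the standard
#' half-open convention: an axis-aligned rectangle from (0.5, 0.5) to
#' (10.5, 20.5) covers exactly 10 x 20 pixels.
#'
#' @param roi An `roi_spec` of kind `"polygon"`, or a vertex matrix.
#' @param image_shape (n_rows, n_cols) of the target image.
#' @return A [region_mask()]; degenerate (zero-area) polygons give an
#'   empty mask with a warning.
#' @export
rasterize_roi <- function(roi, image_shape) {
  verts <- if (inherits(roi, "roi_spec")) {
    if (roi$kind != "polygon") stop("only polygon ROIs can be rasterized; ",
                                    "label ROIs index a label image")
    roi$vertices
  } else as.matrix(roi)
  if (any(verts[, 1] < 0 | verts[, 1] > image_shape[1] |
          verts[, 2] < 0 | verts[, 2] > image_shape[2]))
    stop("ROI vertices fall outside the image bounds")
  yy <- verts[, 1]; xx <- verts[, 2]
  # shoelace area; zero flags a degenerate polygon
  n <- length(yy)
  j <- c(n, seq_len(n - 1L))
  if (abs(sum(xx * yy[j] - xx[j] * yy)) / 2 < .Machine$double.eps * 100)
    warning("degenerate polygon (zero area): empty mask")
  cy <- seq_len(image_shape[1]) - 0.5
  cx <- seq_len(image_shape[2]) - 0.5
  inside <- matrix(FALSE, image_shape[1], image_shape[2])
  # even-odd crossing number, vectorized over pixel centres per edge
  py <- matrix(rep(cy, image_shape[2]), image_shape[1], image_shape[2])
  px <- matrix(rep(cx, each = image_shape[1]), image_shape[1], image_shape[2])
  for (e in seq_len(n)) {
    y1 <- yy[e]; x1 <- xx[e]; y2 <- yy[j[e]]; x2 <- xx[j[e]]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  region_mask(inside, sprintf("rasterize(%s)",
                              if (inherits(roi, "roi_spec")) roi$roi_id
                              else "polygon"))
}

#' Read / write ROI JSON
#'
#' Schema: `{"rois": [{"id": "...", "kind": "polygon",
#' "vertices": [[y, x], ...], "channel": 1}, ...]}`.
#'
#' @param path JSON file path.
#' @return A list of `roi_spec`s.
#' @export
read_rois <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc$rois, function(r) {
    verts <- if (!is.null(r$vertices))
      do.call(rbind, lapply(r$vertices, unlist))
    roi_spec(r$id, r$kind %||% "polygon", vertices = verts,
             label = r$label, channel = r$channel %||% NA_integer_)
  })
}

#' @rdname read_rois
#' @param rois List of `roi_spec`s.
#' @export
write_rois <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    out <- list(id = r$roi_id, kind = r$kind)
    if (!is.null(r$vertices))
      out$vertices <- lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ]))
    if (!is.null(r$label)) out$label <- r$label
    if (!is.na(r$channel)) out$channel <- r$channel
    out
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a table of records as CSV
#'
#' UTF-8, '.' decimal separator, header row, stable column order, no row
#' names; numeric values keep full (>= 15 significant digit) precision so
#' a read-back reproduces them.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
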