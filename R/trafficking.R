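#' Configuration for the endosomal-accumulation ("Puncti") pipeline
#'
#' Parameters for quantifying receptor fluorescence at marker-defined
#' endosomes over a time-lapse movie.
#'
#' @param marker_channel,receptor_channel Channel indices.
#' @param marker_threshold Manual marker threshold, or `NULL` for Otsu
#'   within the refined cell ROI (computed on the temporal max
#'   projection).
#' @param cell_roi Optional initial cell ROI (mask or `roi_spec`);
#'   `NULL` uses the whole frame before refinement.
#' @param refine_cell_roi Refine the cell ROI by thresholding (Otsu) a
#'   maximal temporal projection of the receptor channel and smoothing?
#' @param min_area_px Minimum marker-component area kept (default 3 px).
#' @param closing Apply the 1-px dilate-then-erode smoothing to the
#'   marker mask?
#' @param mask_mode `"per-frame"` (marker mask recomputed each frame,
#'   default) or `"projection"` (one mask from the temporal max
#'   projection of the marker channel, applied to every frame).
#' @param measure `"mean"` (average receptor fluorescence in the mask,
#'   default) or `"integrated"`.
#' @param background_method Passed to [estimate_background()].
#' @param normalize_mode `"F/F0"` (default) or `"dF/F0"`.
#' @return A `puncti_config` list.
#' @export
puncti_config <- function(marker_channel = 1L, receptor_channel = 2L,
                          marker_threshold = NULL, cell_roi = NULL,
                          refine_cell_roi = TRUE,
                          min_area_px = 3L, closing = TRUE,
                          mask_mode = c("per-frame", "projection"),
                          measure = c("mean", "integrated"),
                          background_method = "exterior",
                          normalize_mode = c("F/F0", "dF/F0")) {
  stopifnot(min_area_px >= 1L)
  structure(list(marker_channel = marker_channel,
                 receptor_channel = receptor_channel,
                 marker_threshold = marker_threshold, cell_roi = cell_roi,
                 refine_cell_roi = refine_cell_roi,
                 min_area_px = as.integer(min_area_px), closing = closing,
                 mask_mode = match.arg(mask_mode),
                 measure = match.arg(measure),
                 background_method = background_method,
                 normalize_mode = match.arg(normalize_mode)),
            class = "puncti_config")
}

# filled convex hull of a mask's foreground, via the hull polygon over
# pixel outer corners rasterized back to pixels
convex_hull_mask <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(m)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  verts <- cbind(idx[h, 1], idx[h, 2])  # outer corners pad by half a pixel
  hull <- as_mask_matrix(rasterize_roi(verts - 1, dim(m)))
  hull | m
}

# marker mask for one frame: threshold within cell ROI, drop < min_area_px
# components, then 1-px dilate / 1-px erode
puncti_marker_mask <- function(marker_img, cell_mask, threshold, cfg) {
  mask <- threshold_mask(marker_img, threshold, restrict_to = cell_mask)
  puncta <- size_filter(connected_components(mask), cfg$min_area_px)
  m <- region_mask(puncta$labels > 0L, mask$provenance)
  if (cfg$closing) m <- smooth_mask(m)
  m
}

#' Receptor accumulation trace at marker-defined endosomes
#'
#' The live-cell quantification: refine the cell ROI on a maximal temporal
#' projection of the receptor channel; per frame, threshold the marker
#' channel within that ROI, drop components smaller than 3 px, smooth with
#' a 1-px dilation then 1-px erosion, measure the mean receptor
#' fluorescence under the mask, subtract background; finally normalize the
#' whole trace to the pre-agonist baseline.
#'
#' Frames whose marker mask comes out empty are recorded as `NA` with a
#' warning, never as zero.
#'
#' @param movie An [image_stack()] with a t axis and calibration carrying
#'   `frame_interval` and `agonist_frame`.
#' @param cfg A [puncti_config()].
#' @return A [fluor_trace()] in state `"F/F0"` (or `"dF/F0"`), with
#'   per-frame `mask_area_px` diagnostics.
#' @export
puncti_accumulation_trace <- function(movie, cfg = puncti_config()) {
  stopifnot(inherits(movie, "image_stack"), inherits(cfg, "puncti_config"))
  n_t <- dim(movie$pixels)[1]
  if (n_t < 2L) stop("movie must have a time axis with >= 2 frames")
  sh <- dim(movie$pixels)[4:5]

  user_roi <- if (!is.null(cfg$cell_roi)) resolve_roi(cfg$cell_roi, sh)
  cell <- user_roi %||% region_mask(matrix(TRUE, sh[1], sh[2]), "full-frame")
  if (cfg$refine_cell_roi) {
    proj <- max_project_t(movie, cfg$receptor_channel)
    # Otsu on log intensities splits background from cell rather than dim
    # cell regions from bright ones, which is what ROI refinement needs
    thr <- expm1(auto_threshold(log1p(proj), restrict_to = cell))
    cell <- smooth_mask(threshold_mask(proj, thr, restrict_to = cell))
  }
  # background region: outside the drawn ROI and outside the convex hull
  # of the refined ROI — the hull covers dim cytoplasm even when the
  # refinement kept only receptor-bright structures (membrane, endosomes)
  bg_excl <- region_mask(convex_hull_mask(as_mask_matrix(cell)) |
                           (if (is.null(user_roi)) FALSE
                            else as_mask_matrix(user_roi)))

  marker_proj <- max_project_t(movie, cfg$marker_channel)
  thr_m <- cfg$marker_threshold %||%
    auto_threshold(marker_proj, restrict_to = cell)

  fixed_mask <- NULL
  if (cfg$mask_mode == "projection")
    fixed_mask <- puncti_marker_mask(marker_proj, cell, thr_m, cfg)

  vals <- numeric(n_t)
  areas <- integer(n_t)
  for (t in seq_len(n_t)) {
    rec <- max_project_z(movie, cfg$receptor_channel, t)
    mask <- fixed_mask %||%
      puncti_marker_mask(max_project_z(movie, cfg$marker_channel, t),
                         cell, thr_m, cfg)
    areas[t] <- mask_area(mask)
    if (areas[t] == 0L) {
      warning("frame ", t, ": empty marker mask; value recorded as missing")
      vals[t] <- NA_real_
      next
    }
    # background from outside both the drawn and the refined cell ROI
    bg <- estimate_background(rec, bg_excl, method = cfg$background_method)
    mvals <- rec[as_mask_matrix(mask)] - bg
    vals[t] <- if (cfg$measure == "mean") mean(mvals) else sum(mvals)
  }
  times <- frame_times_min(n_t, movie$calibration)
  raw <- fluor_trace(times, vals, state = "raw", mask_area_px = areas)
  normalize_baseline(raw, mode = cfg$normalize_mode)
}
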