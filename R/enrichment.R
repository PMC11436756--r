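#' Estimate image background level
#'
#' Default method: mean intensity over pixels outside the cell mask
#' (optionally restricted to a user-supplied background ROI). Alternative:
#' a low percentile of the whole frame.
#'
#' @param image Numeric (y, x) matrix.
#' @param cell_mask [region_mask()] or logical matrix marking the cell.
#' @param method `"exterior"` (default) or `"percentile"`.
#' @param background_roi Optional mask: average only over this region.
#' @param percentile Percentile used by the percentile method (default 5).
#' @return Background level, intensity per pixel.
#' @export
estimate_background <- function(image, cell_mask,
                                method = c("exterior", "percentile"),
                                background_roi = NULL, percentile = 5) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "percentile")
    return(unname(stats::quantile(image, percentile / 100)))
  if (!is.null(background_roi))
    return(mean(image[as_mask_matrix(background_roi)]))
  cm <- as_mask_matrix(cell_mask)
  if (!any(cm)) stop("cell mask is empty")
  ext <- !cm
  if (!any(ext)) stop("cell mask covers the whole frame; supply a ",
                      "'background_roi' or use the percentile method")
  mean(image[ext])
}

#' Compartment enrichment index
#'
#' Ratio of a protein's background-subtracted fluorescence in a compartment
#' mask to its fluorescence over the whole cell. Two conventions:
#' \describe{
#'   \item{mean-ratio (default)}{mean(compartment) / mean(cell) — a
#'     concentration enrichment, 1 for a uniformly distributed protein,
#'     independent of compartment size.}
#'   \item{integrated-ratio}{sum(compartment) / sum(cell) — the fraction of
#'     total cellular fluorescence in the compartment.}
#' }
#' Pixels are clipped at 0 after background subtraction. The compartment
#' mask is intersected with the cell mask.
#'
#' @param image Numeric (y, x) matrix (the protein channel).
#' @param compartment_mask,cell_mask Masks; compartment auto-intersected
#'   with cell.
#' @param background Background level (intensity/px) subtracted per pixel.
#' @param convention `"mean-ratio"` or `"integrated-ratio"`.
#' @param cell_id Optional identifier.
#' @param compartment Compartment label carried into the result.
#' @return An `enrichment_result` (one-row data.frame subclass) with
#'   columns cell_id, compartment, convention, index,
#'   compartment_fluorescence, cell_fluorescence, background, empty_mask.
#' @export
enrichment_index <- function(image, compartment_mask, cell_mask,
                             background = 0,
                             convention = c("mean-ratio", "integrated-ratio"),
                             cell_id = NA_character_,
                             compartment = NA_character_) {
  convention <- match.arg(convention)
  stopifnot(is.matrix(image))
  cm <- as_mask_matrix(cell_mask)
  pm <- as_mask_matrix(compartment_mask) & cm
  if (!any(cm)) stop("cell mask is empty")
  img <- pmax(image - background, 0)
  cell_vals <- img[cm]
  if (convention == "mean-ratio") {
    cell_stat <- mean(cell_vals)
  } else cell_stat <- sum(cell_vals)
  if (cell_stat <= 0)
    stop("cell fluorescence is zero after background subtraction; ",
         "enrichment undefined")
  empty <- !any(pm)
  comp_vals <- img[pm]
  comp_stat <- if (empty) 0
               else if (convention == "mean-ratio") mean(comp_vals)
               else sum(comp_vals)
  if (empty) warning("empty compartment mask: index reported as 0")
  out <- data.frame(cell_id = cell_id, compartment = compartment,
                    convention = convention,
                    index = comp_stat / cell_stat,
                    compartment_fluorescence = if (empty) 0 else sum(comp_vals),
                    cell_fluorescence = sum(cell_vals),
                    background = background,
                    empty_mask = empty)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Endosome mask from a marker channel
#'
#' Thresholds the endosomal-marker channel (strictly above threshold)
#' inside the cell ROI; the resulting mask is then applied to the protein
#' channel to measure endosomal enrichment.
#'
#' @param marker_image Numeric matrix, the marker channel (z-projected).
#' @param cell_mask Cell ROI mask.
#' @param threshold Manual intensity threshold, or `NULL` to use
#'   [auto_threshold()] (Otsu) within the cell.
#' @return A [region_mask()].
#' @export
endosome_mask_from_marker <- function(marker_image, cell_mask,
                                      threshold = NULL) {
  if (is.null(threshold))
    threshold <- auto_threshold(marker_image, restrict_to = cell_mask)
  threshold_mask(marker_image, threshold, restrict_to = cell_mask)
}

#' Count internal puncta and classify the cell
#'
#' Thresholds the protein channel inside the cell, labels connected
#' components, removes components smaller than `min_area_px`, and counts
#' the survivors. A cell with `threshold_puncta` (default 10) or more
#' puncta is classified positive.
#'
#' @param ac_image Numeric matrix (the protein channel, z-projected).
#' @param cell_mask Cell ROI mask.
#' @param threshold Manual intensity threshold, or `NULL` for Otsu within
#'   the cell.
#' @param min_area_px Minimum component area kept (default 3 px).
#' @param threshold_puncta Positivity cutoff on the count (default 10,
#'   inclusive).
#' @param connectivity Component adjacency, 4 or 8.
#' @param cell_id Optional identifier.
#' @return A `cell_classification` one-row data.frame: cell_id, n_puncta,
#'   positive, threshold_puncta.
#' @export
count_internal_puncta <- function(ac_image, cell_mask, threshold = NULL,
                                  min_area_px = 3L, threshold_puncta = 10L,
                                  connectivity = 8L,
                                  cell_id = NA_character_) {
  if (is.null(threshold))
    threshold <- auto_threshold(ac_image, restrict_to = cell_mask)
  mask <- threshold_mask(ac_image, threshold, restrict_to = cell_mask)
  puncta <- size_filter(connected_components(mask, connectivity), min_area_px)
  n <- nrow(puncta$components)
  out <- data.frame(cell_id = cell_id, n_puncta = n,
                    positive = n >= threshold_puncta,
                    threshold_puncta = as.integer(threshold_puncta))
  class(out) <- c("cell_classification", "data.frame")
  out
}

#' Fraction of positive cells in a population
#'
#' @param classifications data.frame with a logical `positive` column
#'   (rows = cells), as produced by [count_internal_puncta()].
#' @return List: `percent` (100 * n_positive / n_total), `n_positive`,
#'   `n_total`.
#' @export
fraction_positive <- function(classifications) {
  stopifnot(is.data.frame(classifications),
            "positive" %in% names(classifications),
            nrow(classifications) >= 1L)
  n_pos <- sum(classifications$positive)
  n_tot <- nrow(classifications)
  list(percent = 100 * n_pos / n_tot, n_positive = n_pos, n_total = n_tot)
}

#' Ciliary enrichment of a protein channel
#'
#' Composition used for fixed-cell cilia measurements: z-max-project the
#' protein channel, rasterize / accept the cilium and cell ROIs (drawn on
#' the ciliary-marker channel), estimate and subtract background, and
#' compute the enrichment index.
#'
#' @param stack An [image_stack()] (single timepoint).
#' @param cilium_roi,cell_roi [region_mask()]s or logical matrices, or
#'   `roi_spec`s (see [rasterize_roi()]).
#' @param channel Protein channel index (default 2).
#' @param background `NULL` to estimate via [estimate_background()], or a
#'   numeric level.
#' @param convention Ratio convention, see [enrichment_index()].
#' @param cell_id Optional identifier.
#' @return An `enrichment_result`.
#' @export
cilia_enrichment <- function(stack, cilium_roi, cell_roi, channel = 2L,
                             background = NULL,
                             convention = "mean-ratio",
                             cell_id = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  img <- max_project_z(stack, channel = channel, t = 1L)
  sh <- dim(img)
  cil <- resolve_roi(cilium_roi, sh)
  cell <- resolve_roi(cell_roi, sh)
  if (is.null(background))
    background <- estimate_background(img, cell)
  enrichment_index(img, cil, cell, background = background,
                   convention = convention, cell_id = cell_id,
                   compartment = "cilium")
}

#' Endosomal enrichment of a protein channel
#'
#' Composition used for fixed-cell endosome measurements: z-max-project
#' both channels, derive the endosome mask from the marker channel inside
#' the cell ROI, then compute the enrichment index on the protein channel.
#'
#' @param stack An [image_stack()] with marker and protein channels.
#' @param cell_roi Cell ROI mask or `roi_spec`.
#' @param marker_channel,protein_channel Channel indices (defaults 1, 2).
#' @param marker_threshold Manual marker threshold or `NULL` for Otsu.
#' @param background As in [cilia_enrichment()].
#' @param convention Ratio convention.
#' @param cell_id Optional identifier.
#' @return An `enrichment_result`.
#' @export
endosome_enrichment <- function(stack, cell_roi, marker_channel = 1L,
                                protein_channel = 2L,
                                marker_threshold = NULL, background = NULL,
                                convention = "mean-ratio",
                                cell_id = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  marker <- max_project_z(stack, channel = marker_channel, t = 1L)
  protein <- max_project_z(stack, channel = protein_channel, t = 1L)
  cell <- resolve_roi(cell_roi, dim(marker))
  endo <- endosome_mask_from_marker(marker, cell, marker_threshold)
  if (is.null(background))
    background <- estimate_background(protein, cell)
  enrichment_index(protein, endo, cell, background = background,
                   convention = convention, cell_id = cell_id,
                   compartment = "endosome")
}

# accept region_mask, logical matrix, or roi_spec
resolve_roi <- function(roi, image_shape) {
  if (inherits(roi, "roi_spec")) rasterize_roi(roi, image_shape)
  else region_mask(as_mask_matrix(roi))
}
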