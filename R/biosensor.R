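#' Normalize a trace to its Fsk/IBMX saturation epoch
#'
#' Divides every value by the mean over the Fsk/IBMX frames, putting the
#' trace on a fraction-of-maximal-stimulation scale. Applied to cADDis and
#' non-targeted PKA-sensor traces after baseline normalization.
#'
#' @param trace A [fluor_trace()].
#' @param fsk_frames Indices of the saturation-epoch frames; defaults to
#'   the trace's own `fsk_frames`.
#' @return A [fluor_trace()] in state `"fsk-normalized"`.
#' @export
fskibmx_normalize <- function(trace, fsk_frames = trace$fsk_frames) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (trace$state == "fsk-normalized") stop("trace is already Fsk-normalized")
  if (is.null(fsk_frames) || length(fsk_frames) == 0L)
    stop("'fsk_frames' must be a nonempty set of frame indices")
  fsk_mean <- mean(trace$values[fsk_frames], na.rm = TRUE)
  if (!is.finite(fsk_mean) || fsk_mean <= 0)
    stop("Fsk/IBMX epoch mean must be positive")
  out <- fluor_trace(trace$times_min, trace$values / fsk_mean,
                     state = "raw", mask_area_px = trace$mask_area_px,
                     fsk_frames = fsk_frames)
  out$state <- "fsk-normalized"
  out
}

# samples of the trace restricted to [t_start, t_end], with linearly
# interpolated values inserted exactly at the window boundaries
window_samples <- function(trace, t_start, t_end) {
  tt <- trace$times_min; vv <- trace$values
  ok <- !is.na(vv)
  if (any(!ok)) {  # interpolate missing frames for integration only
    vv <- stats::approx(tt[ok], vv[ok], xout = tt, rule = 2)$y
  }
  if (t_start < min(tt) || t_end > max(tt))
    stop(sprintf("integration window [%g, %g] outside trace span [%g, %g]",
                 t_start, t_end, min(tt), max(tt)))
  inside <- tt > t_start & tt < t_end
  t_out <- c(t_start, tt[inside], t_end)
  v_out <- c(stats::approx(tt, vv, xout = t_start)$y, vv[inside],
             stats::approx(tt, vv, xout = t_end)$y)
  list(t = t_out, v = v_out)
}

#' Area under a trace over a time window
#'
#' Trapezoidal integral of the trace over [t_start, t_end] minutes, with
#' the window boundaries hit exactly by linear interpolation, so that
#' adjacent phases add exactly: AUC(0,5) + AUC(5,30) = AUC(0,30).
#'
#' @param trace A [fluor_trace()].
#' @param t_start,t_end Window bounds in minutes, within the trace span.
#' @return Area in value-units x minutes.
#' @export
integrate_phase <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "fluor_trace"), t_start < t_end)
  w <- window_samples(trace, t_start, t_end)
  pracma::trapz(w$t, w$v)
}

#' Peak response within a window
#'
#' Maximum sampled value with time in (t_start, t_end]; pre-agonist frames
#' are excluded by the default window. Ties report the earliest time.
#'
#' @param trace A [fluor_trace()].
#' @param window (t_start, t_end] in minutes; default (0, 30].
#' @return List: `value`, `time_min`.
#' @export
peak_value <- function(trace, window = c(0, 30)) {
  stopifnot(inherits(trace, "fluor_trace"))
  sel <- which(trace$times_min > window[1] & trace$times_min <= window[2] &
                 !is.na(trace$values))
  if (length(sel) == 0L) stop("no samples in the peak window")
  i <- sel[which.max(trace$values[sel])]  # which.max takes the first tie
  list(value = trace$values[i], time_min = trace$times_min[i])
}

#' Plateau response within a window
#'
#' Arithmetic mean of the samples whose time lies in [t_start, t_end]
#' minutes, both ends inclusive; default [20, 30], the sustained late
#' phase.
#'
#' @param trace A [fluor_trace()].
#' @param window Inclusive window in minutes.
#' @return Mean value over the window.
#' @export
plateau_value <- function(trace, window = c(20, 30)) {
  stopifnot(inherits(trace, "fluor_trace"))
  sel <- trace$times_min >= window[1] & trace$times_min <= window[2] &
    !is.na(trace$values)
  if (!any(sel)) stop("no samples in the plateau window")
  mean(trace$values[sel])
}

#' Summarize one biosensor trace into phase statistics
#'
#' Computes the standard per-cell summary: early AUC over (0, 5] min, late
#' AUC over (5, 30] min, total AUC over (0, 30], peak (max over (0, 30])
#' and plateau (mean over [20, 30]).
#'
#' @param trace A [fluor_trace()] (typically dF/F0, optionally
#'   Fsk-normalized).
#' @param cell_id Optional identifier carried into the output.
#' @param phase_split Boundary between early and late phases, minutes.
#' @param t_max End of the response window, minutes.
#' @return One-row data.frame: cell_id, auc_early, auc_late, auc_total,
#'   peak, peak_time_min, plateau.
#' @export
summarize_phases <- function(trace, cell_id = NA_character_,
                             phase_split = 5, t_max = 30) {
  pk <- peak_value(trace, c(0, t_max))
  data.frame(cell_id = cell_id,
             auc_early = integrate_phase(trace, 0, phase_split),
             auc_late = integrate_phase(trace, phase_split, t_max),
             auc_total = integrate_phase(trace, 0, t_max),
             peak = pk$value, peak_time_min = pk$time_min,
             plateau = plateau_value(trace, c(t_max - 10, t_max)))
}

#' Normalize per-cell summaries to a reference condition
#'
#' Divides each summary statistic by the mean of that statistic in the
#' reference condition, so the reference condition's own mean maps to 1.
#'
#' @param summaries data.frame with a `condition` column and numeric
#'   statistic columns (as from [summarize_phases()] plus `condition`).
#' @param reference_condition Condition label to normalize to.
#' @param stats Character vector of columns to normalize.
#' @return The data.frame with normalized statistic columns; the reference
#'   means used are recorded in `attr(, "reference_means")`.
#' @export
normalize_to_condition <- function(summaries, reference_condition,
                                   stats = c("auc_early", "auc_late",
                                             "auc_total", "peak", "plateau")) {
  stopifnot(is.data.frame(summaries), "condition" %in% names(summaries))
  ref <- summaries$condition == reference_condition
  if (!any(ref)) stop("reference condition '", reference_condition,
                      "' not present")
  stats <- intersect(stats, names(summaries))
  ref_means <- vapply(stats, function(s) mean(summaries[[s]][ref]), 0)
  for (s in stats) summaries[[s]] <- summaries[[s]] / ref_means[[s]]
  attr(summaries, "reference_means") <- ref_means
  summaries
}

#' Extract a background-subtracted, baseline-normalized ROI trace
#'
#' Per-frame mean fluorescence within a cell (or nuclear/cytoplasmic/
#' endosomal) ROI, background-subtracted and dF/F0-normalized to the
#' pre-agonist baseline. The same machinery serves whole-cell and
#' compartment-targeted sensor movies.
#'
#' @param movie An [image_stack()] with a time axis and calibration
#'   carrying `frame_interval` and `agonist_frame`.
#' @param roi_mask A [region_mask()] or logical matrix (nonempty).
#' @param background Scalar background intensity, a per-frame numeric
#'   vector, or `NULL` to estimate per frame as the mean outside the ROI.
#' @param channel Channel index.
#' @param mode Final normalization, `"dF/F0"` (default) or `"F/F0"`.
#' @return A [fluor_trace()].
#' @export
roi_trace <- function(movie, roi_mask, background = NULL, channel = 1L,
                      mode = c("dF/F0", "F/F0")) {
  mode <- match.arg(mode)
  stopifnot(inherits(movie, "image_stack"))
  m <- as_mask_matrix(roi_mask)
  if (!any(m)) stop("ROI mask is empty")
  n_t <- dim(movie$pixels)[1]
  raw <- vapply(seq_len(n_t), function(t) {
    fr <- max_project_z(movie, channel, t)
    bg <- if (is.null(background)) mean(fr[!m])
          else if (length(background) > 1L) background[t] else background
    mean(fr[m]) - bg
  }, 0)
  times <- frame_times_min(n_t, movie$calibration)
  normalize_baseline(fluor_trace(times, raw, state = "raw",
                                 fsk_frames = movie$calibration$fsk_frames),
                     mode = mode)
}
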