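#' Per-frame fluorescence trace
#'
#' A scalar time series anchored at agonist addition (t = 0, minutes),
#' with an explicit normalization state that can only move forward:
#' `"raw"` -> `"F/F0"` or `"dF/F0"` -> `"fsk-normalized"`.
#'
#' @param times_min Numeric vector of frame times, minutes, strictly
#'   increasing; negative values are pre-agonist baseline.
#' @param values Numeric vector, same length; `NA` marks frames where the
#'   measurement was undefined (e.g. an empty mask).
#' @param state Normalization state.
#' @param mask_area_px Optional per-frame mask area diagnostic.
#' @param fsk_frames Optional indices of the Fsk/IBMX epoch.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(times_min, values,
                        state = c("raw", "F/F0", "dF/F0", "fsk-normalized"),
                        mask_area_px = NULL, fsk_frames = NULL) {
  state <- match.arg(state)
  stopifnot(length(times_min) == length(values))
  if (any(diff(times_min) <= 0)) stop("'times_min' must be strictly increasing")
  structure(list(times_min = as.numeric(times_min),
                 values = as.numeric(values),
                 state = state,
                 mask_area_px = mask_area_px,
                 fsk_frames = fsk_frames),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d frames, t = %.2f..%.2f min, state '%s'\n",
              length(x$values), min(x$times_min), max(x$times_min), x$state))
  invisible(x)
}

#' @export
plot.fluor_trace <- function(x, ..., xlab = "time (min)", ylab = x$state) {
  graphics::plot(x$times_min, x$values, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  out <- data.frame(time_min = x$times_min, value = x$values)
  if (!is.null(x$mask_area_px)) out$mask_area_px <- x$mask_area_px
  out
}

#' Normalize a trace to its pre-agonist baseline
#'
#' F0 is the mean over all frames with t < 0. Mode `"F/F0"` divides by F0;
#' mode `"dF/F0"` computes (F - F0) / F0.
#'
#' @param trace A [fluor_trace()] in state `"raw"`.
#' @param mode `"F/F0"` or `"dF/F0"`.
#' @return A normalized [fluor_trace()].
#' @export
normalize_baseline <- function(trace, mode = c("F/F0", "dF/F0")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fluor_trace"))
  if (trace$state != "raw")
    stop("trace is already normalized ('", trace$state,
         "'); normalization state only moves forward")
  base <- trace$values[trace$times_min < 0]
  base <- base[!is.na(base)]
  if (length(base) == 0L) stop("no pre-agonist baseline frames present")
  f0 <- mean(base)
  if (f0 <= 0) stop("baseline mean F0 must be > 0 for ratio normalization")
  vals <- if (mode == "F/F0") trace$values / f0 else (trace$values - f0) / f0
  fluor_trace(trace$times_min, vals, state = mode,
              mask_area_px = trace$mask_area_px, fsk_frames = trace$fsk_frames)
}
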