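#' Event stream container
#'
#' Scission-event times from one patched cell: a recording starts in
#' cell-attached (CA) mode and switches to whole-cell (WC) mode at
#' `mode_boundary`, when the pipette solution starts dialysing into the
#' cytoplasm.
#'
#' @param event_times event times in seconds from recording start,
#'   non-negative.
#' @param mode_boundary CA -> WC switch time (seconds).
#' @param cell_area cell footprint in square micrometers (optional).
#' @param cell_id optional identifier.
#' @return an `event_stream`.
#' @export
event_stream <- function(event_times, mode_boundary, cell_area = NA_real_,
                         cell_id = NA_character_) {
  event_times <- sort(as.numeric(event_times))
  if (length(event_times) && event_times[1] < 0)
    stop("event times must be non-negative")
  stop_if_not_scalar_num(mode_boundary, "mode_boundary", nonneg = TRUE)
  structure(list(event_times = event_times, mode_boundary = mode_boundary,
                 cell_area = cell_area, cell_id = cell_id),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events, CA/WC boundary at %.0f s\n",
              length(x$event_times), x$mode_boundary))
  invisible(x)
}

#' Normalized cumulative event curve
#'
#' Step curve of cumulative detections versus time, scaled so that the
#' count at `normalization_time` of cell-attached recording (default
#' 280 s, the 70th cell-attached frame) equals 100. The whole-cell
#' segment continues on the same scale, so cells with very different
#' basal endocytic activity can be pooled.
#'
#' @param stream an [event_stream()].
#' @param normalization_time seconds of CA time at which the curve is
#'   set to 100 (default 280).
#' @return a `cumulative_curve` data frame (`time`, `value`) with the
#'   mode boundary and normalization count as attributes.
#' @export
cumulative_curve <- function(stream, normalization_time = 280) {
  tt <- stream$event_times
  n0 <- sum(tt <= normalization_time)
  if (n0 == 0L)
    stop("no events before the normalization time; cell unusable")
  out <- data.frame(time = c(0, tt),
                    value = 100 * (0:length(tt)) / n0)
  class(out) <- c("cumulative_curve", "data.frame")
  attr(out, "mode_boundary") <- stream$mode_boundary
  attr(out, "normalization_count") <- n0
  out
}

#' Whole-cell over cell-attached event-frequency ratio
#'
#' The endocytosis-inhibition metric f = 100 * F_WC / F_CA, where F_CA
#' is the event frequency in a window of cell-attached time (default
#' minutes 2-4 after recording start) and F_WC the frequency in a
#' window of whole-cell time (default minutes 8-10 after break-in).
#' Windows are half-open `[start, end)`.
#'
#' @param stream an [event_stream()].
#' @param ca_window,wc_window windows in minutes on the CA / WC clocks
#'   (defaults `c(2, 4)` and `c(8, 10)`).
#' @return a `frequency_ratio_result`: `F_CA` and `F_WC` in events/min
#'   and `f` in percent.
#' @export
frequency_ratio <- function(stream, ca_window = c(2, 4), wc_window = c(8, 10)) {
  ca_s <- ca_window * 60
  wc_s <- wc_window * 60
  tt <- stream$event_times
  ca_t <- tt[tt < stream$mode_boundary]
  wc_t <- tt[tt >= stream$mode_boundary] - stream$mode_boundary
  n_ca <- sum(ca_t >= ca_s[1] & ca_t < ca_s[2])
  n_wc <- sum(wc_t >= wc_s[1] & wc_t < wc_s[2])
  F_ca <- n_ca / diff(ca_window)
  F_wc <- n_wc / diff(wc_window)
  if (F_ca == 0)
    stop("no cell-attached events in the reference window; ratio undefined")
  structure(list(F_CA = F_ca, F_WC = F_wc, f = 100 * F_wc / F_ca,
                 ca_window = ca_window, wc_window = wc_window),
            class = "frequency_ratio_result")
}

#' @export
print.frequency_ratio_result <- function(x, ...) {
  cat(sprintf("F_CA = %.2f ev/min [%g-%g min CA], F_WC = %.2f ev/min [%g-%g min WC], f = %.1f%%\n",
              x$F_CA, x$ca_window[1], x$ca_window[2],
              x$F_WC, x$wc_window[1], x$wc_window[2], x$f))
  invisible(x)
}

#' Event frequency per unit membrane area
#'
#' @param n_events event count.
#' @param cell_area cell footprint in square micrometers.
#' @param duration recording duration in minutes.
#' @return events per minute per square micrometer.
#' @export
event_density_frequency <- function(n_events, cell_area, duration) {
  stop_if_not_scalar_num(cell_area, "cell_area", positive = TRUE)
  stop_if_not_scalar_num(duration, "duration", positive = TRUE)
  n_events / (cell_area * duration)
}

#' Fluorescent-cluster density in a cell mask
#'
#' Segments an image (e.g. the maximum projection of a transferrin
#' uptake z-stack) by wavelet decomposition, counts the clusters whose
#' centroid falls inside the cell mask, and reports the density per
#' square micrometer. When densities for a control group are supplied,
#' the value is additionally expressed as a percentage of the control
#' mean, so the control group averages 100 by construction.
#'
#' @param image numeric matrix.
#' @param mask logical matrix (cell mask).
#' @param params a [segmentation_params()].
#' @param pixel_size_um pixel size in micrometers (default 0.15).
#' @param control_densities optional numeric vector of control-group
#'   densities (clusters per square micrometer).
#' @return a `cluster_density_result`: `n_clusters`, `cell_area` (um^2),
#'   `density`, and `normalized_value` (percent of control mean, NA
#'   without controls).
#' @export
cluster_density <- function(image, mask, params = segmentation_params(),
                            pixel_size_um = 0.15, control_densities = NULL) {
  if (!any(mask)) stop("cell mask is empty")
  obj <- segment_frame(image, params)
  inside <- if (nrow(obj) == 0L) logical(0) else {
    xi <- pmin(pmax(round(obj$x), 1L), ncol(mask))
    yi <- pmin(pmax(round(obj$y), 1L), nrow(mask))
    mask[cbind(yi, xi)]
  }
  n <- sum(inside)
  area <- sum(mask) * pixel_size_um^2
  dens <- n / area
  structure(list(n_clusters = n, cell_area = area, density = dens,
                 normalized_value = if (is.null(control_densities)) NA_real_
                                    else 100 * dens / mean(control_densities)),
            class = "cluster_density_result")
}

#' @export
print.cluster_density_result <- function(x, ...) {
  cat(sprintf("%d clusters over %.1f um^2 (%.3f um^-2)",
              x$n_clusters, x$cell_area, x$density))
  if (!is.na(x$normalized_value))
    cat(sprintf(", %.1f%% of control", x$normalized_value))
  cat("\n")
  invisible(x)
}
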