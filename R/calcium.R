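# Population calcium-imaging analysis: dF/F normalisation, event
# detection, neuropil subtraction, the layer-2 global event rate and
# coactivity as a function of depth in layer 2.

#' Per-ROI fluorescence trace container
#'
#' @param traces numeric matrix, frames x ROIs (raw fluorescence).
#' @param sampling_rate acquisition rate, Hz.
#' @param roi_id integer ROI labels (default column index).
#' @param depth_norm per-ROI normalised depth in layer 2 (0 superficial,
#'   1 deep), or `NA`.
#' @param pixel_count per-ROI pixel counts (used by [filter_rois()]).
#' @param centroid optional 2-column matrix of ROI centroids (pixels).
#' @return Object of class `roi_trace_set`.
#' @export
roi_trace_set <- function(traces, sampling_rate, roi_id = NULL,
                          depth_norm = NULL, pixel_count = NULL,
                          centroid = NULL) {
  traces <- as.matrix(traces)
  .assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  n <- ncol(traces)
  structure(list(
    traces = traces, sampling_rate = sampling_rate,
    roi_id = as.integer(roi_id %||% seq_len(n)),
    depth_norm = as.numeric(depth_norm %||% rep(NA_real_, n)),
    pixel_count = as.integer(pixel_count %||% rep(NA_integer_, n)),
    centroid = centroid), class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d ROIs x %d frames @ %g Hz (%.1f min)\n",
              ncol(x$traces), nrow(x$traces), x$sampling_rate,
              nrow(x$traces) / x$sampling_rate / 60))
  invisible(x)
}

#' Drop undersized ROIs
#'
#' ROIs with fewer than `min_pixels` pixels (default 70) are rejected.
#' ROIs with unknown pixel counts are kept.
#'
#' @param rois a [roi_trace_set()].
#' @param min_pixels minimum ROI size in pixels.
#' @return The filtered `roi_trace_set`.
#' @export
filter_rois <- function(rois, min_pixels = 70) {
  stopifnot(inherits(rois, "roi_trace_set"))
  keep <- is.na(rois$pixel_count) | rois$pixel_count >= min_pixels
  rois$traces <- rois$traces[, keep, drop = FALSE]
  rois$roi_id <- rois$roi_id[keep]
  rois$depth_norm <- rois$depth_norm[keep]
  rois$pixel_count <- rois$pixel_count[keep]
  if (!is.null(rois$centroid)) rois$centroid <- rois$centroid[keep, , drop = FALSE]
  rois
}

#' Baseline-window dF/F normalisation
#'
#' The baseline is the contiguous `window`-sample stretch with the lowest
#' standard deviation (earliest window on ties); `F0` is its mean and the
#' trace is normalised as `(F - F0) / F0`. The window SD is also returned
#' in dF/F units.
#'
#' @param trace raw fluorescence series (length >= `window`).
#' @param window baseline window length in samples (default 6).
#' @return list with `dff`, `f0`, `baseline_sd` (dF/F units) and
#'   `window_start` (frame index of the chosen window).
#' @examples
#' r <- delta_f_over_f(c(50, 50, 50, 50, 50, 50, 100, 100))
#' r$dff[7]  # == 1
#' @export
delta_f_over_f <- function(trace, window = 6) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < window)
    stop(sprintf("trace has %d samples; need at least %d", n, window),
         call. = FALSE)
  m <- stats::embed(trace, window)          # row i = trace[i + window - 1 .. i]
  mu <- rowMeans(m)
  ss <- rowSums(m^2)
  var_w <- pmax((ss - window * mu^2) / (window - 1), 0)
  k <- which.min(var_w)                     # earliest window on ties
  f0 <- mu[k]
  if (f0 <= 0)
    stop("baseline mean F0 <= 0: non-physical fluorescence", call. = FALSE)
  list(dff = (trace - f0) / f0, f0 = f0,
       baseline_sd = sqrt(var_w[k]) / f0, window_start = k)
}

#' Robust noise scale of a dF/F trace
#'
#' Median-absolute-deviation estimate of the baseline noise SD, robust to
#' sparse calcium transients. Used as the default scale for the 2.5-SD
#' detection threshold; the minimum-SD baseline-window estimate
#' ([delta_f_over_f()]) is available via `sd_method = "baseline_window"`
#' in the pipeline functions.
#'
#' @param dff dF/F series.
#' @return noise SD estimate in dF/F units.
#' @export
estimate_noise_sd <- function(dff) stats::mad(dff)

.detection_sd <- function(dffobj, sd_method = c("mad", "baseline_window")) {
  switch(match.arg(sd_method),
         mad = estimate_noise_sd(dffobj$dff),
         baseline_window = dffobj$baseline_sd)
}

#' Threshold event detection on a dF/F trace
#'
#' Events are maximal runs of frames with `dff > threshold_sd *
#' baseline_sd`, at least `min_width` frames long. Incomplete events
#' touching the first or last frame are excluded.
#'
#' @param dff dF/F series.
#' @param baseline_sd noise SD in dF/F units (>= 0). A zero SD (noise-free
#'   trace) makes any positive excursion count, with a warning.
#' @param threshold_sd detection threshold in SD units (default 2.5).
#' @param min_width minimum event width in consecutive frames (default 2).
#' @return data.frame with `onset`, `offset` (frame indices), `width` and
#'   `peak_dff`, sorted by onset; zero rows when nothing is detected.
#' @export
detect_events <- function(dff, baseline_sd, threshold_sd = 2.5,
                          min_width = 2) {
  .assert_scalar_num(baseline_sd, "baseline_sd", 0)
  if (baseline_sd == 0)
    warning("baseline_sd is 0: any positive excursion counts as an event")
  thr <- threshold_sd * baseline_sd
  above <- dff > thr
  n <- length(above)
  empty <- data.frame(onset = integer(0), offset = integer(0),
                      width = integer(0), peak_dff = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width & starts > 1L & ends < n
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  peak <- mapply(function(a, b) max(dff[a:b]), starts, ends)
  data.frame(onset = starts, offset = ends,
             width = ends - starts + 1L, peak_dff = peak)
}

#' Optional event curation filters
#'
#' Replaces the manual curation step of hand-reviewed recordings with
#' explicit, reproducible filters. All filters default to off.
#'
#' @param events event data.frame from [detect_events()].
#' @param min_peak_dff minimum peak dF/F, or `NULL`.
#' @param min_width minimum width in frames, or `NULL`.
#' @param min_iei_frames minimum inter-event interval (onset-to-onset,
#'   frames); later events violating it are dropped. `NULL` to disable.
#' @return The filtered event data.frame.
#' @export
filter_events <- function(events, min_peak_dff = NULL, min_width = NULL,
                          min_iei_frames = NULL) {
  if (!is.null(min_peak_dff)) events <- events[events$peak_dff >= min_peak_dff, ]
  if (!is.null(min_width)) events <- events[events$width >= min_width, ]
  if (!is.null(min_iei_frames) && nrow(events) > 1L) {
    keep <- rep(TRUE, nrow(events))
    last <- events$onset[1L]
    for (i in seq_len(nrow(events))[-1L]) {
      if (events$onset[i] - last < min_iei_frames) keep[i] <- FALSE
      else last <- events$onset[i]
    }
    events <- events[keep, ]
  }
  rownames(events) <- NULL
  events
}

#' Neuropil-corrected dF/F trace for one ROI
#'
#' Estimates the local neuropil contribution from `n_pixels` randomly
#' selected non-cell pixels (label 0) within `radius_px` of the ROI
#' centroid, normalises it with the same baseline-window rule and
#' subtracts it from the ROI dF/F. The pixel selection is seeded and
#' reproducible.
#'
#' @param movie numeric array, rows x cols x frames.
#' @param labels integer matrix (rows x cols), 0 = background/neuropil.
#' @param roi_id label of the ROI to correct.
#' @param radius_px neuropil sampling radius around the ROI centroid
#'   (default 70 pixels).
#' @param n_pixels number of neuropil pixels to draw (default: ROI size).
#'   If fewer are eligible, all are used with a warning; none is an error.
#' @param seed RNG seed for the pixel draw.
#' @return list with `corrected` (dF/F), `roi_dff`, `neuropil_dff`,
#'   `pixels` (linear indices of the drawn neuropil pixels) and `f0`s.
#' @export
neuropil_correct <- function(movie, labels, roi_id, radius_px = 70,
                             n_pixels = NULL, seed = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  ny <- dim(movie)[1]; nx <- dim(movie)[2]; nt <- dim(movie)[3]
  labels <- matrix(as.integer(labels), ny, nx)
  roi_lin <- which(labels == roi_id)
  if (length(roi_lin) == 0L)
    stop("no pixels with label ", roi_id, call. = FALSE)
  rows <- (roi_lin - 1L) %% ny + 1L
  cols <- (roi_lin - 1L) %/% ny + 1L
  cen <- c(mean(rows), mean(cols))
  all_rows <- rep(seq_len(ny), times = nx)
  all_cols <- rep(seq_len(nx), each = ny)
  within <- (all_rows - cen[1])^2 + (all_cols - cen[2])^2 <= radius_px^2
  eligible <- which(within & labels == 0L)
  if (length(eligible) == 0L)
    stop("no eligible neuropil pixels within ", radius_px,
         " px of ROI centroid", call. = FALSE)
  n_pixels <- n_pixels %||% length(roi_lin)
  if (length(eligible) < n_pixels) {
    warning(sprintf("only %d eligible neuropil pixels (requested %d); using all",
                    length(eligible), n_pixels))
    sel <- eligible
  } else {
    sel <- .with_seed(seed, sort(sample(eligible, n_pixels)))
  }
  flat <- matrix(movie, ny * nx, nt)
  roi_trace <- colMeans(flat[roi_lin, , drop = FALSE])
  np_trace <- colMeans(flat[sel, , drop = FALSE])
  roi_dff <- delta_f_over_f(roi_trace)
  np_dff <- delta_f_over_f(np_trace)
  list(corrected = roi_dff$dff - np_dff$dff, roi_dff = roi_dff$dff,
       neuropil_dff = np_dff$dff, pixels = sel,
       roi_f0 = roi_dff$f0, neuropil_f0 = np_dff$f0)
}

#' Global layer-2 event rate
#'
#' Averages fluorescence over all pixels of a rectangular layer-2 band
#' (neuropil included), normalises, detects events and reports the rate in
#' events per minute. Recordings shorter than `min_duration_min` (default
#' 5 min) are excluded unless `allow_short = TRUE`.
#'
#' @param movie numeric array rows x cols x frames, or `NULL` when `trace`
#'   is given directly.
#' @param band `c(row_min, row_max)` band of movie rows spanning layer 2.
#' @param sampling_rate frames per second.
#' @param trace optional pre-averaged band trace (overrides `movie`).
#' @param min_duration_min inclusion threshold in minutes.
#' @param allow_short override the inclusion rule (for testing).
#' @param threshold_sd,min_width,sd_method detection settings, see
#'   [detect_events()] and [estimate_noise_sd()].
#' @return list with `status` ("ok" or "excluded: < 5 min"),
#'   `rate_per_min`, `events`, `duration_min`.
#' @export
global_event_rate <- function(movie = NULL, band = NULL, sampling_rate,
                              trace = NULL, min_duration_min = 5,
                              allow_short = FALSE, threshold_sd = 2.5,
                              min_width = 2, sd_method = "mad") {
  .assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  if (is.null(trace)) {
    stopifnot(length(dim(movie)) == 3L, length(band) == 2L)
    ny <- dim(movie)[1]; nx <- dim(movie)[2]; nt <- dim(movie)[3]
    rows <- seq(band[1], band[2])
    flat <- matrix(movie, ny * nx, nt)
    lin <- as.vector(outer(rows, (seq_len(nx) - 1L) * ny, `+`))
    trace <- colMeans(flat[lin, , drop = FALSE])
  }
  duration_min <- length(trace) / sampling_rate / 60
  if (duration_min < min_duration_min && !allow_short)
    return(list(status = sprintf("excluded: < %g min", min_duration_min),
                rate_per_min = NA_real_, events = NULL,
                duration_min = duration_min))
  d <- delta_f_over_f(trace)
  ev <- detect_events(d$dff, .detection_sd(d, sd_method),
                      threshold_sd = threshold_sd, min_width = min_width)
  list(status = "ok", rate_per_min = nrow(ev) / duration_min, events = ev,
       duration_min = duration_min)
}

#' Detect events across a field of view
#'
#' Runs [delta_f_over_f()] and [detect_events()] on every ROI of a
#' [roi_trace_set()].
#'
#' @param rois a `roi_trace_set`.
#' @param threshold_sd,min_width see [detect_events()].
#' @param sd_method noise scale for the threshold: `"mad"` (robust, the
#'   default) or `"baseline_window"` (SD of the minimum-SD 6-sample
#'   window).
#' @return data.frame with `roi_id`, `onset`, `offset`, `width`,
#'   `peak_dff`; ROIs without events contribute no rows.
#' @export
detect_fov_events <- function(rois, threshold_sd = 2.5, min_width = 2,
                              sd_method = "mad") {
  stopifnot(inherits(rois, "roi_trace_set"))
  out <- lapply(seq_len(ncol(rois$traces)), function(j) {
    d <- delta_f_over_f(rois$traces[, j])
    ev <- detect_events(d$dff, .detection_sd(d, sd_method),
                        threshold_sd = threshold_sd, min_width = min_width)
    if (nrow(ev)) cbind(roi_id = rois$roi_id[j], ev) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(roi_id = integer(0), onset = integer(0),
                      offset = integer(0), width = integer(0),
                      peak_dff = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coactivity of layer-2 neurons as a function of depth
#'
#' For each event of each active ROI, the coactive set is the set of other
#' detected ROIs with at least one event whose span overlaps the reference
#' event's span (>= 1 shared frame). The per-event coactive fraction uses
#' the total number of detected ROIs in the field of view as denominator,
#' self excluded (the self-included convention is reported alongside), and
#' is averaged over the ROI's events. Records are binned into depth thirds
#' of layer 2 and a superficial-vs-deep comparison is emitted.
#'
#' @param events data.frame with `roi_id`, `onset`, `offset` (e.g. from
#'   [detect_fov_events()]).
#' @param rois data.frame with `roi_id` and `depth_norm` for every
#'   detected ROI in the field of view, or a [roi_trace_set()].
#' @return list of class `coactivity_result`: `records` (one row per
#'   active ROI: `roi_id`, `depth_norm`, `n_events`,
#'   `mean_coactive_fraction`, `mean_coactive_fraction_incl`, `third`) and
#'   `comparison` (superficial vs deep third: means, difference, Welch t
#'   p-value when both bins have >= 2 records).
#' @export
coactivity <- function(events, rois) {
  if (inherits(rois, "roi_trace_set"))
    rois <- data.frame(roi_id = rois$roi_id, depth_norm = rois$depth_norm)
  stopifnot(all(c("roi_id", "depth_norm") %in% names(rois)),
            all(c("roi_id", "onset", "offset") %in% names(events)))
  n_total <- nrow(rois)
  active <- sort(unique(events$roi_id))
  if (length(active) == 0L)
    stop("no active ROI: coactivity undefined", call. = FALSE)

  recs <- lapply(active, function(r) {
    ev_r <- events[events$roi_id == r, , drop = FALSE]
    frac <- vapply(seq_len(nrow(ev_r)), function(i) {
      hit <- events$onset <= ev_r$offset[i] & events$offset >= ev_r$onset[i]
      k <- length(setdiff(unique(events$roi_id[hit]), r))
      k
    }, 0)
    data.frame(
      roi_id = r,
      depth_norm = rois$depth_norm[match(r, rois$roi_id)],
      n_events = nrow(ev_r),
      mean_coactive_fraction =
        if (n_total > 1L) mean(frac / (n_total - 1L)) else NA_real_,
      mean_coactive_fraction_incl = mean((frac + 1) / n_total))
  })
  records <- do.call(rbind, recs)
  records$third <- cut(records$depth_norm, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
                       labels = c("superficial", "middle", "deep"),
                       right = FALSE)

  sup <- records$mean_coactive_fraction[records$third == "superficial"]
  dee <- records$mean_coactive_fraction[records$third == "deep"]
  comparison <- list(
    n_superficial = length(sup), n_deep = length(dee),
    mean_superficial = if (length(sup)) mean(sup) else NA_real_,
    mean_deep = if (length(dee)) mean(dee) else NA_real_,
    difference = if (length(sup) && length(dee)) mean(dee) - mean(sup)
      else NA_real_,
    p_value = if (length(sup) >= 2L && length(dee) >= 2L &&
                  (stats::sd(sup) > 0 || stats::sd(dee) > 0))
      stats::t.test(dee, sup)$p.value else NA_real_)
  structure(list(records = records, comparison = comparison,
                 n_detected_rois = n_total),
            class = "coactivity_result")
}

#' @export
print.coactivity_result <- function(x, ...) {
  cat(sprintf("<coactivity_result> %d active / %d detected ROIs\n",
              nrow(x$records), x$n_detected_rois))
  cmp <- x$comparison
  cat(sprintf("  superficial third: %.3f (n=%d)   deep third: %.3f (n=%d)\n",
              cmp$mean_superficial, cmp$n_superficial,
              cmp$mean_deep, cmp$n_deep))
  cat(sprintf("  deep - superficial = %+.3f (t-test p = %s)\n",
              cmp$difference,
              if (is.na(cmp$p_value)) "NA" else format.pval(cmp$p_value)))
  invisible(x)
}

#' Read a TIFF movie or label mask
#'
#' Thin wrappers over the tiff package. `read_movie_tiff()` returns a
#' rows x cols x frames array; `read_label_mask_tiff()` an integer matrix.
#'
#' @param path TIFF file path.
#' @return numeric array / integer matrix.
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF movies", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' @rdname read_movie_tiff
#' @export
read_label_mask_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF masks", call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Read per-ROI traces from a long-format CSV
#'
#' Expects columns `frame`, `roi_id`, `F` and optionally `depth_norm` and
#' `pixel_count` (constant within ROI).
#'
#' @param path CSV path.
#' @param sampling_rate frames per second.
#' @return A [roi_trace_set()].
#' @export
read_roi_traces_csv <- function(path, sampling_rate) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "roi_id", "F") %in% names(df)))
  ids <- sort(unique(df$roi_id))
  frames <- sort(unique(df$frame))
  traces <- matrix(NA_real_, length(frames), length(ids))
  for (j in seq_along(ids)) {
    sub <- df[df$roi_id == ids[j], ]
    traces[match(sub$frame, frames), j] <- sub$F
  }
  if (anyNA(traces)) stop("missing (frame, roi_id) combinations in ", path,
                          call. = FALSE)
  grab <- function(col) if (col %in% names(df))
    vapply(ids, function(i) df[[col]][match(i, df$roi_id)], 0) else NULL
  roi_trace_set(traces, sampling_rate, roi_id = ids,
                depth_norm = grab("depth_norm"),
                pixel_count = grab("pixel_count"))
}
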