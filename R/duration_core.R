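#' Signal-processing parameters of the EGM duration algorithm
#'
#' The algorithm has three knobs: the sliding SD-window length `w` (ms),
#' the SD-threshold `theta` as a fraction of the SD-curve maximum, and the
#' duration cutoff `c` (ms) above which an EGM counts as abnormally
#' prolonged. The validated operating point is 40 ms / 0.15 / 70 ms; the
#' ranges explored during validation were 10--45 ms, 0.10--0.50 and
#' 60--80 ms. Any `w` of at least 2 samples, `theta` in (0, 1] and positive
#' `c` are accepted.
#'
#' @param sd_window_ms Sliding SD-window length in ms (default 40).
#' @param sd_threshold_frac Fraction of the SD-curve maximum in (0, 1]
#'   (default 0.15).
#' @param duration_cutoff_ms Abnormality cutoff in ms (default 70);
#'   prolongation uses a strict `>` comparison.
#' @return An object of class `duration_params`.
#' @export
duration_params <- function(sd_window_ms = 40, sd_threshold_frac = 0.15,
                            duration_cutoff_ms = 70) {
  if (!.is_scalar_num(sd_window_ms) || sd_window_ms <= 0)
    .stopf("duration_params: sd_window_ms must be positive")
  if (!.is_scalar_num(sd_threshold_frac) ||
      sd_threshold_frac <= 0 || sd_threshold_frac > 1)
    .stopf("duration_params: sd_threshold_frac must be in (0, 1]")
  if (!.is_scalar_num(duration_cutoff_ms) || duration_cutoff_ms <= 0)
    .stopf("duration_params: duration_cutoff_ms must be positive")
  structure(list(sd_window_ms = sd_window_ms,
                 sd_threshold_frac = sd_threshold_frac,
                 duration_cutoff_ms = duration_cutoff_ms),
            class = "duration_params")
}

# centred moving-window population SD, window truncated at the edges.
# windows are [i - floor((wn-1)/2), i + floor(wn/2)], i.e. exactly wn
# samples in the interior for both parities. cumulative sums over the
# mean-centred trace keep the variance difference well conditioned.
.sliding_sd_num <- function(x, wn) {
  n <- length(x)
  if (wn < 2L) .stopf("sliding_sd: window must span at least 2 samples")
  if (wn > n) .stopf("sliding_sd: window (%d samples) longer than trace (%d)", wn, n)
  x0 <- x - mean(x)
  s1 <- c(0, cumsum(x0))
  s2 <- c(0, cumsum(x0 * x0))
  i <- seq_len(n)
  lo <- pmax(1L, i - (wn - 1L) %/% 2L)
  hi <- pmin(n, i + wn %/% 2L)
  k <- hi - lo + 1
  S1 <- s1[hi + 1L] - s1[lo]
  S2 <- s2[hi + 1L] - s2[lo]
  v <- S2 / k - (S1 / k)^2
  # windows whose variance is tiny relative to the cumulative-sum error
  # scale are ill-conditioned (catastrophic cancellation); recompute those
  # few directly so the curve matches a naive evaluation to full precision
  suspect <- which(v * k < s2[n + 1L] * 1e-4)
  for (i in suspect) {
    w <- x0[lo[i]:hi[i]]
    mw <- sum(w) / k[i]
    v[i] <- sum((w - mw)^2) / k[i]
  }
  sqrt(pmax(v, 0))
}

#' Sliding standard-deviation transform of an EGM
#'
#' Transforms the signal into its SD-curve: `values[i]` is the population
#' standard deviation (divide by n) of the samples in a window of
#' `sd_window_ms` centred at sample `i`. At the trace edges the window is
#' truncated to the available samples, so the curve has the same length as
#' the trace. The SD-curve tracks local changes in amplitude and frequency
#' and is the basis for onset/offset detection.
#'
#' @param trace An [egm_trace] (or numeric vector at 1 kHz).
#' @param sd_window_ms Window length in ms; converted to samples by
#'   rounding half up; must span at least 2 samples and at most the trace.
#' @return An object of class `sd_curve` with fields `values` (mV, all
#'   `>= 0`), `window_ms` and `sampling_rate_hz`.
#' @export
sliding_sd <- function(trace, sd_window_ms) {
  trace <- .as_trace(trace)
  wn <- .ms_to_samples(sd_window_ms, trace$sampling_rate_hz)
  structure(list(values = .sliding_sd_num(trace$samples, wn),
                 window_ms = sd_window_ms,
                 sampling_rate_hz = trace$sampling_rate_hz),
            class = "sd_curve")
}

#' Detect EGM onset and offset on an SD-curve
#'
#' The detection threshold is `sd_threshold_frac` times the SD-curve
#' maximum. Onset is the first sample at or above the threshold, offset the
#' last; both always exist when the curve has a positive maximum because
#' the argmax itself qualifies. A flat zero curve signals a trace with no
#' detectable activity: `degenerate = TRUE` and `NA` indices are returned
#' rather than an error, so batch processing of full maps never stops.
#'
#' @param curve An [sliding_sd()] result, or a bare non-negative numeric
#'   vector.
#' @param sd_threshold_frac Fraction of the curve maximum in (0, 1].
#' @return List with `onset`, `offset` (1-based sample indices, `NA` when
#'   degenerate) and `degenerate`.
#' @export
detect_onset_offset <- function(curve, sd_threshold_frac) {
  v <- if (inherits(curve, "sd_curve")) curve$values else as.numeric(curve)
  if (!.is_scalar_num(sd_threshold_frac) ||
      sd_threshold_frac <= 0 || sd_threshold_frac > 1)
    .stopf("detect_onset_offset: sd_threshold_frac must be in (0, 1]")
  m <- max(v)
  if (m <= 0)
    return(list(onset = NA_integer_, offset = NA_integer_, degenerate = TRUE))
  thr <- sd_threshold_frac * m
  hit <- which(v >= thr)
  list(onset = hit[1L], offset = hit[length(hit)], degenerate = FALSE)
}

.duration_result <- function(onset, offset, fs, cutoff_ms, degenerate) {
  if (degenerate)
    return(structure(list(onset_ms = NA_real_, offset_ms = NA_real_,
                          duration_ms = 0, prolonged = FALSE,
                          degenerate = TRUE),
                     class = "duration_result"))
  onset_ms <- (onset - 1) * 1000 / fs
  offset_ms <- (offset - 1) * 1000 / fs
  dur <- offset_ms - onset_ms
  structure(list(onset_ms = onset_ms, offset_ms = offset_ms,
                 duration_ms = dur, prolonged = dur > cutoff_ms,
                 degenerate = FALSE),
            class = "duration_result")
}

#' @export
print.duration_result <- function(x, ...) {
  if (x$degenerate) cat("<duration_result> degenerate (no detectable activity)\n")
  else cat(sprintf("<duration_result> onset %.1f ms, offset %.1f ms, duration %.1f ms%s\n",
                   x$onset_ms, x$offset_ms, x$duration_ms,
                   if (x$prolonged) " [prolonged]" else ""))
  invisible(x)
}

#' Estimate the duration of one bipolar EGM
#'
#' Full single-trace pipeline: zero-phase bandpass (and notch, when
#' enabled) -> sliding-SD transform -> percent-of-maximum threshold
#' detection -> duration in ms, flagged as prolonged when strictly greater
#' than the cutoff. Traces with a flat zero SD-curve (no activity) yield
#' duration 0 with `degenerate = TRUE`.
#'
#' @param trace An [egm_trace] (or numeric vector at 1 kHz).
#' @param params A [duration_params] object.
#' @param spec A [filter_spec]; the preprocessing applied before the
#'   SD transform.
#' @return An object of class `duration_result` with fields `onset_ms`,
#'   `offset_ms`, `duration_ms`, `prolonged`, `degenerate`.
#' @examples
#' tr <- generate_egm(egm_morphology("border"), seed = 1)
#' egm_duration(tr, duration_params(40, 0.15, 70))
#' @export
egm_duration <- function(trace, params = duration_params(),
                         spec = filter_spec()) {
  trace <- .as_trace(trace)
  filt <- egm_filter(trace, spec)
  curve <- sliding_sd(filt, params$sd_window_ms)
  det <- detect_onset_offset(curve, params$sd_threshold_frac)
  .duration_result(det$onset, det$offset, trace$sampling_rate_hz,
                   params$duration_cutoff_ms, det$degenerate)
}

#' Per-point EGM durations for a whole map
#'
#' Applies [egm_duration()] to every point of the map. Results are ordered
#' by `point_id`, so permuting the stored point order never changes the
#' output. The number of degenerate (no-activity) traces is logged.
#'
#' @param map An [eam_map].
#' @param params A [duration_params] object.
#' @param spec A [filter_spec].
#' @return `data.frame` with columns `point_id`, `onset_ms`, `offset_ms`,
#'   `duration_ms`, `prolonged`, `degenerate`, one row per point.
#' @export
map_durations <- function(map, params = duration_params(),
                          spec = filter_spec()) {
  if (!inherits(map, "eam_map")) .stopf("map_durations: 'map' must be an eam_map")
  if (nrow(map$points) == 0L) .stopf("map_durations: map has no points")
  fs <- map$sampling_rate_hz
  filt <- .filter_matrix(map$egm, fs, spec)
  wn <- .ms_to_samples(params$sd_window_ms, fs)
  n <- nrow(filt)
  onset <- offset <- rep(NA_integer_, n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    det <- detect_onset_offset(.sliding_sd_num(filt[i, ], wn),
                               params$sd_threshold_frac)
    degen[i] <- det$degenerate
    if (!det$degenerate) { onset[i] <- det$onset; offset[i] <- det$offset }
  }
  onset_ms <- (onset - 1) * 1000 / fs
  offset_ms <- (offset - 1) * 1000 / fs
  dur <- ifelse(degen, 0, offset_ms - onset_ms)
  res <- data.frame(point_id = map$points$point_id,
                    onset_ms = onset_ms, offset_ms = offset_ms,
                    duration_ms = dur,
                    prolonged = !degen & dur > params$duration_cutoff_ms,
                    degenerate = degen)
  res <- res[order(res$point_id), , drop = FALSE]
  rownames(res) <- NULL
  if (any(degen))
    .msg(sprintf("map %s: %d of %d traces degenerate (no detectable activity)",
                 map$patient_id, sum(degen), n))
  res
}
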