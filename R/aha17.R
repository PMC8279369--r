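# AHA 17-segment geometry
#
# Rings along the long axis (t = 0 at base_center, t = 1 at apex):
#   t < 1/3 basal, 1/3 <= t < 2/3 mid, 2/3 <= t < 0.85 apical, t >= 0.85 apex.
# Circumferential angle phi is measured from the septal direction,
# counterclockwise when viewed from the apex. The septum spans the
# anteroseptal and inferoseptal segments, so the mid-septal direction is
# their shared boundary: basal/mid sector edges sit at 0, 60, ..., 300 deg
# with [0,60) -> anteroseptal. The apical ring has four 90 deg sectors
# centred on the anatomical directions (septal sector centred at phi = 0,
# edges at -45/45/135/225 deg). All intervals are half-open on the lower
# edge, so the assignment is total and deterministic.

.BASAL_IDS <- c(2L, 1L, 6L, 5L, 4L, 3L)   # [0,60),[60,120),... from septum, ccw
.MID_IDS <- .BASAL_IDS + 6L
.APICAL_IDS <- c(14L, 13L, 16L, 15L)      # [-45,45),[45,135),...

#' Segment names of the AHA 17-segment model
#'
#' @return Character vector of length 17, indexed by segment id.
#' @export
aha_segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior",
    "apical lateral", "apex")
}

# segment adjacency (shared edges on the bull's-eye, rings linked by
# angular overlap); used by the synthetic cohort to grow border halos
.AHA_NEIGHBORS <- list(
  `1` = c(2L, 6L, 7L),          `2` = c(1L, 3L, 8L),
  `3` = c(2L, 4L, 9L),          `4` = c(3L, 5L, 10L),
  `5` = c(4L, 6L, 11L),         `6` = c(1L, 5L, 12L),
  `7` = c(1L, 8L, 12L, 13L),    `8` = c(2L, 7L, 9L, 13L, 14L),
  `9` = c(3L, 8L, 10L, 14L, 15L), `10` = c(4L, 9L, 11L, 15L),
  `11` = c(5L, 10L, 12L, 15L, 16L), `12` = c(6L, 7L, 11L, 13L, 16L),
  `13` = c(7L, 8L, 12L, 14L, 16L, 17L), `14` = c(8L, 9L, 13L, 15L, 17L),
  `15` = c(9L, 10L, 11L, 14L, 16L, 17L), `16` = c(11L, 12L, 13L, 15L, 17L),
  `17` = c(13L, 14L, 15L, 16L))

aha_neighbors <- function(segment) .AHA_NEIGHBORS[[as.character(segment)]]

#' Assign 3-D positions to AHA 17-segment ids
#'
#' Deterministic geometric assignment replacing manual expert landmarking:
#' the normalized long-axis coordinate selects the ring (basal / mid /
#' apical / apex cap at t >= 0.85) and the circumferential angle from the
#' septal direction selects the sector (six 60 degree sectors in the basal
#' and mid rings, four 90 degree sectors apically). See the package
#' vignette for the exact boundary conventions.
#'
#' @param position Numeric length-3 position in mm, or an n x 3 matrix.
#' @param landmarks An [lv_landmarks] object.
#' @param guard_mm Positions whose long-axis coordinate lies more than
#'   this many mm outside the base--apex extent trigger an out-of-chamber
#'   warning and are clamped to the nearest ring (default 30).
#' @return Integer vector of segment ids in 1..17.
#' @export
assign_segment <- function(position, landmarks, guard_mm = 30) {
  if (!inherits(landmarks, "lv_landmarks"))
    .stopf("assign_segment: 'landmarks' must be an lv_landmarks object")
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3L)
  axis <- landmarks$apex - landmarks$base_center
  L <- .vnorm(axis)
  u <- axis / L
  e1 <- landmarks$septal_direction
  e2 <- .cross3(u, e1)  # ccw viewed from the apex
  d <- sweep(p, 2L, landmarks$base_center)
  t_mm <- as.numeric(d %*% u)
  if (any(t_mm < -guard_mm | t_mm > L + guard_mm))
    warning(sprintf("assign_segment: %d position(s) lie > %g mm outside the long-axis extent; assigned to the nearest ring",
                    sum(t_mm < -guard_mm | t_mm > L + guard_mm), guard_mm),
            call. = FALSE)
  t <- pmin(1, pmax(0, t_mm / L))
  phi <- atan2(as.numeric(d %*% e2), as.numeric(d %*% e1)) %% (2 * pi)
  deg <- phi * 180 / pi
  seg <- integer(nrow(p))
  basal <- t < 1 / 3
  mid <- !basal & t < 2 / 3
  apical <- !basal & !mid & t < 0.85
  cap <- t >= 0.85
  sec6 <- pmin(5L, as.integer(deg %/% 60))
  seg[basal] <- .BASAL_IDS[sec6[basal] + 1L]
  seg[mid] <- .MID_IDS[sec6[mid] + 1L]
  sec4 <- pmin(3L, as.integer(((deg + 45) %% 360) %/% 90))
  seg[apical] <- .APICAL_IDS[sec4[apical] + 1L]
  seg[cap] <- 17L
  seg
}

#' Classify bipolar voltage into scar stages
#'
#' Standard substrate-mapping cutoffs: healthy myocardium above 1.0 mV,
#' scar border zone 0.2--1.0 mV (boundaries inclusive) and dense scar
#' below 0.2 mV.
#'
#' @param mean_voltage_mv Non-negative voltage(s) in mV.
#' @return Character vector in `c("healthy", "border", "dense")`.
#' @export
classify_voltage <- function(mean_voltage_mv) {
  if (!is.numeric(mean_voltage_mv) || anyNA(mean_voltage_mv) ||
      any(mean_voltage_mv < 0))
    .stopf("classify_voltage: voltages must be non-negative numbers")
  ifelse(mean_voltage_mv > 1.0, "healthy",
         ifelse(mean_voltage_mv < 0.2, "dense", "border"))
}

#' Per-segment summary of durations, voltage and ablation
#'
#' Aggregates per-point results onto the 17-segment model: per segment the
#' point count, the arithmetic mean EGM duration (degenerate no-activity
#' points excluded, exclusions logged), the arithmetic mean bipolar
#' voltage, the voltage class of that mean, whether any ablation lesion
#' falls in the segment, and the abnormality flag (segment mean duration
#' strictly greater than the cutoff). Empty segments carry voltage class
#' `"empty"` and `NA` flags.
#'
#' @param map An [eam_map].
#' @param durations Per-point results from [map_durations()]; must cover
#'   exactly the map's points.
#' @param cutoff_ms Duration cutoff in ms (default 70).
#' @param lesion_radius_mm Optional lesion radius: with the default 0 a
#'   segment is ablated iff a lesion centre is assigned to it; with a
#'   positive radius a segment is also ablated when any of its points lies
#'   within the radius of a lesion.
#' @return `data.frame` with 17 rows and columns `segment`, `n_points`,
#'   `mean_duration_ms`, `mean_voltage_mv`, `voltage_class`, `ablated`,
#'   `abnormal`.
#' @export
summarize_segments <- function(map, durations, cutoff_ms = 70,
                               lesion_radius_mm = 0) {
  if (!inherits(map, "eam_map"))
    .stopf("summarize_segments: 'map' must be an eam_map")
  if (!all(c("point_id", "duration_ms", "degenerate") %in% names(durations)))
    .stopf("summarize_segments: 'durations' must come from map_durations()")
  idx <- match(map$points$point_id, durations$point_id)
  if (anyNA(idx))
    .stopf("summarize_segments: durations do not cover all map points")
  dur <- durations$duration_ms[idx]
  degen <- durations$degenerate[idx]
  pos <- as.matrix(map$points[, c("x_mm", "y_mm", "z_mm")])
  seg <- assign_segment(pos, map$landmarks)
  if (sum(degen))
    .msg(sprintf("segment summary: excluding %d degenerate point(s) from duration means",
                 sum(degen)))
  segf <- factor(seg, levels = 1:17)
  n_points <- as.integer(table(segf))
  mean_dur <- as.numeric(tapply(dur[!degen], segf[!degen], mean))
  mean_volt <- as.numeric(tapply(map$points$bipolar_voltage_mv, segf, mean))
  ablated <- rep(FALSE, 17L)
  if (nrow(map$lesions) > 0L) {
    lpos <- as.matrix(map$lesions[, c("x_mm", "y_mm", "z_mm")])
    lseg <- assign_segment(lpos, map$landmarks)
    ablated[unique(lseg)] <- TRUE
    if (lesion_radius_mm > 0) {
      for (j in seq_len(nrow(lpos))) {
        d2 <- colSums((t(pos) - lpos[j, ])^2)
        near <- seg[d2 <= lesion_radius_mm^2]
        ablated[unique(near)] <- TRUE
      }
    }
  }
  empty <- n_points == 0L
  out <- data.frame(
    segment = 1:17,
    n_points = n_points,
    mean_duration_ms = mean_dur,
    mean_voltage_mv = mean_volt,
    voltage_class = ifelse(empty, "empty", classify_voltage(ifelse(empty, 0, mean_volt))),
    ablated = ifelse(empty, NA, ablated),
    abnormal = ifelse(empty | is.na(mean_dur), NA, mean_dur > cutoff_ms))
  attr(out, "cutoff_ms") <- cutoff_ms
  attr(out, "patient_id") <- map$patient_id
  out
}
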