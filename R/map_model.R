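#' Bipolar electrogram trace
#'
#' A single bipolar electrogram: a uniformly sampled voltage sequence (mV)
#' tied to a 3-D mapping point. The default sampling rate of 1000 Hz matches
#' high-density mapping exports in which samples are spaced 1 ms apart.
#'
#' @param samples Numeric vector of voltages in mV; non-empty, all finite.
#' @param sampling_rate_hz Samples per second; must be > 0. Default 1000.
#' @param point_id Identifier of the mapping point the trace belongs to.
#' @return An object of class `egm_trace`.
#' @export
egm_trace <- function(samples, sampling_rate_hz = 1000, point_id = NA_integer_) {
  if (length(samples) == 0L) .stopf("egm_trace: 'samples' must be non-empty")
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    .stopf("egm_trace: 'samples' must be finite numeric values")
  if (!.is_scalar_num(sampling_rate_hz) || sampling_rate_hz <= 0)
    .stopf("egm_trace: 'sampling_rate_hz' must be a positive number")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         point_id = point_id),
    class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat(sprintf("<egm_trace> point %s: %d samples @ %g Hz (%.0f ms), range [%.3g, %.3g] mV\n",
              as.character(x$point_id), length(x$samples), x$sampling_rate_hz,
              length(x$samples) * 1000 / x$sampling_rate_hz,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.egm_trace <- function(x) length(x$samples)

# accept either an egm_trace or a bare numeric vector (then rate required)
.as_trace <- function(trace, sampling_rate_hz = 1000) {
  if (inherits(trace, "egm_trace")) return(trace)
  egm_trace(trace, sampling_rate_hz)
}

#' Anatomical landmarks of a left-ventricular map
#'
#' Formalizes the manually set landmarks that anchor the 17-segment
#' transform: the apex, the centre of the mitral annulus plane
#' (`base_center`) and a direction in the short-axis plane pointing toward
#' the septum. The septal direction is re-projected orthogonal to the long
#' axis and normalised, so any vector with a non-zero short-axis component
#' is accepted.
#'
#' @param apex,base_center Numeric length-3 positions in mm.
#' @param septal_direction Numeric length-3 vector; projected orthogonal to
#'   the long axis (base -> apex) and scaled to unit norm.
#' @return An object of class `lv_landmarks` with fields `apex`,
#'   `base_center`, `septal_direction` (unit, orthogonal to the axis).
#' @export
lv_landmarks <- function(apex, base_center, septal_direction) {
  apex <- as.numeric(apex); base_center <- as.numeric(base_center)
  septal_direction <- as.numeric(septal_direction)
  for (v in list(apex, base_center, septal_direction))
    if (length(v) != 3L || !.is_num(v))
      .stopf("lv_landmarks: landmarks must be finite length-3 numeric vectors")
  axis <- apex - base_center
  L <- .vnorm(axis)
  if (L == 0) .stopf("lv_landmarks: apex and base_center must differ")
  u <- axis / L
  s <- septal_direction - sum(septal_direction * u) * u
  ns <- .vnorm(s)
  if (ns < 1e-9)
    .stopf("lv_landmarks: septal_direction is parallel to the long axis")
  structure(list(apex = apex, base_center = base_center,
                 septal_direction = s / ns),
            class = "lv_landmarks")
}

#' Electroanatomic map container
#'
#' A patient's high-density map: mapping points (3-D position in mm,
#' bipolar peak-to-peak voltage in mV, one EGM trace per point), optional
#' triangulated endocardial mesh, anatomical landmarks and ablation-lesion
#' coordinates. EGM traces are stored as one matrix row per point, all of
#' equal length, at a common sampling rate.
#'
#' @param patient_id Identifier string.
#' @param points `data.frame` with columns `point_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `bipolar_voltage_mv` and optionally `projection_distance_mm`
#'   (NA allowed: retained by projection filtering).
#' @param egm Numeric matrix, `nrow(points)` rows (same order as `points`),
#'   one EGM sample per column, in mV.
#' @param landmarks An [lv_landmarks] object.
#' @param sampling_rate_hz EGM sampling rate, default 1000.
#' @param mesh Optional list with `vertices` (n x 3 matrix, mm) and `faces`
#'   (m x 3 integer matrix of 1-based vertex indices).
#' @param lesions Optional `data.frame` with columns `x_mm`, `y_mm`, `z_mm`.
#' @return An object of class `eam_map`.
#' @export
eam_map <- function(patient_id, points, egm, landmarks,
                    sampling_rate_hz = 1000, mesh = NULL, lesions = NULL) {
  if (!is.data.frame(points)) .stopf("eam_map: 'points' must be a data.frame")
  req <- c("point_id", "x_mm", "y_mm", "z_mm", "bipolar_voltage_mv")
  miss <- setdiff(req, names(points))
  if (length(miss))
    .stopf("eam_map: points table is missing required field(s): %s",
           paste(miss, collapse = ", "))
  if (anyDuplicated(points$point_id))
    .stopf("eam_map: point_id values must be unique")
  if (any(points$bipolar_voltage_mv < 0, na.rm = TRUE))
    .stopf("eam_map: bipolar_voltage_mv must be >= 0")
  if (!"projection_distance_mm" %in% names(points))
    points$projection_distance_mm <- NA_real_
  if (any(points$projection_distance_mm < 0, na.rm = TRUE))
    .stopf("eam_map: projection_distance_mm must be >= 0")
  egm <- as.matrix(egm)
  if (nrow(egm) != nrow(points))
    .stopf("eam_map: EGM matrix has %d rows but points table has %d",
           nrow(egm), nrow(points))
  if (!inherits(landmarks, "lv_landmarks"))
    .stopf("eam_map: 'landmarks' must be an lv_landmarks object")
  if (!is.null(mesh)) {
    mesh$vertices <- as.matrix(mesh$vertices)
    mesh$faces <- matrix(as.integer(as.matrix(mesh$faces)), ncol = 3L)
    if (ncol(mesh$vertices) != 3L) .stopf("eam_map: mesh vertices must be n x 3")
    if (any(mesh$faces < 1L) || any(mesh$faces > nrow(mesh$vertices)))
      .stopf("eam_map: mesh face indices refer to non-existent vertices")
  }
  if (!is.null(lesions)) {
    lesions <- as.data.frame(lesions)
    if (!all(c("x_mm", "y_mm", "z_mm") %in% names(lesions)))
      .stopf("eam_map: lesions table requires columns x_mm, y_mm, z_mm")
  } else {
    lesions <- data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0))
  }
  structure(list(patient_id = as.character(patient_id),
                 points = points, egm = egm,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 landmarks = landmarks, mesh = mesh, lesions = lesions),
            class = "eam_map")
}

#' @export
print.eam_map <- function(x, ...) {
  cat(sprintf("<eam_map> patient %s: %d points, %d EGM samples @ %g Hz, %d lesions%s\n",
              x$patient_id, nrow(x$points), ncol(x$egm), x$sampling_rate_hz,
              nrow(x$lesions),
              if (is.null(x$mesh)) "" else
                sprintf(", mesh %d vertices / %d faces",
                        nrow(x$mesh$vertices), nrow(x$mesh$faces))))
  invisible(x)
}

#' Extract one point's trace from a map
#'
#' @param map An [eam_map].
#' @param point_id Identifier of the point.
#' @return An [egm_trace].
#' @export
map_trace <- function(map, point_id) {
  i <- match(point_id, map$points$point_id)
  if (is.na(i)) .stopf("map_trace: no point with id %s", as.character(point_id))
  egm_trace(map$egm[i, ], map$sampling_rate_hz, point_id)
}

# ------------------------------------------------------------------ EAMX I/O
# EAMX: a versioned open directory layout.
#   header.json        patient_id, schema_version, sampling_rate_hz,
#                      n_points, n_samples, landmarks
#   points.csv         point_id,x_mm,y_mm,z_mm,bipolar_voltage_mv,
#                      projection_distance_mm
#   egm.csv            point_id + s1..sN sample columns (mV)
#   mesh_vertices.csv  x_mm,y_mm,z_mm            (optional)
#   mesh_faces.csv     v1,v2,v3 0-based indices  (optional)
#   lesions.csv        x_mm,y_mm,z_mm            (optional)

.EAMX_VERSION <- "1.0"

# CSV writer preserving doubles bit-exactly (17 significant digits is
# sufficient for IEEE-754 round-trip; fwrite alone keeps only 15)
.fwrite_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  data.table::fwrite(df, path, quote = FALSE)
}

#' Write an electroanatomic map in EAMX format
#'
#' EAMX is this package's documented open interchange layout: a directory
#' holding a JSON header plus plain-text CSV tables (see Details). All
#' numeric fields round-trip exactly through [read_eamx()].
#'
#' @details Files written: `header.json`, `points.csv`, `egm.csv`, and,
#'   when present, `mesh_vertices.csv`, `mesh_faces.csv` (0-based indices
#'   on disk) and `lesions.csv`.
#' @param map An [eam_map].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_eamx <- function(map, path) {
  if (!inherits(map, "eam_map")) .stopf("write_eamx: 'map' must be an eam_map")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L)
    .stopf("write_eamx: cannot write to '%s'", path)
  hdr <- list(format = "EAMX", schema_version = .EAMX_VERSION,
              patient_id = map$patient_id,
              sampling_rate_hz = map$sampling_rate_hz,
              n_points = nrow(map$points), n_samples = ncol(map$egm),
              landmarks = list(apex = map$landmarks$apex,
                               base_center = map$landmarks$base_center,
                               septal_direction = map$landmarks$septal_direction))
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .fwrite_precise(map$points, file.path(path, "points.csv"))
  egm_df <- as.data.frame(map$egm)
  names(egm_df) <- paste0("s", seq_len(ncol(map$egm)))
  egm_df <- cbind(data.frame(point_id = map$points$point_id), egm_df)
  .fwrite_precise(egm_df, file.path(path, "egm.csv"))
  if (!is.null(map$mesh)) {
    v <- as.data.frame(map$mesh$vertices)
    names(v) <- c("x_mm", "y_mm", "z_mm")
    .fwrite_precise(v, file.path(path, "mesh_vertices.csv"))
    f <- as.data.frame(map$mesh$faces - 1L)
    names(f) <- c("v1", "v2", "v3")
    .fwrite_precise(f, file.path(path, "mesh_faces.csv"))
  }
  if (nrow(map$lesions))
    .fwrite_precise(map$lesions, file.path(path, "lesions.csv"))
  invisible(path)
}

#' Read an electroanatomic map in EAMX format
#'
#' @param path EAMX directory written by [write_eamx()] (or by any tool
#'   following the documented schema).
#' @param max_projection_mm Optional electrode-to-surface projection
#'   distance filter in mm: points whose `projection_distance_mm` exceeds
#'   it are dropped (points without a recorded distance are retained).
#'   High-density mapping systems typically acquire with a 3 mm limit.
#' @return An [eam_map].
#' @export
read_eamx <- function(path, max_projection_mm = NULL) {
  if (!dir.exists(path)) .stopf("read_eamx: no such directory '%s'", path)
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) .stopf("read_eamx: missing header.json in '%s'", path)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (f in c("patient_id", "sampling_rate_hz", "n_points", "n_samples", "landmarks"))
    if (is.null(hdr[[f]]))
      .stopf("read_eamx: header.json is missing required field '%s'", f)
  for (f in c("apex", "base_center", "septal_direction"))
    if (is.null(hdr$landmarks[[f]]))
      .stopf("read_eamx: header landmarks are missing required field '%s'", f)
  pts <- as.data.frame(data.table::fread(file.path(path, "points.csv")))
  req <- c("point_id", "x_mm", "y_mm", "z_mm", "bipolar_voltage_mv")
  miss <- setdiff(req, names(pts))
  if (length(miss))
    .stopf("read_eamx: points.csv is missing required field(s): %s",
           paste(miss, collapse = ", "))
  egm_dt <- data.table::fread(file.path(path, "egm.csv"))
  if (!"point_id" %in% names(egm_dt))
    .stopf("read_eamx: egm.csv is missing required field 'point_id'")
  if (ncol(egm_dt) - 1L != hdr$n_samples)
    .stopf("read_eamx: egm.csv has %d sample columns but header declares %d",
           ncol(egm_dt) - 1L, hdr$n_samples)
  if (nrow(egm_dt) != nrow(pts) || !identical(egm_dt$point_id, pts$point_id))
    .stopf("read_eamx: egm.csv rows do not match points.csv point_ids")
  egm <- as.matrix(egm_dt[, -1L])
  dimnames(egm) <- NULL
  mesh <- NULL
  if (file.exists(file.path(path, "mesh_vertices.csv"))) {
    v <- as.matrix(data.table::fread(file.path(path, "mesh_vertices.csv")))
    f <- as.matrix(data.table::fread(file.path(path, "mesh_faces.csv"))) + 1L
    dimnames(v) <- dimnames(f) <- NULL
    mesh <- list(vertices = v, faces = f)
  }
  lesions <- NULL
  if (file.exists(file.path(path, "lesions.csv")))
    lesions <- as.data.frame(data.table::fread(file.path(path, "lesions.csv")))
  lm <- lv_landmarks(hdr$landmarks$apex, hdr$landmarks$base_center,
                     hdr$landmarks$septal_direction)
  map <- eam_map(hdr$patient_id, pts, egm, lm,
                 sampling_rate_hz = hdr$sampling_rate_hz,
                 mesh = mesh, lesions = lesions)
  if (!is.null(max_projection_mm))
    map <- filter_projection(map, max_projection_mm)
  map
}

#' Drop points exceeding a projection-distance limit
#'
#' Points whose electrode-to-surface projection distance exceeds
#' `max_projection_mm` are removed; points with no recorded distance are
#' retained (only what is measurable is filtered). The operation is
#' idempotent.
#'
#' @param map An [eam_map].
#' @param max_projection_mm Limit in mm (mapping systems commonly use 3).
#' @return The filtered [eam_map].
#' @export
filter_projection <- function(map, max_projection_mm) {
  keep <- is.na(map$points$projection_distance_mm) |
    map$points$projection_distance_mm <= max_projection_mm
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    .msg(sprintf("projection filter (> %g mm): dropped %d of %d points",
                 max_projection_mm, n_drop, nrow(map$points)))
    map$points <- map$points[keep, , drop = FALSE]
    rownames(map$points) <- NULL
    map$egm <- map$egm[keep, , drop = FALSE]
  }
  map
}
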