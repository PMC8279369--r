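# Synthetic left-ventricular cohorts with scar architecture and
# class-specific EGM morphologies, so the whole pipeline is testable
# without clinical data.

#' EGM morphology archetype
#'
#' Operationalizes the three canonical substrate classes: healthy
#' myocardium (high-amplitude, short, sharp deflections), scar border zone
#' (low-amplitude, fractionated, prolonged) and dense scar (very
#' low-amplitude, prolonged). Class bands follow the standard voltage
#' cutoffs; `true_duration_ms` is the generator-side ground truth, defined
#' as the support of the noise-free composite wavelet above 1% of its
#' peak, independent of the detector under test.
#'
#' @param class `"healthy"`, `"border"` or `"dense"`.
#' @param true_duration_ms Ground-truth duration in ms. Defaults drawn per
#'   class: healthy 20--45, border 70--160, dense 70--200.
#' @param amplitude_mv Peak-to-peak amplitude in mV. Defaults per class:
#'   healthy 1.2--6, border 0.2--1.0, dense 0.03--0.19.
#' @param n_components Number of staggered wavelet components
#'   (fractionation). Defaults: healthy 1--2, border 3--6, dense 3--8.
#' @return An object of class `egm_morphology`.
#' @export
egm_morphology <- function(class = c("healthy", "border", "dense"),
                           true_duration_ms = NULL, amplitude_mv = NULL,
                           n_components = NULL) {
  class <- match.arg(class)
  if (is.null(true_duration_ms))
    true_duration_ms <- switch(class,
                               healthy = stats::runif(1, 20, 45),
                               border = stats::runif(1, 70, 160),
                               dense = stats::runif(1, 70, 200))
  if (is.null(amplitude_mv))
    amplitude_mv <- switch(class,
                           healthy = stats::runif(1, 1.2, 6),
                           border = stats::runif(1, 0.2, 1.0),
                           dense = stats::runif(1, 0.03, 0.19))
  if (is.null(n_components))
    n_components <- switch(class,
                           healthy = sample(1:2, 1),
                           border = sample(3:6, 1),
                           dense = sample(3:8, 1))
  ok <- switch(class,
               healthy = amplitude_mv > 1.0 && true_duration_ms < 50 &&
                 n_components <= 2,
               border = amplitude_mv >= 0.2 && amplitude_mv <= 1.0 &&
                 true_duration_ms >= 70 && true_duration_ms <= 160 &&
                 n_components >= 3,
               dense = amplitude_mv < 0.2 && true_duration_ms >= 70 &&
                 true_duration_ms <= 200)
  if (!ok) .stopf("egm_morphology: parameters violate the '%s' class bands", class)
  structure(list(class = class, true_duration_ms = true_duration_ms,
                 amplitude_mv = amplitude_mv, n_components = n_components),
            class = "egm_morphology")
}

#' Generate one synthetic bipolar EGM
#'
#' The waveform is a sum of `n_components` Gaussian-enveloped sinusoids
#' with per-component random centre frequencies in 80--200 Hz (so the
#' content survives the 30--250 Hz analysis bandpass), staggered to span
#' the requested ground-truth duration, centred in the trace, scaled to
#' the exact peak-to-peak amplitude and overlaid with white noise of the
#' given RMS. The envelope widths and stagger are rescaled iteratively so
#' the realized support (above 1% of peak) matches `true_duration_ms` to
#' within the sampling grid; the realized onset/offset/duration are
#' attached as the `truth` attribute.
#'
#' @param morphology An [egm_morphology].
#' @param sampling_rate_hz Sampling rate (default 1000).
#' @param trace_ms Trace length in ms; must be at least
#'   `true_duration_ms + 100`. Default 400.
#' @param noise_mv RMS of the additive white noise in mV (default 0.01,
#'   the noise floor of mini-basket acquisition).
#' @param seed Optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return An [egm_trace] with attribute `truth`: list with `onset_ms`,
#'   `offset_ms`, `duration_ms`, `class`.
#' @export
generate_egm <- function(morphology, sampling_rate_hz = 1000, trace_ms = 400,
                         noise_mv = 0.01, seed = NULL) {
  stopifnot(inherits(morphology, "egm_morphology"))
  D <- morphology$true_duration_ms
  if (trace_ms < D + 100)
    .stopf("generate_egm: trace_ms (%g) must be >= true_duration_ms + 100 (%g)",
           trace_ms, D + 100)
  .with_seed(seed, {
    fs <- sampling_rate_hz
    n <- .ms_to_samples(trace_ms, fs)
    t_ms <- (seq_len(n) - 1) * 1000 / fs
    mid <- (t_ms[1L] + t_ms[n]) / 2
    k <- morphology$n_components
    freq <- stats::runif(k, 80, 200)          # Hz
    amp <- stats::runif(k, 0.7, 1)            # relative component amplitudes
    phase <- stats::runif(k, 0, 2 * pi)
    # envelope width and stagger, rescaled so the 1%-of-peak support of the
    # composite matches D on the sampling grid
    sigma <- rep(D / (2.5 * k + 3.5), k)
    centers <- if (k == 1L) 0 else seq(-0.5, 0.5, length.out = k) *
      (D - 6.06 * sigma[1L])
    supp <- function(x) {
      idx <- which(abs(x) >= 0.01 * max(abs(x)))
      c(idx[1L], idx[length(idx)])
    }
    compose <- function(scl) {
      x <- numeric(n)
      for (j in seq_len(k)) {
        tc <- t_ms - mid - scl * centers[j]
        x <- x + amp[j] * sin(2 * pi * freq[j] * tc / 1000 + phase[j]) *
          exp(-tc^2 / (2 * (scl * sigma[j])^2))
      }
      x
    }
    scl <- 1
    for (it in 1:3) {
      x <- compose(scl)
      s <- supp(x)
      meas <- (s[2L] - s[1L]) * 1000 / fs
      if (meas > 0) scl <- scl * D / meas
    }
    x <- compose(scl)
    x <- x * morphology$amplitude_mv / (max(x) - min(x))
    s <- supp(x)
    truth <- list(onset_ms = t_ms[s[1L]], offset_ms = t_ms[s[2L]],
                  duration_ms = t_ms[s[2L]] - t_ms[s[1L]],
                  class = morphology$class)
    if (noise_mv > 0) x <- x + stats::rnorm(n, 0, noise_mv)
    out <- egm_trace(x, fs)
    attr(out, "truth") <- truth
    out
  })
}

#' Synthetic cohort specification
#'
#' The generator's defaults mirror the mapped-cohort conditions: 16
#' patients, high-density maps (default 2000 points; clinical maps average
#' about 7900), a 0.01 mV noise floor, dense-scar cores with a border-zone
#' halo, and ablation in the scar and halo segments.
#'
#' @param n_patients Number of patients (default 16).
#' @param points_per_map Mapping points per map (default 2000, minimum 17).
#' @param scar_segments Segments carrying a dense-scar core: an integer
#'   vector applied to every patient, a list of such vectors (one per
#'   patient), or `NULL` to draw per patient (1 basal/mid segment pair,
#'   favouring the inferior basal wall, plus its same-ring neighbour).
#' @param border_halo Surround the dense core with a border-zone annulus?
#'   Default `TRUE`.
#' @param noise_mv EGM noise RMS in mV (default 0.01).
#' @param ablate_on Ablation rule: `"scar_and_border"` (default; lesion
#'   sites drawn inside the scar and halo segments), `"scar_only"`, or an
#'   integer vector of segment ids (custom list, applied to every patient).
#' @param scar_radii Optional fixed `c(dense, border)` scar radii in mm;
#'   `NULL` (default) draws them per patient (dense core 14--24 mm, border
#'   annulus a further 8--22 mm) to emulate the natural variability of
#'   infarct extent.
#' @param trace_ms EGM window length in ms (default 400).
#' @param seed Random seed driving the whole cohort (default 1).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16, points_per_map = 2000,
                        scar_segments = NULL, border_halo = TRUE,
                        noise_mv = 0.01,
                        ablate_on = "scar_and_border",
                        scar_radii = NULL,
                        trace_ms = 400, seed = 1) {
  if (n_patients < 1) .stopf("cohort_spec: n_patients must be >= 1")
  if (points_per_map < 17) .stopf("cohort_spec: points_per_map must be >= 17")
  if (noise_mv < 0) .stopf("cohort_spec: noise_mv must be >= 0")
  if (is.character(ablate_on))
    ablate_on <- match.arg(ablate_on, c("scar_and_border", "scar_only"))
  else if (!all(ablate_on %in% 1:17))
    .stopf("cohort_spec: custom ablate_on must be segment ids in 1..17")
  if (identical(ablate_on, "scar_only") && !is.null(scar_segments) &&
      length(unlist(scar_segments)) == 0L)
    .stopf("cohort_spec: ablate_on='scar_only' requires non-empty scar_segments")
  if (!is.null(scar_radii) &&
      (length(scar_radii) != 2L || !.is_num(scar_radii) ||
       scar_radii[1L] <= 0 || scar_radii[2L] < scar_radii[1L]))
    .stopf("cohort_spec: scar_radii must be c(dense, border) with 0 < dense <= border")
  structure(list(n_patients = n_patients, points_per_map = points_per_map,
                 scar_segments = scar_segments, border_halo = border_halo,
                 noise_mv = noise_mv, ablate_on = ablate_on,
                 scar_radii = scar_radii,
                 trace_ms = trace_ms, seed = seed),
            class = "cohort_spec")
}

# truncated half-ellipsoid LV shell: base disc of radius 25 mm at the
# base_center plane, apex 80 mm away along the long axis
.LV_LENGTH <- 80
.LV_RADIUS <- 25

.lv_surface_point <- function(t, phi) {
  r <- .LV_RADIUS * sqrt(pmax(0, 1 - t^2))
  cbind(r * cos(phi), r * sin(phi), -.LV_LENGTH * t)
}

#' Generate the synthetic LV geometry
#'
#' Truncated-ellipsoid endocardial shell (long axis 80 mm, basal radius
#' 25 mm), triangulated on a regular axial/circumferential grid with an
#' apex cap, plus consistent landmarks: apex at the pole, base centre at
#' the truncation-plane centroid, septal direction along +x. The
#' construction is deterministic, so a given seed always yields a
#' bit-identical mesh.
#'
#' @param seed Unused by the deterministic construction; kept so cohort
#'   code can thread its seed through uniformly.
#' @param n_axial,n_circ Grid resolution (defaults 30 x 24).
#' @return List with `mesh` (vertices, 1-based faces) and `landmarks`.
#' @export
generate_geometry <- function(seed = 1, n_axial = 30, n_circ = 24) {
  tg <- seq(0, 0.995, length.out = n_axial)
  pg <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  grid <- expand.grid(phi = pg, t = tg, KEEP.OUT.ATTRS = FALSE)
  verts <- .lv_surface_point(grid$t, grid$phi)
  apex_idx <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -.LV_LENGTH))
  faces <- NULL
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  fl <- vector("list", (n_axial - 1L) * n_circ + n_circ)
  kf <- 0L
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_circ)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      kf <- kf + 1L
      fl[[kf]] <- rbind(c(a, b, d), c(a, d, cc))
    }
  }
  for (j in seq_len(n_circ)) {
    kf <- kf + 1L
    fl[[kf]] <- rbind(c(idx(n_axial, j), idx(n_axial, j + 1L), apex_idx))
  }
  faces <- do.call(rbind, fl)
  lm <- lv_landmarks(apex = c(0, 0, -.LV_LENGTH), base_center = c(0, 0, 0),
                     septal_direction = c(1, 0, 0))
  list(mesh = list(vertices = verts, faces = faces), landmarks = lm)
}

# area-weighted sampling of the shell (surface of revolution)
.sample_shell <- function(n) {
  tg <- seq(0.002, 0.998, length.out = 512L)
  r <- .LV_RADIUS * sqrt(1 - tg^2)
  drdt <- -.LV_RADIUS * tg / sqrt(1 - tg^2)
  w <- r * sqrt(.LV_LENGTH^2 + drdt^2)
  t <- sample(tg, n, replace = TRUE, prob = w) +
    stats::runif(n, -0.001, 0.001)
  t <- pmin(0.999, pmax(0, t))
  phi <- stats::runif(n, 0, 2 * pi)
  .lv_surface_point(t, phi)
}

# default per-patient scar designation: one basal/mid primary segment
# (favouring the inferior basal wall, where post-infarct scar is most
# frequent) plus one same-ring neighbour
.draw_scar_segments <- function() {
  cand <- c(3L, 4L, 5L, 9L, 10L, 11L)
  prob <- c(0.10, 0.375, 0.15, 0.10, 0.175, 0.10)
  primary <- sample(cand, 1L, prob = prob)
  ring <- if (primary <= 6L) 1:6 else 7:12
  side <- ring[(match(primary, ring) - 1L + c(-1L, 1L)) %% 6L + 1L]
  sort(c(primary, sample(side, 1L)))
}

# continuous scar architecture: per-point tissue class from the distance
# to the nearest scar-core centre (core -> dense, annulus -> border),
# with a jittered boundary so class fields cross segment borders the way
# real infarct scar does. Scar extent varies per patient (infarct size is
# highly variable), so border halos cover adjacent segments to varying
# degree: some ablated segments end up diluted with healthy tissue and
# classify voltage-healthy or duration-normal, as in clinical cohorts.
.SCAR_R_DENSE_RANGE <- c(14, 24)
.SCAR_R_BORDER_EXTRA <- c(8, 22)
.SCAR_EDGE_SD <- 4

.segment_centroids <- function(landmarks) {
  # centroids of the 17 segments on the analytic shell
  tg <- seq(0.01, 0.99, length.out = 60L)
  pg <- seq(0, 2 * pi, length.out = 121L)[-121L]
  grid <- expand.grid(t = tg, phi = pg, KEEP.OUT.ATTRS = FALSE)
  pos <- .lv_surface_point(grid$t, grid$phi)
  seg <- assign_segment(pos, landmarks)
  t(vapply(1:17, function(s) colMeans(pos[seg == s, , drop = FALSE]),
           numeric(3L)))
}

#' Generate a synthetic electroanatomic cohort
#'
#' For each patient, mapping points are sampled area-uniformly on the LV
#' shell; dense-scar cores are placed at the centroids of the designated
#' scar segments and each point's tissue class follows its (jittered)
#' distance to the nearest core, so dense scar grades into a border-zone
#' halo that grades into healthy myocardium across segment boundaries.
#' Voltages are drawn inside the class band, EGMs from the class
#' morphology archetypes, and ablation lesions are placed at 1--3 random
#' mapping points of every segment selected by the ablation rule (scar
#' segments and, by default, their halo neighbours). Everything is
#' reproducible from the spec seed.
#'
#' @param spec A [cohort_spec].
#' @return List of [eam_map] objects; each carries a `truth` attribute
#'   (`data.frame` with `point_id`, `class`, `true_duration_ms`,
#'   `true_onset_ms`, `true_offset_ms`) and a `roles` attribute (the
#'   per-segment role: `"scar"`, `"halo"` or `"healthy"`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  geo <- generate_geometry(spec$seed)
  cent <- .segment_centroids(geo$landmarks)
  .with_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(pat) {
      scar <- if (is.null(spec$scar_segments)) .draw_scar_segments()
        else if (is.list(spec$scar_segments)) as.integer(spec$scar_segments[[pat]])
        else as.integer(spec$scar_segments)
      halo <- if (spec$border_halo)
        sort(setdiff(unique(unlist(lapply(scar, aha_neighbors))), scar))
      else integer(0)
      roles <- rep("healthy", 17L)
      roles[halo] <- "halo"
      roles[scar] <- "scar"

      n <- spec$points_per_map
      pos <- .sample_shell(n)
      dmin <- sqrt(Reduce(pmin, lapply(scar, function(s)
        colSums((t(pos) - cent[s, ])^2))))
      dj <- dmin + stats::rnorm(n, 0, .SCAR_EDGE_SD)
      if (is.null(spec$scar_radii)) {
        r_dense <- stats::runif(1, .SCAR_R_DENSE_RANGE[1L], .SCAR_R_DENSE_RANGE[2L])
        r_border <- if (spec$border_halo)
          r_dense + stats::runif(1, .SCAR_R_BORDER_EXTRA[1L], .SCAR_R_BORDER_EXTRA[2L])
        else r_dense
      } else {
        r_dense <- spec$scar_radii[1L]
        r_border <- if (spec$border_halo) spec$scar_radii[2L] else r_dense
      }
      class <- ifelse(dj < r_dense, "dense",
                      ifelse(dj < r_border, "border", "healthy"))
      voltage <- numeric(n)
      voltage[class == "healthy"] <- stats::runif(sum(class == "healthy"), 1.2, 6)
      voltage[class == "border"] <- stats::runif(sum(class == "border"), 0.2, 1.0)
      voltage[class == "dense"] <- stats::runif(sum(class == "dense"), 0.03, 0.19)

      n_samp <- .ms_to_samples(spec$trace_ms, 1000)
      egm <- matrix(0, nrow = n, ncol = n_samp)
      truth <- data.frame(point_id = seq_len(n), class = class,
                          true_duration_ms = NA_real_,
                          true_onset_ms = NA_real_, true_offset_ms = NA_real_)
      for (i in seq_len(n)) {
        tr <- generate_egm(egm_morphology(class[i]), trace_ms = spec$trace_ms,
                           noise_mv = spec$noise_mv)
        egm[i, ] <- tr$samples
        tru <- attr(tr, "truth")
        truth$true_duration_ms[i] <- tru$duration_ms
        truth$true_onset_ms[i] <- tru$onset_ms
        truth$true_offset_ms[i] <- tru$offset_ms
      }

      seg <- assign_segment(pos, geo$landmarks)
      abl_segs <- switch(as.character(spec$ablate_on[1L]),
                         scar_and_border = c(scar, halo),
                         scar_only = scar,
                         as.integer(spec$ablate_on))
      # discrete lesion sites (VT-termination points), drawn uniformly at
      # random mapping points of the eligible segments; only a subset of
      # eligible segments ends up ablated, and because halo segments are
      # diluted with healthy tissue some ablated segments classify
      # voltage-healthy, as in clinical substrate modification
      members <- which(seg %in% abl_segs)
      lesions <- if (length(members)) {
        n_sites <- min(sample(7:12, 1L), length(members))
        pick <- sample(members, n_sites)
        data.frame(x_mm = pos[pick, 1L], y_mm = pos[pick, 2L],
                   z_mm = pos[pick, 3L])
      } else data.frame(x_mm = numeric(0), y_mm = numeric(0),
                        z_mm = numeric(0))

      pts <- data.frame(point_id = seq_len(n),
                        x_mm = pos[, 1L], y_mm = pos[, 2L], z_mm = pos[, 3L],
                        bipolar_voltage_mv = voltage,
                        projection_distance_mm = stats::runif(n, 0, 3))
      map <- eam_map(sprintf("SYN%02d", pat), pts, egm, geo$landmarks,
                     sampling_rate_hz = 1000, mesh = geo$mesh,
                     lesions = lesions)
      attr(map, "truth") <- truth
      attr(map, "roles") <- roles
      map
    })
  })
}
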