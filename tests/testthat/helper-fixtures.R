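# shared fixtures; everything is generated in code at test time

options(egmdur.verbose = FALSE)

test_landmarks <- function() {
  lv_landmarks(apex = c(0, 0, -80), base_center = c(0, 0, 0),
               septal_direction = c(1, 0, 0))
}

# brute-force oracle: centred truncated-window population SD, one window
# at a time (independent of the cumulative-sum implementation)
naive_sliding_sd <- function(x, wn) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - (wn - 1L) %/% 2L)
    hi <- min(n, i + wn %/% 2L)
    w <- x[lo:hi]
    sqrt(mean((w - mean(w))^2))
  }, numeric(1L))
}

# 1 s @ 1 kHz trace holding one band-limited wavelet of given support
# (onset at `at_ms`), on a configurable noise floor
burst_trace <- function(duration_ms = 60, at_ms = 400, amp_mv = 1,
                        noise_mv = 0.01, f_hz = 120, n_ms = 1000,
                        seed = NULL) {
  build <- function() {
    t_ms <- 0:(n_ms - 1)
    sigma <- duration_ms / 6.06   # support above 1% of peak = 6.06 sigma
    ctr <- at_ms + duration_ms / 2
    x <- sin(2 * pi * f_hz * (t_ms - ctr) / 1000) *
      exp(-(t_ms - ctr)^2 / (2 * sigma^2))
    x <- x * amp_mv / (max(x) - min(x))
    if (noise_mv > 0) x <- x + rnorm(n_ms, 0, noise_mv)
    egm_trace(x, 1000)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# position on the test-landmark shell at normalized long-axis depth t and
# circumferential angle phi measured in the landmark frame (from the
# septal direction, counterclockwise viewed from the apex)
shell_pos <- function(t, phi_deg) {
  lm <- test_landmarks()
  u <- (lm$apex - lm$base_center) / 80
  e1 <- lm$septal_direction
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  r <- 25 * sqrt(pmax(0, 1 - t^2))
  phi <- phi_deg * pi / 180
  cbind(r * cos(phi) * e1[1] + r * sin(phi) * e2[1],
        r * cos(phi) * e1[2] + r * sin(phi) * e2[2],
        -80 * t + r * cos(phi) * e1[3] + r * sin(phi) * e2[3])
}

# small hand-built map: points placed at chosen segment centroids so the
# per-segment composition is known by construction
toy_map <- function(seg_t, seg_phi_deg, voltages = NULL, egm = NULL,
                    lesions = NULL, patient_id = "TOY") {
  lm <- test_landmarks()
  n <- length(seg_t)
  pos <- shell_pos(seg_t, seg_phi_deg)
  if (is.null(voltages)) voltages <- rep(2, n)
  if (is.null(egm)) {
    egm <- matrix(0, n, 400)
    egm[, 180:220] <- matrix(rnorm(n * 41, 0, 0.3), n)
  }
  pts <- data.frame(point_id = seq_len(n), x_mm = pos[, 1], y_mm = pos[, 2],
                    z_mm = pos[, 3], bipolar_voltage_mv = voltages,
                    projection_distance_mm = NA_real_)
  eam_map(patient_id, pts, egm, lm, lesions = lesions)
}

# cohort at the validated study scale (16 patients x 2000 points), built
# once per test run and reused by the heavier end-to-end tests
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_spec(seed = 1))
    cache
  }
})

# scaled-down cohort for cheaper composition tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(n_patients = 3,
                                            points_per_map = 250, seed = 7))
    cache
  }
})
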