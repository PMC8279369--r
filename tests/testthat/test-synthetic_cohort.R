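test_that("morphology archetypes respect their class bands", {
  withr::local_seed(2)
  for (i in 1:25) {
    h <- egm_morphology("healthy")
    expect_true(h$amplitude_mv > 1 && h$true_duration_ms < 50 &&
                  h$n_components <= 2)
    b <- egm_morphology("border")
    expect_true(b$amplitude_mv >= 0.2 && b$amplitude_mv <= 1 &&
                  b$true_duration_ms >= 70 && b$true_duration_ms <= 160 &&
                  b$n_components >= 3)
    d <- egm_morphology("dense")
    expect_true(d$amplitude_mv < 0.2 && d$true_duration_ms >= 70 &&
                  d$true_duration_ms <= 200)
  }
  expect_error(egm_morphology("healthy", amplitude_mv = 0.5), "class bands")
  expect_error(egm_morphology("border", true_duration_ms = 30), "class bands")
})

test_that("generate_egm is deterministic, exactly scaled and truth-labelled", {
  m <- egm_morphology("border", true_duration_ms = 120, amplitude_mv = 0.8,
                      n_components = 4)
  a <- generate_egm(m, seed = 5)
  b <- generate_egm(m, seed = 5)
  expect_identical(a$samples, b$samples)
  # noiseless peak-to-peak equals the requested amplitude exactly
  clean <- generate_egm(m, noise_mv = 0, seed = 5)
  expect_equal(max(clean$samples) - min(clean$samples), 0.8,
               tolerance = 1e-9)
  # realized support matches the requested duration on the sample grid
  tru <- attr(clean, "truth")
  expect_lt(abs(tru$duration_ms - 120), 5)
  expect_equal(tru$offset_ms - tru$onset_ms, tru$duration_ms)
  # infeasible window errors
  expect_error(generate_egm(m, trace_ms = 150), "trace_ms")
  # the generator leaves the caller's RNG stream untouched when seeded
  withr::local_seed(77)
  before <- runif(1)
  withr::local_seed(77)
  invisible(generate_egm(m, seed = 5))
  expect_identical(runif(1), before)
})

test_that("the LV geometry is deterministic and covers all 17 segments", {
  g1 <- generate_geometry(1)
  g2 <- generate_geometry(1)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$mesh$faces, g2$mesh$faces)
  v <- g1$mesh$vertices
  expect_true(all(abs(v[, 1]) <= 25 + 1e-9 & abs(v[, 2]) <= 25 + 1e-9 &
                    v[, 3] >= -80 - 1e-9 & v[, 3] <= 1e-9))
  seg <- assign_segment(v, g1$landmarks)
  expect_setequal(unique(seg), 1:17)
  # faces index existing vertices
  expect_true(all(g1$mesh$faces >= 1 & g1$mesh$faces <= nrow(v)))
})

test_that("cohorts are reproducible from their seed", {
  s <- cohort_spec(n_patients = 2, points_per_map = 120, seed = 42)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1[[1L]]$egm, c2[[1L]]$egm)
  expect_identical(c1[[2L]]$points, c2[[2L]]$points)
  expect_identical(c1[[1L]]$lesions, c2[[1L]]$lesions)
  expect_identical(attr(c1[[2L]], "truth"), attr(c2[[2L]], "truth"))
  # and written EAMX files are byte-identical
  d <- withr::local_tempdir()
  write_eamx(c1[[1L]], file.path(d, "a"))
  write_eamx(c2[[1L]], file.path(d, "b"))
  for (f in list.files(file.path(d, "a")))
    expect_identical(readLines(file.path(d, "a", f)),
                     readLines(file.path(d, "b", f)))
})

test_that("generated voltages respect the class bands by construction", {
  maps <- small_cohort()
  for (m in maps) {
    tru <- attr(m, "truth")
    v <- m$points$bipolar_voltage_mv
    expect_true(all(v[tru$class == "healthy"] > 1.0))
    expect_true(all(v[tru$class == "border"] >= 0.2 &
                      v[tru$class == "border"] <= 1.0))
    expect_true(all(v[tru$class == "dense"] < 0.2))
    expect_equal(classify_voltage(v) == "healthy", tru$class == "healthy")
  }
})

test_that("scar core, halo and remote segments recover their classes", {
  # fixed calibrated radii, no noise, single scar segment with halo
  spec <- cohort_spec(n_patients = 1, points_per_map = 3000,
                      scar_segments = 4, border_halo = TRUE,
                      noise_mv = 0, scar_radii = c(20, 38), seed = 3)
  m <- generate_cohort(spec)[[1L]]
  dur <- data.frame(point_id = m$points$point_id, onset_ms = 0, offset_ms = 0,
                    duration_ms = attr(m, "truth")$true_duration_ms,
                    prolonged = FALSE, degenerate = FALSE)
  s <- summarize_segments(m, dur, cutoff_ms = 70)
  expect_equal(s$voltage_class[4L], "dense")
  neighbors <- c(3L, 5L, 10L)
  expect_true(all(s$voltage_class[neighbors] == "border"))
  remote <- setdiff(1:17, c(4L, neighbors))
  expect_true(all(s$voltage_class[remote] == "healthy"))
  # and the halo role drives where lesions can be placed
  lseg <- assign_segment(as.matrix(m$lesions), m$landmarks)
  expect_true(all(lseg %in% c(4L, neighbors)))
})

test_that("detected prolongation agrees with the generated class for most points", {
  m <- study_cohort()[[1L]]
  tru <- attr(m, "truth")
  res <- map_durations(m, duration_params(40, 0.15, 70))
  idx <- match(res$point_id, tru$point_id)
  want <- tru$class[idx] %in% c("border", "dense")
  expect_gte(mean(res$prolonged == want), 0.90)
})

test_that("segment duration means stabilise as maps grow", {
  # truth-level check on healthy (single-class) segments: doubling the
  # point count moves their mean true duration by < 2 ms
  base <- list(scar_segments = 4, scar_radii = c(20, 38), noise_mv = 0)
  m1 <- generate_cohort(do.call(cohort_spec, c(base, points_per_map = 2000,
                                               n_patients = 1, seed = 8)))[[1L]]
  m2 <- generate_cohort(do.call(cohort_spec, c(base, points_per_map = 4000,
                                               n_patients = 1, seed = 9)))[[1L]]
  seg_mean <- function(m) {
    tru <- attr(m, "truth")
    seg <- assign_segment(as.matrix(m$points[, c("x_mm", "y_mm", "z_mm")]),
                          m$landmarks)
    healthy_seg <- setdiff(1:17, c(4L, 3L, 5L, 10L))
    keep <- seg %in% healthy_seg & tru$class == "healthy"
    tapply(tru$true_duration_ms[keep], factor(seg[keep], levels = healthy_seg),
           mean)
  }
  expect_lt(max(abs(seg_mean(m1) - seg_mean(m2)), na.rm = TRUE), 2)
})

test_that("cohort spec validation catches inconsistent requests", {
  expect_error(cohort_spec(points_per_map = 10), ">= 17")
  expect_error(cohort_spec(noise_mv = -1), "noise_mv")
  expect_error(cohort_spec(ablate_on = c(25)), "segment ids")
  expect_error(cohort_spec(scar_radii = c(30, 20)), "scar_radii")
})
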