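#' 2x2 contingency table of segment abnormality vs. ablation
#'
#' Pools per-patient segment summaries into a single 2x2 table of
#' abnormal (segment mean duration above the cutoff) versus ablated
#' segments. Empty segments and segments with no usable duration mean are
#' excluded. With `pool = FALSE` a list of per-patient tables is returned
#' instead (the stratified mode).
#'
#' @param summaries A single [summarize_segments()] result or a list of
#'   them (one per patient).
#' @param pool Pool counts across patients? Default `TRUE`.
#' @return An object of class `contingency_table` with fields `tp`
#'   (abnormal & ablated), `fn` (normal & ablated), `fp` (abnormal & not
#'   ablated), `tn` (normal & not ablated); or a list of such objects.
#' @export
contingency_table <- function(summaries, pool = TRUE) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (!length(summaries)) .stopf("contingency_table: no summaries supplied")
  tally <- function(s) {
    keep <- !is.na(s$abnormal) & !is.na(s$ablated)
    s <- s[keep, , drop = FALSE]
    list(tp = sum(s$abnormal & s$ablated),
         fn = sum(!s$abnormal & s$ablated),
         fp = sum(s$abnormal & !s$ablated),
         tn = sum(!s$abnormal & !s$ablated))
  }
  if (!pool) {
    return(lapply(summaries, function(s)
      do.call(new_contingency_table, tally(s))))
  }
  cells <- Reduce(function(a, b) Map(`+`, a, b), lapply(summaries, tally))
  do.call(new_contingency_table, cells)
}

#' Construct a 2x2 contingency table from counts
#'
#' @param tp,fn,fp,tn Non-negative cell counts (abnormal/normal x
#'   ablated/not); the total must be positive.
#' @return An object of class `contingency_table`.
#' @export
new_contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) .stopf("contingency_table: counts must be >= 0")
  if (sum(cells) <= 0) .stopf("contingency_table: all segments empty (total count 0)")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> tp=%g fn=%g fp=%g tn=%g\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Diagnostic odds ratio with log-normal confidence interval
#'
#' DOR = (tp * tn) / (fn * fp): the odds that an abnormal segment (mean
#' EGM duration above the cutoff) is ablated, relative to a normal
#' segment. When any cell is zero the Haldane--Anscombe correction adds
#' 0.5 to every cell (`corrected = TRUE`). The confidence interval uses
#' the log-normal approximation
#' `exp(log(DOR) +/- z * sqrt(1/tp + 1/fn + 1/fp + 1/tn))` on the
#' (possibly corrected) cells, and the p-value is the matching two-sided
#' z-test of `log(DOR) = 0`.
#'
#' @param table A [contingency_table].
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @return An object of class `dor_result` with fields `dor`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`.
#' @export
diagnostic_odds_ratio <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$tp, table$fn, table$fp, table$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  dor <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(dor = dor,
                 ci_low = exp(log(dor) - z * se),
                 ci_high = exp(log(dor) + z * se),
                 p_value = 2 * stats::pnorm(-abs(log(dor)) / se),
                 corrected = corrected),
            class = "dor_result")
}

#' @export
print.dor_result <- function(x, ...) {
  cat(sprintf("<dor_result> DOR %.4g (95%% CI %.4g-%.4g), P = %.4g%s\n",
              x$dor, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Sensitivity and specificity of ablation-target prediction
#'
#' @param table A [contingency_table]; both margins (ablated and
#'   non-ablated) must be non-empty.
#' @return List with `sensitivity` = tp/(tp+fn) and `specificity` =
#'   tn/(fp+tn), as fractions.
#' @export
sensitivity_specificity <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$tp + table$fn <= 0)
    .stopf("sensitivity_specificity: undefined sensitivity (no ablated segments)")
  if (table$fp + table$tn <= 0)
    .stopf("sensitivity_specificity: undefined specificity (no non-ablated segments)")
  list(sensitivity = table$tp / (table$tp + table$fn),
       specificity = table$tn / (table$fp + table$tn))
}

#' Pearson chi-square test of a 2x2 table
#'
#' Pearson chi-square without continuity correction on 1 degree of
#' freedom (expected counts from the row/column margins).
#'
#' @param table A [contingency_table] with non-zero margins.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  m <- matrix(c(table$tp, table$fn, table$fp, table$tn), nrow = 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stopf("chi_square: a table margin is zero; the test is undefined")
  # small-expected-count caveats are the caller's concern; the statistic
  # itself is the deterministic Pearson formula
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Exact binomial test of a proportion
#'
#' Two-sided p-values use the exact minimum-likelihood method (the sum of
#' `P(X = j)` over all `j` whose point probability does not exceed that of
#' the observed `k`). One-sided p-values are the lower-tail probability
#' `P(X <= k)` under the null proportion, as used to ask whether an
#' observed proportion falls below a stated benchmark such as 0.95.
#'
#' @param k Observed successes (0..n).
#' @param n Number of trials.
#' @param p0 Null proportion in (0, 1).
#' @param sided `"two"` (default) or `"one"` (lower tail).
#' @return The p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!.is_scalar_num(k) || !.is_scalar_num(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    .stopf("binomial_test: need integer 0 <= k <= n")
  if (!.is_scalar_num(p0) || p0 <= 0 || p0 >= 1)
    .stopf("binomial_test: p0 must be in (0, 1)")
  if (sided == "two")
    stats::binom.test(k, n, p0, alternative = "two.sided")$p.value
  else
    stats::pbinom(k, n, p0)
}

#' Grid search of the signal-processing parameters by maximum DOR
#'
#' Evaluates the full (window, threshold, cutoff) lattice on a cohort of
#' maps: for each (w, theta) the per-point durations are computed once
#' (filtering is hoisted out of the loop entirely), then every duration
#' cutoff reuses the cached per-segment means. For every triple the pooled
#' 2x2 table across patients and its DOR (Haldane-corrected when a cell is
#' zero) are recorded; the selected operating point is the lattice argmax,
#' with ties broken toward the smallest window, then threshold, then
#' cutoff. The default lattice is the validated test range: windows
#' 10--45 ms and cutoffs 60--80 ms in 5 ms steps, thresholds 0.10--0.50 in
#' steps of 0.05.
#'
#' @param maps List of [eam_map] objects (the cohort).
#' @param w_range SD-window lengths in ms.
#' @param theta_range SD-threshold fractions.
#' @param c_range Duration cutoffs in ms.
#' @param spec A [filter_spec].
#' @param lesion_radius_mm Passed to the segment ablation rule.
#' @param alpha Significance level for the DOR confidence intervals.
#' @return An object of class `grid_search_result`: `best_params`
#'   ([duration_params]), `best_dor` ([diagnostic_odds_ratio] result) and
#'   `surface`, a `data.frame` with one row per (w, theta, c) triple and
#'   columns `w_ms`, `theta`, `c_ms`, `tp`, `fn`, `fp`, `tn`, `dor`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @export
grid_search_dor <- function(maps, w_range = seq(10, 45, by = 5),
                            theta_range = seq(0.10, 0.50, by = 0.05),
                            c_range = seq(60, 80, by = 5),
                            spec = filter_spec(), lesion_radius_mm = 0,
                            alpha = 0.05) {
  if (!length(maps)) .stopf("grid_search_dor: empty cohort")
  if (!length(w_range) || !length(theta_range) || !length(c_range))
    .stopf("grid_search_dor: empty parameter range")
  n_maps <- length(maps)

  # per-map invariants: filtered EGM matrix, segment ids, ablation flags
  prep <- lapply(maps, function(map) {
    pos <- as.matrix(map$points[, c("x_mm", "y_mm", "z_mm")])
    seg <- assign_segment(pos, map$landmarks)
    ablated <- rep(FALSE, 17L)
    if (nrow(map$lesions) > 0L) {
      lpos <- as.matrix(map$lesions[, c("x_mm", "y_mm", "z_mm")])
      ablated[unique(assign_segment(lpos, map$landmarks))] <- TRUE
      if (lesion_radius_mm > 0) {
        for (j in seq_len(nrow(lpos))) {
          d2 <- colSums((t(pos) - lpos[j, ])^2)
          ablated[unique(seg[d2 <= lesion_radius_mm^2])] <- TRUE
        }
      }
    }
    list(filt = .filter_matrix(map$egm, map$sampling_rate_hz, spec),
         fs = map$sampling_rate_hz, seg = factor(seg, levels = 1:17),
         ablated = ablated)
  })
  if (!any(vapply(prep, function(p) any(p$ablated), logical(1L))))
    .stopf("grid_search_dor: cohort contains no ablated segment; the DOR is undefined for every parameter triple")

  grid <- expand.grid(c_ms = c_range, theta = theta_range, w_ms = w_range,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("w_ms", "theta", "c_ms")]
  cells <- matrix(0, nrow = nrow(grid), ncol = 4L,
                  dimnames = list(NULL, c("tp", "fn", "fp", "tn")))

  n_c <- length(c_range)
  row0 <- 0L
  for (w in w_range) {
    sd_by_map <- lapply(prep, function(p) {
      wn <- .ms_to_samples(w, p$fs)
      S <- p$filt
      for (i in seq_len(nrow(S))) S[i, ] <- .sliding_sd_num(p$filt[i, ], wn)
      S
    })
    mx_by_map <- lapply(sd_by_map, function(S)
      do.call(pmax, as.data.frame(S)))
    for (theta in theta_range) {
      # per-map per-segment mean durations at (w, theta)
      seg_mean <- matrix(NA_real_, nrow = n_maps, ncol = 17L)
      seg_abl <- matrix(NA, nrow = n_maps, ncol = 17L)
      for (m in seq_len(n_maps)) {
        p <- prep[[m]]
        S <- sd_by_map[[m]]
        mx <- mx_by_map[[m]]
        live <- mx > 0
        thr <- theta * mx
        hit <- (S >= thr) + 0                 # thr recycles down columns
        onset <- max.col(hit, ties.method = "first")
        offset <- ncol(S) + 1L - max.col(hit[, ncol(S):1L, drop = FALSE],
                                         ties.method = "first")
        dur <- (offset - onset) * 1000 / p$fs
        ok <- live
        ssum <- tapply(dur[ok], p$seg[ok], sum)
        scnt <- tapply(rep(1, sum(ok)), p$seg[ok], sum)
        seg_mean[m, ] <- as.numeric(ssum) / as.numeric(scnt)
        has_pts <- as.integer(table(p$seg)) > 0L
        seg_abl[m, ] <- ifelse(has_pts, p$ablated, NA)
      }
      usable <- !is.na(seg_mean) & !is.na(seg_abl)
      for (ci in seq_along(c_range)) {
        cc <- c_range[ci]
        abn <- seg_mean > cc
        abl <- seg_abl
        cells[row0 + ci, ] <- c(
          sum(abn & abl & usable, na.rm = TRUE),
          sum(!abn & abl & usable, na.rm = TRUE),
          sum(abn & !abl & usable, na.rm = TRUE),
          sum(!abn & !abl & usable, na.rm = TRUE))
      }
      row0 <- row0 + n_c
    }
  }

  dres <- lapply(seq_len(nrow(grid)), function(i) {
    diagnostic_odds_ratio(new_contingency_table(cells[i, "tp"], cells[i, "fn"],
                                                cells[i, "fp"], cells[i, "tn"]),
                          alpha = alpha)
  })
  surface <- cbind(grid, as.data.frame(cells),
                   dor = vapply(dres, `[[`, numeric(1L), "dor"),
                   ci_low = vapply(dres, `[[`, numeric(1L), "ci_low"),
                   ci_high = vapply(dres, `[[`, numeric(1L), "ci_high"),
                   corrected = vapply(dres, `[[`, logical(1L), "corrected"))
  ord <- order(-surface$dor, surface$w_ms, surface$theta, surface$c_ms)
  best <- ord[1L]
  structure(list(
    best_params = duration_params(surface$w_ms[best], surface$theta[best],
                                  surface$c_ms[best]),
    best_dor = dres[[best]],
    surface = surface),
    class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  p <- x$best_params
  cat(sprintf("<grid_search_result> %d triples; best %g ms / %g / %g ms, DOR %.4g (95%% CI %.4g-%.4g)\n",
              nrow(x$surface), p$sd_window_ms, p$sd_threshold_frac,
              p$duration_cutoff_ms, x$best_dor$dor, x$best_dor$ci_low,
              x$best_dor$ci_high))
  invisible(x)
}
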