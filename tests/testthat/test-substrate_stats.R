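seg_fixture <- function(flags) {
  # minimal summary table carrying just the fields contingency needs
  data.frame(segment = seq_len(nrow(flags)), n_points = 10,
             mean_duration_ms = 80, mean_voltage_mv = 1,
             voltage_class = "border",
             ablated = flags$ablated, abnormal = flags$abnormal)
}

test_that("contingency pools abnormal x ablated counts over patients", {
  one <- seg_fixture(data.frame(abnormal = c(TRUE, TRUE, FALSE, FALSE),
                                ablated = c(TRUE, FALSE, TRUE, FALSE)))
  tab <- contingency_table(one)
  expect_equal(unlist(tab[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  # two identical patients double every cell
  tab2 <- contingency_table(list(one, one))
  expect_equal(unlist(tab2[c("tp", "fn", "fp", "tn")]),
               2 * unlist(tab[c("tp", "fn", "fp", "tn")]))
  # NA-flagged (empty) segments are excluded
  with_na <- one; with_na$abnormal[2L] <- NA
  expect_equal(contingency_table(with_na)$fp, 0)
  # stratified mode returns one table per patient
  strat <- contingency_table(list(one, one), pool = FALSE)
  expect_length(strat, 2L)
  expect_equal(strat[[1L]]$tp, 1)
  # a larger tally equals direct enumeration
  withr::local_seed(14)
  flags <- data.frame(abnormal = sample(c(TRUE, FALSE), 272, TRUE),
                      ablated = sample(c(TRUE, FALSE), 272, TRUE))
  big <- contingency_table(seg_fixture(flags))
  expect_equal(big$tp, sum(flags$abnormal & flags$ablated))
  expect_equal(big$tn, sum(!flags$abnormal & !flags$ablated))
  expect_error(new_contingency_table(0, 0, 0, 0), "total count 0")
})

test_that("DOR matches its closed form, with Haldane correction on zeros", {
  d <- diagnostic_odds_ratio(new_contingency_table(10, 5, 2, 20))
  expect_equal(d$dor, 20)
  expect_false(d$corrected)
  # CI by the log-normal approximation, checked against a manual evaluation
  se <- sqrt(1 / 10 + 1 / 5 + 1 / 2 + 1 / 20)
  expect_equal(d$ci_low, exp(log(20) - qnorm(0.975) * se))
  expect_equal(d$ci_high, exp(log(20) + qnorm(0.975) * se))
  expect_true(d$ci_low <= d$dor && d$dor <= d$ci_high)
  # zero cell: 0.5 added to all four cells
  dc <- diagnostic_odds_ratio(new_contingency_table(5, 0, 2, 10))
  expect_true(dc$corrected)
  expect_equal(dc$dor, (5.5 * 10.5) / (0.5 * 2.5))
  # swapping rows inverts the odds ratio
  d_inv <- diagnostic_odds_ratio(new_contingency_table(5, 10, 20, 2))
  expect_equal(d_inv$dor, 1 / 20)
  # independent table (proportional rows) has DOR 1
  d_ind <- diagnostic_odds_ratio(new_contingency_table(30, 10, 15, 5))
  expect_equal(d_ind$dor, 1, tolerance = 1e-12)
})

test_that("sensitivity/specificity are the margin ratios", {
  ss <- sensitivity_specificity(new_contingency_table(10, 5, 2, 20))
  expect_equal(ss$sensitivity, 10 / 15, tolerance = 1e-4)
  expect_equal(ss$specificity, 20 / 22, tolerance = 1e-4)
  perfect <- sensitivity_specificity(new_contingency_table(7, 0, 0, 9))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1))
  inverted <- sensitivity_specificity(new_contingency_table(0, 7, 9, 0))
  expect_equal(unlist(inverted), c(sensitivity = 0, specificity = 0))
  expect_error(sensitivity_specificity(new_contingency_table(0, 0, 2, 3)),
               "sensitivity")
  expect_error(sensitivity_specificity(new_contingency_table(2, 3, 0, 0)),
               "specificity")
})

test_that("chi-square is the uncorrected Pearson statistic", {
  even <- chi_square(new_contingency_table(10, 10, 10, 10))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  skew <- chi_square(new_contingency_table(20, 5, 5, 20))
  expect_equal(skew$statistic, 18)  # four cells of (7.5^2)/12.5
  # equals the squared two-proportion z statistic
  tab <- new_contingency_table(13, 7, 4, 19)
  z_num <- 13 / 17 - 7 / 26
  p_pool <- 20 / 43
  z <- z_num / sqrt(p_pool * (1 - p_pool) * (1 / 17 + 1 / 26))
  expect_equal(chi_square(tab)$statistic, z^2, tolerance = 1e-12)
  expect_error(chi_square(new_contingency_table(5, 0, 3, 0)), "margin")
})

test_that("binomial tests use exact tails and the minimum-likelihood rule", {
  # whole sample space
  expect_equal(binomial_test(1, 1, 0.95, sided = "one"), 1)
  # lower tail 0.5^3
  expect_equal(binomial_test(0, 3, 0.5, sided = "one"), 0.125)
  # symmetric mode has two-sided p = 1
  expect_equal(binomial_test(10, 20, 0.5), 1)
  # two-sided agrees with an independent minimum-likelihood enumeration
  for (case in list(c(3, 20, 0.4), c(17, 25, 0.5), c(2, 30, 0.2))) {
    k <- case[1]; n <- case[2]; p <- case[3]
    probs <- dbinom(0:n, n, p)
    want <- sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
    expect_equal(binomial_test(k, n, p), want, tolerance = 1e-12)
  }
  expect_error(binomial_test(5, 3, 0.5), "k <= n")
  expect_error(binomial_test(1, 3, 1.2), "p0")
})

test_that("the 95% CI covers a known true odds ratio at its nominal rate", {
  withr::local_seed(100)
  p1 <- 0.6; p2 <- 0.25; n1 <- 60; n2 <- 60
  true_or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  covered <- vapply(1:200, function(i) {
    tp <- rbinom(1, n1, p1); fp <- rbinom(1, n2, p2)
    d <- diagnostic_odds_ratio(new_contingency_table(tp, n1 - tp, fp, n2 - fp))
    d$ci_low <= true_or && true_or <= d$ci_high
  }, logical(1L))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("grid search reproduces the single-run pipeline and honours ties", {
  maps <- small_cohort()
  gs <- grid_search_dor(maps, w_range = c(20, 40), theta_range = c(0.15, 0.3),
                        c_range = c(60, 70, 80))
  expect_equal(nrow(gs$surface), 12L)
  # surface row at (40, 0.15, 70) equals an independent full-pipeline run
  summaries <- lapply(maps, function(m)
    summarize_segments(m, map_durations(m, duration_params(40, 0.15, 70)),
                       cutoff_ms = 70))
  tab <- contingency_table(summaries)
  row <- gs$surface[gs$surface$w_ms == 40 & gs$surface$theta == 0.15 &
                      gs$surface$c_ms == 70, ]
  expect_equal(c(row$tp, row$fn, row$fp, row$tn),
               c(tab$tp, tab$fn, tab$fp, tab$tn))
  expect_equal(row$dor, diagnostic_odds_ratio(tab)$dor)
  # best_dor is the surface maximum; ties break to smallest w, theta, c
  expect_equal(gs$best_dor$dor, max(gs$surface$dor))
  top <- gs$surface[gs$surface$dor == max(gs$surface$dor), ]
  top <- top[order(top$w_ms, top$theta, top$c_ms), ][1L, ]
  expect_equal(gs$best_params$sd_window_ms, top$w_ms)
  expect_equal(gs$best_params$duration_cutoff_ms, top$c_ms)
  # duplicating every patient doubles cells but keeps the argmax
  gs2 <- grid_search_dor(c(maps, maps), w_range = c(20, 40),
                         theta_range = c(0.15, 0.3), c_range = c(60, 70, 80))
  expect_equal(gs2$surface$tp, 2 * gs$surface$tp)
  expect_equal(gs2$best_params$sd_window_ms, gs$best_params$sd_window_ms)
  expect_equal(gs2$best_params$duration_cutoff_ms,
               gs$best_params$duration_cutoff_ms)
  # raising the cutoff never increases the abnormal count
  for (w in c(20, 40)) for (th in c(0.15, 0.3)) {
    s <- gs$surface[gs$surface$w_ms == w & gs$surface$theta == th, ]
    s <- s[order(s$c_ms), ]
    expect_true(all(diff(s$tp + s$fp) <= 0))
  }
})

test_that("grid search fails loudly when no segment was ablated", {
  maps <- lapply(small_cohort(), function(m) {
    m$lesions <- m$lesions[0, ]; m
  })
  expect_error(grid_search_dor(maps, w_range = 40, theta_range = 0.15,
                               c_range = 70), "no ablated segment")
})
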