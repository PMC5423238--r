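make_design <- function(days, levels, reps, analyte = "bup_like",
                        partner = "nal_like", partner_conc = 12.5) {
  rows <- expand.grid(replicate = seq_len(reps), level = levels,
                      day = seq_len(days))
  d <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(rows))),
                  day = rows$day, replicate = rows$replicate,
                  stringsAsFactors = FALSE)
  d[[paste0("conc_", analyte)]] <- rows$level
  d[[paste0("conc_", partner)]] <- partner_conc
  d
}

test_that("accuracy/precision cells reproduce hand-computed CV and Error", {
  design <- make_design(days = 2, levels = c(20, 50), reps = 3)
  set.seed(31)
  found <- design[[paste0("conc_", "bup_like")]] * runif(nrow(design), 0.97, 1.03)
  results <- data.frame(sample_id = design$sample_id, analyte = "bup_like",
                        concentration_ugml = found,
                        stringsAsFactors = FALSE)
  rep_tab <- accuracy_precision(results, design)
  # oracle: within-day cell for level 20, day 1
  sel <- design$day == 1 & design[["conc_bup_like"]] == 20
  w <- rep_tab[rep_tab$scope == "within_day" & rep_tab$day == 1 &
                 rep_tab$nominal_ugml == 20, ]
  expect_equal(w$mean_found, mean(found[sel]), tolerance = 1e-12)
  expect_equal(w$cv_pct, 100 * sd(found[sel]) / mean(found[sel]),
               tolerance = 1e-12)
  expect_equal(w$error_pct, 100 * (mean(found[sel]) - 20) / 20,
               tolerance = 1e-12)
  expect_equal(w$n, 3L)
  # between-day pools all days
  b <- rep_tab[rep_tab$scope == "between_day" & rep_tab$nominal_ugml == 50, ]
  selb <- design[["conc_bup_like"]] == 50
  expect_equal(b$n, 6L)
  expect_equal(b$sd_found, sd(found[selb]), tolerance = 1e-12)
})

test_that("a mean recovery of 19.97 at the 20 level is an Error of -0.15%", {
  design <- make_design(days = 1, levels = 20, reps = 3)
  results <- data.frame(sample_id = design$sample_id, analyte = "bup_like",
                        concentration_ugml = rep(19.97, 3),
                        stringsAsFactors = FALSE)
  rep_tab <- accuracy_precision(results, design)
  w <- rep_tab[rep_tab$scope == "within_day", ]
  expect_equal(w$error_pct, -0.15, tolerance = 1e-9)
  expect_equal(w$cv_pct, 0)
  expect_equal(w$sd_found, 0)
})

test_that("a mean of 49.95 at the 50 level is an Error of -0.10%", {
  design <- make_design(days = 1, levels = 50, reps = 3)
  results <- data.frame(sample_id = design$sample_id, analyte = "bup_like",
                        concentration_ugml = c(49.90, 49.95, 50.00),
                        stringsAsFactors = FALSE)
  rep_tab <- accuracy_precision(results, design)
  w <- rep_tab[rep_tab$scope == "within_day", ]
  expect_equal(w$error_pct, -0.10, tolerance = 1e-9)
})

test_that("unknown sample ids are a join error", {
  design <- make_design(days = 1, levels = 20, reps = 2)
  results <- data.frame(sample_id = c("s001", "ghost"), analyte = "bup_like",
                        concentration_ugml = c(20, 20),
                        stringsAsFactors = FALSE)
  expect_error(accuracy_precision(results, design), "ghost")
})

test_that("standard-addition recovery follows its definition", {
  r <- standard_addition_recovery(50, c(10, 20), c(60, 70))
  expect_equal(r$spikes$recovery_pct, c(100, 100))
  r2 <- standard_addition_recovery(50, 10, 60.5)
  expect_equal(r2$spikes$recovery_pct, 105)
  expect_error(standard_addition_recovery(50, c(0, 10), c(50, 60)), "> 0")
})

test_that("noise-free tablet spiking recovers 100% at every level", {
  sc <- quiet_config()
  st <- run_study(sc)
  expect_equal(st$recovery$a$spikes$recovery_pct, rep(100, 3),
               tolerance = 1e-3)
  expect_equal(st$recovery$b$spikes$recovery_pct, rep(100, 3),
               tolerance = 1e-3)
})

test_that("two-sample t behaves under symmetry and degeneracy", {
  expect_equal(two_sample_t(2, 0.1, 3, 2, 0.1, 3)$t, 0)
  t1 <- two_sample_t(2.05, 0.04, 3, 2.00, 0.02, 4)
  t2 <- two_sample_t(2.00, 0.02, 4, 2.05, 0.04, 3)
  expect_equal(t1$t, -t2$t, tolerance = 1e-12)
  expect_equal(t1$df, 5L)
  deg <- two_sample_t(2.1, 0, 3, 2.0, 0, 3)
  expect_true(deg$degenerate)
  expect_identical(deg$t, Inf)
})

test_that("pooled t on the printed tablet summaries is about 0.42", {
  # printed summary statistics are rounded, so the recomputed statistic
  # differs slightly from the published 0.397
  tt <- two_sample_t(2.01, 0.04, 3, 2.02, 0.01, 3)
  expect_equal(abs(tt$t), 0.42, tolerance = 0.005)
  expect_equal(tt$df, 4L)
})

test_that("variance-ratio F reproduces the worked tablet comparison", {
  f <- variance_ratio_f(0.01, 0.04)
  expect_equal(f, 0.0625, tolerance = 1e-12)
  expect_lte(abs(f - 0.063), 5.1e-4)  # printed value is the half-up rounding
  expect_equal(variance_ratio_f(0.02, 0.02), 1)
  expect_equal(variance_ratio_f(0.04, 0.01), 16)
  expect_equal(variance_ratio_f(0.01, 0.04),
               1 / variance_ratio_f(0.04, 0.01), tolerance = 1e-12)
  expect_error(variance_ratio_f(0.01, 0), "> 0")
})

test_that("critical values agree with published statistical tables", {
  expect_equal(round(t_critical(2, 0.05), 3), 4.303)
  expect_equal(round(f_critical(2, 2, 0.05), 2), 19.00)
  expect_equal(round(t_critical(Inf, 0.05), 3), 1.960)
  expect_error(t_critical(0, 0.05), "df")
  expect_error(f_critical(2, 2, 1.5), "alpha")
})

test_that("method comparison applies the reference-in-numerator convention", {
  mc <- method_comparison(2.01, 0.04, 3, 2.02, 0.01, 3)
  expect_lte(abs(mc$f_stat - 0.063), 5.1e-4)
  expect_equal(mc$t_df, 4L)
  expect_true(mc$equivalent)
  mc2 <- method_comparison(2.01, 0.04, 3, 2.02, 0.01, 3,
                           f_convention = "test_over_ref")
  expect_equal(mc2$f_stat, 16, tolerance = 1e-12)
  # zero-variance test method degenerates the ratio instead of erroring
  mc3 <- method_comparison(2.00, 0, 3, 2.001, 0.01, 3)
  expect_identical(mc3$f_stat, Inf)
})

test_that("paired t uses n - 1 degrees of freedom", {
  x <- c(2.01, 1.98, 2.03); y <- c(2.02, 1.99, 2.02)
  pt <- paired_t(x, y)
  expect_equal(pt$df, 2L)
  expect_equal(pt$t, t.test(x, y, paired = TRUE)$statistic[[1]],
               tolerance = 1e-12)
})
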