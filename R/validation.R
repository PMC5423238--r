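#' Within-day and between-day accuracy and precision
#'
#' Joins quantitation results to their nominal concentrations and tabulates,
#' per (analyte, level), the within-day cells (replicates of a single day,
#' typically n = 3) and the between-day cells (all days pooled, typically
#' n = 9) with
#' \describe{
#'   \item{cv_pct}{coefficient of variation, `100 * sd / mean` -- precision;}
#'   \item{error_pct}{relative error, `100 * (mean_found - nominal) /
#'     nominal` -- accuracy (negative means under-recovery).}
#' }
#'
#' @param results Data.frame of quantitation results ([quantify()] output)
#'   with columns `sample_id`, `analyte`, `concentration_ugml`.
#' @param design Data.frame with one row per sample: `sample_id`, `day`,
#'   `replicate`, and nominal concentrations in columns named
#'   `conc_<analyte>`.
#' @return Data.frame with columns `analyte`, `scope` (`"within_day"` /
#'   `"between_day"`), `day` (NA for between-day), `nominal_ugml`,
#'   `mean_found`, `sd_found`, `cv_pct`, `error_pct`, `n`.
#' @export
accuracy_precision <- function(results, design) {
  stopifnot(is.data.frame(results), is.data.frame(design))
  need <- c("sample_id", "analyte", "concentration_ugml")
  if (!all(need %in% names(results))) {
    stop("accuracy_precision: results must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  idx <- match(results$sample_id, design$sample_id)
  if (anyNA(idx)) {
    stop("accuracy_precision: sample id(s) not in design: ",
         paste(unique(results$sample_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  nominal <- vapply(seq_len(nrow(results)), function(i) {
    col <- paste0("conc_", results$analyte[i])
    if (is.null(design[[col]])) {
      stop("accuracy_precision: design lacks column '", col, "'",
           call. = FALSE)
    }
    design[[col]][idx[i]]
  }, 0)
  day <- design$day[idx]

  cell <- function(found, nom, scope, d) {
    m <- mean(found)
    s <- if (length(found) >= 2L) stats::sd(found) else NA_real_
    data.frame(analyte = NA_character_, scope = scope, day = d,
               nominal_ugml = nom, mean_found = m, sd_found = s,
               cv_pct = if (is.na(s)) NA_real_ else 100 * s / m,
               error_pct = 100 * (m - nom) / nom,
               n = length(found), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (an in unique(results$analyte)) {
    sel <- results$analyte == an
    for (nom in sort(unique(nominal[sel]))) {
      lv <- sel & nominal == nom
      for (d in sort(unique(day[lv]))) {
        r <- cell(results$concentration_ugml[lv & day == d], nom,
                  "within_day", d)
        r$analyte <- an
        rows[[length(rows) + 1L]] <- r
      }
      r <- cell(results$concentration_ugml[lv], nom, "between_day", NA)
      r$analyte <- an
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard-addition recovery
#'
#' Classical standard addition: the recovery of each spike is the found
#' increment over the unspiked sample, relative to the amount added:
#' `recovery_pct = 100 * (found_spiked - found_base) / added`.
#'
#' @param found_base Concentration found in the unspiked sample (ug/mL).
#' @param added Amounts added (ug/mL), all positive.
#' @param found_spiked Concentrations found in the spiked samples (ug/mL),
#'   same length as `added`.
#' @return An object of class `"recovery_report"`: data.frame `spikes`
#'   (added, found, recovery_pct) plus `mean_recovery_pct` and
#'   `sd_recovery_pct`.
#' @export
standard_addition_recovery <- function(found_base, added, found_spiked) {
  stopifnot(length(added) == length(found_spiked), length(found_base) == 1L)
  if (any(added <= 0)) {
    stop("standard_addition_recovery: added amounts must be > 0",
         call. = FALSE)
  }
  rec <- 100 * (found_spiked - found_base) / added
  structure(list(
    spikes = data.frame(added = added, found = found_spiked,
                        recovery_pct = rec),
    mean_recovery_pct = mean(rec),
    sd_recovery_pct = if (length(rec) >= 2L) stats::sd(rec) else NA_real_
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> standard addition\n")
  print(x$spikes, row.names = FALSE)
  cat(sprintf("  mean recovery %.2f%% +/- %.2f%% (n = %d)\n",
              x$mean_recovery_pct, x$sd_recovery_pct, nrow(x$spikes)))
  invisible(x)
}

#' Two-sample t statistic from summary statistics
#'
#' Pooled-variance two-sample t on (mean, sd, n) summaries, with
#' `df = n_a + n_b - 2`.  Two methods that agree give |t| below the critical
#' value.  When both SDs are zero the statistic is 0 for equal means and
#' +/-Inf (flagged) for unequal means.
#'
#' @param mean_a,sd_a,n_a Summary of group a.
#' @param mean_b,sd_b,n_b Summary of group b.
#' @return List with `t`, `df`, `degenerate` (TRUE when both SDs are zero
#'   and the means differ).
#' @export
two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2L, n_b >= 2L, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  if (se == 0) {
    if (mean_a == mean_b) {
      return(list(t = 0, df = df, degenerate = FALSE))
    }
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, degenerate = TRUE))
  }
  list(t = (mean_a - mean_b) / se, df = df, degenerate = FALSE)
}

#' Paired t statistic
#'
#' For n paired determinations (e.g. the same tablets assayed by two
#' methods), the t statistic of the mean difference with `df = n - 1`.
#'
#' @param x,y Paired observation vectors of equal length >= 2.
#' @return List with `t`, `df`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  sdd <- stats::sd(d)
  df <- length(d) - 1L
  if (sdd == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = df, degenerate = TRUE))
  }
  list(t = mean(d) / (sdd / sqrt(length(d))), df = df, degenerate = FALSE)
}

#' Variance-ratio F statistic
#'
#' `F = sd_num^2 / sd_den^2`.  The numerator/denominator assignment is the
#' caller's; [method_comparison()] offers a convention that places the
#' reference method's variance in the numerator.
#'
#' @param sd_num SD in the numerator, non-negative.
#' @param sd_den SD in the denominator, positive.
#' @return The F statistic (scalar, >= 0).
#' @export
variance_ratio_f <- function(sd_num, sd_den) {
  stopifnot(sd_num >= 0)
  if (sd_den <= 0) {
    stop("variance_ratio_f: denominator SD must be > 0", call. = FALSE)
  }
  (sd_num / sd_den)^2
}

#' Critical values of t and F
#'
#' Two-tailed Student t quantile at `1 - alpha/2` and upper F quantile at
#' `1 - alpha`.  `t_critical(2, 0.05)` is 4.303 and
#' `f_critical(2, 2, 0.05)` is 19.00, the familiar table entries for n = 3
#' per group; `df = Inf` gives the normal-quantile limit 1.960.
#'
#' @param df,df1,df2 Degrees of freedom (>= 1; `Inf` allowed for t).
#' @param alpha Significance level in (0, 1).
#' @return Critical value (scalar).
#' @export
t_critical <- function(df, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) {
    stop("t_critical: alpha must be in (0, 1)", call. = FALSE)
  }
  if (df < 1) stop("t_critical: df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' @rdname t_critical
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) {
    stop("f_critical: alpha must be in (0, 1)", call. = FALSE)
  }
  if (df1 < 1 || df2 < 1) stop("f_critical: df must be >= 1", call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

#' Method comparison by t- and F-test
#'
#' Compares a test method against a reference method from their summary
#' statistics: pooled two-sample t for the means and variance-ratio F for the
#' precisions.  With `f_convention = "match_paper"` the reference method's
#' variance goes in the numerator (the convention under which a test method
#' noisier than the reference gives F < 1).  The two methods are declared
#' equivalent when neither statistic exceeds its critical value.
#'
#' @param mean_test,sd_test,n_test Test-method summary.
#' @param mean_ref,sd_ref,n_ref Reference-method summary.
#' @param alpha Significance level; default 0.05.
#' @param f_convention `"match_paper"` (reference variance in the numerator)
#'   or `"test_over_ref"`.
#' @return An object of class `"method_comparison"`.
#' @export
method_comparison <- function(mean_test, sd_test, n_test,
                              mean_ref, sd_ref, n_ref, alpha = 0.05,
                              f_convention = c("match_paper",
                                               "test_over_ref")) {
  f_convention <- match.arg(f_convention)
  tt <- two_sample_t(mean_test, sd_test, n_test, mean_ref, sd_ref, n_ref)
  if (f_convention == "match_paper") {
    sds <- c(sd_ref, sd_test)
    fdf <- c(n_ref - 1L, n_test - 1L)
  } else {
    sds <- c(sd_test, sd_ref)
    fdf <- c(n_test - 1L, n_ref - 1L)
  }
  # a zero-variance group degenerates the ratio rather than erroring out
  f_stat <- if (sds[2L] > 0) variance_ratio_f(sds[1L], sds[2L])
            else if (sds[1L] == 0) 1 else Inf
  t_crit <- t_critical(tt$df, alpha)
  f_crit <- f_critical(fdf[1L], fdf[2L], alpha)
  structure(list(
    mean_test = mean_test, sd_test = sd_test, n_test = n_test,
    mean_ref = mean_ref, sd_ref = sd_ref, n_ref = n_ref,
    t_stat = tt$t, t_df = tt$df, f_stat = f_stat,
    f_df1 = fdf[1L], f_df2 = fdf[2L],
    t_crit = t_crit, f_crit = f_crit, alpha = alpha,
    f_convention = f_convention,
    degenerate_t = tt$degenerate,
    equivalent = is.finite(tt$t) && abs(tt$t) <= t_crit && f_stat <= f_crit
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  cat(sprintf("  test: %.4g +/- %.4g (n = %d); reference: %.4g +/- %.4g (n = %d)\n",
              x$mean_test, x$sd_test, x$n_test,
              x$mean_ref, x$sd_ref, x$n_ref))
  cat(sprintf("  t = %.3f (df %d, critical %.3f); F = %.3f (df %d,%d, critical %.2f)\n",
              x$t_stat, x$t_df, x$t_crit, x$f_stat, x$f_df1, x$f_df2,
              x$f_crit))
  cat("  methods", if (x$equivalent) "agree" else "DIFFER",
      sprintf("at alpha = %g\n", x$alpha))
  invisible(x)
}
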