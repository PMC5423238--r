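#' Study configuration
#'
#' Assembles the complete configuration of the in-silico assay study:
#' analyte presets, calibration and validation designs, derivative search
#' space, selection thresholds, noise model and master seed.  The defaults
#' reproduce the assay's study design: calibration over 7 levels 20-80 ug/mL
#' of the major analyte with 12.5 ug/mL of the minor one held fixed (and 7
#' levels 5-20 ug/mL against 50 ug/mL fixed), six replicate curves,
#' validation at 3 concentration levels x 3 replicates x 3 days, tablet
#' assay of a 2 mg / 0.5 mg label claim, and standard-addition recovery at
#' three spike levels.
#'
#' @param models Named list of two [analyte_model()]s; first is the major
#'   analyte ("a"), second the minor ("b").
#' @param grid A [wl_grid()].
#' @param noise A [noise_model()]; its seed field is ignored (per-stage
#'   seeds are spawned from `seed`).
#' @param seed Master seed; fixes the whole run bit-for-bit.
#' @param orders,delta_lambdas Derivative search space.  The default pins
#'   the established working point (third order, delta-lambda 28 nm); give
#'   vectors to search, e.g. `orders = 1:4, delta_lambdas = c(14, 28, 42)`.
#' @param backend Derivative backend for all stages.
#' @param max_residual,max_stability_nm Selection thresholds, see
#'   [select_working_pair()].
#' @param calib_levels_a,calib_levels_b Calibration levels (ug/mL).
#' @param calib_fixed_b,calib_fixed_a Fixed partner concentrations during
#'   calibration of a and of b respectively (ug/mL).
#' @param calib_replicates Replicates per calibration level.
#' @param val_levels_a,val_levels_b Validation levels (ug/mL).
#' @param val_days,val_replicates Validation days and replicates per day.
#' @param screen_levels_a,screen_levels_b Pure-component concentrations used
#'   for wavelength screening.
#' @param screen_scans Repeat scans averaged per screening level.
#' @param tablet_n Tablet determinations for the method comparison.
#' @param ref_sd_rel Relative SD of the simulated reference method.
#' @param spikes_a,spikes_b Standard-addition spike amounts (ug/mL).
#' @param excipient_baseline_au Excipient background amplitude for tablet
#'   spectra (AU).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(models = default_analyte_models(),
                         grid = wl_grid(),
                         noise = noise_model(),
                         seed = 20170501,
                         orders = 3L,
                         delta_lambdas = 28,
                         backend = "diff",
                         max_residual = 0.02,
                         max_stability_nm = 0.2,
                         calib_levels_a = c(20, 30, 40, 50, 60, 70, 80),
                         calib_levels_b = c(5, 7.5, 10, 12.5, 15, 17.5, 20),
                         calib_fixed_b = 12.5,
                         calib_fixed_a = 50,
                         calib_replicates = 6L,
                         val_levels_a = c(20, 50, 80),
                         val_levels_b = c(5, 12.5, 20),
                         val_days = 3L,
                         val_replicates = 3L,
                         screen_levels_a = c(20, 40, 60, 80),
                         screen_levels_b = c(5, 10, 15, 20),
                         screen_scans = 6L,
                         tablet_n = 3L,
                         ref_sd_rel = 0.005,
                         spikes_a = c(10, 20, 30),
                         spikes_b = c(2.5, 5, 7.5),
                         excipient_baseline_au = 0.003) {
  stopifnot(length(models) == 2L,
            inherits(models[[1L]], "analyte_model"),
            inherits(models[[2L]], "analyte_model"))
  rng <- function(m, lv) {
    if (any(lv < m$valid_range[1L] | lv > m$valid_range[2L])) {
      stop("study_config: levels ", paste(lv, collapse = ", "),
           " outside the valid range of '", m$name, "'", call. = FALSE)
    }
  }
  rng(models[[1L]], calib_levels_a); rng(models[[2L]], calib_levels_b)
  rng(models[[1L]], val_levels_a); rng(models[[2L]], val_levels_b)
  structure(list(
    models = models, grid = grid, noise = noise, seed = as.integer(seed),
    orders = as.integer(orders), delta_lambdas = delta_lambdas,
    backend = backend,
    max_residual = max_residual, max_stability_nm = max_stability_nm,
    calib_levels_a = calib_levels_a, calib_levels_b = calib_levels_b,
    calib_fixed_b = calib_fixed_b, calib_fixed_a = calib_fixed_a,
    calib_replicates = as.integer(calib_replicates),
    val_levels_a = val_levels_a, val_levels_b = val_levels_b,
    val_days = as.integer(val_days),
    val_replicates = as.integer(val_replicates),
    screen_levels_a = screen_levels_a, screen_levels_b = screen_levels_b,
    screen_scans = as.integer(screen_scans),
    tablet_n = as.integer(tablet_n), ref_sd_rel = ref_sd_rel,
    spikes_a = spikes_a, spikes_b = spikes_b,
    excipient_baseline_au = excipient_baseline_au
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Scalar fields of [study_config()] can be overridden from a YAML file;
#' analyte models may be given as `models: {a: {name:, valid_range: [lo,
#' hi], bands: [[center, sigma, epsilon], ...]}, b: {...}}`.
#'
#' @param path YAML file path.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$models)) {
    args$models <- lapply(y$models, function(m) {
      analyte_model(m$name, lapply(m$bands, function(b)
        gaussian_band(b[[1L]], b[[2L]], b[[3L]])),
        as.numeric(m$valid_range))
    })
  }
  if (!is.null(y$grid)) {
    args$grid <- wl_grid(y$grid$start_nm, y$grid$stop_nm, y$grid$step_nm)
  }
  if (!is.null(y$noise)) {
    args$noise <- noise_model(
      sd_au = if (is.null(y$noise$sd_au)) 0.002 else y$noise$sd_au,
      baseline_drift_au = if (is.null(y$noise$baseline_drift_au)) 0.005
                          else y$noise$baseline_drift_au)
  }
  scalar <- intersect(names(y), setdiff(names(formals(study_config)),
                                        c("models", "grid", "noise")))
  args[scalar] <- y[scalar]
  do.call(study_config, args)
}

# Pure-component screening spectra for one analyte, one per level; each
# level is the average of `scans` repeat scans, the usual practice when
# assigning working wavelengths from standards.
screen_set <- function(model, levels, noise, grid, seed, scans = 6L) {
  lapply(seq_along(levels), function(i) {
    reps <- lapply(seq_len(scans), function(j) {
      nz <- noise
      if (!is.null(nz)) nz$seed <- derive_seed(seed, 100L * i + j)
      simulate_spectrum(model, levels[i], noise = nz, grid = grid)$absorbance
    })
    spectrum(grid, Reduce(`+`, reps) / scans,
             label = sprintf("%s_screen_%g", model$name, levels[i]),
             meta = list(analyte = model$name, conc = levels[i],
                         scans = scans))
  })
}

#' Optimize derivative settings and select working wavelengths
#'
#' Loops [screen_candidates()] and [select_working_pair()] over the
#' derivative search space (orders x delta-lambda values) and retains the
#' feasible setting whose worse analyte has the best noise-normalized
#' sensitivity, i.e. the expected signal-to-noise of the top-of-range
#' reading given the noise gain of the difference kernel at that order and
#' offset.  This is the algorithmic form of tuning order and delta-lambda
#' for maximum sensitivity and reproducibility.
#'
#' @param config A [study_config()].
#' @param seed Seed for the screening spectra.
#' @return List with `selection` (from [select_working_pair()]), `order`,
#'   `delta_lambda_nm`, `candidates_a`, `candidates_b`, and the score
#'   `table` of all settings tried.
#' @export
optimize_settings <- function(config, seed = config$seed) {
  ma <- config$models[[1L]]; mb <- config$models[[2L]]
  sa <- screen_set(ma, config$screen_levels_a, config$noise, config$grid,
                   derive_seed(seed, 101L), scans = config$screen_scans)
  sb <- screen_set(mb, config$screen_levels_b, config$noise, config$grid,
                   derive_seed(seed, 202L), scans = config$screen_scans)
  best <- NULL
  rows <- list()
  for (ord in config$orders) {
    for (dl in config$delta_lambdas) {
      res <- try({
        ca <- screen_candidates(sa, sb, ord, dl, backend = config$backend)
        cb <- screen_candidates(sb, sa, ord, dl, backend = config$backend)
        sel <- select_working_pair(ca, cb, config$max_residual,
                                   config$max_stability_nm)
        # noise SD gain of the iterated difference kernel
        gain <- sqrt(choose(2 * ord, ord)) / dl^ord
        snr <- min(sel$a$sensitivity * max(config$calib_levels_a),
                   sel$b$sensitivity * max(config$calib_levels_b)) /
          (config$noise$sd_au * gain)
        list(sel = sel, snr = snr, ca = ca, cb = cb)
      }, silent = TRUE)
      ok <- !inherits(res, "try-error")
      rows[[length(rows) + 1L]] <- data.frame(
        order = ord, delta_lambda_nm = dl, feasible = ok,
        snr = if (ok) res$snr else NA_real_)
      if (ok && (is.null(best) || res$snr > best$snr)) {
        best <- c(res, list(order = ord, delta_lambda_nm = dl))
      }
    }
  }
  if (is.null(best)) {
    stop("optimize_settings: no (order, delta_lambda) setting produced a ",
         "feasible working pair", call. = FALSE)
  }
  list(selection = best$sel, order = best$order,
       delta_lambda_nm = best$delta_lambda_nm,
       candidates_a = best$ca, candidates_b = best$cb,
       table = do.call(rbind, rows))
}

measure_amplitude <- function(spec, wavelength_nm, order, dl, backend) {
  amplitude_at(derivative(spec, order, dl, backend = backend), wavelength_nm)
}

#' Run the complete in-silico assay study
#'
#' Executes every stage of the zero-crossing derivative assay on synthetic
#' spectra: wavelength screening and selection, calibration of both
#' analytes, a within/between-day validation campaign, a tablet assay
#' compared against a simulated reference method by t- and F-test, and
#' standard-addition recovery.  All randomness derives from the
#' configuration's master seed, so a run is bit-for-bit reproducible.
#'
#' @param config A [study_config()].
#' @param seed Optional master-seed override.
#' @return An object of class `"zc_study"`: list with `selection`,
#'   `settings`, `calibration` (curves + summary table), `precision_accuracy`
#'   (within/between-day table), `tablet` (per-analyte method comparisons),
#'   `recovery` (per-analyte recovery reports), `manifest`.
#' @examples
#' \donttest{
#' st <- run_study(study_config(seed = 1))
#' print(st)
#' }
#' @export
run_study <- function(config = study_config(), seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  master <- config$seed
  ma <- config$models[[1L]]; mb <- config$models[[2L]]
  noise <- config$noise
  grid <- config$grid
  backend <- config$backend

  ## 1. wavelength screening / settings optimization
  opt <- optimize_settings(config, seed = derive_seed(master, 1L))
  ord <- opt$order; dl <- opt$delta_lambda_nm
  wl_a <- opt$selection$a$wavelength_nm
  wl_b <- opt$selection$b$wavelength_nm

  ## 2. calibration (mixtures, varied analyte against fixed partner)
  fit_one <- function(varied, levels, fixed, fixed_conc, wl, stage_seed,
                      analyte) {
    nz <- noise; nz$seed <- stage_seed
    specs <- generate_calibration_set(varied, levels, fixed, fixed_conc,
                                      noise = nz,
                                      replicates = config$calib_replicates,
                                      grid = grid)
    conc <- vapply(specs, function(s) s$meta$level, 0)
    amp <- vapply(specs, measure_amplitude, 0, wavelength_nm = wl,
                  order = ord, dl = dl, backend = backend)
    fit_calibration(conc, amp, range_ugml = range(levels),
                    wavelength_nm = wl, order = ord, delta_lambda_nm = dl,
                    analyte = analyte)
  }
  curve_a <- fit_one(ma, config$calib_levels_a, mb, config$calib_fixed_b,
                     wl_a, derive_seed(master, 2L), ma$name)
  curve_b <- fit_one(mb, config$calib_levels_b, ma, config$calib_fixed_a,
                     wl_b, derive_seed(master, 3L), mb$name)

  calib_table <- do.call(rbind, lapply(list(curve_a, curve_b), function(cc) {
    data.frame(analyte = cc$analyte, wavelength_nm = cc$wavelength_nm,
               order = cc$order, delta_lambda_nm = cc$delta_lambda_nm,
               range_low = cc$range_ugml[1L], range_high = cc$range_ugml[2L],
               slope = cc$slope, intercept = cc$intercept,
               sd_slope = cc$sd_slope, rsd_slope_pct = cc$rsd_slope_pct,
               sd_intercept = cc$sd_intercept, r = cc$r,
               n_points = cc$n_points, stringsAsFactors = FALSE)
  }))

  ## 3. within/between-day validation campaign
  val_seed <- derive_seed(master, 4L)
  design_rows <- list()
  results_rows <- list()
  k <- 0L
  run_val <- function(varied, levels, fixed, fixed_conc, wl, curve, tag) {
    for (d in seq_len(config$val_days)) {
      for (lv in levels) {
        for (r in seq_len(config$val_replicates)) {
          k <<- k + 1L
          sid <- sprintf("%s_d%d_c%g_r%d", tag, d, lv, r)
          nz <- noise; nz$seed <- derive_seed(val_seed, k)
          sp <- simulate_spectrum(list(varied, fixed), c(lv, fixed_conc),
                                  noise = nz, grid = grid, label = sid)
          amp <- measure_amplitude(sp, wl, ord, dl, backend)
          # boundary levels sit on the range edge; the in_range flag in the
          # results carries the information, so no per-sample warning here
          q <- suppressWarnings(quantify(amp, curve, sample_id = sid))
          drow <- data.frame(sample_id = sid, level = lv, day = d,
                             replicate = r, stringsAsFactors = FALSE)
          drow[[paste0("conc_", varied$name)]] <- lv
          drow[[paste0("conc_", fixed$name)]] <- fixed_conc
          design_rows[[length(design_rows) + 1L]] <<- drow
          results_rows[[length(results_rows) + 1L]] <<- q
        }
      }
    }
  }
  run_val(ma, config$val_levels_a, mb, config$calib_fixed_b, wl_a, curve_a,
          "valA")
  run_val(mb, config$val_levels_b, ma, config$calib_fixed_a, wl_b, curve_b,
          "valB")
  design <- do.call(rbind, lapply(design_rows, function(d) {
    for (col in c(paste0("conc_", ma$name), paste0("conc_", mb$name))) {
      if (is.null(d[[col]])) d[[col]] <- NA_real_
    }
    d
  }))
  results <- do.call(rbind, results_rows)
  pa_table <- accuracy_precision(results, design)

  ## 4. tablet assay + method comparison against a simulated reference
  tab_seed <- derive_seed(master, 5L)
  mg_per_conc <- 10 * 4 / 1000  # 10 mL flask, 4x dilution: ug/mL -> mg
  found_a <- numeric(config$tablet_n)
  found_b <- numeric(config$tablet_n)
  for (i in seq_len(config$tablet_n)) {
    nz <- noise; nz$seed <- derive_seed(tab_seed, i)
    ts <- generate_tablet_sample(
      models = config$models, noise = nz, grid = grid,
      excipient_baseline_au = config$excipient_baseline_au)
    found_a[i] <- suppressWarnings(
      quantify(measure_amplitude(ts, wl_a, ord, dl, backend),
               curve_a, sample_id = paste0("tab", i)))$concentration_ugml
    found_b[i] <- suppressWarnings(
      quantify(measure_amplitude(ts, wl_b, ord, dl, backend),
               curve_b, sample_id = paste0("tab", i)))$concentration_ugml
  }
  found_a_mg <- found_a * mg_per_conc
  found_b_mg <- found_b * mg_per_conc
  ref <- with_seed(derive_seed(master, 6L), function() {
    list(a = 2.0 * (1 + stats::rnorm(config$tablet_n, 0, config$ref_sd_rel)),
         b = 0.5 * (1 + stats::rnorm(config$tablet_n, 0, config$ref_sd_rel)))
  })
  cmp_a <- method_comparison(mean(found_a_mg), stats::sd(found_a_mg),
                             config$tablet_n, mean(ref$a), stats::sd(ref$a),
                             config$tablet_n)
  cmp_b <- method_comparison(mean(found_b_mg), stats::sd(found_b_mg),
                             config$tablet_n, mean(ref$b), stats::sd(ref$b),
                             config$tablet_n)

  ## 5. standard-addition recovery on the tablet solution
  rec_seed <- derive_seed(master, 7L)
  nz <- noise; nz$seed <- derive_seed(rec_seed, 1L)
  base_sp <- generate_tablet_sample(
    models = config$models, noise = nz, grid = grid,
    excipient_baseline_au = config$excipient_baseline_au)
  base_a <- suppressWarnings(
    quantify(measure_amplitude(base_sp, wl_a, ord, dl, backend),
             curve_a, "base"))$concentration_ugml
  base_b <- suppressWarnings(
    quantify(measure_amplitude(base_sp, wl_b, ord, dl, backend),
             curve_b, "base"))$concentration_ugml
  conc_a0 <- 2.0 * 1000 / 10 / 4   # nominal tablet solution, ug/mL
  conc_b0 <- 0.5 * 1000 / 10 / 4
  spike_found <- function(adds, which_a) {
    vapply(seq_along(adds), function(i) {
      nzi <- noise
      nzi$seed <- derive_seed(rec_seed, 10L * which_a + i)
      ca <- conc_a0 + if (which_a == 1L) adds[i] else 0
      cb <- conc_b0 + if (which_a == 2L) adds[i] else 0
      sp <- simulate_spectrum(config$models, c(ca, cb), noise = nzi,
                              grid = grid, label = "spiked")
      wlx <- if (which_a == 1L) wl_a else wl_b
      cv <- if (which_a == 1L) curve_a else curve_b
      suppressWarnings(
        quantify(measure_amplitude(sp, wlx, ord, dl, backend), cv,
                 "spiked")$concentration_ugml)
    }, 0)
  }
  rec_a <- standard_addition_recovery(base_a, config$spikes_a,
                                      spike_found(config$spikes_a, 1L))
  rec_b <- standard_addition_recovery(base_b, config$spikes_b,
                                      spike_found(config$spikes_b, 2L))

  structure(list(
    settings = list(order = ord, delta_lambda_nm = dl, backend = backend,
                    search_table = opt$table),
    selection = list(wavelength_a_nm = wl_a, wavelength_b_nm = wl_b,
                     candidates_a = opt$candidates_a,
                     candidates_b = opt$candidates_b,
                     pair = opt$selection),
    calibration = list(curve_a = curve_a, curve_b = curve_b,
                       table = calib_table),
    precision_accuracy = pa_table,
    validation_results = results,
    validation_design = design,
    tablet = list(
      comparison_a = cmp_a, comparison_b = cmp_b,
      table = data.frame(
        analyte = c(ma$name, mb$name),
        label_mg = c(2.0, 0.5),
        found_mean_mg = c(mean(found_a_mg), mean(found_b_mg)),
        found_sd_mg = c(stats::sd(found_a_mg), stats::sd(found_b_mg)),
        ref_mean_mg = c(mean(ref$a), mean(ref$b)),
        ref_sd_mg = c(stats::sd(ref$a), stats::sd(ref$b)),
        t_stat = c(cmp_a$t_stat, cmp_b$t_stat),
        f_stat = c(cmp_a$f_stat, cmp_b$f_stat),
        t_crit = c(cmp_a$t_crit, cmp_b$t_crit),
        f_crit = c(cmp_a$f_crit, cmp_b$f_crit),
        equivalent = c(cmp_a$equivalent, cmp_b$equivalent),
        stringsAsFactors = FALSE)),
    recovery = list(a = rec_a, b = rec_b,
                    table = data.frame(
                      analyte = c(ma$name, mb$name),
                      mean_recovery_pct = c(rec_a$mean_recovery_pct,
                                            rec_b$mean_recovery_pct),
                      sd_recovery_pct = c(rec_a$sd_recovery_pct,
                                          rec_b$sd_recovery_pct),
                      stringsAsFactors = FALSE)),
    manifest = list(seed = master, package_version =
                      as.character(utils::packageVersion("zerocross")),
                    noise_sd_au = noise$sd_au,
                    baseline_drift_au = noise$baseline_drift_au,
                    timestamp = NA_character_)
  ), class = "zc_study")
}

#' @export
print.zc_study <- function(x, ...) {
  cat("<zc_study> zero-crossing derivative assay study\n")
  cat(sprintf("  settings: order %d, delta-lambda %g nm (%s)\n",
              x$settings$order, x$settings$delta_lambda_nm,
              x$settings$backend))
  cat(sprintf("  working wavelengths: %.1f nm (a), %.1f nm (b)\n",
              x$selection$wavelength_a_nm, x$selection$wavelength_b_nm))
  cat(sprintf("  calibration r: %.4f (a), %.4f (b)\n",
              x$calibration$curve_a$r, x$calibration$curve_b$r))
  pa <- x$precision_accuracy
  cat(sprintf("  max CV %.2f%%, max |Error| %.2f%% over %d cells\n",
              max(pa$cv_pct, na.rm = TRUE),
              max(abs(pa$error_pct)), nrow(pa)))
  cat(sprintf("  recovery: %.2f%% (a), %.2f%% (b)\n",
              x$recovery$a$mean_recovery_pct, x$recovery$b$mean_recovery_pct))
  cat(sprintf("  tablet t/F within critical values: %s (a), %s (b)\n",
              x$tablet$comparison_a$equivalent,
              x$tablet$comparison_b$equivalent))
  invisible(x)
}

round_df <- function(df, spec) {
  for (col in names(spec)) {
    if (!is.null(df[[col]])) df[[col]] <- round(df[[col]], spec[[col]])
  }
  df
}

#' Write study report tables
#'
#' Writes the study's tables as CSV and a combined JSON (numerically
#' identical to the CSVs) into a directory: `calibration.csv`,
#' `precision_accuracy.csv`, `tablet_comparison.csv`, `recovery.csv`,
#' `candidates.csv`, `selection.json`, `manifest.json`, `report.json`.
#' Concentrations, CV and Error are rounded to 2 decimals, wavelengths to 1.
#'
#' @param study A `"zc_study"` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
report_tables <- function(study, dir) {
  stopifnot(inherits(study, "zc_study"))
  need <- c("selection", "calibration", "precision_accuracy", "tablet",
            "recovery", "manifest")
  missing <- need[vapply(need, function(n) is.null(study[[n]]), TRUE)]
  if (length(missing)) {
    stop("report_tables: study bundle is missing stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calib <- round_df(study$calibration$table,
                    list(wavelength_nm = 1, range_low = 2, range_high = 2))
  pa <- round_df(study$precision_accuracy,
                 list(nominal_ugml = 2, mean_found = 2, sd_found = 2,
                      cv_pct = 2, error_pct = 2))
  tab <- round_df(study$tablet$table,
                  list(label_mg = 2, found_mean_mg = 2, found_sd_mg = 2,
                       ref_mean_mg = 2, ref_sd_mg = 2, t_stat = 3,
                       f_stat = 3, t_crit = 3, f_crit = 2))
  rec <- round_df(study$recovery$table,
                  list(mean_recovery_pct = 2, sd_recovery_pct = 2))
  cand <- rbind(cbind(analyte_measured = "a", study$selection$candidates_a),
                cbind(analyte_measured = "b", study$selection$candidates_b))
  cand <- round_df(cand, list(wavelength_nm = 1))
  sel <- list(wavelength_a_nm = round(study$selection$wavelength_a_nm, 1),
              wavelength_b_nm = round(study$selection$wavelength_b_nm, 1),
              order = study$settings$order,
              delta_lambda_nm = study$settings$delta_lambda_nm)
  files <- c(calibration = "calibration.csv",
             precision_accuracy = "precision_accuracy.csv",
             tablet_comparison = "tablet_comparison.csv",
             recovery = "recovery.csv", candidates = "candidates.csv")
  utils::write.csv(calib, file.path(dir, files[["calibration"]]),
                   row.names = FALSE)
  utils::write.csv(pa, file.path(dir, files[["precision_accuracy"]]),
                   row.names = FALSE)
  utils::write.csv(tab, file.path(dir, files[["tablet_comparison"]]),
                   row.names = FALSE)
  utils::write.csv(rec, file.path(dir, files[["recovery"]]),
                   row.names = FALSE)
  utils::write.csv(cand, file.path(dir, files[["candidates"]]),
                   row.names = FALSE)
  jsonlite::write_json(sel, file.path(dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(calibration = calib, precision_accuracy = pa,
         tablet_comparison = tab, recovery = rec, selection = sel,
         manifest = study$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  out <- c(file.path(dir, files), file.path(dir, c("selection.json",
                                                   "manifest.json",
                                                   "report.json")))
  invisible(out)
}
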