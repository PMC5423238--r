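#' Gaussian absorption band
#'
#' One Gaussian band of a pure-component absorptivity model:
#' `epsilon * exp(-(lambda - center)^2 / (2 sigma^2))` AU per ug/mL at unit
#' concentration.  Gaussian bands are the standard approximation for
#' solution-phase UV absorption envelopes.
#'
#' @param center_nm Band center (nm), within 180-370 nm.
#' @param sigma_nm Band width (nm), positive.
#' @param epsilon Absorptivity amplitude at the band center (AU per ug/mL).
#' @return An object of class `"gaussian_band"`.
#' @export
gaussian_band <- function(center_nm, sigma_nm, epsilon) {
  stopifnot(is.numeric(center_nm), is.numeric(sigma_nm), is.numeric(epsilon))
  if (sigma_nm <= 0) stop("gaussian_band: sigma_nm must be > 0", call. = FALSE)
  if (center_nm < 180 || center_nm > 370) {
    stop("gaussian_band: center_nm must lie within 180-370 nm", call. = FALSE)
  }
  if (epsilon < 0) stop("gaussian_band: epsilon must be >= 0", call. = FALSE)
  structure(list(center_nm = center_nm, sigma_nm = sigma_nm,
                 epsilon = epsilon), class = "gaussian_band")
}

#' Pure-component analyte model
#'
#' A named band system obeying the Beer-Lambert law: the pure spectrum at
#' concentration c equals `c * sum(bands)` -- strictly linear in c over the
#' validated range.
#'
#' @param name Analyte name.
#' @param bands List of [gaussian_band()]s.
#' @param valid_range Length-2 numeric, validated concentration range
#'   (ug/mL).
#' @return An object of class `"analyte_model"`.
#' @export
analyte_model <- function(name, bands, valid_range) {
  stopifnot(is.character(name), length(valid_range) == 2L,
            valid_range[1L] < valid_range[2L])
  if (!length(bands) || !all(vapply(bands, inherits, TRUE, "gaussian_band"))) {
    stop("analyte_model: bands must be a non-empty list of gaussian_band",
         call. = FALSE)
  }
  structure(list(name = name, bands = bands,
                 valid_range = as.numeric(valid_range)),
            class = "analyte_model")
}

#' @export
print.analyte_model <- function(x, ...) {
  cat(sprintf("<analyte_model> '%s': %d bands, valid %g-%g ug/mL\n",
              x$name, length(x$bands), x$valid_range[1L], x$valid_range[2L]))
  for (b in x$bands) {
    cat(sprintf("  band: center %g nm, sigma %g nm, epsilon %g\n",
                b$center_nm, b$sigma_nm, b$epsilon))
  }
  invisible(x)
}

#' Pure-component absorbance
#'
#' Evaluate an analyte model's Beer-Lambert absorbance at concentration
#' `conc` on a grid.
#'
#' @param model An [analyte_model()].
#' @param conc Concentration (ug/mL), non-negative.
#' @param grid A [wl_grid()].
#' @return Numeric absorbance vector (AU), one value per grid point.
#' @export
pure_absorbance <- function(model, conc, grid = wl_grid()) {
  stopifnot(inherits(model, "analyte_model"))
  if (conc < 0) stop("pure_absorbance: concentration must be >= 0",
                     call. = FALSE)
  wl <- wavelengths(grid)
  a <- numeric(length(wl))
  for (b in model$bands) {
    a <- a + b$epsilon * exp(-(wl - b$center_nm)^2 / (2 * b$sigma_nm^2))
  }
  conc * a
}

#' Preset overlapping analyte models
#'
#' Two band systems emulating a buprenorphine-like major component
#' (validated 20-80 ug/mL) and a naloxone-like minor component (validated
#' 5-20 ug/mL) whose zero-order spectra overlap intensively throughout
#' 230-300 nm, so that neither can be read directly from the raw absorbance.
#' Their third-derivative spectra (delta-lambda 28 nm) each show at least one
#' zero crossing in the 245-265 nm region, which is what makes zero-crossing
#' quantitation of the mixture possible.  Band positions and widths are
#' plausible for morphinan-type chromophores in alkaline methanol; they are
#' not fitted to any measured spectrum.
#'
#' @return A named list with elements `bup_like` and `nal_like`, each an
#'   [analyte_model()].
#' @examples
#' m <- default_analyte_models()
#' max(pure_absorbance(m$bup_like, 50))
#' @export
default_analyte_models <- function() {
  list(
    bup_like = analyte_model(
      "bup_like",
      bands = list(
        gaussian_band(241.2, 19.8, 0.0019),
        gaussian_band(251.9, 8.5, 0.0242),
        gaussian_band(235.3, 8.9, 0.0126)
      ),
      valid_range = c(20, 80)
    ),
    nal_like = analyte_model(
      "nal_like",
      bands = list(
        gaussian_band(254.9, 20.4, 0.0073),
        gaussian_band(253.3, 9.7, 0.0576),
        gaussian_band(261.0, 3.5, 0.0181),
        gaussian_band(204.7, 10.2, 0.0706)
      ),
      valid_range = c(5, 20)
    )
  )
}

#' Instrument noise model
#'
#' Additive i.i.d. Gaussian photometric noise plus an optional slowly
#' varying (quadratic) baseline drift.  With a non-NULL seed the realized
#' noise is bit-for-bit reproducible and the caller's RNG state is left
#' untouched.
#'
#' @param sd_au Photometric noise SD (AU), non-negative.  Default 0.002 AU,
#'   typical short-term noise of a bench-top double-beam instrument.
#' @param baseline_drift_au Maximum amplitude of the quadratic baseline
#'   drift (AU), non-negative.  Default 0.005 AU.
#' @param seed Optional integer seed.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd_au = 0.002, baseline_drift_au = 0.005,
                        seed = NULL) {
  if (sd_au < 0) stop("noise_model: sd_au must be >= 0", call. = FALSE)
  if (baseline_drift_au < 0) {
    stop("noise_model: baseline_drift_au must be >= 0", call. = FALSE)
  }
  structure(list(sd_au = sd_au, baseline_drift_au = baseline_drift_au,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

# Evaluate code with a temporarily fixed RNG state; NULL seed uses (and
# advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code()
}

# Deterministic child-seed derivation (Lehmer step, kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + 1009 * k) %% 2147483647)
}

noise_realization <- function(noise, grid) {
  wl <- wavelengths(grid)
  n <- length(wl)
  eps <- if (noise$sd_au > 0) stats::rnorm(n, 0, noise$sd_au) else numeric(n)
  if (noise$baseline_drift_au > 0) {
    u <- 2 * (wl - wl[1L]) / (wl[n] - wl[1L]) - 1
    co <- stats::runif(3L, -1, 1)
    base <- co[1L] + co[2L] * u + co[3L] * u^2
    m <- max(abs(base))
    amp <- stats::runif(1L, 0, noise$baseline_drift_au)
    if (m > 0) eps <- eps + base / m * amp
  }
  eps
}

#' Simulate a mixture spectrum
#'
#' Additive Beer-Lambert mixture of pure components plus instrument noise:
#' `A(lambda) = sum_k c_k * a_k(lambda) + baseline + noise`.  Nominal
#' concentrations and the seed are recorded in the spectrum metadata.
#'
#' @param models List of [analyte_model()]s (a single model may be passed
#'   unwrapped).
#' @param concs Numeric vector of concentrations (ug/mL), one per model,
#'   non-negative.
#' @param noise A [noise_model()], or NULL for a noise-free spectrum.
#' @param grid A [wl_grid()].
#' @param label Spectrum label.
#' @param meta Extra metadata merged into the spectrum's metadata.
#' @return A [spectrum()].
#' @examples
#' m <- default_analyte_models()
#' s <- simulate_spectrum(m, c(50, 12.5), noise = noise_model(seed = 1))
#' s
#' @export
simulate_spectrum <- function(models, concs, noise = noise_model(),
                              grid = wl_grid(), label = "", meta = list()) {
  if (inherits(models, "analyte_model")) models <- list(models)
  stopifnot(length(models) == length(concs))
  if (any(concs < 0)) {
    stop("simulate_spectrum: concentrations must be >= 0", call. = FALSE)
  }
  a <- numeric(grid$n)
  for (k in seq_along(models)) {
    a <- a + pure_absorbance(models[[k]], concs[k], grid)
  }
  info <- list()
  for (k in seq_along(models)) {
    info[[paste0("conc_", models[[k]]$name)]] <- concs[k]
  }
  if (length(models) == 1L) {
    info$analyte <- models[[1L]]$name
    info$conc <- concs[1L]
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    a <- a + with_seed(noise$seed, function() noise_realization(noise, grid))
    info$noise_sd_au <- noise$sd_au
    info$baseline_drift_au <- noise$baseline_drift_au
    if (!is.null(noise$seed)) info$seed <- noise$seed
  }
  spectrum(grid, a, label = label, meta = utils::modifyList(info, meta))
}

#' Generate a calibration set
#'
#' Mixtures with one analyte varied over its calibration levels in the
#' presence of a fixed concentration of the other -- the standard design for
#' validating zero-crossing selectivity.  The two default assay designs are
#' 7 levels 20-80 ug/mL with 12.5 ug/mL of the fixed partner, and 7 levels
#' 5-20 ug/mL with 50 ug/mL of the fixed partner (see
#' [study_config()]).
#'
#' @param varied [analyte_model()] whose concentration is varied.
#' @param levels Concentrations (ug/mL) of `varied`, all within its valid
#'   range.
#' @param fixed [analyte_model()] held at a constant concentration.
#' @param fixed_conc Concentration (ug/mL) of `fixed`.
#' @param noise A [noise_model()]; its seed (when set) spawns one child seed
#'   per spectrum so the whole set is reproducible.
#' @param replicates Replicates per level (0 gives an empty list).
#' @param grid A [wl_grid()].
#' @return List of [spectrum()]s, one per (level, replicate), with nominal
#'   concentrations, level, and replicate in the metadata.
#' @export
generate_calibration_set <- function(varied, levels, fixed, fixed_conc,
                                     noise = noise_model(), replicates = 1L,
                                     grid = wl_grid()) {
  stopifnot(inherits(varied, "analyte_model"), inherits(fixed, "analyte_model"))
  if (any(levels < varied$valid_range[1L] | levels > varied$valid_range[2L])) {
    stop("generate_calibration_set: levels outside the valid range ",
         varied$valid_range[1L], "-", varied$valid_range[2L], " ug/mL of '",
         varied$name, "'", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) return(list())
  out <- vector("list", length(levels) * replicates)
  i <- 0L
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      nz <- noise
      if (!is.null(noise) && !is.null(noise$seed)) {
        nz$seed <- derive_seed(noise$seed, i)
      }
      out[[i]] <- simulate_spectrum(
        list(varied, fixed), c(levels[li], fixed_conc), noise = nz,
        grid = grid,
        label = sprintf("%s_L%02d_r%d", varied$name, li, r),
        meta = list(level = levels[li], replicate = r))
    }
  }
  out
}

#' Simulate a tablet sample spectrum
#'
#' Converts a two-analyte label claim (default 2 mg + 0.5 mg per tablet,
#' dissolved to 10 mL and diluted 4-fold, giving 50 and 12.5 ug/mL) into
#' solution concentrations, adds a smooth quadratic excipient baseline, and
#' simulates the mixture spectrum.
#'
#' @param models Named list of two [analyte_model()]s (major analyte first).
#' @param major_mg,minor_mg Label claim per tablet (mg), positive.
#' @param volume_ml Volumetric flask volume (mL), positive.
#' @param dilution_factor Further dilution factor, positive.
#' @param excipient_baseline_au Peak amplitude of a fixed smooth excipient
#'   background (AU), non-negative.
#' @param noise A [noise_model()] or NULL.
#' @param grid A [wl_grid()].
#' @return A [spectrum()] with nominal concentrations (ug/mL) and the mg
#'   claims in the metadata.
#' @export
generate_tablet_sample <- function(models = default_analyte_models(),
                                   major_mg = 2, minor_mg = 0.5,
                                   volume_ml = 10, dilution_factor = 4,
                                   excipient_baseline_au = 0.003,
                                   noise = noise_model(),
                                   grid = wl_grid()) {
  stopifnot(length(models) == 2L)
  if (major_mg <= 0 || minor_mg <= 0) {
    stop("generate_tablet_sample: per-tablet masses must be > 0",
         call. = FALSE)
  }
  if (volume_ml <= 0 || dilution_factor <= 0) {
    stop("generate_tablet_sample: volume and dilution factor must be > 0",
         call. = FALSE)
  }
  if (excipient_baseline_au < 0) {
    stop("generate_tablet_sample: excipient_baseline_au must be >= 0",
         call. = FALSE)
  }
  # mg per tablet -> ug, into volume_ml, then diluted
  conc <- c(major_mg, minor_mg) * 1000 / volume_ml / dilution_factor
  s <- simulate_spectrum(models, conc, noise = noise, grid = grid,
                         label = "tablet",
                         meta = list(major_mg = major_mg, minor_mg = minor_mg,
                                     volume_ml = volume_ml,
                                     dilution_factor = dilution_factor))
  if (excipient_baseline_au > 0) {
    wl <- wavelengths(grid)
    u <- (wl - wl[1L]) / (wl[length(wl)] - wl[1L])
    # fixed gentle scattering-like background, decaying to the red
    s$absorbance <- s$absorbance + excipient_baseline_au * (1 - u)^2
    s$meta$excipient_baseline_au <- excipient_baseline_au
  }
  s
}
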