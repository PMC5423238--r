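#' Fit a calibration curve
#'
#' Ordinary least squares of derivative amplitude (Y) on concentration (X),
#' the working model of single-wavelength quantitation: under the
#' Beer-Lambert law and a linear derivative operator, the derivative
#' amplitude at a fixed wavelength is an affine function of concentration.
#' Standard errors of slope and intercept come from the residual variance;
#' `r` is the signed Pearson correlation of (X, Y).
#'
#' @param concentration Concentrations (ug/mL); at least 3 points over at
#'   least 3 distinct values.
#' @param amplitude Measured derivative amplitudes, same length.
#' @param range_ugml Validated concentration range; default the span of the
#'   calibration levels.
#' @param wavelength_nm,order,delta_lambda_nm Optional provenance recorded
#'   in the curve (working wavelength and derivative settings).
#' @param analyte Optional analyte name.
#' @return An object of class `"calcurve"` with fields `slope`, `intercept`,
#'   `sd_slope`, `rsd_slope_pct`, `sd_intercept`, `r`, `range_ugml`,
#'   `n_points`, `degenerate`, and the underlying `lm` fit.  Supported
#'   methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' x <- c(20, 30, 40, 50, 60, 70, 80)
#' y <- 0.0174 * x + 0.0359
#' cc <- fit_calibration(x, y)
#' coef(cc)
#' quantify(predict(cc, newconc = 55), cc)
#' @export
fit_calibration <- function(concentration, amplitude,
                            range_ugml = range(concentration),
                            wavelength_nm = NA_real_, order = NA_integer_,
                            delta_lambda_nm = NA_real_,
                            analyte = NA_character_) {
  x <- as.numeric(concentration)
  y <- as.numeric(amplitude)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("fit_calibration: need at least 3 calibration points", call. = FALSE)
  }
  if (length(unique(x)) < 3L) {
    if (length(unique(x)) == 1L) {
      stop("fit_calibration: all concentrations identical (singular design)",
           call. = FALSE)
    }
    stop("fit_calibration: need at least 3 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # summary.lm warns on zero-residual designs; exact calibration data are a
  # legitimate input here (noise-free simulations), so quiet it
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  degenerate <- isTRUE(all.equal(stats::var(y), 0, tolerance = 1e-300)) ||
    stats::var(y) == 0
  r <- if (degenerate) 0 else stats::cor(x, y)
  slope <- if (degenerate) 0 else unname(co[2L])
  structure(list(
    slope = slope,
    intercept = unname(co[1L]),
    sd_slope = unname(se[2L]),
    rsd_slope_pct = if (slope != 0) 100 * unname(se[2L]) / abs(slope)
                    else Inf,
    sd_intercept = unname(se[1L]),
    r = r,
    range_ugml = as.numeric(range_ugml),
    n_points = length(x),
    degenerate = degenerate,
    wavelength_nm = wavelength_nm,
    order = order,
    delta_lambda_nm = delta_lambda_nm,
    analyte = analyte,
    fit = fit,
    data = data.frame(concentration = x, amplitude = y)
  ), class = "calcurve")
}

#' @export
print.calcurve <- function(x, digits = 4, ...) {
  eq <- sprintf("Y = %s X %s %s",
                format(x$slope, digits = digits),
                if (x$intercept < 0) "-" else "+",
                format(abs(x$intercept), digits = digits))
  cat("<calcurve>", if (!is.na(x$analyte)) paste0("[", x$analyte, "]") else "",
      eq, "\n")
  cat(sprintf("  r = %.4f, n = %d, range %g-%g ug/mL\n",
              x$r, x$n_points, x$range_ugml[1L], x$range_ugml[2L]))
  if (!is.na(x$wavelength_nm)) {
    cat(sprintf("  measured at %.1f nm (order %d, delta-lambda %g nm)\n",
                x$wavelength_nm, x$order, x$delta_lambda_nm))
  }
  if (x$degenerate) cat("  WARNING: degenerate fit (flat response)\n")
  invisible(x)
}

#' @export
summary.calcurve <- function(object, ...) {
  out <- data.frame(
    parameter = c("slope", "intercept", "sd_slope", "rsd_slope_pct",
                  "sd_intercept", "r", "n_points", "range_low", "range_high"),
    value = c(object$slope, object$intercept, object$sd_slope,
              object$rsd_slope_pct, object$sd_intercept, object$r,
              object$n_points, object$range_ugml[1L], object$range_ugml[2L]))
  class(out) <- c("summary.calcurve", "data.frame")
  attr(out, "curve") <- object
  out
}

#' @export
print.summary.calcurve <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
coef.calcurve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted amplitude at given concentrations
#'
#' @param object A `"calcurve"`.
#' @param newconc Concentrations (ug/mL); default the calibration points.
#' @param ... Unused.
#' @return Predicted derivative amplitudes.
#' @export
predict.calcurve <- function(object, newconc = NULL, ...) {
  if (is.null(newconc)) newconc <- object$data$concentration
  object$intercept + object$slope * as.numeric(newconc)
}

#' @export
residuals.calcurve <- function(object, ...) {
  object$data$amplitude - predict(object)
}

#' @export
plot.calcurve <- function(x, ...,
                          xlab = "concentration (ug/mL)",
                          ylab = "derivative amplitude") {
  graphics::plot(x$data$concentration, x$data$amplitude,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Quantify an unknown from its derivative amplitude
#'
#' Inverts the calibration line: `concentration = (amplitude - intercept) /
#' slope`.  Concentrations outside the validated range are flagged
#' (`in_range = FALSE`) with a warning but still returned, the usual assay
#' practice being to flag and re-run at a different dilution.
#'
#' @param amplitude Measured derivative amplitude(s).
#' @param curve A `"calcurve"`.
#' @param sample_id Optional sample id(s), recycled.
#' @return A data.frame with columns `sample_id`, `analyte`,
#'   `concentration_ugml`, `amplitude`, `in_range`.
#' @export
quantify <- function(amplitude, curve, sample_id = NA_character_) {
  stopifnot(inherits(curve, "calcurve"))
  if (curve$slope == 0) {
    stop("quantify: calibration slope is zero; cannot invert", call. = FALSE)
  }
  amplitude <- as.numeric(amplitude)
  conc <- (amplitude - curve$intercept) / curve$slope
  in_range <- conc >= curve$range_ugml[1L] & conc <= curve$range_ugml[2L]
  if (any(!in_range)) {
    warning(sprintf(
      "quantify: %d result(s) outside the validated range %g-%g ug/mL",
      sum(!in_range), curve$range_ugml[1L], curve$range_ugml[2L]),
      call. = FALSE)
  }
  data.frame(sample_id = rep_len(as.character(sample_id), length(amplitude)),
             analyte = rep_len(curve$analyte, length(amplitude)),
             concentration_ugml = conc, amplitude = amplitude,
             in_range = in_range, stringsAsFactors = FALSE)
}
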