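#' Derivative spectrum
#'
#' Compute the nth-order derivative of an absorbance spectrum with respect
#' to wavelength, in the idiom of scanning derivative spectrophotometers: an
#' iterated symmetric difference with full offset delta-lambda,
#' `D1(lambda) = (A(lambda + dl/2) - A(lambda - dl/2)) / dl`, applied n
#' times.  Large delta-lambda values act as a built-in low-pass filter, which
#' is why instrument methods quote delta-lambda instead of a smoothing
#' window.  A Savitzky-Golay polynomial derivative is available as an
#' alternative backend; both are linear operators, the property that makes
#' zero-crossing quantitation of additive mixtures valid.
#'
#' The output grid is the source grid trimmed by `order * delta_lambda / 2`
#' at each end (Savitzky-Golay trims at least half its window): derivative
#' values are only reported where fully supported by data, never from
#' padding.
#'
#' @param spec A [spectrum()].
#' @param order Derivative order, 1-4.
#' @param delta_lambda_nm Wavelength offset delta-lambda (nm); must be a
#'   positive integer multiple of twice the grid step so that half-offsets
#'   land on grid points.
#' @param backend `"diff"` (iterated symmetric difference, default) or
#'   `"savgol"` (Savitzky-Golay local polynomial fit, window spanning
#'   approximately delta-lambda).
#' @return An object of class `"deriv_spectrum"`: trimmed `grid`, `amplitude`
#'   (AU nm^-order), `order`, `delta_lambda_nm`, `backend`, `source_label`.
#' @examples
#' m <- default_analyte_models()
#' s <- simulate_spectrum(m$bup_like, 50, noise = NULL)
#' d3 <- derivative(s, order = 3, delta_lambda_nm = 28)
#' range(d3$amplitude)
#' @export
derivative <- function(spec, order, delta_lambda_nm,
                       backend = c("diff", "savgol")) {
  stopifnot(inherits(spec, "spectrum"))
  backend <- match.arg(backend)
  order <- as.integer(order)
  if (!(order %in% 1:4)) {
    stop("derivative: order must be 1, 2, 3 or 4", call. = FALSE)
  }
  step <- spec$grid$step_nm
  half_pts <- delta_lambda_nm / (2 * step)
  if (delta_lambda_nm <= 0 || abs(half_pts - round(half_pts)) > 1e-6) {
    stop("derivative: delta_lambda_nm (", delta_lambda_nm,
         ") must be a positive integer multiple of twice the grid step (",
         2 * step, " nm)", call. = FALSE)
  }
  half_pts <- as.integer(round(half_pts))

  if (backend == "diff") {
    amp <- spec$absorbance
    for (k in seq_len(order)) {
      n <- length(amp)
      if (n - 2L * half_pts < 1L) {
        stop("derivative: grid too short for order ", order,
             " at delta_lambda ", delta_lambda_nm, " nm", call. = FALSE)
      }
      idx <- (half_pts + 1L):(n - half_pts)
      amp <- (amp[idx + half_pts] - amp[idx - half_pts]) / delta_lambda_nm
    }
    trim_pts <- order * half_pts
  } else {
    # window ~ delta-lambda wide, odd, and large enough for the quartic fit
    p <- 4L
    w <- as.integer(round(delta_lambda_nm / step)) + 1L
    if (w %% 2L == 0L) w <- w + 1L
    w <- max(w, p + 3L - (p + 3L) %% 2L + 1L)  # smallest odd w > p + 1
    amp_full <- signal::sgolayfilt(spec$absorbance, p = p, n = w, m = order,
                                   ts = step)
    trim_pts <- max(order * half_pts, (w - 1L) %/% 2L)
    n <- length(amp_full)
    if (n - 2L * trim_pts < 1L) {
      stop("derivative: grid too short for order ", order,
           " at delta_lambda ", delta_lambda_nm, " nm", call. = FALSE)
    }
    amp <- amp_full[(trim_pts + 1L):(n - trim_pts)]
  }

  n_out <- spec$grid$n - 2L * trim_pts
  if (n_out < 9L) {
    stop("derivative: trimmed grid has ", n_out,
         " points (< 9); reduce order or delta_lambda", call. = FALSE)
  }
  grid <- wl_grid(spec$grid$start_nm + trim_pts * step,
                  spec$grid$stop_nm - trim_pts * step, step)
  if (!all(is.finite(amp))) {
    stop("derivative: non-finite derivative amplitude", call. = FALSE)
  }
  structure(list(grid = grid, amplitude = amp, order = order,
                 delta_lambda_nm = delta_lambda_nm, backend = backend,
                 source_label = spec$label),
            class = "deriv_spectrum")
}

#' @export
wavelengths.deriv_spectrum <- function(x) wavelengths(x$grid)

#' @export
print.deriv_spectrum <- function(x, ...) {
  cat(sprintf(
    "<deriv_spectrum> order %d, delta-lambda %g nm (%s) of '%s': %g-%g nm\n",
    x$order, x$delta_lambda_nm, x$backend, x$source_label,
    x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' @export
plot.deriv_spectrum <- function(x, ..., type = "l",
                                xlab = "wavelength (nm)", ylab = NULL) {
  if (is.null(ylab)) {
    ylab <- sprintf("D%d amplitude (AU nm^-%d)", x$order, x$order)
  }
  graphics::plot(wavelengths(x), x$amplitude, type = type,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  invisible(x)
}

#' Derivative amplitude at a wavelength
#'
#' Linear interpolation between bracketing grid points; exact when the
#' wavelength sits on the grid.  Wavelengths outside the trimmed derivative
#' grid are an error (no extrapolation).
#'
#' @param ds A `"deriv_spectrum"` from [derivative()].
#' @param wavelength_nm Wavelength (nm) inside the trimmed grid.
#' @return Derivative amplitude (AU nm^-order), scalar.
#' @export
amplitude_at <- function(ds, wavelength_nm) {
  stopifnot(inherits(ds, "deriv_spectrum"), length(wavelength_nm) == 1L)
  tol <- 1e-9
  if (wavelength_nm < ds$grid$start_nm - tol ||
      wavelength_nm > ds$grid$stop_nm + tol) {
    stop(sprintf(
      "amplitude_at: %.4f nm outside the trimmed grid %.4f-%.4f nm",
      wavelength_nm, ds$grid$start_nm, ds$grid$stop_nm), call. = FALSE)
  }
  stats::approx(wavelengths(ds), ds$amplitude, xout = wavelength_nm,
                rule = 2)$y
}
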