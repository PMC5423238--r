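#' Uniform wavelength grid
#'
#' Construct a uniform wavelength grid for UV-Vis spectra.  The default grid
#' spans 200-350 nm at 0.1 nm spacing, the usual scan range for aromatic
#' pharmaceuticals in solution; 0.1 nm resolves working wavelengths reported
#' to one decimal place.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Grid spacing (nm), positive; `(stop_nm - start_nm)` must be
#'   an integer multiple of `step_nm`.
#' @return An object of class `"wl_grid"` with fields `start_nm`, `stop_nm`,
#'   `step_nm` and `n` (number of points, at least 9).
#' @examples
#' g <- wl_grid()
#' g$n
#' head(wavelengths(g))
#' @export
wl_grid <- function(start_nm = 200, stop_nm = 350, step_nm = 0.1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (!(start_nm < stop_nm)) {
    stop("wl_grid: start_nm must be < stop_nm", call. = FALSE)
  }
  if (step_nm <= 0) stop("wl_grid: step_nm must be > 0", call. = FALSE)
  n <- round((stop_nm - start_nm) / step_nm) + 1L
  if (abs(start_nm + (n - 1L) * step_nm - stop_nm) > 1e-6 * step_nm) {
    stop("wl_grid: (stop_nm - start_nm) is not an integer multiple of step_nm",
         call. = FALSE)
  }
  if (n < 9L) {
    stop("wl_grid: grid must have at least 9 points, got ", n, call. = FALSE)
  }
  structure(list(start_nm = start_nm, stop_nm = stop_nm,
                 step_nm = step_nm, n = as.integer(n)),
            class = "wl_grid")
}

#' Wavelength vector of a grid or spectrum
#'
#' @param x A `"wl_grid"` or `"spectrum"` object.
#' @return Numeric vector of wavelengths (nm), ascending.
#' @export
wavelengths <- function(x) UseMethod("wavelengths")

#' @export
wavelengths.wl_grid <- function(x) x$start_nm + (seq_len(x$n) - 1L) * x$step_nm

#' @export
wavelengths.spectrum <- function(x) wavelengths(x$grid)

#' @export
length.wl_grid <- function(x) x$n

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %.4g-%.4g nm, step %.4g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  abs(a$start_nm - b$start_nm) < tol &&
    abs(a$stop_nm - b$stop_nm) < tol &&
    abs(a$step_nm - b$step_nm) < tol
}

#' Absorbance spectrum on a uniform grid
#'
#' Container for a zero-order absorbance spectrum: absorbance units (AU)
#' versus wavelength on a uniform grid, with free-form acquisition metadata
#' (solvent, nominal concentrations, replicate/day ids, ...).
#'
#' @param grid A [wl_grid()].
#' @param absorbance Numeric vector of absorbances (AU), one per grid point,
#'   all finite.
#' @param label Short text label.
#' @param meta Named list of metadata.
#' @return An object of class `"spectrum"`.
#' @examples
#' g <- wl_grid(200, 350, 0.5)
#' s <- spectrum(g, exp(-(wavelengths(g) - 260)^2 / 200), label = "demo")
#' s
#' @export
spectrum <- function(grid, absorbance, label = "", meta = list()) {
  stopifnot(inherits(grid, "wl_grid"))
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != grid$n) {
    stop("spectrum: absorbance length (", length(absorbance),
         ") does not match grid length (", grid$n, ")", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("spectrum: absorbance values must all be finite", call. = FALSE)
  }
  stopifnot(is.list(meta))
  structure(list(grid = grid, absorbance = absorbance,
                 label = as.character(label)[1L], meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s': %.4g-%.4g nm (%d pts), A in [%.4g, %.4g] AU\n",
              x$label, x$grid$start_nm, x$grid$stop_nm, x$grid$n,
              min(x$absorbance), max(x$absorbance)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "wavelength (nm)",
                          ylab = "absorbance (AU)", type = "l") {
  graphics::plot(wavelengths(x), x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, main = x$label, ...)
  invisible(x)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto a target grid lying inside the source wavelength
#' range.  Extrapolation is refused: absorbances are only reported where
#' bracketed by measured points.  Linear interpolation is exact for affine
#' absorbance functions and the identity on a matching grid.
#'
#' @param spec A [spectrum()].
#' @param grid Target [wl_grid()], within the source range.
#' @return A [spectrum()] on `grid`; metadata and label are carried over.
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"), inherits(grid, "wl_grid"))
  tol <- 1e-9
  if (grid$start_nm < spec$grid$start_nm - tol ||
      grid$stop_nm > spec$grid$stop_nm + tol) {
    stop(sprintf(
      "resample: target grid %.4g-%.4g nm outside source range %.4g-%.4g nm",
      grid$start_nm, grid$stop_nm, spec$grid$start_nm, spec$grid$stop_nm),
      call. = FALSE)
  }
  if (grids_identical(spec$grid, grid)) {
    out <- spec
    out$grid <- grid
    return(out)
  }
  # rule = 2 only guards against fp jitter at the endpoints; genuine
  # extrapolation was rejected above
  a <- stats::approx(wavelengths(spec), spec$absorbance,
                     xout = wavelengths(grid), rule = 2)$y
  spectrum(grid, a, label = spec$label, meta = spec$meta)
}
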