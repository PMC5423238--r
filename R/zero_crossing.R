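#' Find zero crossings of a derivative spectrum
#'
#' One crossing is reported per sign change between consecutive amplitudes,
#' positioned by linear interpolation; an exact zero on a grid point is
#' reported at that wavelength.  Crossing positions are invariant under
#' positive scaling of the source spectrum, which is why they can serve as
#' concentration-independent working wavelengths.
#'
#' @param ds A `"deriv_spectrum"` from [derivative()].
#' @return A data.frame with columns `wavelength_nm` (ascending),
#'   `direction` (`"+-"` or `"-+"`), `order`, `delta_lambda_nm`, `analyte`
#'   (the source label).  Zero rows when the amplitude never changes sign.
#' @export
find_zero_crossings <- function(ds) {
  stopifnot(inherits(ds, "deriv_spectrum"))
  wl <- wavelengths(ds)
  y <- ds$amplitude
  n <- length(y)
  pos <- numeric(0)
  dir <- character(0)
  i <- 1L
  while (i <= n) {
    if (y[i] == 0) {
      # exact grid-point zero: report once, classify by flanking signs
      j <- i
      while (j < n && y[j + 1L] == 0) j <- j + 1L
      left <- if (i > 1L) sign(y[i - 1L]) else 0
      right <- if (j < n) sign(y[j + 1L]) else 0
      if (left != right && (left != 0 || right != 0)) {
        pos <- c(pos, wl[i])
        dir <- c(dir, if (right < left) "+-" else "-+")
      }
      i <- j + 1L
    } else if (i < n && y[i + 1L] != 0 && sign(y[i]) != sign(y[i + 1L])) {
      frac <- y[i] / (y[i] - y[i + 1L])
      pos <- c(pos, wl[i] + frac * (wl[i + 1L] - wl[i]))
      dir <- c(dir, if (y[i] > 0) "+-" else "-+")
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(wavelength_nm = pos, direction = dir,
             order = rep(ds$order, length(pos)),
             delta_lambda_nm = rep(ds$delta_lambda_nm, length(pos)),
             analyte = rep(ds$source_label, length(pos)),
             stringsAsFactors = FALSE)
}

# Pull a named scalar out of spectrum metadata, with a clear error.
meta_conc <- function(spec, what) {
  v <- spec$meta$conc
  if (is.null(v)) {
    stop(what, ": spectrum '", spec$label,
         "' carries no 'conc' metadata; pass concentrations explicitly",
         call. = FALSE)
  }
  as.numeric(v)
}

#' Screen candidate working wavelengths
#'
#' Ranks the zero crossings of the interferent's derivative spectrum as
#' candidate wavelengths for measuring the target.  For each crossing of the
#' interferent's mean normalized derivative the candidate records
#' \describe{
#'   \item{sensitivity}{slope of the target's derivative amplitude versus
#'     target concentration at the consensus crossing (AU nm^-order per
#'     ug/mL);}
#'   \item{crossing_stability_nm}{SD of the crossing position across the
#'     interferent concentrations -- for strictly Beer-Lambert spectra the
#'     crossings do not move with concentration, so this is a noise/model
#'     diagnostic;}
#'   \item{residual_interference}{|slope of the interferent amplitude versus
#'     interferent concentration at the consensus crossing| divided by the
#'     sensitivity (dimensionless); the fraction of one concentration unit
#'     of interferent that leaks into the target reading.}
#' }
#'
#' @param target List of pure target [spectrum()]s spanning at least 3
#'   distinct concentrations.
#' @param interferent List of pure interferent [spectrum()]s spanning at
#'   least 3 distinct concentrations, on the same grid.
#' @param order Derivative order (1-4).
#' @param delta_lambda_nm Derivative offset (nm).
#' @param target_conc,interferent_conc Optional concentration vectors;
#'   default is the `conc` metadata written by [simulate_spectrum()].
#' @param backend Derivative backend, see [derivative()].
#' @return A data.frame of class `"candidate_table"`, sorted by descending
#'   sensitivity, with columns `wavelength_nm`, `direction`, `sensitivity`,
#'   `crossing_stability_nm`, `residual_interference`, `usable`.  Zero rows
#'   when the interferent's derivative never changes sign.
#' @export
screen_candidates <- function(target, interferent, order, delta_lambda_nm,
                              target_conc = NULL, interferent_conc = NULL,
                              backend = "diff") {
  if (is.null(target_conc)) {
    target_conc <- vapply(target, meta_conc, 0, what = "screen_candidates")
  }
  if (is.null(interferent_conc)) {
    interferent_conc <- vapply(interferent, meta_conc, 0,
                               what = "screen_candidates")
  }
  if (length(unique(target_conc)) < 3L ||
      length(unique(interferent_conc)) < 3L) {
    stop("screen_candidates: need >= 3 distinct concentrations for both ",
         "target and interferent", call. = FALSE)
  }
  g0 <- target[[1L]]$grid
  for (s in c(target, interferent)) {
    if (!grids_identical(s$grid, g0)) {
      stop("screen_candidates: all spectra must share one grid",
           call. = FALSE)
    }
  }
  d_t <- lapply(target, derivative, order = order,
                delta_lambda_nm = delta_lambda_nm, backend = backend)
  d_i <- lapply(interferent, derivative, order = order,
                delta_lambda_nm = delta_lambda_nm, backend = backend)

  # consensus crossing set: crossings of the mean of max-normalized
  # interferent derivatives (robust to the concentration scaling)
  norm_amp <- vapply(d_i, function(d) {
    m <- max(abs(d$amplitude))
    if (m == 0) d$amplitude else d$amplitude / m
  }, numeric(d_i[[1L]]$grid$n))
  mean_ds <- d_i[[1L]]
  mean_ds$amplitude <- rowMeans(norm_amp)
  mean_ds$source_label <- "interferent_mean"
  cons <- find_zero_crossings(mean_ds)
  if (nrow(cons) == 0L) {
    return(structure(
      data.frame(wavelength_nm = numeric(0), direction = character(0),
                 sensitivity = numeric(0), crossing_stability_nm = numeric(0),
                 residual_interference = numeric(0), usable = logical(0)),
      class = c("candidate_table", "data.frame")))
  }
  per_spec_cross <- lapply(d_i, function(d) find_zero_crossings(d)$wavelength_nm)

  # per-concentration response of the target across the whole grid; its
  # maximum sets the scale against which a candidate's sensitivity is judged
  amp_t_mat <- vapply(d_t, function(d) d$amplitude, numeric(d_t[[1L]]$grid$n))
  slope_scale <- max(abs(apply(amp_t_mat, 1L, ols_slope, x = target_conc)))

  out <- lapply(seq_len(nrow(cons)), function(k) {
    lam0 <- cons$wavelength_nm[k]
    # match the nearest crossing of each individual interferent spectrum
    matched <- vapply(per_spec_cross, function(p) {
      if (!length(p)) return(NA_real_)
      p[which.min(abs(p - lam0))]
    }, 0)
    matched <- matched[!is.na(matched) &
                         abs(matched - lam0) <= delta_lambda_nm / 2]
    if (length(matched) < 2L) {
      lam <- lam0
      stab <- NA_real_
    } else {
      lam <- mean(matched)
      stab <- stats::sd(matched)
    }
    amp_t <- vapply(d_t, amplitude_at, 0, wavelength_nm = lam)
    amp_i <- vapply(d_i, amplitude_at, 0, wavelength_nm = lam)
    sens <- abs(ols_slope(target_conc, amp_t))
    leak <- abs(ols_slope(interferent_conc, amp_i))
    ok <- sens > 1e-6 * slope_scale
    data.frame(wavelength_nm = lam, direction = cons$direction[k],
               sensitivity = sens, crossing_stability_nm = stab,
               residual_interference = if (ok) leak / sens else Inf,
               usable = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$sensitivity), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_table", "data.frame"))
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Select the working wavelength pair
#'
#' From the candidate tables of the two analytes, keep the candidates whose
#' residual interference and crossing-position instability fall below the
#' thresholds, then pick the most sensitive one for each analyte.  Ties are
#' broken by smaller residual interference, then by lower wavelength.
#'
#' @param candidates_for_a,candidates_for_b `"candidate_table"`s from
#'   [screen_candidates()] (measuring analyte a at crossings of b, and vice
#'   versa).
#' @param max_residual Largest acceptable residual interference
#'   (dimensionless); default 0.02.
#' @param max_stability_nm Largest acceptable crossing-position SD (nm);
#'   default 0.2 (two grid steps on the default grid).
#' @return List with elements `a` and `b`, each a one-row candidate
#'   data.frame.
#' @export
select_working_pair <- function(candidates_for_a, candidates_for_b,
                                max_residual = 0.02, max_stability_nm = 0.2) {
  pick <- function(cand, who) {
    if (!nrow(cand)) {
      stop("select_working_pair: no zero-crossing candidates for analyte ",
           who, call. = FALSE)
    }
    stab <- cand$crossing_stability_nm
    ok <- cand$usable &
      cand$residual_interference <= max_residual &
      (is.na(stab) | stab <= max_stability_nm)
    if (!any(ok)) {
      best <- cand[order(cand$residual_interference), , drop = FALSE][1L, ]
      stop(sprintf(
        paste0("select_working_pair: no feasible candidate for analyte %s ",
               "(thresholds: residual <= %g, stability <= %g nm); best ",
               "rejected: %.1f nm with residual %.3g, stability %.3g nm"),
        who, max_residual, max_stability_nm, best$wavelength_nm,
        best$residual_interference, best$crossing_stability_nm),
        call. = FALSE)
    }
    feas <- cand[ok, , drop = FALSE]
    feas <- feas[order(-feas$sensitivity, feas$residual_interference,
                       feas$wavelength_nm), , drop = FALSE]
    feas[1L, , drop = FALSE]
  }
  list(a = pick(candidates_for_a, "a"), b = pick(candidates_for_b, "b"))
}
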