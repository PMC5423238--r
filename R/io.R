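#' Read a spectrum from CSV
#'
#' Canonical on-disk format: a two-column CSV with header
#' `wavelength_nm,absorbance`, optionally preceded by `# key=value` comment
#' lines carrying metadata.  Wavelengths must be strictly monotone (ascending
#' or descending; descending input is stored ascending) and, unless
#' `resample_to` is given, uniformly spaced.
#'
#' @param path Path to a CSV file.
#' @param resample_to Optional [wl_grid()]: if the file's spacing is
#'   non-uniform, linearly interpolate onto this grid instead of failing.
#' @return A [spectrum()].  The label defaults to the file stem when no
#'   `# label=` header is present.
#' @export
read_spectrum_csv <- function(path, resample_to = NULL) {
  if (!file.exists(path)) {
    stop("read_spectrum_csv: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_meta_comments(lines[is_comment])
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L) {
    stop("read_spectrum_csv: no data rows in ", path, call. = FALSE)
  }
  header <- tolower(gsub("\\s", "", body[1L]))
  if (!identical(strsplit(header, ",")[[1L]][1:2],
                 c("wavelength_nm", "absorbance"))) {
    stop("read_spectrum_csv: expected header 'wavelength_nm,absorbance', got '",
         body[1L], "'", call. = FALSE)
  }
  rows <- strsplit(body[-1L], ",")
  bad <- which(vapply(rows, length, 1L) < 2L)
  if (length(bad)) {
    stop("read_spectrum_csv: malformed row at data line ", bad[1L],
         ": '", body[-1L][bad[1L]], "'", call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 1L)))
  ab <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  bad <- which(!is.finite(wl) | !is.finite(ab))
  if (length(bad)) {
    stop("read_spectrum_csv: non-numeric value at data line ", bad[1L],
         ": '", body[-1L][bad[1L]], "'", call. = FALSE)
  }
  spectrum_from_xy(wl, ab, meta = meta,
                   label = if (is.null(meta$label)) strip_ext(basename(path))
                           else meta$label,
                   resample_to = resample_to, what = "read_spectrum_csv")
}

strip_ext <- function(x) sub("\\.[^.]*$", "", x)

parse_meta_comments <- function(comment_lines) {
  meta <- list()
  for (ln in comment_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

# Shared validation/normalization for the CSV and JCAMP readers: enforce
# strict monotonicity, ascending storage and uniform spacing (or resample).
spectrum_from_xy <- function(wl, ab, meta, label, resample_to, what) {
  if (length(wl) < 2L) {
    stop(what, ": need at least 2 points to define a grid", call. = FALSE)
  }
  d <- diff(wl)
  if (all(d < 0)) {        # descending scan: store ascending
    wl <- rev(wl)
    ab <- rev(ab)
    d <- -rev(d)
  }
  if (any(d <= 0)) {
    stop(what, ": wavelengths must be strictly monotone", call. = FALSE)
  }
  step <- stats::median(d)
  uniform <- max(abs(d - step)) <= 1e-6 * step
  if (!uniform) {
    if (is.null(resample_to)) {
      stop(what, ": non-uniform wavelength spacing; pass resample_to= to ",
           "interpolate onto a uniform grid", call. = FALSE)
    }
    s <- spectrum(wl_grid(wl[1L], wl[length(wl)],
                          (wl[length(wl)] - wl[1L]) / (length(wl) - 1L)),
                  stats::approx(wl, ab, xout = seq(wl[1L], wl[length(wl)],
                                                   length.out = length(wl)))$y,
                  label = label, meta = meta)
    return(resample(s, resample_to))
  }
  grid <- wl_grid(wl[1L], wl[length(wl)], step)
  s <- spectrum(grid, ab, label = label, meta = meta)
  if (!is.null(resample_to)) s <- resample(s, resample_to)
  s
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]: metadata (and the label) are written as
#' `# key=value` comment lines before the `wavelength_nm,absorbance` header.
#' Absorbances are written with enough digits that a read/write round trip
#' reproduces them to better than 1e-9 AU on an identical grid.
#'
#' @param spec A [spectrum()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("write_spectrum_csv: cannot open '", path, "' for writing: ",
         conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  if (nzchar(spec$label)) {
    writeLines(sprintf("# label=%s", spec$label), con)
  }
  meta <- spec$meta[setdiff(names(spec$meta), "label")]
  for (key in names(meta)) {
    writeLines(sprintf("# %s=%s", key, format(meta[[key]], digits = 15)), con)
  }
  writeLines("wavelength_nm,absorbance", con)
  writeLines(sprintf("%.6f,%.12g", wavelengths(spec), spec$absorbance), con)
  invisible(path)
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports only the fixed-point `##XYDATA=(X++(Y..Y))` layout common in
#' instrument exports: `##FIRSTX`, `##LASTX`, `##DELTAX`/`##NPOINTS`,
#' `##XFACTOR`, `##YFACTOR`, then data lines of an X value followed by one or
#' more Y values.  Compressed (SQZ/DIF/DUP) encodings are not supported.
#'
#' @param path Path to a JCAMP-DX file.
#' @param resample_to Optional target [wl_grid()].
#' @return A [spectrum()].
#' @export
read_spectrum_jcamp <- function(path, resample_to = NULL) {
  if (!file.exists(path)) {
    stop("read_spectrum_jcamp: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(default)
    suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", hit[1L]))))
  }
  title_hit <- grep("^##TITLE\\s*=", lines, ignore.case = TRUE, value = TRUE)
  label <- if (length(title_hit)) trimws(sub("^[^=]*=", "", title_hit[1L]))
           else strip_ext(basename(path))
  xf <- ldr("XFACTOR", 1)
  yf <- ldr("YFACTOR", 1)
  start <- grep("^##XYDATA\\s*=\\s*\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines,
                ignore.case = TRUE)
  if (!length(start)) {
    stop("read_spectrum_jcamp: no ##XYDATA=(X++(Y..Y)) block in ", path,
         call. = FALSE)
  }
  end <- grep("^##", lines)
  end <- end[end > start[1L]]
  data_lines <- lines[(start[1L] + 1L):(if (length(end)) end[1L] - 1L
                                        else length(lines))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) {
    stop("read_spectrum_jcamp: empty XYDATA block", call. = FALSE)
  }
  wl <- numeric(0)
  ab <- numeric(0)
  for (i in seq_along(data_lines)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(trimws(data_lines[i]), "[,;[:space:]]+")[[1L]]))
    if (length(vals) < 2L || anyNA(vals)) {
      stop("read_spectrum_jcamp: unparseable XYDATA line ", i, ": '",
           data_lines[i], "' (compressed encodings are not supported)",
           call. = FALSE)
    }
    ys <- vals[-1L]
    # X of each subsequent Y advances by DELTAX (inferred below if absent)
    wl <- c(wl, vals[1L], rep(NA_real_, length(ys) - 1L))
    ab <- c(ab, ys)
  }
  dx <- ldr("DELTAX")
  if (is.na(dx)) {
    firstx <- ldr("FIRSTX")
    lastx <- ldr("LASTX")
    np <- ldr("NPOINTS", length(ab))
    if (is.na(firstx) || is.na(lastx)) {
      stop("read_spectrum_jcamp: need ##DELTAX or ##FIRSTX/##LASTX",
           call. = FALSE)
    }
    dx <- (lastx - firstx) / (np - 1)
  }
  for (j in seq_along(wl)) {
    if (is.na(wl[j])) wl[j] <- wl[j - 1L] + dx
  }
  spectrum_from_xy(wl * xf, ab * yf, meta = list(source = "jcamp-dx"),
                   label = label, resample_to = resample_to,
                   what = "read_spectrum_jcamp")
}
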