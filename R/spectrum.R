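#' Construct a 1-D NMR spectrum
#'
#' A spectrum is a tibble with columns `ppm` (chemical shift, parts per
#' million, stored descending as is conventional for NMR display) and
#' `intensity` (arbitrary units), carrying the spectrometer frequency in MHz
#' as an attribute. All quantification in this package is ratio-based, so the
#' absolute intensity scale is irrelevant; the frequency matters because
#' scalar couplings are constant in Hz, not ppm.
#'
#' @param ppm Numeric vector of chemical shifts (ppm). Must be strictly
#'   monotonic; it is reordered to descending if supplied ascending.
#' @param intensity Numeric vector of the same length; all values finite.
#' @param spectrometer_freq Spectrometer frequency in MHz (default 400).
#' @return A tibble of class `nmr_spectrum` with columns `ppm`, `intensity`.
#' @examples
#' s <- nmr_spectrum(seq(10, -0.5, length.out = 512), rnorm(512, 0, 0.01))
#' spectrometer_freq(s)
#' @export
nmr_spectrum <- function(ppm, intensity, spectrometer_freq = 400) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(ppm) < 2) stop("a spectrum needs at least 2 points", call. = FALSE)
  d <- diff(ppm)
  if (all(d > 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("`ppm` must be strictly monotonic", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0) {
    stop("`spectrometer_freq` must be a positive number (MHz)", call. = FALSE)
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "spectrometer_freq") <- spectrometer_freq
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' @rdname nmr_spectrum
#' @param x An `nmr_spectrum`.
#' @export
spectrometer_freq <- function(x) {
  f <- attr(x, "spectrometer_freq")
  if (is.null(f)) 400 else f
}

is_nmr_spectrum <- function(x) inherits(x, "nmr_spectrum")

assert_spectrum <- function(x) {
  if (!is_nmr_spectrum(x)) {
    stop("expected an `nmr_spectrum` (see `nmr_spectrum()`)", call. = FALSE)
  }
  invisible(x)
}

#' Read and write spectra as two-column text
#'
#' The plain-text dialect is whitespace-separated `ppm intensity` pairs, one
#' per line; lines starting with `#` are comments. This is the lowest common
#' denominator exchanged between NMR processing programs.
#'
#' @param path File path.
#' @param spectrometer_freq Frequency in MHz to attach on read (the text
#'   format does not carry it). A `# spectrometer_freq_mhz:` comment written
#'   by [write_spectrum_txt()] overrides this.
#' @return [read_spectrum_txt()] returns an `nmr_spectrum`;
#'   [write_spectrum_txt()] returns `path` invisibly.
#' @export
read_spectrum_txt <- function(path, spectrometer_freq = 400) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*spectrometer_freq_mhz:", lines, value = TRUE)
  if (length(hdr) >= 1) {
    spectrometer_freq <- as.numeric(sub("^#\\s*spectrometer_freq_mhz:\\s*", "", hdr[1]))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("no data lines in ", path, call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x) as.numeric(x[1:2])))
  nmr_spectrum(m[, 1], m[, 2], spectrometer_freq = spectrometer_freq)
}

#' @rdname read_spectrum_txt
#' @param spec An `nmr_spectrum`.
#' @export
write_spectrum_txt <- function(spec, path) {
  assert_spectrum(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spectrometer_freq_mhz: %g", spectrometer_freq(spec)), con)
  writeLines(sprintf("%.8g %.10g", spec$ppm, spec$intensity), con)
  invisible(path)
}

#' Read and write spectra in JCAMP-DX (XYDATA, AFFN)
#'
#' Covers the fixed-step `##XYDATA=(X++(Y..Y))` form with AFFN (plain
#' decimal) values, which is what most 1-D exports use. Compression schemes
#' (SQZ/DIF/DUP) and multi-block files are not supported.
#'
#' @param path File path.
#' @return [read_jcamp()] returns an `nmr_spectrum`; [write_jcamp()] returns
#'   `path` invisibly.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  num_field <- function(key, default = NA_real_) {
    v <- suppressWarnings(as.numeric(get_field(key)))
    if (is.na(v)) default else v
  }
  xfactor <- num_field("XFACTOR", 1)
  yfactor <- num_field("YFACTOR", 1)
  freq <- num_field("\\.OBSERVE FREQUENCY", 400)
  i0 <- grep("^##XYDATA=", lines)
  if (length(i0) == 0) stop("no ##XYDATA block in ", path, call. = FALSE)
  iend <- grep("^##END=", lines)
  iend <- if (length(iend)) min(iend[iend > i0[1]]) else length(lines) + 1
  body <- lines[(i0[1] + 1):(iend - 1)]
  body <- body[!grepl("^\\s*$", body)]
  xs <- list()
  ys <- list()
  for (ln in body) {
    tok <- as.numeric(strsplit(trimws(ln), "[\\s,]+", perl = TRUE)[[1]])
    if (length(tok) < 2) next
    x0 <- tok[1] * xfactor
    yv <- tok[-1] * yfactor
    npt <- num_field("NPOINTS")
    firstx <- num_field("FIRSTX")
    lastx <- num_field("LASTX")
    step <- if (!is.na(npt) && !is.na(firstx) && !is.na(lastx) && npt > 1) {
      (lastx - firstx) / (npt - 1)
    } else {
      NA_real_
    }
    if (is.na(step)) stop("JCAMP file lacks FIRSTX/LASTX/NPOINTS; cannot infer x grid", call. = FALSE)
    xs[[length(xs) + 1]] <- x0 + step * (seq_along(yv) - 1)
    ys[[length(ys) + 1]] <- yv
  }
  nmr_spectrum(unlist(xs), unlist(ys), spectrometer_freq = freq)
}

#' @rdname read_jcamp
#' @param spec An `nmr_spectrum`.
#' @param title Title line for the JCAMP header.
#' @export
write_jcamp <- function(spec, path, title = "osmoquant spectrum") {
  assert_spectrum(spec)
  x <- rev(spec$ppm) # ascending for the X++(Y..Y) grid
  y <- rev(spec$intensity)
  ymax <- max(abs(y))
  yfactor <- if (ymax > 0) ymax / 1e8 else 1
  yi <- y / yfactor
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##.OBSERVE FREQUENCY=%g", spectrometer_freq(spec)),
    sprintf("##FIRSTX=%.10g", x[1]),
    sprintf("##LASTX=%.10g", x[length(x)]),
    sprintf("##NPOINTS=%d", length(x)),
    "##XFACTOR=1",
    sprintf("##YFACTOR=%.10g", yfactor),
    "##XYDATA=(X++(Y..Y))"
  )
  writeLines(hdr, con)
  per_line <- 6
  idx <- seq(1, length(x), by = per_line)
  lines <- vapply(idx, function(i) {
    j <- min(i + per_line - 1, length(x))
    paste(c(sprintf("%.10g", x[i]), sprintf("%.6f", yi[i:j])), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines("##END=", con)
  invisible(path)
}

#' Plot a spectrum
#'
#' Standard NMR display: intensity against chemical shift with the ppm axis
#' reversed (high field to the right).
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
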