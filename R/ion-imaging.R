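#' Segmentation result container
#'
#' @param masks Named list of logical matrices `background`, `cytoplasm`,
#'   `vacuole`, pairwise disjoint and of equal dimension.
#' @param thresholds Numeric length-2 `(t_low, t_high)`, `t_low < t_high`.
#' @param background_regions A tibble of exactly 4 rectangular ROIs with
#'   columns `row_min`, `row_max`, `col_min`, `col_max`.
#' @return A list of class `segmentation_result`.
#' @export
new_segmentation <- function(masks, thresholds, background_regions) {
  stopifnot(all(c("background", "cytoplasm", "vacuole") %in% names(masks)))
  if (!(thresholds[1] < thresholds[2])) {
    stop("thresholds must satisfy t_low < t_high", call. = FALSE)
  }
  overlap <- (masks$background & masks$cytoplasm) |
    (masks$background & masks$vacuole) | (masks$cytoplasm & masks$vacuole)
  if (any(overlap)) stop("masks must be pairwise disjoint", call. = FALSE)
  background_regions <- tibble::as_tibble(background_regions)
  if (nrow(background_regions) != 4) {
    stop("exactly 4 background regions are required", call. = FALSE)
  }
  structure(
    list(masks = masks, thresholds = c(t_low = unname(thresholds[1]),
                                       t_high = unname(thresholds[2])),
         background_regions = background_regions),
    class = "segmentation_result"
  )
}

# default background ROIs: 4 corner squares, side = 1/16 of image width
corner_regions <- function(height, width) {
  s <- max(2L, as.integer(floor(width / 16)))
  tibble::tibble(
    row_min = c(1L, 1L, height - s + 1L, height - s + 1L),
    row_max = c(s, s, height, height),
    col_min = c(1L, width - s + 1L, 1L, width - s + 1L),
    col_max = c(s, width, s, width)
  )
}

#' Segment a micrograph into background / cytoplasm / vacuole strata
#'
#' Pixels are classified by two intensity thresholds: background when
#' I <= t_low, cytoplasm when t_low < I <= t_high, vacuole when I > t_high
#' (the stratum ordering I_B < I_C < I_V). When thresholds are omitted they
#' are chosen by three-class between-class variance maximisation (a
#' two-threshold Otsu criterion on a 256-bin histogram).
#'
#' @param img Numeric matrix of non-negative finite intensities.
#' @param thresholds Optional numeric length-2 `(t_low, t_high)`.
#' @param background_regions Optional 4-row ROI tibble; defaults to the four
#'   image corners.
#' @return A `segmentation_result`.
#' @export
segment <- function(img, thresholds = NULL, background_regions = NULL) {
  check_image(img)
  if (is.null(thresholds)) {
    thresholds <- otsu3_thresholds(img)
  } else if (!(thresholds[1] < thresholds[2])) {
    stop("thresholds must satisfy t_low < t_high", call. = FALSE)
  }
  masks <- list(
    background = img <= thresholds[1],
    cytoplasm = img > thresholds[1] & img <= thresholds[2],
    vacuole = img > thresholds[2]
  )
  if (!any(masks$cytoplasm)) {
    stop("empty cytoplasm stratum: thresholds (", signif(thresholds[1], 4), ", ",
         signif(thresholds[2], 4), ") leave no pixels between them", call. = FALSE)
  }
  new_segmentation(masks, thresholds,
                   background_regions %||% corner_regions(nrow(img), ncol(img)))
}

# two-threshold Otsu: exhaustive search over histogram bin pairs maximising
# between-class variance
otsu3_thresholds <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("uniform image: no separable intensity strata", call. = FALSE)
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  total_mean <- cm[n_bins]
  best <- c(NA, NA)
  best_var <- -Inf
  for (i in seq_len(n_bins - 2)) {
    w0 <- cw[i]
    if (w0 == 0) next
    m0 <- cm[i] / w0
    j <- (i + 1):(n_bins - 1)
    w1 <- cw[j] - cw[i]
    w2 <- 1 - cw[j]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m1 <- (cm[j] - cm[i]) / w1
    m2 <- (total_mean - cm[j]) / w2
    bv <- w0 * (m0 - total_mean)^2 + w1 * (m1 - total_mean)^2 +
      w2 * (m2 - total_mean)^2
    bv[!ok] <- -Inf
    k <- which.max(bv)
    if (bv[k] > best_var) {
      best_var <- bv[k]
      best <- c(br[i + 1], br[j[k] + 1])
    }
  }
  if (!is.finite(best_var)) {
    stop("could not separate three intensity strata", call. = FALSE)
  }
  best
}

check_image <- function(img) {
  if (!is.matrix(img) || length(img) == 0) {
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(img)) || any(img < 0)) {
    stop("image intensities must be finite and >= 0", call. = FALSE)
  }
  invisible(img)
}

#' Mean background intensity over four regions
#'
#' Equal-weight mean of the per-region mean intensities, so unequal region
#' sizes do not bias the estimate.
#'
#' @param img Numeric intensity matrix.
#' @param regions ROI tibble (`row_min`, `row_max`, `col_min`, `col_max`);
#'   defaults to the four image corners.
#' @return The background level I_B (scalar).
#' @export
background_mean <- function(img, regions = NULL) {
  check_image(img)
  regions <- tibble::as_tibble(regions %||% corner_regions(nrow(img), ncol(img)))
  per_roi <- purrr::pmap_dbl(regions, function(row_min, row_max, col_min, col_max, ...) {
    if (row_min < 1 || col_min < 1 || row_max > nrow(img) || col_max > ncol(img) ||
        row_min > row_max || col_min > col_max) {
      stop("background region outside the image", call. = FALSE)
    }
    mean(img[row_min:row_max, col_min:col_max])
  })
  mean(per_roi)
}

#' Corrected relative fluorescence of the cytoplasm
#'
#' Implements the corrected relative fluorescence statistic: with I_C the
#' summed intensity over the cytoplasm mask (vacuole pixels excluded), A_C
#' the cytoplasm pixel area and I_B the mean per-pixel background level,
#' \deqn{CRF_C = I_C - A_C \cdot I_B, \qquad CRF_{norm} = CRF_C / A_C.}
#' CRF_C is the background-corrected integrated signal and may be negative
#' for dim cells; it is reported as computed. CRF_norm is the per-pixel
#' corrected mean, invariant to adding a constant to every pixel and
#' equivariant under intensity rescaling. Vacuole statistics are reported
#' alongside but never enter the CRF.
#'
#' @param img Numeric intensity matrix.
#' @param seg A `segmentation_result` for `img`.
#' @param background_regions Optional ROI tibble overriding the ones stored
#'   in `seg`.
#' @return A one-row tibble: `i_b`, `a_c`, `i_c_total`, `crf_c`, `crf_norm`,
#'   `a_v`, `i_v_mean`.
#' @export
crf <- function(img, seg, background_regions = NULL) {
  check_image(img)
  stopifnot(inherits(seg, "segmentation_result"))
  cyt <- seg$masks$cytoplasm
  if (!any(cyt)) stop("cytoplasm mask is empty (A_C = 0)", call. = FALSE)
  i_b <- background_mean(img, background_regions %||% seg$background_regions)
  a_c <- sum(cyt)
  i_c_total <- sum(img[cyt])
  crf_c <- i_c_total - a_c * i_b
  vac <- seg$masks$vacuole
  tibble::tibble(
    i_b = i_b, a_c = a_c, i_c_total = i_c_total,
    crf_c = crf_c, crf_norm = crf_c / a_c,
    a_v = sum(vac),
    i_v_mean = if (any(vac)) mean(img[vac]) else NA_real_
  )
}

#' Summarise per-cell CRF values by group
#'
#' @param results A data frame with one row per cell, a `crf_norm` column
#'   and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A tibble per group: `group`, `n`, `mean_crf_norm`, `sd_crf_norm`
#'   (sample sd; `NA` for single-cell groups, where it is undefined).
#' @export
summarize_cells <- function(results, group = "group") {
  results <- tibble::as_tibble(results)
  if (!all(c(group, "crf_norm") %in% names(results))) {
    stop("`results` needs columns '", group, "' and 'crf_norm'", call. = FALSE)
  }
  out <- dplyr::group_by(results, group = .data[[group]])
  out <- dplyr::summarise(
    out,
    n = dplyr::n(),
    mean_crf_norm = mean(.data$crf_norm),
    sd_crf_norm = ifelse(dplyr::n() > 1, stats::sd(.data$crf_norm), NA_real_),
    .groups = "drop"
  )
  out
}

#' Read and write grayscale images
#'
#' TIFF and PNG round-trip through the `tiff` and `png` packages, which
#' represent samples on a 0-1 scale; intensities are mapped to 0-65535
#' counts on write and scaled back on read. TIFF is written at 16 bits and
#' faithful to one count; PNG is an 8-bit container here (quantisation step
#' 257 counts), fine for inspection, not for measurement. PGM (portable
#' graymap, plain `P2` text variant) is read and written directly and
#' preserves integer counts; it is the format used for plain-text fixtures.
#'
#' @param path File path; the format is chosen by extension
#'   (`.tif`/`.tiff`, `.png`, `.pgm`).
#' @return [read_image()] returns a numeric intensity matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = to_gray(tiff::readTIFF(path)) * 65535,
    png = to_gray(png::readPNG(path)) * 65535,
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
}

#' @rdname read_image
#' @param img Numeric intensity matrix (arbitrary non-negative units; values
#'   above 65535 are clipped for TIFF/PNG output).
#' @export
write_image <- function(img, path) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png")) {
    scaled <- pmin(img, 65535) / 65535
    if (ext == "png") png::writePNG(scaled, path) else {
      tiff::writeTIFF(scaled, path, bits.per.sample = 16)
    }
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

to_gray <- function(a) {
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  v <- as.numeric(tok[-1])
  w <- v[1]; h <- v[2]
  px <- v[-(1:3)] # drop width, height, maxval
  if (length(px) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  maxval <- max(1, ceiling(max(img)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(round(img), 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read rectangular ROIs from a JSON file
#'
#' Expects a JSON array of objects with `row_min`, `row_max`, `col_min`,
#' `col_max` fields (1-based, inclusive).
#'
#' @param path JSON file path.
#' @return A tibble of ROIs.
#' @export
read_roi_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Plot CRF group summaries
#'
#' @param summary Output of [summarize_cells()].
#' @return A ggplot with group means and +/- sd error bars.
#' @export
plot_crf_groups <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group, y = .data$mean_crf_norm)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_crf_norm - .data$sd_crf_norm,
                   ymax = .data$mean_crf_norm + .data$sd_crf_norm),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = expression(CRF[norm])) +
    ggplot2::theme_minimal()
}
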