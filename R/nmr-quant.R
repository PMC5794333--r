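#' Detect peaks in a 1-D spectrum
#'
#' Local maxima whose height exceeds `min_snr` times a robust noise estimate
#' (median absolute deviation of a signal-free region, by default 9-10 ppm).
#' Maxima inside exclusion windows are dropped; the default window 4.6-4.9
#' ppm masks the residual HOD resonance of D2O samples.
#'
#' @param spec An `nmr_spectrum`.
#' @param min_snr Signal-to-noise threshold (> 0). With a noise estimate of
#'   exactly zero (noise-free simulations) any positive local maximum counts.
#' @param exclusion_windows List of length-2 numeric ppm intervals to omit.
#' @param noise_region Length-2 ppm interval used for the noise estimate.
#' @return A tibble with columns `shift`, `height`, sorted by shift
#'   descending. Empty (zero rows) for a featureless spectrum.
#' @export
detect_peaks <- function(spec, min_snr = 3,
                         exclusion_windows = list(c(4.6, 4.9)),
                         noise_region = c(9, 10)) {
  assert_spectrum(spec)
  if (min_snr <= 0) stop("min_snr must be > 0", call. = FALSE)
  y <- spec$intensity
  x <- spec$ppm
  n <- length(y)
  noise <- spectrum_noise_sd(spec, noise_region)
  thr <- if (noise > 0) min_snr * noise else 0
  i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] > y[-(1:2)]) + 1
  i <- i[y[i] > thr]
  if (length(i) && length(exclusion_windows)) {
    keep <- rep(TRUE, length(i))
    for (w in exclusion_windows) {
      keep <- keep & !(x[i] >= min(w) & x[i] <= max(w))
    }
    i <- i[keep]
  }
  out <- tibble::tibble(shift = x[i], height = y[i])
  dplyr::arrange(out, dplyr::desc(.data$shift))
}

# robust noise level from a (presumed) signal-free region; falls back to the
# whole spectrum when the region lies outside the axis
spectrum_noise_sd <- function(spec, noise_region) {
  sel <- spec$ppm >= min(noise_region) & spec$ppm <= max(noise_region)
  y <- if (sum(sel) >= 16) spec$intensity[sel] else spec$intensity
  stats::mad(y)
}

#' Assign detected peaks to library solutes
#'
#' Each reference peak is matched to the nearest detected peak within `tol`
#' ppm, greedily by distance (ties broken toward lower ppm), never assigning
#' one detected peak to two reference peaks of the same solute. A solute is
#' identified only when every one of its reference peaks found a match --
#' single-peak coincidence is not accepted as identification.
#'
#' @param peaks Tibble from [detect_peaks()] (columns `shift`, `height`).
#' @param library Reference library, see [solute_library()].
#' @param tol Matching tolerance in ppm (> 0, default 0.03).
#' @return A tibble with one row per reference peak: `solute`, `ref_shift`,
#'   `n_protons`, `quant`, `detected_shift`, `shift_error`, `height`, and a
#'   per-solute logical `identified`.
#' @export
assign_solutes <- function(peaks, library = solute_library(), tol = 0.03) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  library <- validate_library(library)
  peaks <- dplyr::arrange(tibble::as_tibble(peaks), .data$shift) # order-invariant
  out <- purrr::map_dfr(split(library, library$solute), function(refs) {
    refs <- dplyr::arrange(refs, .data$shift)
    match_solute_peaks(refs, peaks, tol)
  })
  out <- dplyr::group_by(out, .data$solute)
  out <- dplyr::mutate(out, identified = all(!is.na(.data$detected_shift)))
  dplyr::ungroup(out)
}

# greedy nearest matching of one solute's reference peaks to detected peaks
match_solute_peaks <- function(refs, peaks, tol) {
  nref <- nrow(refs)
  det_shift <- rep(NA_real_, nref)
  det_height <- rep(NA_real_, nref)
  if (nrow(peaks) > 0) {
    cand <- expand.grid(r = seq_len(nref), p = seq_len(nrow(peaks)))
    cand$dist <- abs(refs$shift[cand$r] - peaks$shift[cand$p])
    cand <- cand[cand$dist <= tol, , drop = FALSE]
    cand <- cand[order(cand$dist, peaks$shift[cand$p]), , drop = FALSE]
    used_r <- logical(nref)
    used_p <- logical(nrow(peaks))
    for (k in seq_len(nrow(cand))) {
      r <- cand$r[k]; p <- cand$p[k]
      if (used_r[r] || used_p[p]) next
      used_r[r] <- TRUE
      used_p[p] <- TRUE
      det_shift[r] <- peaks$shift[p]
      det_height[r] <- peaks$height[p]
    }
  }
  tibble::tibble(
    solute = refs$solute, ref_shift = refs$shift, n_protons = refs$n_protons,
    quant = refs$quant, detected_shift = det_shift,
    shift_error = det_shift - refs$shift, height = det_height
  )
}

#' Integrate a peak over a window with endpoint baseline subtraction
#'
#' Trapezoidal integral of intensity over `[center - window, center +
#' window]` after subtracting the straight line through the two window
#' endpoints. The linear baseline removes slowly varying tails of
#' neighbouring resonances; the result is floored at 0.
#'
#' @param spec An `nmr_spectrum`.
#' @param center Window centre, ppm.
#' @param window Window half-width, ppm (> 0). The full window must lie
#'   inside the axis.
#' @param baseline_flank Optional half-width (ppm) of a flank just outside
#'   each window edge over which the baseline level at that edge is
#'   averaged. The default 0 takes the bare endpoint intensities; a nonzero
#'   flank suppresses the noise a single endpoint would inject into the
#'   baseline (the flank must still lie inside the axis and should stay
#'   clear of neighbouring resonances).
#' @return A single non-negative area in intensity x ppm units.
#' @export
integrate_peak <- function(spec, center, window, baseline_flank = 0) {
  assert_spectrum(spec)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (baseline_flank < 0) stop("baseline_flank must be >= 0", call. = FALSE)
  lo <- center - window
  hi <- center + window
  if (lo - baseline_flank < min(spec$ppm) || hi + baseline_flank > max(spec$ppm)) {
    stop("integration window [", lo, ", ", hi, "] (plus flank) falls outside ",
         "the ppm axis", call. = FALSE)
  }
  sel <- spec$ppm >= lo & spec$ppm <= hi
  x <- rev(spec$ppm[sel]) # ascending
  y <- rev(spec$intensity[sel])
  if (length(x) < 2) stop("integration window contains fewer than 2 points", call. = FALSE)
  level_lo <- flank_level(spec, lo, -baseline_flank, y[1])
  level_hi <- flank_level(spec, hi, baseline_flank, y[length(y)])
  base <- level_lo + (level_hi - level_lo) * (x - x[1]) / (x[length(x)] - x[1])
  yc <- y - base
  area <- sum(diff(x) * (yc[-1] + yc[-length(yc)]) / 2)
  max(area, 0)
}

# baseline level at a window edge: the bare endpoint, or the mean over a
# flank extending `flank` ppm outward from the edge
flank_level <- function(spec, edge, flank, endpoint_value) {
  if (flank == 0) return(endpoint_value)
  rng <- sort(c(edge, edge + flank))
  sel <- spec$ppm >= rng[1] & spec$ppm <= rng[2]
  if (sum(sel) < 2) return(endpoint_value)
  mean(spec$intensity[sel])
}

#' Quantify solutes against the internal standard
#'
#' Molar tube concentration from areas: c_s = (A_s / A_std) * (n_std / n_s)
#' * c_std, using each identified solute's quantification peak. The
#' proton-count factor converts per-proton signal to per-molecule signal and
#' is what makes the result molar. Solutes not identified in the spectrum are
#' reported at 0 mol/l; a missing standard peak makes the spectrum unusable
#' and is an error.
#'
#' @param spec An `nmr_spectrum`.
#' @param library Reference library; rows whose solute equals the standard's
#'   name are not quantified.
#' @param standard An [internal_standard()].
#' @param tol Peak-matching tolerance, ppm.
#' @param window Integration half-width, ppm. The default 0.004 ppm (1.6 Hz
#'   at 400 MHz, about one linewidth) keeps the 3.27/3.29 ppm GB/Ect pair
#'   from bleeding into each other; the Lorentzian tail fraction lost
#'   outside the narrow window cancels in the ratio to the standard because
#'   every peak shares the window and linewidth.
#' @param baseline_flank Baseline-averaging flank per window edge, ppm;
#'   defaults to half the window. See [integrate_peak()].
#' @param min_snr,exclusion_windows Passed to [detect_peaks()].
#' @return A tibble with one row per non-standard library solute: `solute`,
#'   `identified`, `detected_shift`, `area`, `tube_conc_mol_l`.
#' @export
quantify <- function(spec, library = solute_library(),
                     standard = internal_standard(), tol = 0.03,
                     window = 0.004, baseline_flank = window / 2,
                     min_snr = 3,
                     exclusion_windows = list(c(4.6, 4.9))) {
  assert_spectrum(spec)
  library <- validate_library(library)
  peaks <- detect_peaks(spec, min_snr = min_snr,
                        exclusion_windows = exclusion_windows)
  std_area <- standard_area(spec, peaks, standard, tol, window, baseline_flank)
  asn <- assign_solutes(peaks, library, tol = tol)
  qrows <- dplyr::filter(asn, .data$quant, .data$solute != standard$name)
  area <- purrr::map2_dbl(qrows$detected_shift, qrows$identified, function(sh, id) {
    if (!id || is.na(sh)) return(0)
    integrate_peak(spec, sh, window, baseline_flank)
  })
  tibble::tibble(
    solute = qrows$solute,
    identified = qrows$identified,
    detected_shift = qrows$detected_shift,
    area = area,
    tube_conc_mol_l = area / std_area * standard$n_protons / qrows$n_protons *
      standard$concentration
  )
}

standard_area <- function(spec, peaks, standard, tol, window, baseline_flank = 0) {
  near <- peaks[abs(peaks$shift - standard$shift) <= tol, ]
  if (nrow(near) == 0) {
    stop("internal standard '", standard$name, "' peak not detected near ",
         standard$shift, " ppm; spectrum unusable for quantification",
         call. = FALSE)
  }
  ctr <- near$shift[which.max(near$height)]
  a <- integrate_peak(spec, ctr, window, baseline_flank)
  if (a <= 0) {
    stop("internal standard peak integrates to zero area", call. = FALSE)
  }
  a
}

#' Scale a tube concentration to intracellular molarity
#'
#' The measured amount in the NMR tube (tube concentration x sample volume)
#' is divided by the total cell volume it came from (cell count x mean
#' single-cell volume). Exactly bilinear in `tube_conc` and
#' `sample_volume_l`, inverse-linear in `n_cells` and `cell_volume_pl`.
#'
#' @param tube_conc Concentration in the tube, mol/l (>= 0).
#' @param sample_volume_l Tube sample volume, litres.
#' @param n_cells Number of cells extracted into the sample (> 0).
#' @param cell_volume_pl Mean single-cell volume, picolitres (> 0); 8.01 pl
#'   is the cylinder-plus-cones estimate for *S. salinarum*.
#' @return Intracellular concentration, mol/l.
#' @examples
#' intracellular_concentration(1 / 600e-6 * 1e-6, 600e-6, 1e5, 8.01) # 1 umol over 1e5 cells
#' @export
intracellular_concentration <- function(tube_conc, sample_volume_l, n_cells,
                                        cell_volume_pl = 8.01) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0", call. = FALSE)
  if (any(cell_volume_pl <= 0)) stop("cell_volume_pl must be > 0", call. = FALSE)
  if (any(tube_conc < 0)) stop("tube_conc must be >= 0", call. = FALSE)
  tube_conc * sample_volume_l / (n_cells * cell_volume_pl * 1e-12)
}

#' Resolve labelled and unlabelled glycine betaine plus ectoine
#'
#' Unlabelled GB is estimated from the central singlet at the GB
#' quantification shift; the 1,2-13C2 isotopologue from the summed satellite
#' doublet at +/- J/(2 x frequency) ppm around it; ectoine from its
#' quantification peak. All areas are proton-count corrected and one common
#' integration window is used throughout, so Lorentzian capture fractions
#' cancel in the ratios. The result is normalised so the smallest nonzero
#' component equals 1.
#'
#' @param spec An `nmr_spectrum`.
#' @param library Reference library (must contain `gb_name` and `ect_name`).
#' @param standard An [internal_standard()] (used only to anchor detection).
#' @param j_hz One-bond 13C-H coupling in Hz (default 144). The satellite
#'   offset J/(2f) must exceed twice the window or the satellites are not
#'   resolvable from the central peak and an error is raised.
#' @param tol Peak-matching tolerance, ppm.
#' @param window Common integration half-width, ppm (default 0.006; at 144 Hz
#'   and 400 MHz the satellite at 3.45 ppm sits only 0.01 ppm from ectoine's
#'   3.44 ppm resonance, so the window must stay narrow).
#' @param gb_name,ect_name Library names of the two solutes.
#' @return A tibble with columns `component` (`"GB"`, `"13C2-GB"`,
#'   `"Ect"`), `area`, `conc_rel` (proton-corrected area) and `ratio`.
#' @export
label_ratio <- function(spec, library = solute_library(),
                        standard = internal_standard(), j_hz = 144,
                        tol = 0.03, window = 0.006,
                        gb_name = "GB", ect_name = "Ect") {
  assert_spectrum(spec)
  library <- validate_library(library)
  freq <- spectrometer_freq(spec)
  off <- j_hz / (2 * freq)
  if (off <= 2 * window) {
    stop("satellite offset J/(2f) = ", signif(off, 3),
         " ppm does not clear the integration window (", window,
         " ppm); satellites overlap the central peak -- increase J, the ",
         "field, or narrow the window", call. = FALSE)
  }
  gb_q <- library[library$solute == gb_name & library$quant, ]
  ect_q <- library[library$solute == ect_name & library$quant, ]
  if (nrow(gb_q) != 1 || nrow(ect_q) != 1) {
    stop("library must contain quantification peaks for '", gb_name,
         "' and '", ect_name, "'", call. = FALSE)
  }
  peaks <- detect_peaks(spec)
  # snap no farther than the window itself, or a neighbouring resonance
  # (Ect at 3.29 ppm, 0.02 from GB's 3.27) would be mistaken for the target
  snap <- min(tol, window)
  ctr_gb <- refine_center(peaks, gb_q$shift, snap)
  ctr_ect <- refine_center(peaks, ect_q$shift, snap)
  a_central <- integrate_peak(spec, ctr_gb, window)
  a_sat <- integrate_peak(spec, refine_center(peaks, gb_q$shift - off, snap), window) +
    integrate_peak(spec, refine_center(peaks, gb_q$shift + off, snap), window)
  a_ect <- integrate_peak(spec, ctr_ect, window)
  conc_rel <- c(a_central / gb_q$n_protons, a_sat / gb_q$n_protons,
                a_ect / ect_q$n_protons)
  nz <- conc_rel[conc_rel > 0]
  ratio <- if (length(nz)) conc_rel / min(nz) else conc_rel
  tibble::tibble(
    component = c(gb_name, paste0("13C2-", gb_name), ect_name),
    area = c(a_central, a_sat, a_ect),
    conc_rel = conc_rel,
    ratio = ratio
  )
}

# snap an expected position to the nearest detected maximum within tol;
# fall back to the nominal position when nothing is there (area ~ 0 then)
refine_center <- function(peaks, expected, tol) {
  if (nrow(peaks) == 0) return(expected)
  d <- abs(peaks$shift - expected)
  if (min(d) <= tol) peaks$shift[which.min(d)] else expected
}
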