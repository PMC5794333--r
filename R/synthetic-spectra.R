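#' Configuration for synthetic 1-D proton spectra
#'
#' Defaults emulate routine solution-state acquisition on a 400-MHz
#' instrument: a -0.5 to 10 ppm window, Lorentzian lines of 1.5 Hz full width
#' at half maximum, and a grid fine enough (32768 points, ~0.13 Hz/pt) to put
#' a dozen samples across each line.
#'
#' @param ppm_min,ppm_max Axis limits in ppm.
#' @param n_points Number of grid points (>= 2).
#' @param spectrometer_freq Spectrometer frequency, MHz.
#' @param linewidth Full width at half maximum of each line, Hz.
#' @param noise_sd Standard deviation of additive Gaussian noise, intensity
#'   units (0 = noise-free).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(ppm_min = -0.5, ppm_max = 10, n_points = 32768,
                                spectrometer_freq = 400, linewidth = 1.5,
                                noise_sd = 0, seed = NULL) {
  if (!(ppm_min < ppm_max)) stop("ppm_min must be < ppm_max", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (linewidth <= 0) stop("linewidth must be > 0 (Hz)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(ppm_min = ppm_min, ppm_max = ppm_max, n_points = as.integer(n_points),
         spectrometer_freq = spectrometer_freq, linewidth = linewidth,
         noise_sd = noise_sd, seed = seed),
    class = "spectrum_sim_config"
  )
}

# Lorentzian profile with unit area: hwhm in ppm
lorentzian <- function(x, center, hwhm) {
  (hwhm / pi) / ((x - center)^2 + hwhm^2)
}

# Render a set of lines (center_ppm, area) onto an intensity vector.
render_lines <- function(ppm, centers, areas, hwhm) {
  y <- numeric(length(ppm))
  for (i in seq_along(centers)) {
    if (areas[i] == 0) next
    y <- y + areas[i] * lorentzian(ppm, centers[i], hwhm)
  }
  y
}

# Expand one reference peak into multiplet lines with binomial (first-order)
# intensities. Returns tibble(center, weight) with weights summing to 1.
multiplet_lines <- function(shift, multiplicity, j_hz, freq) {
  n <- multiplicity_lines(multiplicity)
  if (n == 1) return(tibble::tibble(center = shift, weight = 1))
  if (is.na(j_hz)) j_hz <- 7 # generic vicinal 3J(H,H)
  k <- 0:(n - 1)
  w <- choose(n - 1, k)
  offs <- (k - (n - 1) / 2) * j_hz / freq
  tibble::tibble(center = shift + offs, weight = w / sum(w))
}

#' Simulate a mixture spectrum with an internal standard
#'
#' Every reference peak of every named solute is rendered as a Lorentzian
#' multiplet whose total integrated area equals concentration x proton count
#' (arbitrary intensity units, linear in both), so downstream ratio-based
#' quantification against the standard is exact up to integration error. The
#' internal standard appears at its reference shift (0.0 ppm for TMSP).
#'
#' @param concentrations Named numeric vector, solute name -> concentration in
#'   the tube (mol/l). Every name must exist in `library`.
#' @param standard_conc Internal standard concentration, mol/l.
#' @param library Solute reference library (see [solute_library()]).
#' @param cfg A [spectrum_sim_config()].
#' @param standard_name Library name of the internal standard.
#' @return An `nmr_spectrum`.
#' @examples
#' s <- simulate_spectrum(c(GB = 0.002, Ect = 0.001), standard_conc = 0.002,
#'                        cfg = spectrum_sim_config(n_points = 8192))
#' @export
simulate_spectrum <- function(concentrations, standard_conc,
                              library = solute_library(),
                              cfg = spectrum_sim_config(),
                              standard_name = "TMSP") {
  library <- validate_library(library)
  check_sim_concs(concentrations, library, standard_name)
  if (standard_conc < 0) stop("standard_conc must be >= 0", call. = FALSE)
  all_conc <- c(concentrations, stats::setNames(standard_conc, standard_name))
  y <- render_solutes(all_conc, library, cfg)
  y <- add_spectrum_noise(y, cfg)
  nmr_spectrum(sim_axis(cfg), y, spectrometer_freq = cfg$spectrometer_freq)
}

#' Simulate a spectrum containing 13C2-labelled glycine betaine
#'
#' Unlabelled GB contributes an ordinary singlet at each of its shifts. The
#' 1,2-13C2 isotopologue contributes, at every peak marked `c13_split` in the
#' library, a symmetric doublet split by the one-bond 13C-H coupling and
#' centred on the parent shift, with total area equal to what the same
#' concentration of unlabelled material would give (label conservation).
#' Other solutes and the internal standard are rendered as in
#' [simulate_spectrum()].
#'
#' @param unlabeled_gb,labeled_gb Tube concentrations (mol/l) of the two GB
#'   species.
#' @param other Named numeric vector of additional solute concentrations
#'   (e.g. `c(Ect = 0.001)`); may be empty.
#' @param cfg A [spectrum_sim_config()].
#' @param j_hz One-bond 13C-H coupling constant in Hz (default 144).
#' @param standard_conc,library,standard_name As in [simulate_spectrum()].
#' @param gb_name Library name of glycine betaine.
#' @return An `nmr_spectrum`.
#' @export
simulate_labeled_spectrum <- function(unlabeled_gb, labeled_gb, other = numeric(),
                                      cfg = spectrum_sim_config(), j_hz = 144,
                                      standard_conc = 0.5,
                                      library = solute_library(),
                                      standard_name = "TMSP", gb_name = "GB") {
  library <- validate_library(library)
  if (unlabeled_gb < 0 || labeled_gb < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (j_hz <= 0) stop("j_hz must be > 0", call. = FALSE)
  check_sim_concs(other, library, standard_name)
  if (gb_name %in% names(other)) {
    stop("put all unlabelled GB in `unlabeled_gb`, not in `other`", call. = FALSE)
  }
  base <- c(stats::setNames(unlabeled_gb, gb_name), other,
            stats::setNames(standard_conc, standard_name))
  y <- render_solutes(base, library, cfg)
  # labelled species: split c13-bound peaks into satellites, keep the rest
  gb <- library[library$solute == gb_name, ]
  if (nrow(gb) == 0) stop("solute '", gb_name, "' not in library", call. = FALSE)
  hwhm <- cfg$linewidth / 2 / cfg$spectrometer_freq
  off <- j_hz / (2 * cfg$spectrometer_freq)
  ax <- sim_axis(cfg)
  if (labeled_gb > 0) {
    for (i in seq_len(nrow(gb))) {
      area <- labeled_gb * gb$n_protons[i]
      if (isTRUE(gb$c13_split[i])) {
        y <- y + render_lines(ax, gb$shift[i] + c(-off, off), rep(area / 2, 2), hwhm)
      } else {
        ml <- multiplet_lines(gb$shift[i], gb$multiplicity[i], gb$j_hz[i],
                              cfg$spectrometer_freq)
        y <- y + render_lines(ax, ml$center, area * ml$weight, hwhm)
      }
    }
  }
  y <- add_spectrum_noise(y, cfg)
  nmr_spectrum(ax, y, spectrometer_freq = cfg$spectrometer_freq)
}

sim_axis <- function(cfg) {
  seq(cfg$ppm_max, cfg$ppm_min, length.out = cfg$n_points)
}

check_sim_concs <- function(concentrations, library, standard_name) {
  if (length(concentrations) == 0) return(invisible())
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    stop("`concentrations` must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(concentrations), library$solute)
  if (length(unknown)) {
    stop("solute(s) not in library: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  invisible()
}

render_solutes <- function(concs, library, cfg) {
  ax <- sim_axis(cfg)
  hwhm <- cfg$linewidth / 2 / cfg$spectrometer_freq
  y <- numeric(length(ax))
  for (nm in names(concs)) {
    conc <- concs[[nm]]
    if (conc == 0) next
    pk <- library[library$solute == nm, ]
    for (i in seq_len(nrow(pk))) {
      ml <- multiplet_lines(pk$shift[i], pk$multiplicity[i], pk$j_hz[i],
                            cfg$spectrometer_freq)
      y <- y + render_lines(ax, ml$center, conc * pk$n_protons[i] * ml$weight, hwhm)
    }
  }
  y
}

add_spectrum_noise <- function(y, cfg) {
  if (cfg$noise_sd == 0) return(y)
  noise <- with_sim_seed(cfg$seed, stats::rnorm(length(y), 0, cfg$noise_sd))
  y + noise
}

# run code under a seed without disturbing the caller's RNG stream
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
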