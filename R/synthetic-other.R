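#' Configuration for synthetic ion-imaging micrographs
#'
#' The phantom is the simplest geometry carrying the information the CRF
#' analysis uses: a dark background, an elliptical cell body at an
#' intermediate cytoplasm intensity, and a brighter circular vacuole inside
#' it. Levels must satisfy the stratum ordering background < cytoplasm <
#' vacuole assumed by threshold segmentation.
#'
#' @param height,width Image size in pixels.
#' @param background_level,cytoplasm_level,vacuole_level Mean intensities of
#'   the three strata (arbitrary camera units, >= 0).
#' @param cell_center Numeric length-2 (row, col) centre of the cell ellipse;
#'   default image centre.
#' @param cell_semiaxes Numeric length-2 (row, col) semi-axes in pixels.
#' @param vacuole_center Numeric length-2 (row, col) centre of the vacuole.
#' @param vacuole_radius Vacuole radius in pixels.
#' @param noise_sd Gaussian pixel noise sd (clipped at 0).
#' @param seed Integer seed; `NULL` leaves the RNG untouched.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(height = 96, width = 96,
                             background_level = 10, cytoplasm_level = 50,
                             vacuole_level = 120,
                             cell_center = NULL, cell_semiaxes = c(30, 20),
                             vacuole_center = NULL, vacuole_radius = 7,
                             noise_sd = 0, seed = NULL) {
  if (!(background_level < cytoplasm_level && cytoplasm_level < vacuole_level)) {
    stop("levels must satisfy background < cytoplasm < vacuole", call. = FALSE)
  }
  if (background_level < 0) stop("levels must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cell_center <- cell_center %||% c(height / 2, width / 2)
  vacuole_center <- vacuole_center %||% (cell_center + c(0, cell_semiaxes[2] / 3))
  structure(
    list(height = as.integer(height), width = as.integer(width),
         background_level = background_level, cytoplasm_level = cytoplasm_level,
         vacuole_level = vacuole_level, cell_center = cell_center,
         cell_semiaxes = cell_semiaxes, vacuole_center = vacuole_center,
         vacuole_radius = vacuole_radius, noise_sd = noise_sd, seed = seed),
    class = "image_sim_config"
  )
}

#' Simulate a fluorescence micrograph with known segmentation truth
#'
#' @param cfg An [image_sim_config()].
#' @return A list with `image` (numeric matrix) and `truth` (a
#'   `segmentation_result`: the exact generating masks, midpoint thresholds,
#'   and four corner background regions).
#' @export
simulate_ion_image <- function(cfg = image_sim_config()) {
  stopifnot(inherits(cfg, "image_sim_config"))
  r <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  cc <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  in_cell <- ((r - cfg$cell_center[1]) / cfg$cell_semiaxes[1])^2 +
    ((cc - cfg$cell_center[2]) / cfg$cell_semiaxes[2])^2 <= 1
  in_vac <- (r - cfg$vacuole_center[1])^2 + (cc - cfg$vacuole_center[2])^2 <=
    cfg$vacuole_radius^2
  # geometry checks: cell inside frame, vacuole strictly inside the cell
  ok_frame <- cfg$cell_center[1] - cfg$cell_semiaxes[1] >= 1 &&
    cfg$cell_center[1] + cfg$cell_semiaxes[1] <= cfg$height &&
    cfg$cell_center[2] - cfg$cell_semiaxes[2] >= 1 &&
    cfg$cell_center[2] + cfg$cell_semiaxes[2] <= cfg$width
  if (!ok_frame) stop("cell ellipse does not fit inside the frame", call. = FALSE)
  if (any(in_vac & !in_cell)) {
    stop("vacuole must lie entirely inside the cell", call. = FALSE)
  }
  img <- matrix(cfg$background_level, cfg$height, cfg$width)
  img[in_cell] <- cfg$cytoplasm_level
  img[in_vac] <- cfg$vacuole_level
  if (cfg$noise_sd > 0) {
    img <- with_sim_seed(cfg$seed, {
      img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd), nrow(img))
    })
    img[img < 0] <- 0
  }
  masks <- list(background = !in_cell, cytoplasm = in_cell & !in_vac, vacuole = in_vac)
  thresholds <- c(
    t_low = (cfg$background_level + cfg$cytoplasm_level) / 2,
    t_high = (cfg$cytoplasm_level + cfg$vacuole_level) / 2
  )
  truth <- new_segmentation(masks, thresholds,
                            corner_regions(cfg$height, cfg$width))
  list(image = img, truth = truth)
}

#' Configuration for synthetic Michaelis-Menten rate series
#'
#' Defaults are the substrate design used throughout this package's
#' validation work: 8 substrate levels spanning 0.2-20 x K_m (geometric),
#' triplicate measurements, and a 2% multiplicative coefficient of variation
#' on rates.
#'
#' @param true_Km Generating Michaelis constant, mM (> 0).
#' @param true_Vmax Generating maximal specific activity, U mg^-1 (> 0).
#' @param substrate_concs Substrate concentrations in mM; default 8 levels
#'   from 0.2 to 20 times `true_Km`.
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param replicates Replicates per substrate level (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(true_Km, true_Vmax,
                                substrate_concs = NULL,
                                noise_cv = 0.02, replicates = 3, seed = NULL) {
  if (true_Km <= 0 || true_Vmax <= 0) stop("true_Km and true_Vmax must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  substrate_concs <- substrate_concs %||%
    exp(seq(log(0.2 * true_Km), log(20 * true_Km), length.out = 8))
  if (any(substrate_concs <= 0)) stop("substrate_concs must be > 0", call. = FALSE)
  structure(
    list(true_Km = true_Km, true_Vmax = true_Vmax,
         substrate_concs = substrate_concs, noise_cv = noise_cv,
         replicates = as.integer(replicates), seed = seed),
    class = "kinetics_sim_config"
  )
}

#' Simulate enzyme rate measurements
#'
#' Rates follow v = Vmax * S / (Km + S) * (1 + e), e ~ Normal(0, noise_cv),
#' floored at 0.
#'
#' @param cfg A [kinetics_sim_config()].
#' @param condition,enzyme Labels carried into the output.
#' @return A tibble with columns `substrate_mM`, `replicate`,
#'   `rate_U_per_mg`, `condition`, `enzyme`.
#' @export
simulate_rate_data <- function(cfg, condition = "sim", enzyme = "sim") {
  stopifnot(inherits(cfg, "kinetics_sim_config"))
  s <- rep(cfg$substrate_concs, each = cfg$replicates)
  v0 <- cfg$true_Vmax * s / (cfg$true_Km + s)
  eps <- if (cfg$noise_cv > 0) {
    with_sim_seed(cfg$seed, stats::rnorm(length(s), 0, cfg$noise_cv))
  } else {
    numeric(length(s))
  }
  tibble::tibble(
    substrate_mM = s,
    replicate = rep(seq_len(cfg$replicates), times = length(cfg$substrate_concs)),
    rate_U_per_mg = pmax(v0 * (1 + eps), 0),
    condition = condition,
    enzyme = enzyme
  )
}

#' Configuration for synthetic growth-experiment counts
#'
#' Emulates an osmolyte-feeding experiment: cultures started at a common
#' density, counted after incubation, a control arm and one arm per supplied
#' osmolyte. Defaults reproduce the published endpoint design: triplicate
#' counts, control mean 280 cells/ml, treatment means 983 (GB), 1380 (Ect)
#' and 3247 (Ch) cells/ml. The single `sd_fraction` is a simplification: the
#' published arms had very unequal dispersions (CVs from 0.03 to 0.65); 0.3
#' is a mid-range stand-in.
#'
#' @param control_mean Control arm mean, cells/ml.
#' @param treatment_means Named vector, treatment -> mean cells/ml.
#' @param sd_fraction Replicate sd as a fraction of the arm mean (>= 0).
#' @param n_replicates Replicates per arm (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(control_mean = 280,
                              treatment_means = c(GB = 983, Ect = 1380, Ch = 3247),
                              sd_fraction = 0.3, n_replicates = 3, seed = NULL) {
  if (control_mean < 0 || any(treatment_means < 0)) {
    stop("means must be >= 0", call. = FALSE)
  }
  if (sd_fraction < 0) stop("sd_fraction must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(
    list(control_mean = control_mean, treatment_means = treatment_means,
         sd_fraction = sd_fraction, n_replicates = as.integer(n_replicates),
         seed = seed),
    class = "growth_sim_config"
  )
}

#' Simulate per-replicate cell counts
#'
#' @param cfg A [growth_sim_config()].
#' @return A tibble with columns `treatment`, `replicate`, `cells_per_ml`
#'   (truncated at 0); the control arm is labelled `"control"`.
#' @export
simulate_growth <- function(cfg = growth_sim_config()) {
  stopifnot(inherits(cfg, "growth_sim_config"))
  means <- c(control = unname(cfg$control_mean), cfg$treatment_means)
  n <- cfg$n_replicates
  counts <- with_sim_seed(cfg$seed, {
    unlist(lapply(means, function(m) {
      if (cfg$sd_fraction == 0) rep(m, n) else stats::rnorm(n, m, cfg$sd_fraction * m)
    }))
  })
  tibble::tibble(
    treatment = rep(names(means), each = n),
    replicate = rep(seq_len(n), times = length(means)),
    cells_per_ml = pmax(counts, 0)
  )
}
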