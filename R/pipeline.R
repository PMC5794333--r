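#' Run a configured analysis pipeline
#'
#' Executes a list of stages (simulation, quantification, summaries) in
#' order, writing every output as CSV or plain-text under a run directory
#' and recording parameters, package version and a seed in
#' `run_record.json`. Stage outputs are deterministic under a fixed seed,
#' so a record plus the package version suffices to re-create a run
#' bit-identically.
#'
#' The configuration is a YAML file or an equivalent list with fields:
#' \describe{
#'   \item{seed}{integer, required; seeds every stochastic stage.}
#'   \item{out_dir}{required; created if absent. An existing directory is
#'     never overwritten -- a numeric suffix is appended instead.}
#'   \item{stages}{list; each element has a `stage` field naming one of
#'     `simulate_spectrum`, `simulate_labeled_spectrum`, `simulate_image`,
#'     `simulate_rates`, `simulate_growth`, `quantify_nmr`, `fit_kinetics`,
#'     `demo_salinity_gradient`, plus stage parameters.}
#' }
#'
#' @param config Path to a YAML config or a list.
#' @return A run record (list) with the echoed config, the resolved output
#'   directory and one entry per stage listing the files it wrote.
#' @export
run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  out_dir <- fresh_dir(config$out_dir)
  record <- list(
    config = config,
    package_version = as.character(utils::packageVersion("osmoquant")),
    out_dir = out_dir,
    stages = list()
  )
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    seed <- (config$seed + i) %% .Machine$integer.max
    files <- run_stage(st, seed, out_dir)
    record$stages[[i]] <- list(stage = st$stage, seed = seed, files = files)
  }
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(record)
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  for (f in c("seed", "out_dir", "stages")) {
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'", call. = FALSE)
  }
  if (!is.numeric(config$seed)) stop("config seed must be an integer", call. = FALSE)
  known <- c("simulate_spectrum", "simulate_labeled_spectrum", "simulate_image",
             "simulate_rates", "simulate_growth", "quantify_nmr",
             "fit_kinetics", "demo_salinity_gradient")
  for (st in config$stages) {
    if (is.null(st$stage) || !st$stage %in% known) {
      stop("unknown stage '", st$stage %||% "<missing>", "'; known: ",
           paste(known, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

fresh_dir <- function(base) {
  dir <- base
  k <- 1
  while (dir.exists(dir)) {
    dir <- paste0(base, "-", k)
    k <- k + 1
  }
  dir.create(dir, recursive = TRUE)
  dir
}

run_stage <- function(st, seed, out_dir) {
  name <- st$name %||% st$stage
  path <- function(ext) file.path(out_dir, paste0(name, ext))
  switch(st$stage,
    simulate_spectrum = {
      cfg <- do.call(spectrum_sim_config, c(st$cfg %||% list(), list(seed = seed)))
      spec <- simulate_spectrum(unlist(st$concentrations),
                                standard_conc = st$standard_conc %||% 0.5,
                                cfg = cfg)
      write_spectrum_txt(spec, path(".txt"))
      path(".txt")
    },
    simulate_labeled_spectrum = {
      cfg <- do.call(spectrum_sim_config, c(st$cfg %||% list(), list(seed = seed)))
      spec <- simulate_labeled_spectrum(
        unlabeled_gb = st$unlabeled_gb, labeled_gb = st$labeled_gb,
        other = unlist(st$other %||% list()), cfg = cfg,
        j_hz = st$j_hz %||% 144, standard_conc = st$standard_conc %||% 0.5
      )
      write_spectrum_txt(spec, path(".txt"))
      path(".txt")
    },
    simulate_image = {
      cfg <- do.call(image_sim_config, c(st$cfg %||% list(), list(seed = seed)))
      sim <- simulate_ion_image(cfg)
      write_image(sim$image, path(".pgm"))
      path(".pgm")
    },
    simulate_rates = {
      cfg <- kinetics_sim_config(
        true_Km = st$true_Km, true_Vmax = st$true_Vmax,
        substrate_concs = st$substrate_concs %||% NULL,
        noise_cv = st$noise_cv %||% 0.02,
        replicates = st$replicates %||% 3, seed = seed
      )
      readr::write_csv(simulate_rate_data(cfg, condition = st$condition %||% "sim"),
                       path(".csv"))
      path(".csv")
    },
    simulate_growth = {
      cfg <- do.call(growth_sim_config, c(st$cfg %||% list(), list(seed = seed)))
      readr::write_csv(simulate_growth(cfg), path(".csv"))
      path(".csv")
    },
    quantify_nmr = {
      spec <- read_spectrum_txt(st$spectrum)
      q <- quantify(spec,
                    standard = internal_standard(concentration = st$standard_mol_l %||% 0.5),
                    window = st$window %||% 0.01)
      if (!is.null(st$n_cells)) {
        q$intracellular_mol_l <- intracellular_concentration(
          q$tube_conc_mol_l, st$sample_volume_l %||% 600e-6,
          st$n_cells, st$cell_volume_pl %||% 8.01
        )
      }
      readr::write_csv(q, path(".csv"))
      path(".csv")
    },
    fit_kinetics = {
      d <- readr::read_csv(st$rates, show_col_types = FALSE)
      fits <- purrr::map_dfr(split(d, d$condition), function(dd) glance(fit_mm(dd)))
      readr::write_csv(fits, path(".csv"))
      path(".csv")
    },
    demo_salinity_gradient = {
      demo <- demo_salinity_gradient(seed = seed,
                                     n_replicates = st$n_replicates %||% 6,
                                     noise_sd = st$noise_sd %||% 0)
      readr::write_csv(demo$means, path("-means.csv"))
      readr::write_csv(demo$regression, path("-regression.csv"))
      c(path("-means.csv"), path("-regression.csv"))
    }
  )
}

#' Published per-salinity mean intracellular osmolyte concentrations
#'
#' The five salinities at which mean intracellular concentrations of both
#' glycine betaine and ectoine were reported, with the NaCl molarity
#' conversion. These serve as generating ground truth for the salinity
#' gradient demonstration.
#'
#' @return A tibble: `salinity_pct`, `nacl_mol_l`, `gb_mol_l`, `ect_mol_l`.
#' @export
salinity_gradient_means <- function() {
  tibble::tibble(
    salinity_pct = c(5, 11, 13, 19, 21),
    nacl_mol_l = round(salinity_to_molarity(c(5, 11, 13, 19, 21)), 2),
    gb_mol_l = c(0.35, 0.85, 1.23, 1.94, 6.35),
    ect_mol_l = c(0.09, 0.23, 0.45, 0.64, 2.0)
  )
}

#' Desk-scale salinity gradient demonstration
#'
#' Re-enacts the osmolyte/salinity experiment end to end on synthetic data:
#' spectra are simulated with generating intracellular GB and Ect
#' concentrations equal to the published per-salinity means (scaled into
#' tube concentrations through the cell count, sample volume and mean cell
#' volume), quantified against the internal standard, scaled back to
#' intracellular molarity, and regressed against external NaCl molarity.
#' The regression, like the published one, uses per-salinity means and
#' excludes the highest salinity (beyond 3.25 mol/l NaCl the response
#' leaves the linear regime).
#'
#' @param seed Integer seed.
#' @param n_replicates Simulated culture replicates per salinity.
#' @param noise_sd Spectral noise sd (0 = noise-free).
#' @param conc_sd_fraction Between-replicate variation of the generating
#'   concentrations as a fraction of the mean (0 = all replicates at the
#'   mean).
#' @param n_cells Cells per sample.
#' @param sample_volume_l Tube volume, litres.
#' @param cell_volume_pl Mean cell volume, pl.
#' @param n_points Spectrum grid size.
#' @return A list with `per_replicate`, `means` (recovered vs generating),
#'   and `regression` (one row per response: GB, Ect, total).
#' @export
demo_salinity_gradient <- function(seed = 1, n_replicates = 6, noise_sd = 0,
                                   conc_sd_fraction = 0, n_cells = 5e4,
                                   sample_volume_l = 600e-6,
                                   cell_volume_pl = 8.01, n_points = 32768) {
  grid <- salinity_gradient_means()
  scale_to_tube <- n_cells * cell_volume_pl * 1e-12 / sample_volume_l
  std <- internal_standard(concentration = 0.5)
  per_rep <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      rep_seed <- (seed * 997 + i * 101 + r) %% 2147483647
      gen <- c(GB = grid$gb_mol_l[i], Ect = grid$ect_mol_l[i])
      if (conc_sd_fraction > 0) {
        gen <- with_sim_seed(rep_seed + 7, {
          pmax(gen * (1 + stats::rnorm(2, 0, conc_sd_fraction)), 0)
        })
      }
      cfg <- spectrum_sim_config(n_points = n_points, noise_sd = noise_sd,
                                 seed = rep_seed)
      spec <- simulate_spectrum(gen * scale_to_tube, standard_conc = std$concentration,
                                cfg = cfg)
      q <- quantify(spec, standard = std)
      q <- q[q$solute %in% c("GB", "Ect"), ]
      tibble::tibble(
        salinity_pct = grid$salinity_pct[i],
        nacl_mol_l = grid$nacl_mol_l[i],
        replicate = r,
        solute = q$solute,
        generating_mol_l = unname(gen[q$solute]),
        recovered_mol_l = intracellular_concentration(
          q$tube_conc_mol_l, sample_volume_l, n_cells, cell_volume_pl
        )
      )
    })
  })
  means <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$salinity_pct, .data$nacl_mol_l, .data$solute),
    generating_mol_l = mean(.data$generating_mol_l),
    recovered_mol_l = mean(.data$recovered_mol_l),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "solute",
                             values_from = c("generating_mol_l", "recovered_mol_l"))
  lin <- dplyr::filter(wide, .data$nacl_mol_l <= 3.25)
  regression <- dplyr::bind_rows(
    dplyr::mutate(linear_fit(lin$nacl_mol_l, lin$recovered_mol_l_GB), response = "GB"),
    dplyr::mutate(linear_fit(lin$nacl_mol_l, lin$recovered_mol_l_Ect), response = "Ect"),
    dplyr::mutate(linear_fit(lin$nacl_mol_l,
                             lin$recovered_mol_l_GB + lin$recovered_mol_l_Ect),
                  response = "total")
  )
  list(per_replicate = per_rep, means = means, regression = regression)
}
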