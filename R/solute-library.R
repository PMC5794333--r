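#' Default compatible-solute reference library
#'
#' Peak tables for the solutes relevant to halophile osmolyte work: glycine
#' betaine (GB), ectoine (Ect), choline (Ch), and the internal standard TMSP
#' (trimethylsilylpropanoic acid, 0.0 ppm, nine equivalent protons). One peak
#' per solute carries the `quant` flag and is the one used for molar
#' quantification; the others serve identification (a solute counts as
#' identified only when every one of its reference peaks is matched).
#'
#' Published shift tables for ectoine's methyl resonance differ between
#' sources (2.25 vs 2.44 ppm, both in D2O); the library carries both and the
#' `ect_quant` argument selects which carries the quantification flag.
#'
#' The `c13_split` column marks peaks whose protons sit on the carbons that
#' are 13C in the 1,2-13C2 isotopologue of GB, i.e. the peaks that turn into
#' one-bond J-split satellite doublets in labelled material.
#'
#' @param ect_quant Which ectoine methyl shift quantifies: `"2.25"`
#'   (default) or `"2.44"`.
#' @return A tibble with columns `solute`, `shift` (ppm), `multiplicity`,
#'   `j_hz`, `n_protons`, `quant`, `c13_split`, `label`.
#' @examples
#' solute_library()
#' @export
solute_library <- function(ect_quant = c("2.25", "2.44")) {
  ect_quant <- match.arg(ect_quant)
  lib <- tibble::tribble(
    ~solute, ~shift, ~multiplicity, ~j_hz, ~n_protons, ~quant, ~c13_split, ~label,
    "GB",    3.91,  "singlet", NA_real_, 2, FALSE, TRUE,  "-CH2-",
    "GB",    3.27,  "singlet", NA_real_, 9, TRUE,  TRUE,  "-N+(CH3)3",
    "Ect",   4.01,  "singlet", NA_real_, 1, FALSE, FALSE, "-CH",
    "Ect",   3.44,  "singlet", NA_real_, 2, FALSE, FALSE, "-CH2-ND",
    "Ect",   3.29,  "singlet", NA_real_, 2, FALSE, FALSE, "-CH2-ND",
    "Ect",   2.44,  "singlet", NA_real_, 3, FALSE, FALSE, "-CH3 (alt)",
    "Ect",   2.25,  "singlet", NA_real_, 3, TRUE,  FALSE, "-CH3",
    "Ect",   2.12,  "singlet", NA_real_, 2, FALSE, FALSE, "-CH2-CH",
    "Ch",    4.07,  "singlet", NA_real_, 2, FALSE, FALSE, "-CH2-OH",
    "Ch",    3.52,  "singlet", NA_real_, 2, FALSE, FALSE, "-CH2-N",
    "Ch",    3.19,  "singlet", NA_real_, 9, TRUE,  FALSE, "-N+(CH3)3",
    "TMSP",  0.00,  "singlet", NA_real_, 9, TRUE,  FALSE, "-Si(CH3)3"
  )
  if (ect_quant == "2.44") {
    lib$quant[lib$solute == "Ect"] <- lib$shift[lib$solute == "Ect"] == 2.44
  }
  validate_library(lib)
}

#' Validate a solute reference library
#'
#' @param lib A data frame shaped like [solute_library()]. `multiplicity`
#'   may be a name (`"singlet"`, `"doublet"`, ...) or a line count.
#' @return The library as a validated tibble (invisibly usable downstream).
#' @export
validate_library <- function(lib) {
  lib <- tibble::as_tibble(lib)
  needed <- c("solute", "shift", "n_protons", "quant")
  missing <- setdiff(needed, names(lib))
  if (length(missing)) {
    stop("library lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"multiplicity" %in% names(lib)) lib$multiplicity <- "singlet"
  if (!"j_hz" %in% names(lib)) lib$j_hz <- NA_real_
  if (!"c13_split" %in% names(lib)) lib$c13_split <- FALSE
  if (any(lib$n_protons < 1)) stop("n_protons must be >= 1", call. = FALSE)
  if (any(lib$shift < -1 | lib$shift > 12)) {
    stop("shifts must lie within the proton window (-1 to 12 ppm)", call. = FALSE)
  }
  nq <- tapply(lib$quant, lib$solute, sum)
  if (any(nq != 1)) {
    stop(
      "each solute needs exactly one quantification peak; offending: ",
      paste(names(nq)[nq != 1], collapse = ", "),
      call. = FALSE
    )
  }
  lib
}

#' Read and write a solute library as YAML
#'
#' The YAML layout is one mapping per solute, each with a `peaks` list of
#' `{shift, multiplicity, n_protons, quant, c13_split, label}` entries.
#'
#' @param path File path.
#' @return [read_library_yaml()] returns a validated library tibble.
#' @export
read_library_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(names(raw), function(nm) {
    purrr::map_dfr(raw[[nm]]$peaks, function(p) {
      tibble::tibble(
        solute = nm,
        shift = as.numeric(p$shift),
        multiplicity = p$multiplicity %||% "singlet",
        j_hz = as.numeric(p$j_hz %||% NA),
        n_protons = as.integer(p$n_protons),
        quant = isTRUE(p$quant),
        c13_split = isTRUE(p$c13_split),
        label = p$label %||% NA_character_
      )
    })
  })
  validate_library(rows)
}

#' @rdname read_library_yaml
#' @param lib A library tibble.
#' @export
write_library_yaml <- function(lib, path) {
  lib <- validate_library(lib)
  out <- lapply(split(lib, lib$solute), function(d) {
    list(peaks = lapply(seq_len(nrow(d)), function(i) {
      p <- list(
        shift = d$shift[i],
        multiplicity = d$multiplicity[i],
        n_protons = d$n_protons[i],
        quant = d$quant[i],
        c13_split = d$c13_split[i]
      )
      if (!is.na(d$j_hz[i])) p$j_hz <- d$j_hz[i]
      if (!is.na(d$label[i])) p$label <- d$label[i]
      p
    }))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Internal standard specification
#'
#' The internal standard underpins all molar results: solute concentration is
#' peak area relative to the standard's, corrected for proton counts, times
#' the standard's known concentration.
#'
#' @param name Solute name in the library (default `"TMSP"`).
#' @param shift Chemical shift in ppm (default 0.0).
#' @param n_protons Equivalent protons under the reference peak (default 9).
#' @param concentration Standard concentration in the tube, mol/l. The
#'   default 0.5 matches a 500 mM spiking protocol.
#' @return A list of class `internal_standard`.
#' @export
internal_standard <- function(name = "TMSP", shift = 0.0, n_protons = 9,
                              concentration = 0.5) {
  if (concentration <= 0) stop("standard concentration must be > 0", call. = FALSE)
  structure(
    list(name = name, shift = shift, n_protons = n_protons,
         concentration = concentration),
    class = "internal_standard"
  )
}

# number of multiplet lines for a named or numeric multiplicity
multiplicity_lines <- function(m) {
  if (is.numeric(m)) return(as.integer(m))
  key <- c(singlet = 1L, doublet = 2L, triplet = 3L, quartet = 4L,
           quintet = 5L, sextet = 6L, septet = 7L)
  out <- key[tolower(as.character(m))]
  if (any(is.na(out))) {
    stop("unknown multiplicity: ", paste(unique(m[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
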