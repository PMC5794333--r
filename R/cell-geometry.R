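#' Cell volume from the cylinder-plus-two-cones model
#'
#' Spindle-shaped ciliate cells are approximated as a cylinder of the
#' measured width and length plus two cones, each with the same base and the
#' full average length as height:
#' \deqn{V_{cyl} = \pi (w/2)^2 L, \qquad V_{2cones} = 2 \cdot \tfrac{1}{3}\pi (w/2)^2 L}
#' and the total is their sum, reported in picolitres (1000 um^3 = 1 pl).
#' The formulas are applied verbatim as published for this organism; note
#' the algebraic consequence total = 5/3 x cylinder volume. Height, though
#' measurable, does not enter the model.
#'
#' @param width_um Cell width in micrometres (>= 0). Vectorised.
#' @param length_um Cell length in micrometres (>= 0). Vectorised.
#' @return A tibble with columns `width_um`, `length_um`, `v_cylinder_um3`,
#'   `v_2cones_um3`, `total_pl`.
#' @examples
#' cell_volume(10, 50) # 6.545 pl
#' @export
cell_volume <- function(width_um, length_um) {
  if (any(width_um < 0) || any(length_um < 0)) {
    stop("cell dimensions must be >= 0", call. = FALSE)
  }
  v_cyl <- pi * (width_um / 2)^2 * length_um
  v_cones <- 2 * (pi * (width_um / 2)^2 * length_um / 3)
  tibble::tibble(
    width_um = width_um, length_um = length_um,
    v_cylinder_um3 = v_cyl, v_2cones_um3 = v_cones,
    total_pl = (v_cyl + v_cones) / 1000
  )
}

#' Convert salinity (% w/v NaCl) to molarity
#'
#' Percent weight-per-volume means grams per 100 ml, so `percent * 10` g/l,
#' divided by the molar mass of NaCl (58.44 g/mol).
#'
#' @param percent_wv Salinity in % w/v (>= 0). Vectorised.
#' @return NaCl concentration in mol/l.
#' @examples
#' salinity_to_molarity(21) # 3.59 at two decimals
#' @export
salinity_to_molarity <- function(percent_wv) {
  if (any(percent_wv < 0)) stop("salinity must be >= 0", call. = FALSE)
  percent_wv * 10 / 58.44
}
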