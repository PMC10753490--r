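#' Load the packaged allometric coefficient sets
#'
#' One power-law coefficient set per physiological equation: basal metabolic
#' rate from mass for seabirds and for ducks, lower critical temperature (LCT)
#' from mass, and thermal conductance from mass in each of three media
#' (fully submerged, sitting on water, in air). Each set records the mass unit
#' its equation expects; the public interface always takes grams and converts
#' internally.
#'
#' @return Data frame with columns `equation_id`, `quantity`, `a`, `b`,
#'   `mass_unit`, `output_unit`, `provenance`, `source_note`. Each equation is
#'   `a * mass^b` with mass in `mass_unit`.
#' @export
load_allometric_coefficients <- function() {
  co <- read_teb_csv("allometry_coefficients.csv")
  need <- c("bmr_seabird", "bmr_duck", "lct",
            "tc_in_water", "tc_on_water", "tc_air")
  if (!all(need %in% co$equation_id)) {
    stop("allometry coefficient file is incomplete; missing: ",
         paste(setdiff(need, co$equation_id), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(co$a)) || any(!is.finite(co$b))) {
    stop("allometry coefficients must be finite", call. = FALSE)
  }
  co
}

# evaluate one packaged power law at a mass given in grams
eval_allometry <- function(equation_id, mass_g, coefficients) {
  row <- coefficients[coefficients$equation_id == equation_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown or duplicated equation id '", equation_id, "'", call. = FALSE)
  }
  m <- switch(row$mass_unit,
    g = mass_g,
    kg = mass_g / 1000,
    stop("unsupported mass unit '", row$mass_unit, "'", call. = FALSE)
  )
  row$a * m^row$b
}

check_mass <- function(mass_g) {
  if (!is.numeric(mass_g) || any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("body mass must be a positive, finite number of grams", call. = FALSE)
  }
  if (any(mass_g < 20 | mass_g > 15000)) {
    warning("mass outside the ~20 g to 15 kg span of marine birds; ",
            "allometric estimates are extrapolations", call. = FALSE)
  }
  invisible(mass_g)
}

#' Basal metabolic rate from body mass
#'
#' Allometric BMR in kJ h^-1. Two published relationships are packaged, one
#' fitted to seabirds and one to wild ducks; the default returns their
#' arithmetic mean, which spans the marine bird clades (seabirds, sea ducks,
#' divers, grebes) the framework covers.
#'
#' @param mass_g Body mass in grams (> 0; a warning is issued outside
#'   20--15000 g).
#' @param method `"mean"` (default), `"seabird"` or `"duck"`.
#' @param coefficients Packaged coefficient table, see
#'   [load_allometric_coefficients()].
#' @return BMR in kJ h^-1.
#' @export
#' @examples
#' bmr_from_mass(5000)
#' bmr_from_mass(5000, method = "seabird")
bmr_from_mass <- function(mass_g, method = c("mean", "seabird", "duck"),
                          coefficients = load_allometric_coefficients()) {
  method <- match.arg(method)
  check_mass(mass_g)
  seabird <- function() eval_allometry("bmr_seabird", mass_g, coefficients) / 24
  duck <- function() eval_allometry("bmr_duck", mass_g, coefficients) / 24
  switch(method,
    seabird = seabird(),
    duck = duck(),
    mean = (seabird() + duck()) / 2
  )
}

#' Lower critical temperature from body mass
#'
#' The ambient temperature below which an endotherm pays an extra
#' thermoregulatory cost. Larger birds have lower LCTs (negative allometric
#' exponent).
#'
#' @inheritParams bmr_from_mass
#' @return LCT in degrees Celsius.
#' @export
#' @examples
#' lct_from_mass(5000)
lct_from_mass <- function(mass_g,
                          coefficients = load_allometric_coefficients()) {
  check_mass(mass_g)
  eval_allometry("lct", mass_g, coefficients)
}

#' Thermal conductance from body mass
#'
#' Per-kilogram thermal conductance (kJ h^-1 degC^-1 kg^-1) in one of three
#' media: fully submerged in water (`"in_water"`), sitting on the water surface
#' (`"on_water"`) or in air (`"air"`). Water conducts heat much faster than
#' air, so for a given mass `in_water > on_water > air`.
#'
#' @inheritParams bmr_from_mass
#' @param medium `"in_water"`, `"on_water"` or `"air"`.
#' @return Conductance in kJ h^-1 degC^-1 kg^-1.
#' @export
#' @examples
#' thermal_conductance(5000, "in_water")
thermal_conductance <- function(mass_g, medium = c("in_water", "on_water", "air"),
                                coefficients = load_allometric_coefficients()) {
  medium <- match.arg(medium)
  check_mass(mass_g)
  eval_allometry(paste0("tc_", medium), mass_g, coefficients)
}

#' Mass-derived physiology profile for one bird
#'
#' Bundles the allometric quantities one day of energy budgeting needs: BMR
#' (kJ h^-1), lower critical temperature (degC) and the three medium-specific
#' thermal conductances. An empirical BMR, where one is available for the
#' species, can be supplied via `bmr_override` and replaces the allometric
#' estimate (the profile records which was used).
#'
#' @inheritParams bmr_from_mass
#' @param bmr_method Method passed to [bmr_from_mass()].
#' @param bmr_override Optional empirical BMR in kJ h^-1 (> 0).
#' @return Object of class `physiology_profile`: list with `mass_g`,
#'   `mass_kg`, `bmr_kj_per_h`, `bmr_source`, `lct_c` and `tc` (named list
#'   `in_water`, `on_water`, `air`).
#' @export
#' @examples
#' physiology_profile(5000)
physiology_profile <- function(mass_g,
                               coefficients = load_allometric_coefficients(),
                               bmr_method = "mean", bmr_override = NULL) {
  check_mass(mass_g)
  if (!is.null(bmr_override)) {
    if (!is.numeric(bmr_override) || length(bmr_override) != 1L ||
        !is.finite(bmr_override) || bmr_override <= 0) {
      stop("bmr_override must be a single positive kJ h^-1 value", call. = FALSE)
    }
    bmr <- bmr_override
    src <- "override"
  } else {
    bmr <- bmr_from_mass(mass_g, bmr_method, coefficients)
    src <- paste0("allometric (", bmr_method, ")")
  }
  structure(
    list(
      mass_g = mass_g,
      mass_kg = mass_g / 1000,
      bmr_kj_per_h = bmr,
      bmr_source = src,
      lct_c = lct_from_mass(mass_g, coefficients),
      tc = list(
        in_water = thermal_conductance(mass_g, "in_water", coefficients),
        on_water = thermal_conductance(mass_g, "on_water", coefficients),
        air = thermal_conductance(mass_g, "air", coefficients)
      )
    ),
    class = "physiology_profile"
  )
}

#' @export
print.physiology_profile <- function(x, ...) {
  cat(sprintf("Physiology profile (%.0f g)\n", x$mass_g))
  cat(sprintf("  BMR: %.2f kJ/h [%s]\n", x$bmr_kj_per_h, x$bmr_source))
  cat(sprintf("  LCT: %.2f degC\n", x$lct_c))
  cat(sprintf("  TC (kJ/h/degC/kg): in water %.3f, on water %.3f, air %.3f\n",
              x$tc$in_water, x$tc$on_water, x$tc$air))
  invisible(x)
}
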