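#' Thermal medium occupied during an activity
#'
#' Maps an activity, given the performing guild, to the medium whose thermal
#' conductance governs heat loss:
#' * `flight` -> `none`: active flapping flight produces excess heat that is
#'   assumed to cover any thermoregulatory requirement, so no cost is charged;
#' * `on_land` -> `air`;
#' * `on_water` -> `on_water` (sitting at the surface);
#' * `forage` -> `in_water` for wing- and foot-propelled diving guilds (the
#'   whole body is submerged), otherwise `on_water` for surface-feeding and
#'   plunge-diving guilds (brief submersion only).
#'
#' @param activity One of [activity_kinds()].
#' @param guild One-row guild data frame, see [guild_of()].
#' @return One of `"in_water"`, `"on_water"`, `"air"`, `"none"`.
#' @export
#' @examples
#' medium_for_activity("forage", guild_of("Alcidae"))
#' medium_for_activity("flight", guild_of("Laridae"))
medium_for_activity <- function(activity, guild) {
  if (!activity %in% activity_kinds()) {
    stop("unknown activity '", activity, "'", call. = FALSE)
  }
  switch(activity,
    flight = "none",
    on_land = "air",
    on_water = "on_water",
    forage = if (grepl("diving", guild$foraging_style) &&
                 !grepl("plunge", guild$foraging_style)) "in_water" else "on_water"
  )
}

# which environmental temperature applies to a medium
temperature_for_medium <- function(medium, sst_c, air_c) {
  switch(medium,
    in_water = sst_c,
    on_water = sst_c,
    air = air_c,
    none = NA_real_,
    stop("unknown medium '", medium, "'", call. = FALSE)
  )
}

#' Thermoregulatory cost of time spent below the lower critical temperature
#'
#' When the environmental temperature is below the bird's lower critical
#' temperature (LCT), extra heat production is required at a rate set by the
#' medium's thermal conductance:
#' `cost_kJ = TC * mass_kg * (LCT - T_env) * hours`,
#' and zero at or above the LCT. The cost is linear in exposure time,
#' continuous at `T_env = LCT`, and grows as the temperature deficit grows.
#'
#' @param tc Thermal conductance, kJ h^-1 degC^-1 kg^-1 (> 0).
#' @param mass_kg Body mass in kilograms (> 0).
#' @param lct_c Lower critical temperature, degC.
#' @param t_env_c Environmental temperature of the occupied medium, degC.
#' @param hours Exposure time in hours (>= 0).
#' @return Cost in kJ (>= 0).
#' @export
#' @examples
#' thermoregulation_cost(2, 3, 10, 4, 5)   # 2*3*(10-4)*5 = 180 kJ
#' thermoregulation_cost(2, 3, 10, 12, 5)  # thermoneutral: 0
thermoregulation_cost <- function(tc, mass_kg, lct_c, t_env_c, hours) {
  if (!is.finite(tc) || tc <= 0) stop("tc must be > 0", call. = FALSE)
  if (!is.finite(mass_kg) || mass_kg <= 0) stop("mass_kg must be > 0", call. = FALSE)
  if (!is.finite(hours) || hours < 0) stop("hours must be >= 0", call. = FALSE)
  if (!is.finite(lct_c) || !is.finite(t_env_c)) {
    stop("temperatures must be finite", call. = FALSE)
  }
  deficit <- max(0, lct_c - t_env_c)
  tc * mass_kg * deficit * hours
}
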