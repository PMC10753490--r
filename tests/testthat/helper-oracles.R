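# Independent oracles used across tests. These re-derive results by different
# routes than the package code paths they check.

# brute-force daily energy: loop over fine time slices and accumulate each
# slice's activity and thermoregulatory cost separately
slice_oracle_dee <- function(hours, sst_c, air_c, multipliers, profile, guild,
                             slice_h = 0.1) {
  total <- 0
  for (a in names(hours)) {
    h <- hours[[a]]
    if (h <= 0) next
    n_full <- floor(h / slice_h)
    slices <- c(rep(slice_h, n_full), h - n_full * slice_h)
    medium <- medium_for_activity(a, guild)
    t_env <- switch(medium, in_water = sst_c, on_water = sst_c,
                    air = air_c, none = NA_real_)
    for (s in slices) {
      total <- total + s * profile$bmr_kj_per_h * multipliers[[a]]
      if (medium != "none" && t_env < profile$lct_c) {
        total <- total + profile$tc[[medium]] * profile$mass_kg *
          (profile$lct_c - t_env) * s
      }
    }
  }
  total
}

# NOAA-style spectral-declination day length, an independent astronomical
# formulation (sunrise equation with the standard 90.833 degree zenith)
noaa_day_length <- function(latitude_deg, day_of_year) {
  lat <- latitude_deg * pi / 180
  gamma <- 2 * pi / 365 * (day_of_year - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat) * cos(decl)) - tan(lat) * tan(decl)
  cos_ha <- min(1, max(-1, cos_ha))
  2 * acos(cos_ha) * 24 / (2 * pi)
}

random_simplex_budget <- function(guild) {
  acts <- performable_activities(guild)
  w <- stats::rexp(length(acts))
  hours <- stats::setNames(numeric(4), activity_kinds())
  hours[acts] <- 24 * w / sum(w)
  hours
}
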