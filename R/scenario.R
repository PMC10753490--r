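#' Hours of daylight from latitude and day of year
#'
#' Standard solar-declination day-length model (CBM model; revolution-angle
#' declination with a -23.44 degree obliquity and the usual 0.833 degree
#' sunrise/sunset depression for refraction), clamped to [0, 24] so polar day
#' and polar night are handled.
#'
#' @param latitude_deg Latitude in degrees, in [-90, 90].
#' @param day_of_year Integer day of a 365-day year, in [1, 365]; vectorised.
#' @return Daylight hours in [0, 24].
#' @export
#' @examples
#' day_length(63.3, 355)   # Arctic midwinter
#' day_length(0, 80)       # equator, ~12 h year-round
day_length <- function(latitude_deg, day_of_year) {
  if (!is.numeric(latitude_deg) || !is.finite(latitude_deg) ||
      latitude_deg < -90 || latitude_deg > 90) {
    stop("latitude must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1 | day_of_year > 365)) {
    stop("day_of_year must lie in [1, 365]", call. = FALSE)
  }
  # revolution angle and solar declination (radians)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  decl <- asin(0.39795 * cos(theta))
  lat <- latitude_deg * pi / 180
  p <- 0.8333 * pi / 180
  cos_h <- (sin(p) + sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 - (24 / pi) * acos(cos_h)
}

#' Synthetic daily temperatures from an annual sinusoid
#'
#' Generates sea-surface and air temperature for given days at one location:
#' `mean + amplitude * cos(2*pi*(day - phase_day)/365)` plus Gaussian noise of
#' standard deviation `noise_sd_c`. Noise is drawn from R's current RNG stream,
#' so results are deterministic once a seed is set.
#'
#' @param climate Named list with `sst_mean_c`, `sst_amplitude_c`,
#'   `sst_phase_day`, `air_mean_c`, `air_amplitude_c`, `air_phase_day`,
#'   `noise_sd_c` (as in the shipped scenario configs' `locations` entries).
#' @param day_of_year Integer vector of days in [1, 365].
#' @return Data frame with columns `day_of_year`, `sst_c`, `air_c`.
#' @export
#' @examples
#' set.seed(1)
#' head(synth_temperature(list(sst_mean_c = 6.5, sst_amplitude_c = 3.5,
#'   sst_phase_day = 233, air_mean_c = 4.5, air_amplitude_c = 6,
#'   air_phase_day = 212, noise_sd_c = 0.4), 1:5))
synth_temperature <- function(climate, day_of_year) {
  need <- c("sst_mean_c", "sst_amplitude_c", "sst_phase_day",
            "air_mean_c", "air_amplitude_c", "air_phase_day", "noise_sd_c")
  if (!all(need %in% names(climate))) {
    stop("climate is missing fields: ",
         paste(setdiff(need, names(climate)), collapse = ", "), call. = FALSE)
  }
  if (climate$sst_amplitude_c < 0 || climate$air_amplitude_c < 0 ||
      climate$noise_sd_c < 0) {
    stop("amplitudes and noise SD must be >= 0", call. = FALSE)
  }
  n <- length(day_of_year)
  sst <- climate$sst_mean_c +
    climate$sst_amplitude_c * cos(2 * pi * (day_of_year - climate$sst_phase_day) / 365) +
    stats::rnorm(n, 0, climate$noise_sd_c)
  air <- climate$air_mean_c +
    climate$air_amplitude_c * cos(2 * pi * (day_of_year - climate$air_phase_day) / 365) +
    stats::rnorm(n, 0, climate$noise_sd_c)
  data.frame(day_of_year = day_of_year, sst_c = sst, air_c = air)
}

scenario_config_fields <- function() {
  c("scenario", "description", "mass_g", "bmr_method", "multiplier_family",
    "assimilation_efficiency", "prey_energy_kj", "breeding_window",
    "breeding_budget", "forage_target_h", "night_rule", "jitter_sd_h",
    "migration", "travel_budget", "locations", "multiplier_overrides")
}

#' Load a great auk scenario configuration
#'
#' Reads one of the shipped YAML configurations (`greatauk_A.yaml`,
#' `greatauk_B.yaml`, `greatauk_C.yaml`) or a user-supplied file with the same
#' schema, and validates it. Scenario A is a year-round resident that returns
#' to land at night; B is a resident that stays at sea at night outside
#' breeding; C swims to a southern (Moroccan-Atlantic) wintering ground for the
#' non-breeding season.
#'
#' @param scenario `"A"`, `"B"` or `"C"` (ignored when `path` is given).
#' @param path Optional path to a YAML file overriding the shipped config.
#' @return Validated config list of class `scenario_config`.
#' @export
#' @examples
#' cfg <- load_scenario_config("A")
#' cfg$night_rule
load_scenario_config <- function(scenario = c("A", "B", "C"), path = NULL) {
  if (is.null(path)) {
    scenario <- match.arg(scenario)
    path <- teb_data_file(paste0("greatauk_", scenario, ".yaml"))
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), scenario_config_fields())
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  need <- c("scenario", "mass_g", "bmr_method", "multiplier_family",
            "assimilation_efficiency", "prey_energy_kj", "breeding_window",
            "breeding_budget", "forage_target_h", "night_rule", "locations")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys) > 0L) {
    stop("config is missing keys: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (!cfg$scenario %in% c("A", "B", "C")) {
    stop("scenario must be A, B or C", call. = FALSE)
  }
  if (!cfg$night_rule %in% c("on_land", "on_water")) {
    stop("night_rule must be 'on_land' or 'on_water'", call. = FALSE)
  }
  bw <- cfg$breeding_window
  if (!(bw$start_day >= 1 && bw$end_day <= 365 && bw$start_day < bw$end_day)) {
    stop("breeding window must lie within the year", call. = FALSE)
  }
  if (cfg$mass_g <= 0) stop("mass_g must be > 0", call. = FALSE)
  if (cfg$assimilation_efficiency <= 0 || cfg$assimilation_efficiency > 1) {
    stop("assimilation_efficiency must lie in (0, 1]", call. = FALSE)
  }
  bb <- cfg$breeding_budget
  if (any(unlist(bb) < 0) ||
      abs(sum(unlist(bb[c("forage_h", "on_water_h", "on_land_h")])) - 24) > 1e-6) {
    stop("breeding budget must be non-negative hours summing to 24", call. = FALSE)
  }
  if (!"colony" %in% names(cfg$locations)) {
    stop("config must define a 'colony' location", call. = FALSE)
  }
  if (cfg$scenario == "C") {
    if (is.null(cfg$migration) || is.null(cfg$travel_budget) ||
        !"wintering" %in% names(cfg$locations)) {
      stop("scenario C requires migration, travel_budget and a wintering location",
           call. = FALSE)
    }
    tb <- cfg$travel_budget
    if (abs(sum(unlist(tb)) - 24) > 1e-6 || any(unlist(tb) < 0)) {
      stop("travel budget must be non-negative hours summing to 24", call. = FALSE)
    }
  }
  if (is.null(cfg$jitter_sd_h)) cfg$jitter_sd_h <- 0
  if (!is.null(cfg$multiplier_overrides)) {
    mo <- cfg$multiplier_overrides
    if (!all(names(mo) %in% activity_kinds()) || any(unlist(mo) <= 0)) {
      stop("multiplier_overrides must map activity kinds to positive values",
           call. = FALSE)
    }
  }
  class(cfg) <- "scenario_config"
  cfg
}

# phase and migration position ("southness" s: 0 = colony, 1 = wintering ground)
day_phase <- function(day_of_year, config) {
  bw <- config$breeding_window
  if (day_of_year >= bw$start_day && day_of_year <= bw$end_day) {
    return(list(phase = "breeding", s = 0))
  }
  if (config$scenario == "C") {
    mig <- config$migration
    # days since departure on a 365-day circular timeline
    dsd <- (day_of_year - mig$depart_day) %% 365
    away_len <- ((mig$return_day - mig$depart_day) %% 365) + 1
    if (dsd < away_len) {
      if (dsd < mig$outbound_days) {
        return(list(phase = "travel", s = (dsd + 1) / mig$outbound_days))
      }
      if (dsd >= away_len - mig$inbound_days) {
        j <- dsd - (away_len - mig$inbound_days) + 1
        return(list(phase = "travel", s = 1 - j / mig$inbound_days))
      }
      return(list(phase = "nonbreeding", s = 1))
    }
  }
  list(phase = "nonbreeding", s = 0)
}

#' Build one day's activity budget under a migration scenario
#'
#' Applies the scenario's phase template. During breeding all scenarios use
#' the colony-attendance template. Outside breeding, a resident day allocates
#' up to `forage_target_h` of the daylight to foraging and assigns the night
#' (24 h minus daylight at the occupied latitude) to land (scenario A) or to
#' the water surface (scenarios B and C); remaining daylight is spent resting
#' on water. Scenario C uses the travel template on migration days. The great
#' auk is flightless, so flight hours are always zero. Optional Gaussian
#' jitter perturbs the performed activities and the budget is renormalised to
#' 24 h.
#'
#' @param day_of_year Day in [1, 365].
#' @param config A [load_scenario_config()] object.
#' @param jitter Optional named numeric of per-activity jitter offsets (h).
#' @return List with `hours` (named over [activity_kinds()]), `phase`
#'   (`breeding`/`nonbreeding`/`travel`), `s` (migration position: 0 colony,
#'   1 wintering ground) and `daylight_h`.
#' @export
build_daily_budget <- function(day_of_year, config, jitter = NULL) {
  ph <- day_phase(day_of_year, config)
  hours <- stats::setNames(numeric(4), activity_kinds())
  if (ph$phase == "breeding") {
    bb <- config$breeding_budget
    hours["forage"] <- bb$forage_h
    hours["on_water"] <- bb$on_water_h
    hours["on_land"] <- bb$on_land_h
    daylight <- day_length(config$locations$colony$latitude, day_of_year)
  } else if (ph$phase == "travel") {
    tb <- config$travel_budget
    hours["forage"] <- tb$forage_h
    hours["on_water"] <- tb$on_water_h
    lat <- (1 - ph$s) * config$locations$colony$latitude +
      ph$s * config$locations$wintering$latitude
    daylight <- day_length(lat, day_of_year)
  } else {
    lat <- if (ph$s == 1) config$locations$wintering$latitude else
      config$locations$colony$latitude
    daylight <- day_length(lat, day_of_year)
    night <- 24 - daylight
    hours["forage"] <- min(config$forage_target_h, daylight)
    if (config$night_rule == "on_land") {
      hours["on_land"] <- night
      hours["on_water"] <- daylight - hours["forage"]
    } else {
      hours["on_water"] <- 24 - hours["forage"]
    }
  }
  if (any(hours < 0)) {
    stop("scenario template produced negative hours on day ", day_of_year,
         call. = FALSE)
  }
  if (!is.null(jitter)) {
    performed <- names(hours)[hours > 0]
    hours[performed] <- pmax(0, hours[performed] + jitter[performed])
    if (sum(hours) <= 0) {
      stop("jitter annihilated the budget on day ", day_of_year, call. = FALSE)
    }
    hours <- hours * (24 / sum(hours))
  }
  list(hours = hours, phase = ph$phase, s = ph$s, daylight_h = daylight)
}

#' Simulate a great auk year under one migration scenario
#'
#' Runs 365 days of budget construction, synthetic climate and daily energy
#' accounting for one scenario. All randomness (temperature noise, optional
#' budget jitter) flows from `seed`, and the random draws are laid out so that
#' breeding-window days are identical across scenarios run with the same seed.
#'
#' @param scenario `"A"`, `"B"`, `"C"`, or a [load_scenario_config()] object.
#' @param seed Integer seed recorded in the result.
#' @return Object of class `auk_simulation`: list with `scenario`, `seed`,
#'   `config`, `config_hash`, `daily` (365-row data frame of budgets,
#'   temperatures and energy components) and `summaries`.
#' @export
#' @examples
#' sim <- simulate_year("A", seed = 1)
#' sim$summaries$breeding_intake_mean_kj
simulate_year <- function(scenario, seed = 1L) {
  config <- if (inherits(scenario, "scenario_config")) scenario else
    load_scenario_config(scenario)
  if (!is.numeric(seed) || !is.finite(seed)) stop("seed must be an integer",
                                                  call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)

  days <- 1:365
  # fixed draw order so same-seed runs share breeding-window randomness across
  # scenarios: jitter first, then colony climate, then (C only) wintering
  jitter_mat <- matrix(stats::rnorm(365 * 4, 0, config$jitter_sd_h),
                       nrow = 365, dimnames = list(NULL, activity_kinds()))
  colony <- synth_temperature(config$locations$colony, days)
  wintering <- if ("wintering" %in% names(config$locations)) {
    synth_temperature(config$locations$wintering, days)
  } else NULL

  n <- length(days)
  profile <- physiology_profile(config$mass_g, bmr_method = config$bmr_method)
  table <- load_multiplier_table()
  mult <- resolve_multipliers(config$multiplier_family, table)
  guild <- guild_of(config$multiplier_family, table)
  if (!is.null(config$multiplier_overrides)) {
    for (a in names(config$multiplier_overrides)) {
      mult[[a]] <- config$multiplier_overrides[[a]]
    }
  }

  daily <- data.frame(
    date = as.Date(days - 1, origin = "2023-01-01"), day_of_year = days,
    phase = character(n), s = numeric(n),
    flight_h = numeric(n), forage_h = numeric(n), on_water_h = numeric(n),
    on_land_h = numeric(n), sst_c = numeric(n), air_c = numeric(n),
    bmr_kj_h = profile$bmr_kj_per_h, activity_cost_kj = numeric(n),
    thermo_cost_kj = numeric(n), dee_kj = numeric(n)
  )
  for (i in seq_len(n)) {
    jit <- if (config$jitter_sd_h > 0) jitter_mat[i, ] else NULL
    b <- build_daily_budget(days[i], config, jitter = jit)
    s <- b$s
    sst <- (1 - s) * colony$sst_c[i] + s * (if (is.null(wintering)) colony$sst_c[i] else wintering$sst_c[i])
    air <- (1 - s) * colony$air_c[i] + s * (if (is.null(wintering)) colony$air_c[i] else wintering$air_c[i])
    budget <- activity_budget(daily$date[i], b$hours[["flight"]], b$hours[["forage"]],
                              b$hours[["on_water"]], b$hours[["on_land"]], sst, air)
    de <- daily_energy_expenditure(budget, mult, profile, guild)
    daily$phase[i] <- b$phase
    daily$s[i] <- s
    daily[i, c("flight_h", "forage_h", "on_water_h", "on_land_h")] <- as.list(b$hours)
    daily$sst_c[i] <- sst
    daily$air_c[i] <- air
    daily$activity_cost_kj[i] <- sum(de$activity_cost_kj)
    daily$thermo_cost_kj[i] <- sum(de$thermo_cost_kj)
    daily$dee_kj[i] <- de$total_kj
  }
  daily$intake_kj <- required_intake(daily$dee_kj, config$assimilation_efficiency)
  pc <- prey_count(daily$intake_kj, config$prey_energy_kj)
  daily$prey_items_continuous <- pc$continuous
  daily$prey_items <- pc$items

  structure(
    list(scenario = config$scenario, seed = seed, config = config,
         config_hash = config_hash(config), daily = daily,
         summaries = summarise_simulation(daily)),
    class = "auk_simulation"
  )
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

summarise_simulation <- function(daily) {
  br <- daily$phase == "breeding"
  nb <- !br
  list(
    breeding_mean_dee_kj = mean(daily$dee_kj[br]),
    breeding_sd_dee_kj = stats::sd(daily$dee_kj[br]),
    nonbreeding_mean_dee_kj = mean(daily$dee_kj[nb]),
    nonbreeding_sd_dee_kj = stats::sd(daily$dee_kj[nb]),
    nonbreeding_total_kj = sum(daily$dee_kj[nb]),
    breeding_intake_mean_kj = mean(daily$intake_kj[br]),
    breeding_intake_sd_kj = stats::sd(daily$intake_kj[br]),
    breeding_prey_mean = mean(daily$prey_items_continuous[br]),
    breeding_prey_items = floor(mean(daily$prey_items_continuous[br]) + 0.5)
  )
}

#' @export
print.auk_simulation <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("Great auk simulation, scenario %s (seed %d)\n", x$scenario, x$seed))
  cat(sprintf("  breeding DEE: %.0f +/- %.0f kJ/day; intake %.0f +/- %.0f kJ/day (%.1f sand lance)\n",
              s$breeding_mean_dee_kj, s$breeding_sd_dee_kj,
              s$breeding_intake_mean_kj, s$breeding_intake_sd_kj,
              s$breeding_prey_mean))
  cat(sprintf("  non-breeding DEE: %.0f +/- %.0f kJ/day (total %.0f MJ)\n",
              s$nonbreeding_mean_dee_kj, s$nonbreeding_sd_dee_kj,
              s$nonbreeding_total_kj / 1000))
  invisible(x)
}

#' Percent energy difference between two simulated scenarios
#'
#' Compares summed daily energy expenditure over a window of the year:
#' `100 * (sum(y) - sum(x)) / sum(y)`, i.e. the percentage by which scenario
#' `x` undercuts scenario `y` (positive when `x` is cheaper). Both simulations
#' must cover the same calendar and share the breeding window.
#'
#' @param x,y `auk_simulation` objects.
#' @param window `"nonbreeding"` (default; includes migration travel days),
#'   `"breeding"` or `"year"`.
#' @return Percent difference (single number).
#' @export
#' @examples
#' a <- simulate_year("A", seed = 1)
#' b <- simulate_year("B", seed = 1)
#' compare_scenarios(a, b)   # ~ percent saved by wintering ashore at night
compare_scenarios <- function(x, y, window = c("nonbreeding", "breeding", "year")) {
  window <- match.arg(window)
  stopifnot(inherits(x, "auk_simulation"), inherits(y, "auk_simulation"))
  if (!identical(x$daily$date, y$daily$date)) {
    stop("simulations cover different calendars", call. = FALSE)
  }
  bx <- x$daily$phase == "breeding"
  if (!identical(bx, y$daily$phase == "breeding")) {
    stop("simulations have mismatched breeding windows", call. = FALSE)
  }
  keep <- switch(window,
    nonbreeding = !bx,
    breeding = bx,
    year = rep(TRUE, length(bx))
  )
  100 * (sum(y$daily$dee_kj[keep]) - sum(x$daily$dee_kj[keep])) /
    sum(y$daily$dee_kj[keep])
}
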