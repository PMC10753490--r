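#' Construct a validated one-day activity budget
#'
#' Hours per activity for one calendar day, plus the day's environmental
#' temperatures. Hours must be non-negative and sum to 24 within 1e-6 h;
#' with `renormalise = TRUE` a budget with a different positive total is
#' rescaled proportionally instead of rejected (useful for budgets classified
#' from biologging data), and a message records the adjustment.
#'
#' @param date A `Date` (or ISO 8601 string).
#' @param flight_h,forage_h,on_water_h,on_land_h Hours in each activity.
#' @param sst_c Sea-surface temperature, degC.
#' @param air_c Air temperature, degC.
#' @param renormalise Rescale hours to sum to 24 instead of erroring.
#' @return Object of class `activity_budget`: list with `date`, `hours`
#'   (named numeric over [activity_kinds()]), `sst_c`, `air_c`.
#' @export
#' @examples
#' activity_budget("2023-06-01", forage_h = 7, on_water_h = 5, on_land_h = 12,
#'                 sst_c = 7, air_c = 8)
activity_budget <- function(date, flight_h = 0, forage_h = 0, on_water_h = 0,
                            on_land_h = 0, sst_c, air_c, renormalise = FALSE) {
  date <- as.Date(date)
  if (is.na(date)) stop("invalid date", call. = FALSE)
  hours <- c(flight = flight_h, forage = forage_h,
             on_water = on_water_h, on_land = on_land_h)
  if (any(!is.finite(hours)) || any(hours < 0)) {
    stop("activity hours must be finite and >= 0", call. = FALSE)
  }
  total <- sum(hours)
  if (abs(total - 24) > 1e-6) {
    if (renormalise && total > 0) {
      message(sprintf("renormalising budget for %s: hours summed to %.4f h",
                      format(date), total))
      hours <- hours * (24 / total)
    } else {
      stop(sprintf("budget for %s sums to %.6f h, not 24 h", format(date), total),
           call. = FALSE)
    }
  }
  for (tv in c(sst_c, air_c)) {
    if (!is.finite(tv)) stop("temperatures must be finite", call. = FALSE)
    if (tv < -5 || tv > 45) {
      warning("temperature ", tv, " degC outside the plausible [-5, 45] range",
              call. = FALSE)
    }
  }
  structure(list(date = date, hours = hours, sst_c = sst_c, air_c = air_c),
            class = "activity_budget")
}

#' Daily energy expenditure from a time-activity budget
#'
#' The core accounting step: each activity's cost is its duration times BMR
#' times the activity-specific BMR multiplier, and, when the occupied medium is
#' colder than the bird's lower critical temperature, a thermoregulatory cost
#' is added on top (see [thermoregulation_cost()]). Daily energy expenditure
#' (DEE) is the sum of all components.
#'
#' @param budget An [activity_budget()].
#' @param multipliers Named numeric vector of BMR multipliers, as returned by
#'   [resolve_multipliers()]. Every activity with positive hours must have a
#'   multiplier; a missing one is an error, never a silent zero.
#' @param profile A [physiology_profile()].
#' @param guild One-row guild data frame ([guild_of()]); determines the
#'   thermal medium of each activity.
#' @return Object of class `daily_energy`: list with `date`,
#'   `activity_cost_kj` and `thermo_cost_kj` (named numeric per activity) and
#'   `total_kj`.
#' @export
#' @examples
#' tab <- load_multiplier_table()
#' b <- activity_budget("2023-06-01", forage_h = 7, on_water_h = 5,
#'                      on_land_h = 12, sst_c = 7, air_c = 8)
#' daily_energy_expenditure(b, resolve_multipliers("Spheniscidae", tab),
#'                          physiology_profile(5000), guild_of("Spheniscidae", tab))
daily_energy_expenditure <- function(budget, multipliers, profile, guild) {
  stopifnot(inherits(budget, "activity_budget"),
            inherits(profile, "physiology_profile"))
  acts <- names(budget$hours)
  activity_cost <- stats::setNames(numeric(length(acts)), acts)
  thermo_cost <- stats::setNames(numeric(length(acts)), acts)
  for (a in acts) {
    h <- budget$hours[[a]]
    if (h <= 0) next
    if (!a %in% names(multipliers)) {
      stop("no BMR multiplier available for performed activity '", a, "'",
           call. = FALSE)
    }
    activity_cost[a] <- h * profile$bmr_kj_per_h * multipliers[[a]]
    medium <- medium_for_activity(a, guild)
    if (medium != "none") {
      t_env <- temperature_for_medium(medium, budget$sst_c, budget$air_c)
      thermo_cost[a] <- thermoregulation_cost(
        tc = profile$tc[[medium]], mass_kg = profile$mass_kg,
        lct_c = profile$lct_c, t_env_c = t_env, hours = h)
    }
  }
  structure(
    list(date = budget$date,
         activity_cost_kj = activity_cost,
         thermo_cost_kj = thermo_cost,
         total_kj = sum(activity_cost) + sum(thermo_cost)),
    class = "daily_energy"
  )
}

#' @export
print.daily_energy <- function(x, ...) {
  cat(sprintf("Daily energy expenditure, %s: %.1f kJ\n",
              format(x$date), x$total_kj))
  cat(sprintf("  activity %.1f kJ + thermoregulation %.1f kJ\n",
              sum(x$activity_cost_kj), sum(x$thermo_cost_kj)))
  invisible(x)
}

#' Prey energy intake required to cover expenditure
#'
#' Divides daily energy expenditure by the assimilation efficiency (the
#' metabolisable fraction of ingested prey energy) to give the gross prey
#' energy that must be consumed per day to maintain body mass.
#'
#' @param dee_kj Daily energy expenditure, kJ (>= 0); vectorised.
#' @param assimilation_efficiency Fraction in (0, 1].
#' @return Required intake in kJ of prey per day.
#' @export
#' @examples
#' required_intake(4307.8, 0.744)
required_intake <- function(dee_kj, assimilation_efficiency) {
  if (any(!is.finite(dee_kj)) || any(dee_kj < 0)) {
    stop("dee_kj must be >= 0", call. = FALSE)
  }
  if (!is.finite(assimilation_efficiency) || assimilation_efficiency <= 0 ||
      assimilation_efficiency > 1) {
    stop("assimilation efficiency must lie in (0, 1]", call. = FALSE)
  }
  dee_kj / assimilation_efficiency
}

#' Prey items per day
#'
#' Converts a daily prey-energy requirement into a number of prey items of a
#' given energy content. The continuous value is always reported; the integer
#' count is round-half-up of it.
#'
#' @param intake_kj Required prey energy per day, kJ (> 0); vectorised.
#' @param prey_energy_kj Energy content of one prey item, kJ (> 0).
#' @return List with `continuous` (items per day) and `items`
#'   (round-half-up integer).
#' @export
#' @examples
#' prey_count(5790, 158)
prey_count <- function(intake_kj, prey_energy_kj) {
  if (any(!is.finite(intake_kj)) || any(intake_kj <= 0)) {
    stop("intake_kj must be > 0", call. = FALSE)
  }
  if (!is.finite(prey_energy_kj) || prey_energy_kj <= 0) {
    stop("prey_energy_kj must be > 0", call. = FALSE)
  }
  continuous <- intake_kj / prey_energy_kj
  list(continuous = continuous, items = floor(continuous + 0.5))
}

#' Daily energy expenditure over a multi-day budget table
#'
#' Applies [daily_energy_expenditure()] to every row of a budget data frame
#' (the schema read by [read_budget_csv()]) and appends intake and prey-count
#' columns.
#'
#' @param budgets Data frame with columns `date`, `flight_h`, `forage_h`,
#'   `on_water_h`, `on_land_h`, `sst_c`, `air_c`.
#' @param multipliers,profile,guild As for [daily_energy_expenditure()].
#' @param assimilation_efficiency,prey_energy_kj As for [required_intake()]
#'   and [prey_count()].
#' @param renormalise Passed to [activity_budget()].
#' @return Data frame with one row per day: `date`, `bmr_kj_h`,
#'   `activity_cost_kj`, `thermo_cost_kj`, `dee_kj`, `intake_kj`,
#'   `prey_items_continuous`, `prey_items`.
#' @export
dee_series <- function(budgets, multipliers, profile, guild,
                       assimilation_efficiency = 0.744, prey_energy_kj = 158,
                       renormalise = FALSE) {
  n <- nrow(budgets)
  out <- data.frame(
    date = as.Date(budgets$date),
    bmr_kj_h = rep(profile$bmr_kj_per_h, n),
    activity_cost_kj = numeric(n), thermo_cost_kj = numeric(n),
    dee_kj = numeric(n)
  )
  for (i in seq_len(n)) {
    b <- activity_budget(budgets$date[i], budgets$flight_h[i],
                         budgets$forage_h[i], budgets$on_water_h[i],
                         budgets$on_land_h[i], budgets$sst_c[i],
                         budgets$air_c[i], renormalise = renormalise)
    de <- daily_energy_expenditure(b, multipliers, profile, guild)
    out$activity_cost_kj[i] <- sum(de$activity_cost_kj)
    out$thermo_cost_kj[i] <- sum(de$thermo_cost_kj)
    out$dee_kj[i] <- de$total_kj
  }
  out$intake_kj <- required_intake(out$dee_kj, assimilation_efficiency)
  pc <- prey_count(out$intake_kj, prey_energy_kj)
  out$prey_items_continuous <- pc$continuous
  out$prey_items <- pc$items
  out
}
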