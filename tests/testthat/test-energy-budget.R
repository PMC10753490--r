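tab <- load_multiplier_table()
co <- load_allometric_coefficients()
profile <- physiology_profile(5000, co)
sphen_g <- guild_of("Spheniscidae", tab)
sphen_m <- resolve_multipliers("Spheniscidae", tab)

test_that("unit multipliers at thermoneutral temperatures give 24 x BMR exactly", {
  alc_g <- guild_of("Alcidae", tab)
  ones <- stats::setNames(rep(1, 4), activity_kinds())
  b <- activity_budget("2023-08-01", flight_h = 3, forage_h = 7, on_water_h = 8,
                       on_land_h = 6, sst_c = 20, air_c = 20)
  de <- daily_energy_expenditure(b, ones, profile, alc_g)
  expect_equal(de$total_kj, 24 * profile$bmr_kj_per_h)
  expect_equal(sum(de$thermo_cost_kj), 0)
})

test_that("daily energy matches the brute-force slice oracle on random budgets", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    hours <- random_simplex_budget(sphen_g)
    sst <- stats::runif(1, -2, 25)
    air <- stats::runif(1, -5, 30)
    b <- activity_budget("2023-03-01", hours[["flight"]], hours[["forage"]],
                         hours[["on_water"]], hours[["on_land"]], sst, air)
    de <- daily_energy_expenditure(b, sphen_m, profile, sphen_g)
    oracle <- slice_oracle_dee(hours, sst, air, sphen_m, profile, sphen_g)
    worst <- max(worst, abs(de$total_kj - oracle) / oracle)
  }
  expect_lt(worst, 1e-9)
})

test_that("components decompose: total = activity + thermo, all non-negative", {
  b <- activity_budget("2023-01-15", forage_h = 6, on_water_h = 10, on_land_h = 8,
                       sst_c = 3, air_c = -2)
  de <- daily_energy_expenditure(b, sphen_m, profile, sphen_g)
  expect_identical(de$total_kj, sum(de$activity_cost_kj) + sum(de$thermo_cost_kj))
  expect_true(all(de$activity_cost_kj >= 0) && all(de$thermo_cost_kj >= 0))
})

test_that("doubling multipliers doubles activity cost, leaves thermo unchanged", {
  b <- activity_budget("2023-01-15", forage_h = 6, on_water_h = 10, on_land_h = 8,
                       sst_c = 3, air_c = -2)
  de1 <- daily_energy_expenditure(b, sphen_m, profile, sphen_g)
  de2 <- daily_energy_expenditure(b, sphen_m * 2, profile, sphen_g)
  expect_equal(sum(de2$activity_cost_kj), 2 * sum(de1$activity_cost_kj))
  expect_equal(de2$thermo_cost_kj, de1$thermo_cost_kj)
})

test_that("DEE never decreases as a temperature drops", {
  make <- function(sst, air) {
    b <- activity_budget("2023-01-15", forage_h = 6, on_water_h = 10,
                         on_land_h = 8, sst_c = sst, air_c = air)
    daily_energy_expenditure(b, sphen_m, profile, sphen_g)$total_kj
  }
  for (sst in seq(12, -2, by = -2)) {
    expect_gte(make(sst, 5), make(sst + 2, 5))
    expect_gte(make(5, sst), make(5, sst + 2))
  }
})

test_that("a performed activity without a multiplier errors by name", {
  b <- activity_budget("2023-08-01", flight_h = 2, forage_h = 6, on_water_h = 8,
                       on_land_h = 8, sst_c = 15, air_c = 15)
  expect_error(daily_energy_expenditure(b, sphen_m, profile, sphen_g),
               "'flight'")
})

test_that("budget validation enforces the 24 h invariant, renormalise rescales", {
  expect_error(activity_budget("2023-01-01", forage_h = 10, on_water_h = 10,
                               sst_c = 5, air_c = 5), "not 24")
  expect_message(
    b <- activity_budget("2023-01-01", forage_h = 10, on_water_h = 10,
                         sst_c = 5, air_c = 5, renormalise = TRUE),
    "renormalising")
  expect_equal(sum(b$hours), 24)
  expect_equal(b$hours[["forage"]], 12)
  expect_warning(activity_budget("2023-01-01", forage_h = 24, sst_c = 50,
                                 air_c = 5), "plausible")
})

test_that("required intake divides by assimilation efficiency", {
  expect_equal(required_intake(4307.8, 0.744), 5790.05376344, tolerance = 1e-10)
  expect_identical(required_intake(1234, 1), 1234)
  for (dee in c(10, 4000)) expect_gte(required_intake(dee, 0.744), dee)
  expect_error(required_intake(100, 0), "efficiency")
  expect_error(required_intake(100, 1.2), "efficiency")
  expect_error(required_intake(-1, 0.744))
})

test_that("prey counts report continuous and round-half-up values", {
  pc <- prey_count(5790, 158)
  expect_equal(pc$continuous, 36.6455696203, tolerance = 1e-10)
  expect_identical(pc$items, 37)
  expect_identical(prey_count(158, 158)$items, 1)
  expect_lt(prey_count(100, 158)$continuous, 1)
  expect_identical(prey_count(237, 158)$items, 2)  # exact half rounds up
  expect_error(prey_count(100, 0), "prey_energy")
})

test_that("dee_series reproduces per-day calls and appends intake columns", {
  budgets <- generate_fixture_budgets(5, sphen_g, seed = 7)
  res <- dee_series(budgets, sphen_m, profile, sphen_g,
                    assimilation_efficiency = 0.744, prey_energy_kj = 158)
  expect_equal(nrow(res), 5)
  b1 <- activity_budget(budgets$date[1], budgets$flight_h[1], budgets$forage_h[1],
                        budgets$on_water_h[1], budgets$on_land_h[1],
                        budgets$sst_c[1], budgets$air_c[1])
  de1 <- daily_energy_expenditure(b1, sphen_m, profile, sphen_g)
  expect_equal(res$dee_kj[1], de1$total_kj)
  expect_equal(res$intake_kj, res$dee_kj / 0.744)
})
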