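test_that("day length behaves at the equator, the Arctic circle, and vs an oracle", {
  expect_true(all(abs(day_length(0, 1:365) - 12) < 0.6))
  expect_gt(day_length(66.5, 172), 23.4)      # polar day at the circle
  expect_lt(day_length(80, 355), 0.1)         # polar night
  # independent NOAA-style astronomical oracle, checked once at 52N equinox
  expect_equal(day_length(52, 79), noaa_day_length(52, 79), tolerance = 0.2)
  # symmetry about the solstices
  expect_equal(day_length(52, 172 - 20), day_length(52, 172 + 20), tolerance = 0.1)
})

test_that("day length rejects out-of-range inputs", {
  expect_error(day_length(91, 100), "latitude")
  expect_error(day_length(50, 0), "day_of_year")
})

climate <- list(sst_mean_c = 6.5, sst_amplitude_c = 3.5, sst_phase_day = 233,
                air_mean_c = 4.5, air_amplitude_c = 6, air_phase_day = 212,
                noise_sd_c = 0.4)

test_that("synthetic temperatures: degenerate sinusoid, determinism, calibration", {
  flat <- list(sst_mean_c = 8, sst_amplitude_c = 0, sst_phase_day = 1,
               air_mean_c = 5, air_amplitude_c = 0, air_phase_day = 1,
               noise_sd_c = 0)
  s <- synth_temperature(flat, 1:365)
  expect_true(all(s$sst_c == 8) && all(s$air_c == 5))

  set.seed(11); a <- synth_temperature(climate, 1:365)
  set.seed(11); b <- synth_temperature(climate, 1:365)
  expect_identical(a, b)

  # annual mean of replicate years is unbiased for the configured mean
  set.seed(3)
  means <- replicate(1000, mean(synth_temperature(climate, 1:365)$sst_c))
  se <- climate$noise_sd_c / sqrt(365)
  expect_lt(abs(mean(means) - climate$sst_mean_c), 3 * se / sqrt(1000) + 3 * se)
})

test_that("shipped scenario configs load and disagree only where designed", {
  ca <- load_scenario_config("A")
  cb <- load_scenario_config("B")
  cc <- load_scenario_config("C")
  expect_identical(ca$night_rule, "on_land")
  expect_identical(cb$night_rule, "on_water")
  expect_identical(cc$night_rule, "on_water")
  expect_identical(ca$breeding_window, cb$breeding_window)
  expect_identical(ca$breeding_budget, cc$breeding_budget)
  expect_null(ca$migration)
  expect_false(is.null(cc$migration))
})

test_that("scenario budgets respect the night rules and always sum to 24 h", {
  ca <- load_scenario_config("A")
  cb <- load_scenario_config("B")
  midwinter <- 15
  a <- build_daily_budget(midwinter, ca)
  b <- build_daily_budget(midwinter, cb)
  expect_gte(a$hours[["on_land"]], 24 - a$daylight_h - 1e-9)
  expect_identical(b$hours[["on_land"]], 0)
  for (d in c(1, 60, 121, 150, 181, 200, 300, 365)) {
    for (cfg in list(ca, cb, load_scenario_config("C"))) {
      h <- build_daily_budget(d, cfg)$hours
      expect_equal(sum(h), 24, tolerance = 1e-9)
      expect_true(all(h >= 0))
      expect_identical(h[["flight"]], 0)   # the great auk cannot fly
    }
  }
})

test_that("scenario C occupies the wintering ground in midwinter and travels in between", {
  cc <- load_scenario_config("C")
  expect_identical(build_daily_budget(20, cc)$phase, "nonbreeding")
  expect_identical(build_daily_budget(20, cc)$s, 1)      # at Morocco in January
  mid_out <- cc$migration$depart_day + 10
  tr <- build_daily_budget(mid_out, cc)
  expect_identical(tr$phase, "travel")
  expect_true(tr$s > 0 && tr$s < 1)
  expect_identical(build_daily_budget(cc$migration$return_day + 5, cc)$s, 0)
})

test_that("same seed gives bit-identical simulations; seed is recorded", {
  s1 <- simulate_year("A", seed = 9)
  s2 <- simulate_year("A", seed = 9)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$summaries, s2$summaries)
  expect_identical(s1$seed, 9L)
  expect_identical(s1$config_hash, s2$config_hash)
})

test_that("breeding-window days are identical across scenarios by construction", {
  a <- simulate_year("A", seed = 4)
  b <- simulate_year("B", seed = 4)
  cc <- simulate_year("C", seed = 4)
  br <- a$daily$phase == "breeding"
  expect_identical(a$daily[br, ], b$daily[br, ])
  expect_identical(a$daily[br, ], cc$daily[br, ])
  expect_equal(sum(br), 61)
})

test_that("summaries are recomputable from the daily records", {
  s <- simulate_year("B", seed = 2)
  br <- s$daily$phase == "breeding"
  expect_identical(s$summaries$breeding_mean_dee_kj, mean(s$daily$dee_kj[br]))
  expect_identical(s$summaries$nonbreeding_total_kj, sum(s$daily$dee_kj[!br]))
  expect_identical(s$summaries$breeding_intake_sd_kj, sd(s$daily$intake_kj[br]))
})

test_that("a colder colony climate never decreases annual energy expenditure", {
  cfg <- load_scenario_config("B")
  base <- simulate_year(cfg, seed = 5)
  cfg_cold <- cfg
  cfg_cold$locations$colony$sst_mean_c <- cfg$locations$colony$sst_mean_c - 3
  cold <- simulate_year(cfg_cold, seed = 5)
  expect_gte(sum(cold$daily$dee_kj), sum(base$daily$dee_kj))
  expect_true(all(cold$daily$dee_kj - base$daily$dee_kj > -1e-9))
})

test_that("thermoneutral unit-multiplier configuration collapses to 24 x BMR", {
  cfg <- load_scenario_config("B")
  cfg$locations$colony$sst_mean_c <- 30
  cfg$locations$colony$air_mean_c <- 30
  cfg$locations$colony$sst_amplitude_c <- 0
  cfg$locations$colony$air_amplitude_c <- 0
  cfg$locations$colony$noise_sd_c <- 0
  cfg$multiplier_overrides <- list(forage = 1, on_water = 1, on_land = 1)
  sim <- simulate_year(cfg, seed = 1)
  expect_equal(sim$daily$thermo_cost_kj, rep(0, 365))
  expect_equal(sim$daily$dee_kj, rep(24 * sim$daily$bmr_kj_h[1], 365),
               tolerance = 1e-12)
})

test_that("scenario comparison is zero on self, scale-invariant, and windowed", {
  a <- simulate_year("A", seed = 6)
  b <- simulate_year("B", seed = 6)
  expect_identical(compare_scenarios(a, a), 0)
  pct <- compare_scenarios(a, b, "nonbreeding")
  a2 <- a; b2 <- b
  a2$daily$dee_kj <- a$daily$dee_kj * 2
  b2$daily$dee_kj <- b$daily$dee_kj * 2
  expect_equal(compare_scenarios(a2, b2, "nonbreeding"), pct)
  expect_equal(compare_scenarios(a, b, "breeding"), 0, tolerance = 1e-12)
})

test_that("migratory wintering is thermally cheaper than Arctic residency", {
  b <- simulate_year("B", seed = 8)
  cc <- simulate_year("C", seed = 8)
  nb_b <- b$daily$phase != "breeding"
  nb_c <- cc$daily$phase != "breeding"
  expect_lt(sum(cc$daily$thermo_cost_kj[nb_c]), sum(b$daily$thermo_cost_kj[nb_b]))
})
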