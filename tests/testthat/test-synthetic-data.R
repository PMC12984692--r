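test_that("generator config validates its invariants", {
  expect_error(generator_config(n_records = 12), "n_records")
  expect_error(generator_config(n_cows = 0), "n_cows")
  expect_error(generator_config(snr = 0), "snr")
  expect_error(generator_config(mean_mass = -5), "mean_mass")
  expect_s3_class(generator_config(), "generator_config")
})

test_that("identical config and seed give identical studies", {
  cfg <- generator_config(n_records = 48, seed = 11)
  a <- gen_study(cfg)
  b <- gen_study(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$scans, b$scans)
  expect_identical(a$truth, b$truth)
  c <- gen_study(generator_config(n_records = 48, seed = 12))
  expect_false(identical(a$records, c$records))
})

test_that("default configuration emits exactly 718 hourly records", {
  st <- gen_study(generator_config(seed = 1))
  expect_equal(nrow(st$records), 718)
  expect_equal(nrow(st$truth), 718)
  expect_equal(nrow(st$scans), 4 * 718)
  # two maintenance hours are missing from a 30-day month
  span_hours <- as.numeric(diff(range(st$records$timestamp)), units = "hours")
  expect_equal(span_hours, 719)
})

test_that("noiseless climate is an exact sinusoid with the configured range", {
  cfg <- generator_config(n_records = 48, seed = 3, noise_amplitude = 0,
                          diurnal_amplitude = 6)
  cl <- gen_climate(cfg)
  expect_equal(max(cl$T_out) - min(cl$T_out), 6)
  expect_equal(max(cl$T_in) - min(cl$T_in), 6)
  expect_equal(cl$T_in, cl$T_out + cfg$indoor_temp_offset)
  # daily minimum near 05:00, maximum near 14:00
  day1 <- cl[cl$day == 1, ]
  expect_equal(day1$hour[which.min(day1$T_out)], 5)
  expect_equal(day1$hour[which.max(day1$T_out)], 14)
})

test_that("climate respects physical ranges and the configured mean", {
  cl <- gen_climate(generator_config(seed = 42))
  expect_true(all(cl$RH_in >= 0 & cl$RH_in <= 100))
  expect_true(all(cl$RH_out >= 0 & cl$RH_out <= 100))
  expect_true(all(cl$WD_in >= 0 & cl$WD_in < 360))
  expect_true(all(cl$WD_out >= 0 & cl$WD_out < 360))
  expect_true(all(cl$WS_in >= 0) && all(cl$WS_out >= 0))
  expect_gt(mean(cl$T_in - cl$T_out), 2)  # positive occupancy offset
  # monthly mean within 3 C of the configured November mean
  expect_lt(abs(mean(cl$T_out) - 14), 3)
})

test_that("scans partition the herd and peak after feeding", {
  cfg <- generator_config(n_records = 24, seed = 5)
  sc <- gen_activity_scans(cfg)
  expect_equal(nrow(sc), 96)
  expect_true(all(sc$n_lying + sc$n_standing + sc$n_walking + sc$n_feeding ==
                    cfg$n_cows))
  # feeding counts after noon delivery exceed small-hours feeding
  st <- gen_study(generator_config(n_records = 718, seed = 5))
  hb <- hourly_behaviour(st$scans)
  hod <- as.integer(format(hb$timestamp, "%H"))
  feed_like <- 1 - hb$CLI  # activity proxy
  sc2 <- st$scans
  hod2 <- as.integer(format(sc2$timestamp, "%H"))
  mean_feed_post <- mean(sc2$n_feeding[hod2 %in% 12:14])
  mean_feed_night <- mean(sc2$n_feeding[hod2 %in% 0:4])
  expect_gt(mean_feed_post, mean_feed_night)
  # lying peaks at night
  mean_lie_night <- mean(sc2$n_lying[hod2 %in% 0:4])
  mean_lie_day <- mean(sc2$n_lying[hod2 %in% 12:16])
  expect_gt(mean_lie_night, mean_lie_day)
})

test_that("diet schedule reproduces the published step table", {
  cfg <- generator_config(seed = 1)
  diet <- gen_diet_schedule(cfg)
  expect_equal(nrow(diet), 30)
  d1 <- diet[diet$day == 1, ]
  expect_equal(d1$alfalfa_hay, 4.00)
  expect_equal(d1$citrus_pulp, 21.00)
  expect_equal(d1$flaked_maize_soybean, 4.10)
  # day-1 total ration mass, summed independently from the printed row
  expect_equal(sum(d1[setdiff(names(d1), "day")]),
               4.00 + 3.25 + 3.00 + 1.00 + 0.02 + 10.00 + 21.00 + 0.20 +
                 0.05 + 4.10 + 1.50 + 0.10 + 0.20)
  d18 <- diet[diet$day == 18, ]
  expect_equal(d18$alfalfa_hay, 3.50)
  expect_equal(d18$citrus_pulp, 27.00)
  # days between steps carry the previous ration forward
  expect_equal(diet[diet$day == 15, ]$citrus_pulp, 23.00)
  expect_equal(length(diet_ingredients()), 13)
})

test_that("concentrations respect detection floors and snr calibration", {
  st <- gen_study(generator_config(seed = 42))
  rec <- st$records
  expect_true(all(rec$nh3_in >= 0.2) && all(rec$nh3_out >= 0.2))
  expect_true(all(rec$ch4_in >= 0.4) && all(rec$ch4_out >= 0.4))
  expect_true(all(rec$co2_in >= 1.5) && all(rec$co2_out >= 1.5))
  expect_true(all(st$truth$Q_true > 0))
  # amplitude snr: signal variance over noise variance ~ snr^2, +-20%
  for (gas in c("nh3", "ch4", "co2")) {
    sig <- st$truth[[paste0(gas, "_in_true")]]
    noise <- rec[[paste0(gas, "_in")]] - sig
    ratio <- var(sig) / var(noise)
    expect_gt(ratio, 9 * 0.8)
    expect_lt(ratio, 9 * 1.25)
  }
})

test_that("doubling the herd doubles the noiseless CO2 excess", {
  base <- generator_config(n_records = 48, seed = 9, snr = Inf,
                           noise_amplitude = 0)
  double <- generator_config(n_records = 48, seed = 9, snr = Inf,
                             noise_amplitude = 0, n_cows = 112)
  a <- gen_study(base)$records
  b <- gen_study(double)$records
  # compare in mass-concentration space (same temperatures, same Q_true)
  ex_a <- ppm_to_gm3(a$co2_in, "CO2", a$T_in) - ppm_to_gm3(a$co2_out, "CO2", a$T_out)
  ex_b <- ppm_to_gm3(b$co2_in, "CO2", b$T_in) - ppm_to_gm3(b$co2_out, "CO2", b$T_out)
  expect_equal(ex_b, 2 * ex_a, tolerance = 1e-9)
})

test_that("gen_concentrations rejects misaligned inputs", {
  cfg <- generator_config(n_records = 48, seed = 2)
  cl <- gen_climate(cfg)
  sc <- gen_activity_scans(cfg)
  diet <- gen_diet_schedule(cfg)
  expect_error(gen_concentrations(cfg, cl[1:10, ], sc, diet), "misaligned")
})

test_that("a study round-trips through delimited text", {
  st <- gen_study(generator_config(n_records = 48, seed = 13))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("hourly_records.csv", "scans.csv", "truth.csv", "config.json")))))
  back <- read_study(dir)
  expect_equal(back$records$timestamp, st$records$timestamp)
  num <- vapply(st$records, is.numeric, logical(1))
  for (v in names(st$records)[num]) {
    expect_equal(back$records[[v]], st$records[[v]], tolerance = 1e-12)
  }
  expect_equal(back$truth$Q_true, st$truth$Q_true, tolerance = 1e-12)
  expect_equal(back$config$seed, st$config$seed)

  # identical seeds write byte-identical files
  dir2 <- withr::local_tempdir()
  write_study(gen_study(generator_config(n_records = 48, seed = 13)), dir2)
  expect_identical(
    readLines(file.path(dir, "hourly_records.csv")),
    readLines(file.path(dir2, "hourly_records.csv"))
  )
})
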