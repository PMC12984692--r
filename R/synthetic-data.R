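# Seeded synthetic barn-campaign generator.
#
# Emulates one month of hourly records from a naturally ventilated
# Mediterranean dairy barn in November: diurnal climate with AR(1) noise,
# 15-minute behavioural scans, the published step-wise diet schedule, and
# indoor gas concentrations constructed so that the CO2 mass-balance
# estimator is exactly invertible on noiseless data. Ground-truth latent
# values (true ventilation rate, true emission rates, noiseless
# concentrations) are emitted alongside, so every downstream stage can be
# tested against a known answer.

#' Synthetic study generator configuration
#'
#' All knobs of the synthetic barn campaign. Defaults describe the
#' emulated conditions: a 30-day November campaign (720 hours minus two
#' maintenance hours = 718 hourly records), 56 Friesian cows, daily
#' cleaning at 07:00, feed delivery at noon, milking at 06:00 and 18:00,
#' and a 3:1 signal-to-noise ratio on gas concentrations.
#'
#' @param n_records number of retained hourly rows (default 718).
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param n_cows herd size N (default 56).
#' @param mean_mass average animal mass (kg, default 620).
#' @param days_insemination days after insemination (default 120).
#' @param milk_yield milk yield (kg per day, default 28).
#' @param snr signal-to-noise ratio of the concentration targets: the
#'   variance of the noiseless indoor concentration signal divided by the
#'   added noise variance. `Inf` disables concentration noise.
#' @param cleaning_hour hour of day of manure scraping (default 7).
#' @param feeding_hour hour of day of feed delivery (default 12, noon).
#' @param milking_hours two milking hours (default `c(6, 18)`).
#' @param outdoor_co2_baseline outdoor CO2 concentration (g m^-3,
#'   default 0.78, about 430 ppm at 15 C).
#' @param mean_temp_out monthly mean outdoor temperature (C, default 14,
#'   November on the southern Mediterranean coast).
#' @param diurnal_amplitude peak-to-trough daily outdoor temperature
#'   range (C, default 6).
#' @param indoor_temp_offset mean indoor-minus-outdoor temperature
#'   difference from animal heat (C, default 3).
#' @param noise_amplitude multiplier on all AR(1) climate noise standard
#'   deviations; 0 gives exactly sinusoidal climate.
#' @param drop_hours indices (1-based hour slots from the campaign start)
#'   removed as instrument-maintenance gaps; defaults to two hours in
#'   mid-month so that 30 days yield 718 records.
#' @param start_time campaign start (POSIXct or string, UTC; default
#'   2021-11-01 00:00).
#' @param vent_base,vent_wind phenomenological ventilation model
#'   `Q_true = vent_base + vent_wind * WS_out` (m^3 h^-1 and
#'   m^3 h^-1 per m s^-1).
#' @return an object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_records = 48, seed = 1)
#' @export
generator_config <- function(n_records = 718,
                             seed = 42,
                             n_cows = 56,
                             mean_mass = 620,
                             days_insemination = 120,
                             milk_yield = 28,
                             snr = 3.0,
                             cleaning_hour = 7,
                             feeding_hour = 12,
                             milking_hours = c(6, 18),
                             outdoor_co2_baseline = 0.78,
                             mean_temp_out = 14,
                             diurnal_amplitude = 6,
                             indoor_temp_offset = 3,
                             noise_amplitude = 1,
                             drop_hours = c(360, 361),
                             start_time = "2021-11-01 00:00:00",
                             vent_base = 15000,
                             vent_wind = 9000) {
  cfg <- list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    n_cows = as.integer(n_cows), mean_mass = mean_mass,
    days_insemination = days_insemination, milk_yield = milk_yield,
    snr = snr, cleaning_hour = cleaning_hour, feeding_hour = feeding_hour,
    milking_hours = milking_hours,
    outdoor_co2_baseline = outdoor_co2_baseline,
    mean_temp_out = mean_temp_out, diurnal_amplitude = diurnal_amplitude,
    indoor_temp_offset = indoor_temp_offset,
    noise_amplitude = noise_amplitude,
    drop_hours = as.integer(drop_hours),
    start_time = as.POSIXct(start_time, tz = "UTC"),
    vent_base = vent_base, vent_wind = vent_wind
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_records >= 24,
    cfg$n_cows >= 1,
    cfg$mean_mass > 0,
    cfg$milk_yield >= 0,
    cfg$days_insemination >= 0,
    cfg$snr > 0,
    cfg$noise_amplitude >= 0,
    cfg$diurnal_amplitude >= 0,
    cfg$vent_base > 0, cfg$vent_wind >= 0,
    cfg$cleaning_hour %in% 0:23, cfg$feeding_hour %in% 0:23,
    length(cfg$milking_hours) == 2L,
    cfg$outdoor_co2_baseline > 0,
    !is.na(cfg$start_time)
  )
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d hourly records, %d cows, seed %d, snr %s\n",
    x$n_records, x$n_cows, x$seed, format(x$snr)
  ))
  invisible(x)
}

# Hour slots retained after removing maintenance gaps: candidate slots
# 1:(n + n_drops) minus the drop positions, first n of what remains.
retained_slots <- function(cfg) {
  cand <- seq_len(cfg$n_records + length(cfg$drop_hours))
  keep <- setdiff(cand, cfg$drop_hours)
  keep[seq_len(cfg$n_records)]
}

herd_from_config <- function(cfg) {
  herd_state(cfg$n_cows, cfg$mean_mass, cfg$days_insemination, cfg$milk_yield)
}

#' Generate the synthetic climate series
#'
#' Hourly indoor and outdoor temperature, relative humidity, wind speed
#' and wind direction. Temperatures follow a diurnal cycle with minimum
#' near 05:00 and maximum near 14:00 plus AR(1) noise; indoor temperature
#' is outdoor plus a positive occupancy offset; humidity is inversely
#' coupled to temperature and clipped to `[0, 100]`; wind speed is
#' non-negative and wind direction wraps to `[0, 360)`.
#'
#' @param config a [generator_config()].
#' @return data frame with one row per retained hour: `slot`,
#'   `timestamp`, `day`, `hour`, `T_out`, `T_in`, `RH_out`, `RH_in`,
#'   `WS_out`, `WS_in`, `WD_out`, `WD_in`.
#' @export
gen_climate <- function(config) {
  validate_generator_config(config)
  slots <- retained_slots(config)
  n_all <- max(slots)
  hour_abs <- seq_len(n_all) - 1L
  hod <- hour_abs %% 24
  shape <- diurnal_shape(hod)
  amp <- config$diurnal_amplitude / 2
  na <- config$noise_amplitude

  cl <- with_seed(config$seed + 1L, {
    t_out <- config$mean_temp_out + amp * shape + ar1_noise(n_all, 0.6 * na)
    t_in <- t_out + config$indoor_temp_offset + ar1_noise(n_all, 0.3 * na)
    rh_out <- pmin(100, pmax(0,
      75 - 2.5 * (t_out - config$mean_temp_out) + ar1_noise(n_all, 3 * na)))
    rh_in <- pmin(100, pmax(0, rh_out + 5 + ar1_noise(n_all, 2 * na)))
    ws_out <- pmax(0, 2 + 0.8 * shape + ar1_noise(n_all, 0.4 * na))
    ws_in <- pmax(0, 0.3 * ws_out + ar1_noise(n_all, 0.1 * na))
    wd_out <- (310 + ar1_noise(n_all, 15 * na)) %% 360
    wd_in <- (wd_out + ar1_noise(n_all, 10 * na)) %% 360
    data.frame(slot = seq_len(n_all), hour = hod,
               T_out = t_out, T_in = t_in, RH_out = rh_out, RH_in = rh_in,
               WS_out = ws_out, WS_in = ws_in, WD_out = wd_out, WD_in = wd_in)
  })
  cl <- cl[slots, , drop = FALSE]
  rownames(cl) <- NULL
  cl$timestamp <- config$start_time + (cl$slot - 1L) * 3600
  cl$day <- (cl$slot - 1L) %/% 24 + 1L
  cl[c("slot", "timestamp", "day", "hour",
       "T_out", "T_in", "RH_out", "RH_in",
       "WS_out", "WS_in", "WD_out", "WD_in")]
}

#' Generate 15-minute behavioural scan observations
#'
#' Four scans per retained hour. At each scan the herd is partitioned
#' multinomially into lying / standing / walking / feeding, with
#' time-varying probabilities: lying peaks at night, feeding peaks in the
#' hours after feed delivery.
#'
#' @param config a [generator_config()].
#' @return data frame with one row per scan: `timestamp`, `slot`,
#'   `n_lying`, `n_standing`, `n_walking`, `n_feeding`, `n_total`.
#' @export
gen_activity_scans <- function(config) {
  validate_generator_config(config)
  slots <- retained_slots(config)
  hod <- (slots - 1L) %% 24
  scan_offsets <- c(0, 15, 30, 45) * 60
  hour_frac <- rep(hod, each = 4L) + rep(c(0, 0.25, 0.5, 0.75), times = length(slots))
  ts <- rep(config$start_time + (slots - 1L) * 3600, each = 4L) +
    rep(scan_offsets, times = length(slots))

  # Time-varying behaviour probabilities.
  night <- (cos(2 * pi * (hour_frac - 2) / 24) + 1) / 2   # peaks ~02:00
  dt_feed <- (hour_frac - config$feeding_hour) %% 24
  feed_kernel <- exp(-dt_feed / 2)                        # decays after delivery
  p_lying <- 0.30 + 0.45 * night
  p_feeding <- 0.06 + 0.40 * feed_kernel
  p_walking <- rep(0.05, length(hour_frac))
  tot <- p_lying + p_feeding + p_walking
  scl <- pmin(1, 0.95 / tot)  # leave room for standing
  p_lying <- p_lying * scl
  p_feeding <- p_feeding * scl
  p_walking <- p_walking * scl
  p_standing <- 1 - p_lying - p_feeding - p_walking

  counts <- with_seed(config$seed + 2L, {
    t(vapply(seq_along(hour_frac), function(i) {
      stats::rmultinom(1, config$n_cows,
                       c(p_lying[i], p_standing[i], p_walking[i], p_feeding[i]))[, 1]
    }, numeric(4)))
  })
  data.frame(timestamp = ts, slot = rep(slots, each = 4L),
             n_lying = counts[, 1], n_standing = counts[, 2],
             n_walking = counts[, 3], n_feeding = counts[, 4],
             n_total = as.integer(rowSums(counts)))
}

#' Daily diet schedule
#'
#' Per-day masses (kg) of the 13 ration ingredients. By default this
#' reproduces the published step schedule of the emulated campaign
#' (changes on days 1, 11, 18, 20, 22, 26 and 30), read from the packaged
#' `diet_schedule.csv` fixture; every hour of a day carries that day's
#' ration.
#'
#' @param config a [generator_config()].
#' @param schedule optional replacement schedule: a data frame with a
#'   `day` column (first day each ration applies) and one column per
#'   ingredient.
#' @return data frame with one row per campaign day (`day` plus the 13
#'   ingredient columns).
#' @export
gen_diet_schedule <- function(config, schedule = NULL) {
  validate_generator_config(config)
  if (is.null(schedule)) schedule <- read_diet_fixture()
  stopifnot("day" %in% names(schedule))
  n_days <- max((max(retained_slots(config)) - 1L) %/% 24 + 1L, max(schedule$day))
  idx <- findInterval(seq_len(n_days), schedule$day)
  idx[idx == 0L] <- 1L
  out <- schedule[idx, , drop = FALSE]
  out$day <- seq_len(n_days)
  rownames(out) <- NULL
  out
}

read_diet_fixture <- function() {
  path <- system.file("extdata", "diet_schedule.csv", package = "barngas",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Ingredient columns of the diet schedule
#' @return character vector of the 13 ingredient column names.
#' @export
diet_ingredients <- function() {
  setdiff(names(read_diet_fixture()), "day")
}

#' Generate gas concentrations and latent truth
#'
#' Constructs indoor/outdoor CO2, NH3 and CH4 concentration series (ppm)
#' together with the latent truth that generated them. The construction
#' makes the CO2 mass-balance estimator exactly invertible at infinite
#' signal-to-noise ratio:
#' * `Q_true = vent_base + vent_wind * WS_out` (positive by config),
#' * `P_CO2` from the herd state via [co2_excretion_rate()] at `T_in`,
#' * indoor CO2 = outdoor CO2 + `P_CO2 * N / Q_true`,
#' * true NH3 emission increases smoothly with indoor temperature,
#'   activity index and hours since cleaning,
#' * true CH4 emission scales with total ration mass with a post-feeding
#'   peak,
#' * indoor gas = outdoor gas + `E_true / Q_true`, plus Gaussian noise
#'   whose variance is the noiseless indoor signal variance divided by
#'   `snr`, floored at the instrument detection limits (0.2 ppm NH3,
#'   0.4 ppm CH4, 1.5 ppm CO2).
#'
#' @param config a [generator_config()].
#' @param climate output of [gen_climate()].
#' @param scans output of [gen_activity_scans()].
#' @param diet output of [gen_diet_schedule()].
#' @return list with `concentrations` (per-hour ppm columns `co2_in`,
#'   `co2_out`, `nh3_in`, `nh3_out`, `ch4_in`, `ch4_out`), `truth`
#'   (per-hour `Q_true`, `P_CO2_true`, `E_nh3_true`, `E_ch4_true` and
#'   noiseless indoor ppm `co2_in_true`, `nh3_in_true`, `ch4_in_true`)
#'   and `behaviour` (hourly `CLI`, `CAI`).
#' @export
gen_concentrations <- function(config, climate, scans, diet) {
  validate_generator_config(config)
  n <- nrow(climate)
  if (nrow(scans) != 4L * n) {
    stop("climate and scans are misaligned: expected 4 scans per climate hour",
         call. = FALSE)
  }
  beh <- hourly_behaviour(scans)
  beh <- beh[match(climate$timestamp, beh$timestamp), ]
  if (nrow(beh) != n || anyNA(beh$CAI)) {
    stop("climate and scans are misaligned: every climate hour needs scans",
         call. = FALSE)
  }
  diet_total <- diet_total_for(diet, climate$day)
  if (length(diet_total) != n) {
    stop("climate and diet are misaligned", call. = FALSE)
  }

  herd <- herd_from_config(config)
  q_true <- config$vent_base + config$vent_wind * climate$WS_out
  ex <- co2_excretion_rate(herd, climate$T_in)
  p_co2 <- ex$P_CO2

  hod <- climate$hour
  # Outdoor baselines: deterministic slow diurnal drift around fixed means.
  co2_out_gm3 <- config$outdoor_co2_baseline * (1 + 0.02 * sin(2 * pi * (hod - 4) / 24))
  nh3_out_ppm <- 0.30 + 0.05 * sin(2 * pi * (hod - 6) / 24)
  ch4_out_ppm <- 2.0 + 0.20 * sin(2 * pi * (hod - 6) / 24)
  nh3_out_gm3 <- ppm_to_gm3(nh3_out_ppm, "NH3", climate$T_out)
  ch4_out_gm3 <- ppm_to_gm3(ch4_out_ppm, "CH4", climate$T_out)

  # Latent emission functions (g h^-1), smooth in their drivers.
  # NH3 volatilisation: dominated by indoor temperature, with mild
  # smooth modulation by humidity, animal activity, manure accumulated
  # since the daily scraping, and protein (ration) intake.
  hsc <- (hod - config$cleaning_hour) %% 24
  e_nh3 <- 30 * (1 + 0.05 * (climate$T_in - 14)) *
    (1 + 0.002 * (climate$RH_in - 80)) *
    (0.8 + 0.4 * beh$CAI) *
    (0.85 + 0.3 * hsc / 24) *
    (0.9 + 0.1 * diet_total / 48)
  e_nh3 <- pmax(e_nh3, 1)
  dt_feed <- (hod - config$feeding_hour) %% 24
  feed_kernel <- exp(-dt_feed / 2.5)
  e_ch4 <- 14 * config$n_cows * (diet_total / 48) * (0.75 + 0.5 * feed_kernel)

  co2_in_gm3 <- co2_out_gm3 + p_co2 * config$n_cows / q_true
  nh3_in_gm3 <- nh3_out_gm3 + e_nh3 / q_true
  ch4_in_gm3 <- ch4_out_gm3 + e_ch4 / q_true

  co2_in_ppm <- gm3_to_ppm(co2_in_gm3, "CO2", climate$T_in)
  nh3_in_ppm <- gm3_to_ppm(nh3_in_gm3, "NH3", climate$T_in)
  ch4_in_ppm <- gm3_to_ppm(ch4_in_gm3, "CH4", climate$T_in)
  co2_out_ppm <- gm3_to_ppm(co2_out_gm3, "CO2", climate$T_out)

  # snr is an amplitude ratio: noise sd = signal sd / snr.
  noise_sd <- function(signal) {
    if (is.infinite(config$snr)) 0 else sd_pop(signal) / config$snr
  }
  noisy <- with_seed(config$seed + 3L, {
    list(
      co2_in = co2_in_ppm + stats::rnorm(n, 0, noise_sd(co2_in_ppm)),
      nh3_in = nh3_in_ppm + stats::rnorm(n, 0, noise_sd(nh3_in_ppm)),
      ch4_in = ch4_in_ppm + stats::rnorm(n, 0, noise_sd(ch4_in_ppm))
    )
  })

  conc <- data.frame(
    co2_in = pmax(noisy$co2_in, 1.5),
    co2_out = pmax(co2_out_ppm, 1.5),
    nh3_in = pmax(noisy$nh3_in, 0.2),
    nh3_out = pmax(nh3_out_ppm, 0.2),
    ch4_in = pmax(noisy$ch4_in, 0.4),
    ch4_out = pmax(ch4_out_ppm, 0.4)
  )
  truth <- data.frame(
    timestamp = climate$timestamp,
    Q_true = q_true,
    P_CO2_true = p_co2,
    E_nh3_true = e_nh3,
    E_ch4_true = e_ch4,
    co2_in_true = co2_in_ppm,
    nh3_in_true = nh3_in_ppm,
    ch4_in_true = ch4_in_ppm
  )
  list(concentrations = conc, truth = truth,
       behaviour = data.frame(CLI = beh$CLI, CAI = beh$CAI))
}

diet_total_for <- function(diet, day) {
  ing <- setdiff(names(diet), "day")
  totals <- rowSums(diet[ing])
  totals[match(pmin(day, max(diet$day)), diet$day)]
}

#' Generate a complete synthetic barn study
#'
#' Runs the full generator chain — climate, behavioural scans, diet,
#' concentrations — and assembles exactly `n_records` hourly records plus
#' index-aligned ground truth.
#'
#' @param config a [generator_config()].
#' @return an object of class `barn_study`: a list with `records` (hourly
#'   table: timestamp, climate, CLI/CAI, 13 diet columns, six ppm
#'   concentration columns), `scans` (15-minute scan table), `truth`
#'   (latent values per hour) and `config`.
#' @examples
#' study <- gen_study(generator_config(n_records = 48, seed = 7))
#' nrow(study$records)
#' @export
gen_study <- function(config = generator_config()) {
  validate_generator_config(config)
  climate <- gen_climate(config)
  scans <- gen_activity_scans(config)
  diet <- gen_diet_schedule(config)
  cc <- gen_concentrations(config, climate, scans, diet)

  diet_hourly <- diet[match(pmin(climate$day, max(diet$day)), diet$day),
                      setdiff(names(diet), "day"), drop = FALSE]
  rownames(diet_hourly) <- NULL
  records <- cbind(
    climate[c("timestamp", "day", "hour", "T_in", "T_out", "RH_in", "RH_out",
              "WS_in", "WS_out", "WD_in", "WD_out")],
    cc$behaviour,
    diet_hourly,
    cc$concentrations
  )
  structure(
    list(records = records, scans = scans, truth = cc$truth, config = config),
    class = "barn_study"
  )
}

#' @export
print.barn_study <- function(x, ...) {
  cat(sprintf(
    "<barn_study> %d hourly records (%s to %s), %d scans, %d cows, seed %d\n",
    nrow(x$records),
    format(min(x$records$timestamp)), format(max(x$records$timestamp)),
    nrow(x$scans), x$config$n_cows, x$config$seed
  ))
  invisible(x)
}

#' Write / read a synthetic study as delimited text
#'
#' `write_study()` writes three comma-separated files into `dir`:
#' `hourly_records.csv`, `scans.csv` and `truth.csv`, with ISO-8601
#' timestamps, plus the generator configuration as `config.json`.
#' `read_study()` reads them back; numeric columns round-trip to within
#' floating-point printing precision.
#'
#' @param study a `barn_study` from [gen_study()].
#' @param dir output directory (created if needed).
#' @return `write_study()` returns `dir` invisibly; `read_study()`
#'   returns a `barn_study` (with `config` restored from JSON).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "barn_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wr(study$records, "hourly_records.csv")
  wr(study$scans, "scans.csv")
  wr(study$truth, "truth.csv")
  cfg <- unclass(study$config)
  cfg$start_time <- format(cfg$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  rd <- function(file) {
    df <- utils::read.csv(file.path(dir, file), check.names = FALSE)
    df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
    df
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- generator_config(
    n_records = cfg$n_records, seed = cfg$seed, n_cows = cfg$n_cows,
    mean_mass = cfg$mean_mass, days_insemination = cfg$days_insemination,
    milk_yield = cfg$milk_yield, snr = as.numeric(cfg$snr),
    cleaning_hour = cfg$cleaning_hour, feeding_hour = cfg$feeding_hour,
    milking_hours = cfg$milking_hours,
    outdoor_co2_baseline = cfg$outdoor_co2_baseline,
    mean_temp_out = cfg$mean_temp_out,
    diurnal_amplitude = cfg$diurnal_amplitude,
    indoor_temp_offset = cfg$indoor_temp_offset,
    noise_amplitude = cfg$noise_amplitude, drop_hours = cfg$drop_hours,
    start_time = as.POSIXct(cfg$start_time, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC"),
    vent_base = cfg$vent_base, vent_wind = cfg$vent_wind
  )
  structure(
    list(records = rd("hourly_records.csv"), scans = rd("scans.csv"),
         truth = rd("truth.csv"), config = config),
    class = "barn_study"
  )
}
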